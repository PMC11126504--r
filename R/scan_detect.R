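#' Detect scanning bouts
#'
#' A scanning bout is an on-the-spot rotation during which the ant makes
#' successive stationary head-direction fixations pointing in different
#' directions. A bout is an interval in which (i) the thorax stays within
#' `on_spot_radius` of the interval's own centroid, (ii) the interval lasts at
#' least `min_bout_dur`, and (iii) it contains at least two fixations --
#' sub-intervals of duration >= `fixation_min_dur` whose (smoothed)
#' orientation changes slower than `fixation_max_rot_rate` -- whose mean
#' orientations differ by at least `min_fixation_separation`. Accepted bouts
#' separated by less than `merge_gap` are merged. Detection is fully
#' deterministic.
#'
#' The orientation series is boxcar-smoothed over `smooth_window` frames
#' before rotation rates are estimated, so that frame-to-frame digitization
#' noise of a few degrees does not masquerade as rotation; fixation mean
#' orientations are computed on the raw series.
#'
#' @param traj an [trajectory()] object.
#' @param on_spot_radius maximum thorax excursion from the bout centroid (cm).
#' @param min_bout_dur minimum bout duration (s).
#' @param fixation_min_dur minimum fixation duration (s).
#' @param fixation_max_rot_rate maximum rotation rate inside a fixation (deg/s).
#' @param min_fixation_separation minimum difference between mean orientations
#'   of successive distinct fixations (degrees).
#' @param min_bout_span minimum spread (degrees) between the extreme fixation
#'   mean orientations of a bout; separates true scanning (wide, deliberate
#'   rotations) from the narrow gaze oscillation ants show while walking
#'   slowly.
#' @param max_bout_speed maximum median translation speed (cm/s) of the
#'   thorax during a bout, measured on positions smoothed over
#'   `pos_smooth_window` frames: scanning happens on the spot, so sustained
#'   forward progress disqualifies an interval even when it curls inside
#'   `on_spot_radius`.
#' @param merge_gap bouts closer than this (s) are merged.
#' @param smooth_window odd boxcar window (frames) for rotation-rate
#'   estimation; 1 disables smoothing.
#' @param pos_smooth_window odd boxcar window (frames) for the translation
#'   speed used by `max_bout_speed`.
#' @return a data frame of bouts, one row each, with columns `start_t`,
#'   `end_t`, `x`, `y` (mean thorax position), `n_fixations`, `angular_span`
#'   (degrees, max - min unwrapped orientation in the bout). Zero rows when no
#'   bout is found (including trajectories shorter than `min_bout_dur`).
#'   Detector parameters are attached as attribute `params`.
#' @export
detect_scanning_bouts <- function(traj,
                                  on_spot_radius = 0.5,
                                  min_bout_dur = 0.5,
                                  fixation_min_dur = 0.08,
                                  fixation_max_rot_rate = 50,
                                  min_fixation_separation = 20,
                                  min_bout_span = 60,
                                  max_bout_speed = 0.5,
                                  merge_gap = 0.3,
                                  smooth_window = 5L,
                                  pos_smooth_window = 9L) {
  params <- list(on_spot_radius = on_spot_radius, min_bout_dur = min_bout_dur,
                 fixation_min_dur = fixation_min_dur,
                 fixation_max_rot_rate = fixation_max_rot_rate,
                 min_fixation_separation = min_fixation_separation,
                 min_bout_span = min_bout_span,
                 max_bout_speed = max_bout_speed,
                 merge_gap = merge_gap, smooth_window = smooth_window,
                 pos_smooth_window = pos_smooth_window)
  empty <- structure(
    data.frame(start_t = numeric(0), end_t = numeric(0), x = numeric(0),
               y = numeric(0), n_fixations = integer(0),
               angular_span = numeric(0)),
    params = params)
  n <- nrow(traj)
  fps <- frame_rate_of(traj)
  if ((n - 1L) / fps < min_bout_dur) return(empty)

  orient <- orientation_series(traj)
  sm <- boxcar(orient, as.integer(smooth_window))
  rate <- abs(diff(sm)) * fps          # deg/s between consecutive frames
  x <- traj$thorax_x; y <- traj$thorax_y
  xs <- boxcar(x, as.integer(pos_smooth_window))
  ys <- boxcar(y, as.integer(pos_smooth_window))
  vsm <- sqrt(diff(xs)^2 + diff(ys)^2) * fps   # jitter-robust speed, cm/s

  ## 1. stationary candidate intervals: greedy maximal runs in which every
  ##    thorax point stays within on_spot_radius of the running centroid
  intervals <- stationary_intervals(x, y, on_spot_radius)

  ## 2. keep intervals long enough and with >= 2 separated fixations
  min_bout_frames <- max(2L, ceiling(min_bout_dur * fps))
  bouts <- list()
  for (iv in intervals) {
    i <- iv[1L]; j <- iv[2L]
    if (j - i + 1L < min_bout_frames) next
    fx <- fixations_in(orient, rate, i, j, fps,
                       fixation_min_dur, fixation_max_rot_rate,
                       min_fixation_separation)
    if (length(fx) < 2L) next
    if (max(fx) - min(fx) < min_bout_span) next
    if (stats::median(vsm[i:(j - 1L)]) > max_bout_speed) next
    bouts[[length(bouts) + 1L]] <- c(i, j, length(fx))
  }
  if (!length(bouts)) return(empty)

  ## 3. merge bouts closer than merge_gap
  bouts <- do.call(rbind, bouts)
  merged <- bouts[1L, , drop = FALSE]
  if (nrow(bouts) > 1L) {
    for (k in 2L:nrow(bouts)) {
      last <- nrow(merged)
      gap <- (bouts[k, 1L] - merged[last, 2L]) / fps
      if (gap < merge_gap) {
        merged[last, 2L] <- bouts[k, 2L]
        merged[last, 3L] <- merged[last, 3L] + bouts[k, 3L]
      } else merged <- rbind(merged, bouts[k, , drop = FALSE])
    }
  }

  out <- data.frame(
    start_t = traj$t[merged[, 1L]],
    end_t = traj$t[merged[, 2L]],
    x = vapply(seq_len(nrow(merged)),
               function(k) mean(x[merged[k, 1L]:merged[k, 2L]]), 0),
    y = vapply(seq_len(nrow(merged)),
               function(k) mean(y[merged[k, 1L]:merged[k, 2L]]), 0),
    n_fixations = as.integer(merged[, 3L]),
    angular_span = vapply(seq_len(nrow(merged)), function(k) {
      o <- orient[merged[k, 1L]:merged[k, 2L]]
      max(o) - min(o)
    }, 0))
  structure(out, params = params)
}

## Greedy scan for maximal on-the-spot intervals [i, j] (frame indices):
## extend j while all points i..j lie within radius of their running centroid.
stationary_intervals <- function(x, y, radius) {
  n <- length(x)
  out <- list()
  i <- 1L
  while (i < n) {
    j <- i
    sx <- x[i]; sy <- y[i]
    repeat {
      if (j == n) break
      sx2 <- sx + x[j + 1L]; sy2 <- sy + y[j + 1L]
      m <- j - i + 2L
      cx <- sx2 / m; cy <- sy2 / m
      if (max((x[i:(j + 1L)] - cx)^2 + (y[i:(j + 1L)] - cy)^2) > radius^2) break
      j <- j + 1L; sx <- sx2; sy <- sy2
    }
    if (j > i) out[[length(out) + 1L]] <- c(i, j)
    i <- j + 1L
  }
  out
}

## Fixation mean orientations within frames i..j: maximal slow-rotation runs
## of sufficient duration, de-duplicated so successive fixations differ by at
## least min_sep degrees. Returns the vector of distinct fixation means.
fixations_in <- function(orient, rate, i, j, fps, min_dur, max_rate, min_sep) {
  idx <- i:j
  ridx <- i:(j - 1L)                      # rate[k] spans frames k..k+1
  slow <- rate[ridx] < max_rate
  r <- rle(slow)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  means <- numeric(0)
  min_frames <- max(1L, ceiling(min_dur * fps))
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    len <- r$lengths[k] + 1L              # frames spanned by the slow run
    if (len < min_frames) next
    f0 <- i + starts[k] - 1L
    f1 <- i + ends[k]
    m <- mean(orient[f0:f1])
    if (!length(means) || abs(m - means[length(means)]) >= min_sep)
      means <- c(means, m)
  }
  means
}
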