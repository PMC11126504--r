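#' Convex-hull area of a walk
#'
#' Area (cm^2) of the convex hull enclosing every thorax position visited
#' during the walk; the standard measure of the spatial extent of exploration
#' around the nest. Collinear paths have zero area.
#'
#' @param traj an [trajectory()] object with at least 3 frames.
#' @return area in cm^2.
#' @export
convex_hull_area <- function(traj) {
  x <- traj$thorax_x; y <- traj$thorax_y
  if (length(x) < 3L)
    stop("need at least 3 points for a hull", call. = FALSE)
  h <- grDevices::chull(x, y)
  if (length(h) < 3L) return(0)
  hx <- x[h]; hy <- y[h]
  # shoelace formula over the hull vertices
  abs(sum(hx * c(hy[-1L], hy[1L]) - c(hx[-1L], hx[1L]) * hy)) / 2
}

#' Maximum displacement from the nest
#'
#' The largest distance (cm) of the thorax from the nest entrance at (0, 0)
#' over the whole walk.
#'
#' @param traj an [trajectory()] object.
#' @return distance in cm.
#' @export
max_displacement <- function(traj) {
  max(sqrt(traj$thorax_x^2 + traj$thorax_y^2))
}

#' Duration of a walk
#'
#' Elapsed time (s) from the first to the last tracked frame.
#'
#' @param traj an [trajectory()] object.
#' @return duration in seconds.
#' @export
duration <- function(traj) {
  traj$t[nrow(traj)] - traj$t[1L]
}

#' Mean travel speed excluding stops
#'
#' Per-frame speed is the step length times the frame rate. Frames belonging
#' to a stop -- speed below `stop_speed_thresh` sustained for at least
#' `stop_min_dur` seconds -- are excluded before averaging, so pauses do not
#' dilute the travel speed. If every frame is stopped the function returns 0
#' with a warning.
#'
#' @param traj an [trajectory()] object.
#' @param stop_speed_thresh stop threshold in cm/s (default 0.5).
#' @param stop_min_dur minimum stop duration in seconds (default 0.2).
#' @return mean speed in cm/s.
#' @export
mean_speed <- function(traj, stop_speed_thresh = 0.5, stop_min_dur = 0.2) {
  stopifnot(stop_speed_thresh >= 0, stop_min_dur >= 0)
  fps <- frame_rate_of(traj)
  v <- step_lengths(traj) * fps
  stopped <- stop_mask(v, fps, stop_speed_thresh, stop_min_dur)
  if (all(stopped)) {
    warning("all frames are stopped; mean speed reported as 0")
    return(0)
  }
  mean(v[!stopped])
}

## Logical mask of per-step speeds that belong to a sustained stop.
stop_mask <- function(v, fps, thresh, min_dur) {
  slow <- v < thresh
  r <- rle(slow)
  keep <- r$values & (r$lengths / fps >= min_dur)
  rep(keep, r$lengths)
}

#' Head orientation time series
#'
#' The orientation of the body axis per frame: the direction of the vector
#' from the thorax to the head tip, in degrees counterclockwise from North,
#' unwrapped over time so that the series has no +-360 discontinuities (a full
#' on-the-spot rotation spans 360 continuously).
#'
#' @param traj an [trajectory()] object.
#' @return numeric vector, one unwrapped orientation (degrees) per frame.
#' @export
orientation_series <- function(traj) {
  dx <- traj$head_x - traj$thorax_x
  dy <- traj$head_y - traj$thorax_y
  if (any(dx == 0 & dy == 0))
    stop("zero-length body axis", call. = FALSE)
  unwrap_deg(ccw_from_north(dx, dy))
}

#' Mean orientation angular velocity
#'
#' Mean absolute rate of change of the body-axis orientation, in deg/s:
#' the average of |delta orientation| times the frame rate. The magnitude is
#' used so that left and right gaze oscillations do not cancel.
#'
#' @param traj an [trajectory()] object.
#' @return mean angular speed in deg/s.
#' @export
mean_orient_angular_velocity <- function(traj) {
  o <- orientation_series(traj)
  mean(abs(diff(o))) * frame_rate_of(traj)
}

#' Path straightness
#'
#' Net displacement of the thorax (straight-line distance from the first to
#' the last position) divided by the total path length; lies in [0, 1], with 1
#' a perfectly straight path and 0 a closed loop.
#'
#' @param traj an [trajectory()] object.
#' @return dimensionless value in `[0, 1]`.
#' @export
straightness <- function(traj) {
  len <- sum(step_lengths(traj))
  if (len == 0)
    stop("zero path length: straightness undefined", call. = FALSE)
  n <- nrow(traj)
  net <- sqrt((traj$thorax_x[n] - traj$thorax_x[1L])^2 +
              (traj$thorax_y[n] - traj$thorax_y[1L])^2)
  min(net / len, 1)
}

#' Sinuosity of a path
#'
#' Tortuosity index
#' \deqn{S = 2\left[p\left(\frac{1+c}{1-c} + b^2\right)\right]^{-1/2}}
#' where \eqn{p} is the mean step length (cm), \eqn{c} the mean cosine of
#' turning angles, and \eqn{b} the coefficient of variation of step length.
#' Steps are taken between consecutive video frames (no rediscretization).
#' For a perfectly straight path (\eqn{c \to 1}) the limiting value 0 is
#' returned with attribute `limit = TRUE`. Note the formula is not bounded by
#' 1: small mean step lengths can push it above 1.
#'
#' @param traj an [trajectory()] object with at least 3 frames.
#' @return dimensionless sinuosity (>= 0).
#' @export
sinuosity <- function(traj) {
  st <- steps(traj)
  p <- mean(st$length)
  c_ <- mean(cos(st$turning_angle))
  if (c_ >= 1 - 1e-12)
    return(structure(0, limit = TRUE))
  b <- stats::sd(st$length) / p
  2 * (p * ((1 + c_) / (1 - c_) + b^2))^-0.5
}

#' Maximum expected displacement
#'
#' The dimensionless straightness proxy \eqn{E^a_{max} = \beta/(1-\beta)},
#' with \eqn{\beta} the mean cosine of turning angles: larger values indicate
#' straighter paths and greater expected displacement per step. A perfectly
#' straight path (\eqn{\beta \ge 1 - 10^{-12}}) returns `Inf` with attribute
#' `infinite = TRUE`.
#'
#' @param traj an [trajectory()] object with at least 3 frames.
#' @return dimensionless value (may be `Inf`).
#' @export
emax <- function(traj) {
  st <- steps(traj)
  beta <- mean(cos(st$turning_angle))
  if (beta >= 1 - 1e-12)
    return(structure(Inf, infinite = TRUE))
  beta / (1 - beta)
}

#' All per-walk summary metrics
#'
#' Convenience wrapper computing the full per-walk metric set used by the
#' group comparisons, plus the scanning-bout count.
#'
#' @param traj an [trajectory()] object.
#' @param stop_speed_thresh,stop_min_dur stop-exclusion parameters for
#'   [mean_speed()].
#' @param scan_params scanning-bout detector parameters, see
#'   [detect_scanning_bouts()]; `NULL` uses the defaults.
#' @return a one-row data frame with columns `convex_hull_area`,
#'   `max_displacement`, `duration`, `mean_speed`,
#'   `mean_orient_angular_velocity`, `straightness`, `sinuosity`, `emax`,
#'   `n_scan_bouts`.
#' @export
path_metrics <- function(traj, stop_speed_thresh = 0.5, stop_min_dur = 0.2,
                         scan_params = NULL) {
  bouts <- if (is.null(scan_params)) detect_scanning_bouts(traj)
           else do.call(detect_scanning_bouts, c(list(traj), scan_params))
  data.frame(
    convex_hull_area = convex_hull_area(traj),
    max_displacement = max_displacement(traj),
    duration = duration(traj),
    mean_speed = mean_speed(traj, stop_speed_thresh, stop_min_dur),
    mean_orient_angular_velocity = mean_orient_angular_velocity(traj),
    straightness = straightness(traj),
    sinuosity = as.numeric(sinuosity(traj)),
    emax = as.numeric(emax(traj)),
    n_scan_bouts = nrow(bouts)
  )
}
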