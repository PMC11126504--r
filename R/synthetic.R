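#' Sample von Mises headings
#'
#' Seeded von Mises draws in degrees by the Best-Fisher rejection method;
#' `kappa = 0` gives the circular uniform distribution.
#'
#' @param n number of draws.
#' @param mu_deg mean direction (degrees).
#' @param kappa concentration (>= 0).
#' @return numeric vector of angles in `[0, 360)`.
#' @export
rvonmises_deg <- function(n, mu_deg = 0, kappa = 0) {
  stopifnot(n >= 0, kappa >= 0)
  if (n == 0L) return(numeric(0))
  if (kappa == 0) return(stats::runif(n, 0, 360))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  rr <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 0L
  while (i < n) {
    z <- cos(pi * stats::runif(1))
    f <- (1 + rr * z) / (rr + z)
    cc <- kappa * (rr - f)
    u2 <- stats::runif(1)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      i <- i + 1L
      out[i] <- sign(stats::runif(1) - 0.5) * acos(pmin(pmax(f, -1), 1))
    }
  }
  wrap360(mu_deg + rad2deg(out))
}

#' Generate a heading set
#'
#' Seeded von Mises displacement-test headings for one condition.
#'
#' @param n sample size (>= 1).
#' @param mu mean direction (degrees; 0 = nest direction).
#' @param kappa concentration; 0 gives uniform headings.
#' @param seed integer seed.
#' @param condition condition label.
#' @return a [heading_set()].
#' @export
gen_headings <- function(n, mu = 0, kappa = 0, seed = 1L,
                         condition = "synthetic") {
  stopifnot(n >= 1)
  set.seed(as.integer(seed))
  heading_set(rvonmises_deg(n, mu, kappa), condition)
}

#' Default walk-generator parameters
#'
#' Parameter set for the synthetic walk generators, chosen to emulate the
#' qualitative scales of naive excavator walks: learning-walk loops reaching
#' about 10 cm from the nest (hull area around 20 cm^2, duration under a
#' minute, 1-3 scanning bouts, slow travel), and straight out-and-back
#' excavation trips depositing sand 5-10 cm away at a faster pace with no
#' scanning.
#'
#' @param kind `"learning"` or `"excavation"`.
#' @param ... overrides of any default field.
#' @return a named list of generator parameters.
#' @export
walk_gen_params <- function(kind = c("learning", "excavation"), ...) {
  kind <- match.arg(kind)
  p <- list(
    kind = kind,
    loop_radius = 6.5,       # cm, peak excursion of the learning loop
    loop_span = 120,         # deg, angular sector swept by the loop
    max_excursion = 30,      # cm, hard cap on excursion
    excav_range = c(5, 10),  # cm, sand-drop distance range
    speed_mean = if (kind == "learning") 1.2 else 2.5,  # cm/s
    speed_cv = 0.2,
    turn_kappa = if (kind == "learning") 50 else 400,
    n_scan_bouts = if (kind == "learning") 2L else 0L,
    scan_n_fixations = 3L,
    scan_fixation_dur = 0.4,     # s
    scan_fixation_step = 45,     # deg between successive fixations
    scan_rot_rate = 150,         # deg/s while rotating between fixations
    head_osc_amp = if (kind == "learning") 15 else 25,  # deg
    head_osc_freq = if (kind == "learning") 0.8 else 1.5,  # Hz
    body_length = 0.6,       # cm, thorax-to-head distance
    noise_sd_pos = 0,        # cm, positional jitter
    noise_sd_orient = 0,     # deg, orientation jitter
    frame_rate = 25,
    seed = 1L)
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  p[names(over)] <- over
  if (p$kind == "excavation") p$n_scan_bouts <- 0L
  p
}

## smooth AR(1) noise of length n, sd ~ `sd`, correlation `rho`
ar1_noise <- function(n, sd, rho = 0.95) {
  if (sd == 0 || n == 0L) return(rep(0, n))
  e <- stats::rnorm(n, 0, sd * sqrt(1 - rho^2))
  as.numeric(stats::filter(e, rho, method = "recursive"))
}

## low-frequency random field on s in [0, 1]: a few random harmonics, scaled
## to sd; smooth at any sampling density (no fine-scale arc-length inflation)
fourier_noise <- function(s, sd, n_harm = 5L) {
  if (sd == 0) return(rep(0, length(s)))
  a <- stats::rnorm(n_harm) / seq_len(n_harm)
  ph <- stats::runif(n_harm, 0, 2 * pi)
  v <- rowSums(vapply(seq_len(n_harm), function(k)
    a[k] * cos(2 * pi * k * s + ph[k]), s))
  v * sd / sqrt(sum((a / sqrt(2))^2))
}

## Resample a finely sampled path at per-frame arc-length increments whose
## mean matches the commanded speed exactly (realized mean speed equals
## speed_mean up to frame rounding); speed fluctuates smoothly with cv.
reparam_path <- function(px, py, speed_mean, speed_cv, fps, min_frames = 25L) {
  arc <- c(0, cumsum(sqrt(diff(px)^2 + diff(py)^2)))
  L <- arc[length(arc)]
  n_frames <- max(min_frames, round(L / speed_mean * fps))
  rel <- pmax(1 + ar1_noise(n_frames - 1L, speed_cv), 0.2)
  tgt <- c(0, cumsum(rel)) * L / sum(rel)
  list(x = stats::approx(arc, px, xout = tgt, ties = "ordered", rule = 2)$y,
       y = stats::approx(arc, py, xout = tgt, ties = "ordered", rule = 2)$y,
       length = L)
}

## Assemble a trajectory from per-frame thorax positions and body orientation
## (degrees CCW from North), applying measurement jitter.
assemble_walk <- function(x, y, orient, p, label, ant_id) {
  n <- length(x)
  if (p$noise_sd_pos > 0) {
    x <- x + stats::rnorm(n, 0, p$noise_sd_pos)
    y <- y + stats::rnorm(n, 0, p$noise_sd_pos)
  }
  if (p$noise_sd_orient > 0)
    orient <- orient + stats::rnorm(n, 0, p$noise_sd_orient)
  hd <- deg2rad(orient + 90)
  trajectory(frame = 0:(n - 1L),
             head_x = x + p$body_length * cos(hd),
             head_y = y + p$body_length * sin(hd),
             thorax_x = x, thorax_y = y,
             frame_rate = p$frame_rate, label = label, ant_id = ant_id)
}

## Build the orientation segment of one scanning bout. Returns the sequence
## of orientations (degrees) starting and ending at `base` direction.
bout_orientations <- function(p) {
  fps <- p$frame_rate
  fix_frames <- max(2L, round(p$scan_fixation_dur * fps))
  offs <- (seq_len(p$scan_n_fixations) - 1L) * p$scan_fixation_step *
    rep_len(c(1, -1), p$scan_n_fixations)   # 0, +step, -2 step, ...
  seq_deg <- numeric(0)
  cur <- 0
  for (o in offs) {
    if (o != cur) {
      nrot <- max(1L, ceiling(abs(o - cur) / p$scan_rot_rate * fps))
      seq_deg <- c(seq_deg, seq(cur, o, length.out = nrot + 1L)[-1L])
      cur <- o
    }
    seq_deg <- c(seq_deg, rep(cur, fix_frames))
  }
  # rotate back toward the travel direction
  nrot <- max(1L, ceiling(abs(cur) / p$scan_rot_rate * fps))
  c(seq_deg, seq(cur, 0, length.out = nrot + 1L)[-1L])
}

#' Generate a synthetic learning walk
#'
#' Simulates a naive learning walk: a single loop leaving the nest at (0, 0),
#' sweeping an angular sector around it with peak excursion `loop_radius`
#' (capped by `max_excursion`), and returning to within 1 cm of the nest.
#' Radial and angular jitter give the loop a correlated-random-walk texture;
#' travel speed fluctuates around `speed_mean`. `n_scan_bouts` on-the-spot
#' scanning bouts (stationary thorax, successive head fixations 45 degrees
#' apart) are spliced in at spread-out positions along the loop. The head
#' oscillates sinusoidally about the travel direction between bouts.
#'
#' @param p parameters from [walk_gen_params()] with `kind = "learning"`.
#' @param ant_id identifier stored on the trajectory.
#' @return list with `traj` (an [trajectory()]) and `truth`: ground-truth
#'   list holding `bouts` (data frame of inserted bout start/end times),
#'   `commanded_speed`, `max_excursion`, `path_length`, `n_scan_bouts`.
#' @export
gen_learning_walk <- function(p = walk_gen_params("learning"),
                              ant_id = "ant1") {
  stopifnot(p$kind == "learning")
  if (p$loop_radius > p$max_excursion)
    stop("loop_radius exceeds max_excursion", call. = FALSE)
  set.seed(as.integer(p$seed))
  fps <- p$frame_rate

  ## smooth loop in polar form: r(s) = R sin(pi s) e^eps, theta(s) about a
  ## random departure bearing; jitter scale set by turn_kappa
  m <- 1200L
  s <- seq(0, 1, length.out = m)
  jit <- 1 / sqrt(p$turn_kappa)
  r <- p$loop_radius * sin(pi * s) * exp(fourier_noise(s, jit * 0.6))
  r <- pmin(r, p$max_excursion)
  th0 <- stats::runif(1, 0, 2 * pi)
  ## bearing advances monotonically around the nest: clamp the angular
  ## increment at a fraction of its nominal value so the loop never doubles
  ## back on itself
  span <- deg2rad(p$loop_span)
  dth <- diff(span * (s - 0.5) + fourier_noise(s, jit * 0.5))
  th <- th0 + c(0, cumsum(pmax(dth, 0.25 * span / m)))
  px <- r * cos(th); py <- r * sin(th)

  ## constant-ish speed reparameterization
  rp <- reparam_path(px, py, p$speed_mean, p$speed_cv, fps)
  x <- rp$x; y <- rp$y; L <- rp$length
  n_frames <- length(x)

  ## travel orientation: smoothed tangent heading (unwrapped)
  tang <- ccw_from_north(diff(x), diff(y))
  orient <- boxcar(unwrap_deg(c(tang[1L], tang)), 5L)
  tt <- (seq_along(x) - 1L) / fps
  phase <- stats::runif(1, 0, 2 * pi)
  orient <- orient + p$head_osc_amp * sin(2 * pi * p$head_osc_freq * tt + phase)

  ## splice scanning bouts at spread interior frames
  k <- as.integer(p$n_scan_bouts)
  bout_truth <- data.frame(start_t = numeric(0), end_t = numeric(0))
  if (k > 0L) {
    at <- round(stats::quantile(seq_len(n_frames), (seq_len(k)) / (k + 1),
                                names = FALSE) +
                stats::runif(k, -0.05, 0.05) * n_frames)
    at <- sort(pmin(pmax(at, 10L), n_frames - 10L))
    newx <- list(); newy <- list(); newo <- list()
    prev <- 1L
    starts <- numeric(k); ends <- numeric(k)
    added <- 0L
    for (i in seq_len(k)) {
      seg <- prev:at[i]
      newx[[2 * i - 1L]] <- x[seg]; newy[[2 * i - 1L]] <- y[seg]
      newo[[2 * i - 1L]] <- orient[seg]
      bo <- orient[at[i]] + bout_orientations(p)
      nb <- length(bo)
      newx[[2 * i]] <- rep(x[at[i]], nb); newy[[2 * i]] <- rep(y[at[i]], nb)
      newo[[2 * i]] <- bo
      starts[i] <- (at[i] + added - 1L) / fps
      ends[i] <- (at[i] + added + nb - 1L) / fps
      added <- added + nb
      prev <- at[i] + 1L
    }
    seg <- prev:length(x)
    newx[[2 * k + 1L]] <- x[seg]; newy[[2 * k + 1L]] <- y[seg]
    newo[[2 * k + 1L]] <- orient[seg]
    x <- unlist(newx); y <- unlist(newy); orient <- unlist(newo)
    bout_truth <- data.frame(start_t = starts, end_t = ends)
  }

  traj <- assemble_walk(x, y, orient, p, "learning", ant_id)
  list(traj = traj,
       truth = list(bouts = bout_truth, commanded_speed = p$speed_mean,
                    max_excursion = max(sqrt(x^2 + y^2)),
                    path_length = L, n_scan_bouts = k))
}

#' Generate a synthetic excavation trip
#'
#' Simulates a sand-carrying excavation trip: the ant heads straight out from
#' the nest along a random bearing, drops its load at a distance drawn
#' uniformly from `excav_range` (default 5-10 cm), turns, and heads straight
#' back, without stopping or scanning. Travel is faster than on learning
#' walks; slight heading jitter (concentration `turn_kappa`) gives the legs a
#' natural texture while keeping each leg nearly straight.
#'
#' @param p parameters from [walk_gen_params()] with `kind = "excavation"`.
#' @param ant_id identifier stored on the trajectory.
#' @return list with `traj` and `truth` (`commanded_speed`, `drop_distance`,
#'   `max_excursion`, `outbound_frames`).
#' @export
gen_excavation_trip <- function(p = walk_gen_params("excavation"),
                                ant_id = "ant1") {
  stopifnot(p$kind == "excavation")
  set.seed(as.integer(p$seed))
  fps <- p$frame_rate
  D <- stats::runif(1, p$excav_range[1L], min(p$excav_range[2L], p$max_excursion))
  bearing <- stats::runif(1, 0, 2 * pi)
  step0 <- p$speed_mean / fps
  jit_sd <- 1 / sqrt(p$turn_kappa)

  walk_leg <- function(from, target) {
    # CRW biased at the target until within one step of it
    pos <- from
    hd <- atan2(target[2L] - from[2L], target[1L] - from[1L])
    xs <- numeric(0); ys <- numeric(0)
    repeat {
      to_go <- sqrt(sum((target - pos)^2))
      if (to_go <= step0) break
      aim <- atan2(target[2L] - pos[2L], target[1L] - pos[1L])
      hd <- aim + stats::rnorm(1, 0, jit_sd)
      len <- step0 * pmax(1 + stats::rnorm(1, 0, p$speed_cv), 0.2)
      pos <- pos + len * c(cos(hd), sin(hd))
      xs <- c(xs, pos[1L]); ys <- c(ys, pos[2L])
    }
    cbind(xs, ys)
  }

  tip <- D * c(cos(bearing), sin(bearing))
  out_leg <- walk_leg(c(0, 0), tip)
  back_leg <- walk_leg(tip, c(0, 0))
  px <- c(0, out_leg[, 1L], tip[1L], back_leg[, 1L])
  py <- c(0, out_leg[, 2L], tip[2L], back_leg[, 2L])
  n_out_fine <- nrow(out_leg) + 2L        # fine-path index of the turn
  arc_out <- sum(sqrt(diff(px[1:n_out_fine])^2 + diff(py[1:n_out_fine])^2))
  rp <- reparam_path(px, py, p$speed_mean, p$speed_cv, fps)
  x <- rp$x; y <- rp$y

  tang <- ccw_from_north(diff(x), diff(y))
  orient <- boxcar(unwrap_deg(c(tang[1L], tang)), 7L)
  tt <- (seq_along(x) - 1L) / fps
  phase <- stats::runif(1, 0, 2 * pi)
  orient <- orient + p$head_osc_amp * sin(2 * pi * p$head_osc_freq * tt + phase)

  traj <- assemble_walk(x, y, orient, p, "excavation", ant_id)
  d_along <- c(0, cumsum(sqrt(diff(x)^2 + diff(y)^2)))
  list(traj = traj,
       truth = list(commanded_speed = p$speed_mean, drop_distance = D,
                    max_excursion = max(sqrt(x^2 + y^2)),
                    outbound_frames = sum(d_along <= arc_out)))
}

#' Parametric panoramic scene
#'
#' A minimal landmark scene standing in for the field panorama: upright
#' blocks (grass tussocks, bushes, trees) at given bearings and distances
#' from the nest, on a flat ground plane under an even sky. Synthetic: no
#' attempt at photorealism.
#'
#' @param objects data frame with columns `azimuth_deg` (bearing from the
#'   nest), `distance_m`, `width_m`, `height_m`, `albedo` (intensity in
#'   `[0, 1]`).
#' @param sky_level,ground_level background intensities in `[0, 1]`.
#' @param sun_azimuth world bearing (degrees) of the brightest sky.
#' @param sky_gradient amplitude of the azimuthal sky brightness modulation
#'   (cosine about `sun_azimuth`); a world-fixed cue, like the solar
#'   brightness gradient in real sky.
#' @return a `scene_spec` list.
#' @export
scene_spec <- function(objects, sky_level = 0.85, ground_level = 0.45,
                       sun_azimuth = 0, sky_gradient = 0.08) {
  need <- c("azimuth_deg", "distance_m", "width_m", "height_m", "albedo")
  stopifnot(all(need %in% names(objects)), all(objects$distance_m > 0),
            all(objects$height_m > 0),
            sky_level + sky_gradient <= 1, sky_level - sky_gradient >= 0)
  structure(list(objects = objects, sky_level = sky_level,
                 ground_level = ground_level, sun_azimuth = sun_azimuth,
                 sky_gradient = sky_gradient), class = "scene_spec")
}

#' Default synthetic landmark scene
#'
#' A cluttered semi-arid horizon with the immediate nest surroundings
#' cleared (as in the field protocol): bushes and small trees at 8-25 m that
#' shift moderately with viewing position, plus distant trees (40-90 m)
#' whose bearings are effectively parallax-stable, and a world-fixed
#' azimuthal sky brightness gradient.
#'
#' @param seed integer seed controlling small placement jitter.
#' @return a [scene_spec()].
#' @export
default_scene <- function(seed = 1L) {
  set.seed(as.integer(seed))
  ## the ground near the nest is cleared, as in the field protocol: the
  ## nearest structure sits ~8 m out
  near <- data.frame(
    azimuth_deg = wrap360(c(20, 75, 140, 195, 250, 310) +
                            stats::runif(6, -10, 10)),
    distance_m = c(8, 14, 10, 20, 12, 25) * stats::runif(6, 0.9, 1.1),
    width_m = c(1.2, 2.5, 1.6, 4.0, 2.2, 5.5),
    height_m = c(1.0, 3.0, 1.6, 5.0, 2.5, 8.0),
    albedo = c(0.25, 0.15, 0.3, 0.1, 0.2, 0.08))
  far <- data.frame(
    azimuth_deg = sort(stats::runif(8, 0, 360)),
    distance_m = stats::runif(8, 40, 90),
    width_m = stats::runif(8, 6, 18),
    height_m = stats::runif(8, 5, 14) * stats::runif(8, 0.8, 1.2),
    albedo = stats::runif(8, 0.02, 0.3))
  scene_spec(rbind(near, far), sun_azimuth = stats::runif(1, 0, 360))
}

#' Render an equirectangular panorama of a scene
#'
#' Renders the scene from a viewing position (metres, nest at the origin):
#' sky above the horizon, ground below, and each landmark as a block of
#' angular width `2 atan(w / 2d)` and angular height `atan(h / d)` above the
#' horizon at its bearing, where `d` is its distance from the viewpoint.
#' Nearer objects occlude farther ones. Column 1 faces `heading_of_col0`
#' (by default the bearing from the position back to the nest; North when
#' rendering at the nest itself); successive columns advance clockwise in
#' bearing.
#'
#' @param scene a [scene_spec()].
#' @param position numeric length-2 viewing position in metres.
#' @param n_cols,n_rows grid size (default 360 x 90); rows span elevations
#'   +45 to -45 degrees.
#' @param heading_of_col0 world bearing of column 1 (degrees); `NULL` for the
#'   nest-ward default.
#' @return a [panorama()] object.
#' @export
render_panorama <- function(scene, position = c(0, 0), n_cols = 360L,
                            n_rows = 90L, heading_of_col0 = NULL) {
  stopifnot(n_cols >= 1L, n_rows >= 1L)
  ob <- scene$objects
  ## world positions of objects (bearing measured clockwise from North)
  brad <- deg2rad(90 - ob$azimuth_deg)
  ox <- ob$distance_m * cos(brad); oy <- ob$distance_m * sin(brad)
  dx <- ox - position[1L]; dy <- oy - position[2L]
  d <- sqrt(dx^2 + dy^2)
  if (any(d < ob$width_m / 2))
    stop("viewing position lies inside an object footprint", call. = FALSE)
  bearing <- wrap360(90 - rad2deg(atan2(dy, dx)))   # compass bearing
  halfw <- rad2deg(atan(ob$width_m / (2 * d)))
  top_el <- rad2deg(atan(ob$height_m / d))

  if (is.null(heading_of_col0)) {
    heading_of_col0 <- if (all(position == 0)) 0 else
      wrap360(90 - rad2deg(atan2(-position[2L], -position[1L])))
  }
  step <- 360 / n_cols
  col_bearing <- wrap360(heading_of_col0 + (seq_len(n_cols) - 1L) * step)
  el <- seq(45, -45, length.out = n_rows)            # row elevations

  sky <- scene$sky_level + scene$sky_gradient *
    cos(deg2rad(col_bearing - scene$sun_azimuth))
  img <- matrix(sky, n_rows, n_cols, byrow = TRUE)
  img[el < 0, ] <- scene$ground_level
  ## paint far-to-near so near objects occlude
  for (i in order(d, decreasing = TRUE)) {
    dang <- abs(rad2deg(wrap_pi(deg2rad(col_bearing - bearing[i]))))
    cols <- dang <= halfw[i]
    rows <- el >= 0 & el <= top_el[i]
    if (any(cols) && any(rows)) img[rows, cols] <- ob$albedo[i]
  }
  panorama(img, heading_of_col0)
}

#' Generate a full synthetic study bundle
#'
#' Builds the complete input set of the synthetic experiment in memory:
#' `n_ants` ants each performing one learning walk and three excavation
#' trips; four displacement-test heading sets (2 m conditions drawn from a
#' concentrated von Mises around the nest direction, 4 m conditions uniform);
#' and rendered panoramas at the nest and the four test sites. All
#' randomness derives from `master_seed`.
#'
#' @param n_ants number of ants (default 20).
#' @param master_seed integer master seed.
#' @param heading_n headings per displacement condition (default `n_ants`).
#' @param kappa_2m,kappa_4m von Mises concentrations of the 2 m and 4 m
#'   heading conditions (defaults 3 and 0).
#' @param noise_sd_pos,noise_sd_orient measurement jitter passed to the walk
#'   generators.
#' @param ant_effect_sd lognormal sd of per-ant size/speed multipliers.
#' @param render logical; render the panoramas (default TRUE).
#' @return list with `walks` (list per ant of `LW`, `E1`, `E2`, `E3`
#'   generator outputs), `headings` (list of four [heading_set()]s),
#'   `panoramas` (named list; `NULL` when `render = FALSE`), `scene`,
#'   `params`.
#' @export
gen_experiment_data <- function(n_ants = 20L, master_seed = 1L,
                                heading_n = n_ants, kappa_2m = 3,
                                kappa_4m = 0, noise_sd_pos = 0.02,
                                noise_sd_orient = 1, ant_effect_sd = 0.15,
                                render = TRUE) {
  master_seed <- as.integer(master_seed)
  set.seed(master_seed)
  seeds <- sample.int(2^30, n_ants * 6L + 16L)
  si <- 0L
  nxt <- function() { si <<- si + 1L; seeds[si] }

  walks <- vector("list", n_ants)
  names(walks) <- sprintf("ant%02d", seq_len(n_ants))
  for (a in seq_len(n_ants)) {
    set.seed(nxt())
    eff <- exp(stats::rnorm(2, 0, ant_effect_sd))   # size, speed multipliers
    lw <- gen_learning_walk(walk_gen_params(
      "learning", loop_radius = 6.5 * eff[1L], speed_mean = 1.2 * eff[2L],
      n_scan_bouts = sample(1:3, 1L), noise_sd_pos = noise_sd_pos,
      noise_sd_orient = noise_sd_orient, seed = nxt()),
      ant_id = names(walks)[a])
    es <- lapply(1:3, function(k)
      gen_excavation_trip(walk_gen_params(
        "excavation", speed_mean = 2.5 * eff[2L], noise_sd_pos = noise_sd_pos,
        noise_sd_orient = noise_sd_orient, seed = nxt()),
        ant_id = names(walks)[a]))
    walks[[a]] <- list(LW = lw, E1 = es[[1L]], E2 = es[[2L]], E3 = es[[3L]])
  }

  conds <- list(`2mN` = c(0, 200, kappa_2m), `2mE` = c(200, 0, kappa_2m),
                `4mN` = c(0, 400, kappa_4m), `4mE` = c(400, 0, kappa_4m))
  headings <- lapply(names(conds), function(nm)
    gen_headings(heading_n, mu = 0, kappa = conds[[nm]][3L], seed = nxt(),
                 condition = nm))
  names(headings) <- names(conds)

  scene <- default_scene(seed = nxt())
  panoramas <- NULL
  if (render) {
    positions <- list(nest = c(0, 0), `2mN` = c(0, 2), `2mE` = c(2, 0),
                      `4mN` = c(0, 4), `4mE` = c(4, 0))
    panoramas <- lapply(positions, function(pos)
      render_panorama(scene, pos))
    ## reference aligned with each test's nest-ward bearing is re-rendered in
    ## the rotIDF analysis; the stored nest panorama faces North
  }

  list(walks = walks, headings = headings, panoramas = panoramas,
       scene = scene,
       params = list(n_ants = n_ants, master_seed = master_seed,
                     heading_n = heading_n, kappa_2m = kappa_2m,
                     kappa_4m = kappa_4m, noise_sd_pos = noise_sd_pos,
                     noise_sd_orient = noise_sd_orient,
                     ant_effect_sd = ant_effect_sd))
}

#' Write a synthetic study bundle to disk
#'
#' Materializes [gen_experiment_data()] as the file tree the ingestion
#' functions read: one canonical trajectory CSV per walk under
#' `trajectories/`, a `headings.csv` (`ant_id,condition,angle_deg`),
#' panorama PNGs under `panoramas/`, and a `ground_truth.json` with every
#' inserted scanning bout, commanded speeds and generator parameters.
#' Re-running with the same seed reproduces the files byte for byte.
#'
#' @param out_dir output directory (created if needed).
#' @param ... passed to [gen_experiment_data()].
#' @return invisibly, the bundle from [gen_experiment_data()].
#' @export
gen_experiment <- function(out_dir, ...) {
  bundle <- gen_experiment_data(...)
  dir.create(file.path(out_dir, "trajectories"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "panoramas"), showWarnings = FALSE)

  truth <- list(params = bundle$params, walks = list())
  for (ant in names(bundle$walks)) {
    for (cond in names(bundle$walks[[ant]])) {
      w <- bundle$walks[[ant]][[cond]]
      write_trajectory_csv(w$traj, file.path(
        out_dir, "trajectories", sprintf("%s_%s.csv", ant, cond)))
      truth$walks[[paste(ant, cond, sep = "_")]] <- w$truth
    }
  }
  hs <- do.call(rbind, lapply(bundle$headings, function(h)
    data.frame(ant_id = sprintf("ant%02d", seq_len(h$n)),
               condition = h$condition, angle_deg = h$angles)))
  utils::write.csv(hs, file.path(out_dir, "headings.csv"), row.names = FALSE)
  if (!is.null(bundle$panoramas))
    for (nm in names(bundle$panoramas))
      write_panorama(bundle$panoramas[[nm]],
                     file.path(out_dir, "panoramas", paste0(nm, ".png")))
  jsonlite::write_json(truth, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(bundle)
}
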