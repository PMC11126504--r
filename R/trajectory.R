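#' Construct a nest-centred trajectory
#'
#' A trajectory holds frame-by-frame head-tip and thorax positions of one ant
#' in nest-centred map coordinates: the nest entrance is the origin, +x is
#' East, +y is North, units are centimetres. Time is derived from the frame
#' index at a constant frame rate.
#'
#' @param frame integer frame indices, strictly increasing and contiguous.
#' @param head_x,head_y head-tip coordinates (cm).
#' @param thorax_x,thorax_y thorax coordinates (cm).
#' @param frame_rate frames per second (default 25, standard tracking video).
#' @param label walk kind: one of `"learning"`, `"excavation"`, `"test"`,
#'   `"unknown"`.
#' @param ant_id opaque identifier of the individual.
#' @return an object of class `ant_trajectory`: a data frame with columns
#'   `frame`, `t`, `head_x`, `head_y`, `thorax_x`, `thorax_y` and attributes
#'   `frame_rate`, `label`, `ant_id`.
#' @export
trajectory <- function(frame, head_x, head_y, thorax_x, thorax_y,
                       frame_rate = 25, label = "unknown", ant_id = NA_character_) {
  n <- length(frame)
  if (n < 2L)
    stop("trajectory needs at least 2 frames", call. = FALSE)
  lens <- c(length(head_x), length(head_y), length(thorax_x), length(thorax_y))
  if (any(lens != n))
    stop("coordinate vectors must match the number of frames", call. = FALSE)
  frame <- as.integer(frame)
  if (any(diff(frame) <= 0L))
    stop("frame indices must be strictly increasing", call. = FALSE)
  if (any(diff(frame) != 1L))
    stop("gap in frame indices: trajectories must be contiguous", call. = FALSE)
  xyz <- c(head_x, head_y, thorax_x, thorax_y)
  if (!all(is.finite(xyz)))
    stop("non-finite coordinate", call. = FALSE)
  if (any(head_x == thorax_x & head_y == thorax_y))
    stop("head and thorax coincide on some frame (zero body axis)", call. = FALSE)
  label <- match.arg(label, c("learning", "excavation", "test", "unknown"))
  out <- data.frame(
    frame = frame,
    t = (frame - frame[1L]) / frame_rate,
    head_x = as.numeric(head_x), head_y = as.numeric(head_y),
    thorax_x = as.numeric(thorax_x), thorax_y = as.numeric(thorax_y)
  )
  structure(out,
            frame_rate = frame_rate, label = label, ant_id = ant_id,
            class = c("ant_trajectory", "data.frame"))
}

#' @export
print.ant_trajectory <- function(x, ...) {
  cat(sprintf("<ant_trajectory> %s walk, ant %s: %d frames @ %g fps (%.2f s)\n",
              attr(x, "label"), attr(x, "ant_id"), nrow(x),
              attr(x, "frame_rate"), x$t[nrow(x)] - x$t[1L]))
  invisible(x)
}

frame_rate_of <- function(traj) attr(traj, "frame_rate")

#' Read a digitized tracking table
#'
#' Reads a delimited table of pixel coordinates as produced by video
#' digitization (columns `frame, head_x, head_y, thorax_x, thorax_y`),
#' translates it so that the nest pixel maps to the origin, converts pixels to
#' centimetres, and flips the pixel y-axis (image rows grow downward) into map
#' coordinates where +y is North.
#'
#' @param path path to a CSV/TSV file with the required header.
#' @param frame_rate frames per second of the source video (default 25).
#' @param scale centimetres per pixel; must be positive.
#' @param nest_pixel numeric length-2, pixel coordinates of the nest entrance.
#' @param flip_y logical; if `TRUE` (default) pixel y grows downward and is
#'   negated on ingest.
#' @param sep field separator, `","` by default.
#' @param label,ant_id passed to [trajectory()].
#' @return an [trajectory()] object in nest-centred cm.
#' @export
read_tracking_table <- function(path, frame_rate = 25, scale = 1,
                                nest_pixel = c(0, 0), flip_y = TRUE,
                                sep = ",", label = "unknown", ant_id = NA_character_) {
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0)
    stop("scale must be a positive cm-per-pixel factor", call. = FALSE)
  tab <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE),
    error = function(e) stop("cannot parse tracking table: ", conditionMessage(e),
                             call. = FALSE))
  need <- c("frame", "head_x", "head_y", "thorax_x", "thorax_y")
  if (!all(need %in% names(tab)))
    stop("tracking table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (nrow(tab) < 2L)
    stop("tracking table has fewer than 2 rows", call. = FALSE)
  ysign <- if (flip_y) -1 else 1
  trajectory(
    frame = tab$frame,
    head_x = (tab$head_x - nest_pixel[1L]) * scale,
    head_y = ysign * (tab$head_y - nest_pixel[2L]) * scale,
    thorax_x = (tab$thorax_x - nest_pixel[1L]) * scale,
    thorax_y = ysign * (tab$thorax_y - nest_pixel[2L]) * scale,
    frame_rate = frame_rate, label = label, ant_id = ant_id)
}

#' Write a trajectory as a canonical CSV
#'
#' Columns `t,head_x_cm,head_y_cm,thorax_x_cm,thorax_y_cm`, one row per frame.
#' Together with [read_trajectory_csv()] this round-trips coordinates exactly
#' (values are written with full precision).
#'
#' @param traj an [trajectory()] object.
#' @param path output file path.
#' @export
write_trajectory_csv <- function(traj, path) {
  out <- data.frame(t = traj$t,
                    head_x_cm = traj$head_x, head_y_cm = traj$head_y,
                    thorax_x_cm = traj$thorax_x, thorax_y_cm = traj$thorax_y)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(out), collapse = ","), con)
  writeLines(do.call(paste, c(lapply(out, format, digits = 17, trim = TRUE,
                                     scientific = FALSE), sep = ",")), con)
  invisible(path)
}

#' Read a canonical trajectory CSV
#'
#' @param path file written by [write_trajectory_csv()].
#' @param frame_rate frames per second; the time column is checked against it.
#' @param label,ant_id passed to [trajectory()].
#' @return an [trajectory()] object.
#' @export
read_trajectory_csv <- function(path, frame_rate = 25,
                                label = "unknown", ant_id = NA_character_) {
  tab <- utils::read.csv(path)
  need <- c("t", "head_x_cm", "head_y_cm", "thorax_x_cm", "thorax_y_cm")
  if (!all(need %in% names(tab)))
    stop("not a canonical trajectory CSV", call. = FALSE)
  trajectory(frame = seq_len(nrow(tab)) - 1L,
             head_x = tab$head_x_cm, head_y = tab$head_y_cm,
             thorax_x = tab$thorax_x_cm, thorax_y = tab$thorax_y_cm,
             frame_rate = frame_rate, label = label, ant_id = ant_id)
}

#' Step lengths and turning angles of a thorax path
#'
#' Steps are the movements of the thorax between consecutive frames. Step
#' lengths are Euclidean distances between consecutive thorax positions;
#' turning angles are the changes of direction between consecutive steps,
#' wrapped to `(-pi, pi]`.
#'
#' @param traj an [trajectory()] object with at least 3 frames.
#' @return a list with `length` (n-1 step lengths, cm) and `turning_angle`
#'   (n-2 angles, radians).
#' @export
steps <- function(traj) {
  if (nrow(traj) < 3L)
    stop("need at least 3 frames for turning angles", call. = FALSE)
  dx <- diff(traj$thorax_x)
  dy <- diff(traj$thorax_y)
  len <- sqrt(dx^2 + dy^2)
  hdg <- atan2(dy, dx)
  list(length = len, turning_angle = wrap_pi(diff(hdg)))
}

## Step lengths alone (valid from 2 frames).
step_lengths <- function(traj) {
  sqrt(diff(traj$thorax_x)^2 + diff(traj$thorax_y)^2)
}

#' Optional boxcar smoothing of raw coordinates
#'
#' Raw digitized coordinates are used unsmoothed by default throughout the
#' package; this helper applies a centred moving average (reflecting at the
#' ends) for users who want it.
#'
#' @param traj an [trajectory()] object.
#' @param window odd window length in frames.
#' @return a smoothed [trajectory()] object.
#' @export
smooth_trajectory <- function(traj, window = 5L) {
  stopifnot(window >= 1L, window %% 2L == 1L)
  if (window == 1L) return(traj)
  sm <- function(v) boxcar(v, window)
  trajectory(frame = traj$frame,
             head_x = sm(traj$head_x), head_y = sm(traj$head_y),
             thorax_x = sm(traj$thorax_x), thorax_y = sm(traj$thorax_y),
             frame_rate = frame_rate_of(traj),
             label = attr(traj, "label"), ant_id = attr(traj, "ant_id"))
}

## Centred moving average with edge reflection; window odd.
boxcar <- function(v, window) {
  h <- (window - 1L) %/% 2L
  n <- length(v)
  if (h == 0L || n < window) return(v)
  pad <- c(v[(h + 1L):2L], v, v[(n - 1L):(n - h)])
  as.numeric(stats::filter(pad, rep(1 / window, window), sides = 2L))[(h + 1L):(h + n)]
}
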