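#' Construct a panorama
#'
#' An equirectangular grayscale panorama: a matrix with rows spanning
#' elevation (top row = up) and columns spanning azimuth, intensities in
#' `[0, 1]`. Columns map linearly to azimuth; `heading_of_col0` records the
#' world bearing (degrees) that the first column faces.
#'
#' @param intensity numeric matrix in `[0, 1]`.
#' @param heading_of_col0 azimuth (degrees) of column 1.
#' @return a `panorama` object.
#' @export
panorama <- function(intensity, heading_of_col0 = 0) {
  if (!is.matrix(intensity) || !is.numeric(intensity))
    stop("intensity must be a numeric matrix", call. = FALSE)
  if (!all(is.finite(intensity)) || min(intensity) < 0 || max(intensity) > 1)
    stop("intensities must be finite and in [0, 1]", call. = FALSE)
  if (360 %% ncol(intensity) != 0 && ncol(intensity) %% 360 != 0)
    stop("number of columns must divide or be a multiple of 360", call. = FALSE)
  structure(list(intensity = intensity,
                 azimuth_deg_per_col = 360 / ncol(intensity),
                 heading_of_col0 = wrap360(heading_of_col0)),
            class = "panorama")
}

#' @export
print.panorama <- function(x, ...) {
  cat(sprintf("<panorama> %d x %d (%.3g deg/col), col 1 faces %.1f deg\n",
              nrow(x$intensity), ncol(x$intensity), x$azimuth_deg_per_col,
              x$heading_of_col0))
  invisible(x)
}

#' Read an image file as a grayscale panorama
#'
#' Reads a PNG, converts RGB to luminance (0.299 R + 0.587 G + 0.114 B), and
#' optionally rescales intensities to span `[0, 1]` per image.
#'
#' @param path PNG file path.
#' @param heading_of_col0 world bearing of the first column (degrees).
#' @param normalize rescale to full `[0, 1]` range per image (default TRUE).
#' @return a [panorama()] object.
#' @export
read_panorama <- function(path, heading_of_col0 = 0, normalize = TRUE) {
  img <- png::readPNG(path)
  g <- if (length(dim(img)) == 3L)
    0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L]
  else img
  if (normalize) {
    rng <- range(g)
    if (diff(rng) > 0) g <- (g - rng[1L]) / diff(rng)
  }
  panorama(g, heading_of_col0)
}

#' Write a panorama as a PNG
#'
#' @param p a [panorama()] object.
#' @param path output path.
#' @export
write_panorama <- function(p, path) {
  png::writePNG(p$intensity, path)
  invisible(path)
}

## Roll a panorama's columns so the view rotates by `shift_cols` columns:
## column j of the result shows what column j + shift of the input showed.
roll_panorama <- function(p, shift_cols) {
  nc <- ncol(p$intensity)
  s <- ((shift_cols %% nc) + nc) %% nc
  idx <- ((seq_len(nc) - 1L + s) %% nc) + 1L
  panorama(p$intensity[, idx, drop = FALSE],
           wrap360(p$heading_of_col0 + s * p$azimuth_deg_per_col))
}

#' Rotational image difference function
#'
#' Compares a test panorama with a reference panorama at every 1-degree
#' rotation: for each integer shift s in 0..359, the discrepancy is the
#' root-mean-square pixel intensity difference between the reference and the
#' test panorama rotated by s degrees (`method = "rms"`; mean absolute
#' difference with `method = "mad"`). The minimum of the curve marks the
#' rotation at which the two views match best, and the depth of the curve
#' (mean minus minimum discrepancy) measures how sharp and usable that
#' minimum is.
#'
#' @param reference,test [panorama()] objects of identical shape and azimuth
#'   resolution.
#' @param method `"rms"` (default) or `"mad"`.
#' @return a `rotidf` object: list with `discrepancy` (360 values, one per
#'   degree), `shift_deg` (0..359), `min_value`, `argmin_deg`, `mean_value`,
#'   `median_value`, `depth`, `multiple_minima` flag.
#' @export
rotidf <- function(reference, test, method = c("rms", "mad")) {
  method <- match.arg(method)
  a <- reference$intensity; b <- test$intensity
  if (!all(dim(a) == dim(b)))
    stop("panorama shapes differ; resample explicitly first", call. = FALSE)
  if (reference$azimuth_deg_per_col != test$azimuth_deg_per_col)
    stop("azimuth resolutions differ", call. = FALSE)
  step <- reference$azimuth_deg_per_col
  cols_per_deg <- 1 / step
  if (cols_per_deg != round(cols_per_deg) && step != round(step))
    stop("azimuth resolution must be a whole number of degrees or columns per degree",
         call. = FALSE)
  nc <- ncol(a)
  shifts_deg <- 0:359
  disc <- vapply(shifts_deg, function(s) {
    sc <- s / step
    if (sc != round(sc)) return(NA_real_)
    idx <- ((seq_len(nc) - 1L - as.integer(round(sc))) %% nc) + 1L
    d <- a - b[, idx, drop = FALSE]
    if (method == "rms") sqrt(mean(d^2)) else mean(abs(d))
  }, 0)
  if (anyNA(disc)) {            # coarser than 1 deg/col: evaluate at grid only
    shifts_deg <- shifts_deg[!is.na(disc)]
    disc <- disc[!is.na(disc)]
  }
  mn <- min(disc)
  amins <- shifts_deg[disc == mn]
  structure(list(discrepancy = disc, shift_deg = shifts_deg,
                 min_value = mn, argmin_deg = amins[1L],
                 mean_value = mean(disc), median_value = stats::median(disc),
                 depth = mean(disc) - mn,
                 multiple_minima = length(amins) > 1L,
                 method = method),
            class = "rotidf")
}

#' @export
print.rotidf <- function(x, ...) {
  cat(sprintf("<rotidf> min %.4f at %d deg, mean %.4f, depth %.4f%s\n",
              x$min_value, x$argmin_deg, x$mean_value, x$depth,
              if (x$multiple_minima) " (multiple minima)" else ""))
  invisible(x)
}

#' Best-matching world bearing from a rotIDF
#'
#' The world bearing that the test panorama's best-matching rotation points
#' to: the azimuth of the column that, after the optimal rotation, aligns
#' with the reference's first column. With both panoramas rendered so column
#' 1 faces the nest, a nest-ward match yields the nest bearing.
#'
#' @param result a [rotidf()] object.
#' @param heading_of_col0 world bearing (degrees) of the test panorama's
#'   first column.
#' @return bearing in degrees, with attribute `flagged` when the minimum was
#'   not unique (smallest shift reported) or the curve is flat.
#' @export
best_nest_bearing <- function(result, heading_of_col0 = 0) {
  flat <- result$depth <= .Machine$double.eps
  structure(wrap360(heading_of_col0 + result$argmin_deg),
            flagged = result$multiple_minima || flat)
}

#' Block-mean downsampling of a panorama
#'
#' Reduces a panorama to a target azimuth resolution and row count by
#' averaging equal blocks of pixels; intensities stay in `[0, 1]`.
#'
#' @param p a [panorama()] object.
#' @param az_res target degrees per column; must divide 360 and be a multiple
#'   of the current resolution.
#' @param el_rows target number of rows; must divide the current row count.
#' @return a [panorama()] object.
#' @export
downsample <- function(p, az_res = 1, el_rows = nrow(p$intensity)) {
  if (360 %% az_res != 0)
    stop("az_res must divide 360", call. = FALSE)
  ncol_new <- as.integer(360 / az_res)
  nc <- ncol(p$intensity); nr <- nrow(p$intensity)
  if (nc %% ncol_new != 0L)
    stop("target column count must divide the current one", call. = FALSE)
  if (nr %% el_rows != 0L)
    stop("el_rows must divide the current row count", call. = FALSE)
  cfac <- nc %/% ncol_new; rfac <- nr %/% as.integer(el_rows)
  m <- p$intensity
  # average column blocks then row blocks
  m <- sapply(seq_len(ncol_new), function(j)
    rowMeans(m[, ((j - 1L) * cfac + 1L):(j * cfac), drop = FALSE]))
  m <- t(sapply(seq_len(el_rows), function(i)
    colMeans(m[((i - 1L) * rfac + 1L):(i * rfac), , drop = FALSE])))
  if (el_rows == 1L) m <- matrix(m, nrow = 1L)
  panorama(m, p$heading_of_col0)
}
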