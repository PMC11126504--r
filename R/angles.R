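## Angle helpers shared across the package.
## Internal convention: radians; external (user-facing) angles are degrees.
## Map orientations are measured counterclockwise from North (+y), so an ant
## whose head lies due North of its thorax has orientation 0 and a CCW turn
## increases the angle.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap angles to [0, 360)
#'
#' @param x angles in degrees.
#' @return angles reduced modulo 360 into `[0, 360)`.
#' @export
wrap360 <- function(x) {
  y <- x %% 360
  y[y == 360] <- 0
  y
}

## Wrap radians to (-pi, pi]
wrap_pi <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

## Orientation (degrees CCW from North) of vectors (dx, dy) in map coordinates.
ccw_from_north <- function(dx, dy) {
  wrap360(rad2deg(atan2(dy, dx)) - 90)
}

## Unwrap a degree series: remove +-360 discontinuities by shortest-arc
## accumulation so consecutive differences lie in (-180, 180].
unwrap_deg <- function(x) {
  if (length(x) < 2L) return(x)
  d <- rad2deg(wrap_pi(deg2rad(diff(x))))
  x[1L] + c(0, cumsum(d))
}
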