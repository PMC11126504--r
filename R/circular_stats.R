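#' Construct a heading set
#'
#' A set of final headings (degrees) for one displacement condition, in the
#' nest-relative frame where the nest direction is 0 degrees.
#'
#' @param angles headings in degrees; wrapped to `[0, 360)`.
#' @param condition condition label, e.g. `"2mN"`.
#' @return an object of class `heading_set`.
#' @export
heading_set <- function(angles, condition = "unknown") {
  angles <- as.numeric(angles)
  if (length(angles) < 1L) stop("empty heading set", call. = FALSE)
  if (!all(is.finite(angles))) stop("non-finite heading", call. = FALSE)
  structure(list(angles = wrap360(angles), condition = condition,
                 n = length(angles)),
            class = "heading_set")
}

#' @export
print.heading_set <- function(x, ...) {
  cat(sprintf("<heading_set> %s: n = %d, mean vector %.1f deg (rbar %.2f)\n",
              x$condition, x$n, circ_mean_deg(x$angles), circ_rbar(x$angles)))
  invisible(x)
}

## --- primitives (degrees in, degrees out unless noted) ---------------------

circ_mean_deg <- function(a) {
  r <- deg2rad(a)
  wrap360(rad2deg(atan2(mean(sin(r)), mean(cos(r)))))
}

circ_rbar <- function(a) {
  r <- deg2rad(a)
  sqrt(mean(cos(r))^2 + mean(sin(r))^2)
}

## A1(kappa) = I1(kappa)/I0(kappa), computed on the scaled Bessel functions
## so it is stable for large kappa.
a1 <- function(kappa) {
  besselI(kappa, 1, expon.scaled = TRUE) / besselI(kappa, 0, expon.scaled = TRUE)
}

## ML estimate of the von Mises concentration: solve A1(kappa) = rbar.
## The standard piecewise approximation seeds a uniroot refinement.
a1inv <- function(rbar) {
  if (rbar <= 0) return(0)
  if (rbar >= 1 - 1e-12) return(1e8)
  k0 <- if (rbar < 0.53) 2 * rbar + rbar^3 + 5 * rbar^5 / 6
        else if (rbar < 0.85) -0.4 + 1.39 * rbar + 0.43 / (1 - rbar)
        else 1 / (rbar^3 - 4 * rbar^2 + 3 * rbar)
  lo <- max(k0 / 2, 1e-10); hi <- k0 * 2 + 1
  while (a1(lo) > rbar) lo <- lo / 2
  while (a1(hi) < rbar) hi <- hi * 2
  stats::uniroot(function(k) a1(k) - rbar, c(lo, hi), tol = 1e-12)$root
}

## von Mises log-likelihood at (mu_deg, kappa) for angles a (degrees)
vm_loglik <- function(a, mu_deg, kappa) {
  r <- deg2rad(a - mu_deg)
  sum(kappa * cos(r)) - length(a) * log(2 * pi * besselI(kappa, 0,
                                                        expon.scaled = TRUE)) -
    length(a) * kappa
}

#' Fit a von Mises distribution by maximum likelihood
#'
#' @param h a [heading_set()].
#' @return list with `mu` (degrees), `kappa`, `rbar`, `loglik`.
#' @export
fit_vonmises <- function(h) {
  mu <- circ_mean_deg(h$angles)
  rbar <- circ_rbar(h$angles)
  kappa <- a1inv(rbar)
  list(mu = mu, kappa = kappa, rbar = rbar,
       loglik = vm_loglik(h$angles, mu, kappa))
}

## --- histogram -------------------------------------------------------------

#' 24-wedge circular histogram
#'
#' Counts headings into 24 equal 15-degree wedges, the k-th covering
#' `[15k, 15(k+1))` degrees (half-open bins).
#'
#' @param h a [heading_set()].
#' @return integer vector of 24 counts summing to `h$n`, named by the wedge
#'   lower edges.
#' @export
wedge_histogram <- function(h) {
  bin <- floor(h$angles / 15) %% 24
  counts <- tabulate(bin + 1L, nbins = 24L)
  names(counts) <- as.character(0:23 * 15)
  counts
}

## --- tests -----------------------------------------------------------------

circ_result <- function(...) {
  out <- list(...)
  class(out) <- "circ_test"
  out
}

#' @export
print.circ_test <- function(x, ...) {
  cat("<", x$method, ">\n", sep = "")
  for (nm in setdiff(names(x), "method"))
    if (is.numeric(x[[nm]]) && length(x[[nm]]) == 1L)
      cat(sprintf("  %s = %.4g\n", nm, x[[nm]]))
  invisible(x)
}

#' Rayleigh test of circular uniformity
#'
#' Tests the null of a uniform heading distribution against unimodal
#' clustering, using the mean resultant length: Z = n * rbar^2, with the
#' standard series approximation for the p-value.
#'
#' @param h a [heading_set()] with n >= 2.
#' @return a `circ_test` with `mu`, `rbar`, `z`, `p`, `n`.
#' @export
rayleigh_test <- function(h) {
  if (h$n < 2L) stop("Rayleigh test needs n >= 2", call. = FALSE)
  n <- h$n
  rbar <- circ_rbar(h$angles)
  z <- n * rbar^2
  p <- exp(-z) * (1 + (2 * z - z^2) / (4 * n) -
                    (24 * z - 132 * z^2 + 76 * z^3 - 9 * z^4) / (288 * n^2))
  circ_result(method = "Rayleigh test", mu = circ_mean_deg(h$angles),
              rbar = rbar, z = z, p = min(max(p, 0), 1), n = n)
}

#' V test of clustering toward a known direction
#'
#' A uniformity test with power concentrated toward a prespecified target
#' direction: V = rbar * cos(mu - target), u = V * sqrt(2n), with a one-sided
#' normal approximation for the p-value.
#'
#' @param h a [heading_set()] with n >= 2.
#' @param target target direction in degrees (default 0, the nest direction).
#' @return a `circ_test` with `mu`, `rbar`, `v`, `u`, `p`, `n`.
#' @export
v_test <- function(h, target = 0) {
  if (h$n < 2L) stop("V test needs n >= 2", call. = FALSE)
  mu <- circ_mean_deg(h$angles)
  rbar <- circ_rbar(h$angles)
  v <- rbar * cos(deg2rad(mu - target))
  u <- v * sqrt(2 * h$n)
  circ_result(method = "V test", mu = mu, rbar = rbar, v = v, u = u,
              p = stats::pnorm(u, lower.tail = FALSE), n = h$n,
              target = target)
}

#' Mean-direction confidence interval and target inclusion
#'
#' 95% confidence interval of the mean direction by the large-sample circular
#' dispersion method (delta = (1 - rho2) / (2 rbar^2), half-width
#' asin(q * sqrt(delta / n)) with q a Student-t quantile on n - 1 df, the
#' small-sample correction for estimating the dispersion from the data), with
#' a seeded percentile bootstrap fallback for weakly concentrated samples
#' (rbar below `boot_below`). Returns whether the target direction lies
#' inside the interval, wrap-aware.
#'
#' @param h a [heading_set()] with n >= 5.
#' @param target direction tested for inclusion (degrees; default 0 = nest).
#' @param conf confidence level (default 0.95).
#' @param boot_below rbar threshold under which the bootstrap is used.
#' @param n_boot bootstrap resamples.
#' @param seed integer seed for the bootstrap.
#' @return a `circ_test` with `mu`, `rbar`, `ci_lo`, `ci_hi` (degrees),
#'   `contains_target` (logical), `method_ci`, `degenerate`.
#' @export
mean_ci_test <- function(h, target = 0, conf = 0.95, boot_below = 0.45,
                         n_boot = 2000, seed = 1L) {
  if (h$n < 5L) stop("mean-direction CI needs n >= 5", call. = FALSE)
  mu <- circ_mean_deg(h$angles)
  rbar <- circ_rbar(h$angles)
  zq <- stats::qt(1 - (1 - conf) / 2, h$n - 1)
  if (rbar < 1e-8) {
    return(circ_result(method = "mean-direction CI", mu = mu, rbar = rbar,
                       ci_lo = 0, ci_hi = 360 - 1e-9, contains_target = TRUE,
                       method_ci = "degenerate", degenerate = TRUE))
  }
  if (all(h$angles == h$angles[1L])) {
    # zero dispersion: zero-width interval exactly at the common angle
    lo <- hi <- mu <- h$angles[1L]
    meth <- "dispersion"
  } else if (rbar >= boot_below) {
    r2 <- deg2rad(h$angles - mu)
    rho2 <- sqrt(mean(cos(2 * r2))^2 + mean(sin(2 * r2))^2)
    delta <- (1 - rho2) / (2 * rbar^2)    # circular dispersion
    s <- sqrt(delta / h$n)
    if (zq * s >= 1) {
      lo <- wrap360(mu - 180); hi <- wrap360(mu + 180 - 1e-9)
      meth <- "dispersion(saturated)"
    } else {
      half <- rad2deg(asin(zq * s))
      lo <- wrap360(mu - half); hi <- wrap360(mu + half)
      meth <- "dispersion"
    }
  } else {
    set.seed(as.integer(seed))
    mus <- vapply(seq_len(n_boot), function(i) {
      a <- h$angles[sample.int(h$n, h$n, replace = TRUE)]
      circ_mean_deg(a)
    }, 0)
    dev <- rad2deg(wrap_pi(deg2rad(mus - mu)))  # deviations in (-180, 180]
    qs <- stats::quantile(dev, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                          names = FALSE, type = 7)
    lo <- wrap360(mu + qs[1L]); hi <- wrap360(mu + qs[2L])
    meth <- "bootstrap"
  }
  circ_result(method = "mean-direction CI", mu = mu, rbar = rbar,
              ci_lo = lo, ci_hi = hi,
              contains_target = angle_in_arc(target, lo, hi),
              method_ci = meth, degenerate = FALSE)
}

#' Is an angle inside a circular arc?
#'
#' Wrap-aware inclusion: the arc runs counterclockwise from `lo` to `hi`
#' (both inclusive), so an interval like (335.67, 5.01) degrees contains 0.
#'
#' @param a angle (degrees).
#' @param lo,hi arc endpoints (degrees).
#' @return logical.
#' @export
angle_in_arc <- function(a, lo, hi) {
  a <- wrap360(a); lo <- wrap360(lo); hi <- wrap360(hi)
  if (lo <= hi) a >= lo & a <= hi
  else a >= lo | a <= hi
}

#' Watson-Williams test for equal mean directions
#'
#' Two-sample F test of a common mean direction under von Mises assumptions
#' with shared concentration, using the standard correction factor
#' 1 + 3/(8 kappa_hat). A warning flag is set when the pooled mean resultant
#' length is below 0.45 (test assumption strained).
#'
#' @param h1,h2 [heading_set()] objects, each with n >= 5.
#' @return a `circ_test` with `f`, `df1`, `df2`, `p`, `kappa`, `low_rbar_flag`.
#' @export
watson_williams_test <- function(h1, h2) {
  if (h1$n < 5L || h2$n < 5L)
    stop("Watson-Williams test needs n >= 5 per sample", call. = FALSE)
  n1 <- h1$n; n2 <- h2$n; n <- n1 + n2
  r1 <- n1 * circ_rbar(h1$angles)
  r2 <- n2 * circ_rbar(h2$angles)
  all_a <- c(h1$angles, h2$angles)
  r <- n * circ_rbar(all_a)
  rw <- (r1 + r2) / n
  kappa <- a1inv(rw)
  g <- 1 + 3 / (8 * kappa)
  f <- g * (n - 2) * (r1 + r2 - r) / (n - (r1 + r2))
  f <- max(f, 0)
  circ_result(method = "Watson-Williams test", f = f, df1 = 1, df2 = n - 2,
              p = stats::pf(f, 1, n - 2, lower.tail = FALSE), kappa = kappa,
              low_rbar_flag = rw < 0.45)
}

#' Single-sample von Mises likelihood-ratio test of mean direction
#'
#' Fits a von Mises distribution by maximum likelihood with the mean free,
#' and again with the mean fixed at `target` (concentration re-estimated
#' under the constraint); the likelihood-ratio statistic
#' chi2 = 2 (l_free - l_constrained) is referred to a chi-square distribution
#' with 1 df. The reported `kappa` is the unconstrained estimate.
#'
#' @param h a [heading_set()] with n >= 5.
#' @param target hypothesised mean direction (degrees).
#' @return a `circ_test` with `mu`, `kappa`, `chi2`, `p`, `degenerate`.
#' @export
vonmises_lrt <- function(h, target = 0) {
  if (h$n < 5L) stop("von Mises LRT needs n >= 5", call. = FALSE)
  free <- fit_vonmises(h)
  # constrained fit: mu = target; kappa maximises sum(kappa cos(a - target))
  # - n log(2 pi I0(kappa)), i.e. A1(kappa) = mean cos(a - target), truncated
  # at 0 when the constrained resultant component is negative
  cbar <- mean(cos(deg2rad(h$angles - target)))
  k0 <- if (cbar <= 0) 0 else a1inv(cbar)
  l0 <- vm_loglik(h$angles, target, k0)
  chi2 <- max(2 * (free$loglik - l0), 0)
  circ_result(method = "von Mises LRT", mu = free$mu, kappa = free$kappa,
              chi2 = chi2, p = stats::pchisq(chi2, 1, lower.tail = FALSE),
              degenerate = free$rbar < 1e-8, target = target)
}

#' Final heading of a displacement test
#'
#' The orientation of the thorax-to-head vector on the last frame inside the
#' recording arena, expressed relative to the bearing from the release point
#' to the nest (nest direction = 0 degrees), wrapped to `[0, 360)`. With the
#' nest at the origin and a release 2 m North of it, a head pointing due South
#' reads 0 and a head pointing due East reads 270.
#'
#' @param traj an [trajectory()] object; coordinates in the frame of the
#'   displacement recording with the nest at the origin.
#' @param release_point numeric length-2, release position (cm).
#' @param arena_radius radius (cm) of the recording area around the release
#'   point; the exit frame is the last frame with the thorax inside it.
#' @return final heading in degrees with attribute `exited` (`FALSE` when the
#'   ant never left the arena and the last frame was used).
#' @export
final_heading <- function(traj, release_point = c(0, 0), arena_radius = 50) {
  d <- sqrt((traj$thorax_x - release_point[1L])^2 +
            (traj$thorax_y - release_point[2L])^2)
  outside <- which(d > arena_radius)
  exited <- length(outside) > 0L
  last_in <- if (exited) max(outside[1L] - 1L, 1L) else nrow(traj)
  head_dir <- ccw_from_north(traj$head_x[last_in] - traj$thorax_x[last_in],
                             traj$head_y[last_in] - traj$thorax_y[last_in])
  nest_dir <- ccw_from_north(-release_point[1L], -release_point[2L])
  structure(wrap360(nest_dir - head_dir), exited = exited)
}

#' Table-style summary of the circular test battery for one condition
#'
#' Runs the mean vector, Rayleigh, V and von Mises likelihood-ratio tests plus
#' the mean-direction CI on one heading set, toward a target direction.
#'
#' @param h a [heading_set()].
#' @param target target direction in degrees (0 = nest).
#' @param seed seed for the bootstrap CI fallback.
#' @return one-row data frame with columns `condition`, `n`, `mu`, `rbar`,
#'   `ci_lo`, `ci_hi`, `ci_contains_target`, `rayleigh_z`, `rayleigh_p`,
#'   `v_u`, `v_p`, `lrt_chi2`, `lrt_kappa`, `lrt_p`.
#' @export
heading_battery <- function(h, target = 0, seed = 1L) {
  ray <- rayleigh_test(h)
  vt <- v_test(h, target)
  ci <- mean_ci_test(h, target, seed = seed)
  lrt <- vonmises_lrt(h, target)
  data.frame(condition = h$condition, n = h$n, mu = ray$mu, rbar = ray$rbar,
             ci_lo = ci$ci_lo, ci_hi = ci$ci_hi,
             ci_contains_target = ci$contains_target,
             rayleigh_z = ray$z, rayleigh_p = ray$p,
             v_u = vt$u, v_p = vt$p,
             lrt_chi2 = lrt$chi2, lrt_kappa = lrt$kappa, lrt_p = lrt$p)
}
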