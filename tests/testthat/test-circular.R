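test_that("wedge histogram uses half-open 15-degree bins", {
  h <- heading_set(c(0, 14.9))
  expect_equal(unname(wedge_histogram(h)), c(2, rep(0, 23)))

  h <- heading_set(15)
  expect_equal(unname(wedge_histogram(h))[2], 1)

  h <- heading_set(7.5 + 15 * (0:23))
  expect_equal(unname(wedge_histogram(h)), rep(1, 24))
  expect_equal(sum(wedge_histogram(h)), h$n)
})

test_that("Rayleigh test matches its closed forms", {
  h <- heading_set(rep(37, 20))
  r <- rayleigh_test(h)
  expect_equal(r$rbar, 1)
  expect_equal(r$z, 20)
  expect_equal(r$mu, 37)

  h <- heading_set(45 * (0:7))
  r <- rayleigh_test(h)
  expect_equal(r$rbar, 0, tolerance = 1e-12)
  expect_equal(r$z, 0, tolerance = 1e-12)
  expect_gt(r$p, 0.99)

  expect_error(rayleigh_test(heading_set(10)), "n >= 2")
})

test_that("Rayleigh test has high power on concentrated samples", {
  set.seed(101)
  rej <- 0
  for (i in 1:1000) {
    h <- heading_set(rvonmises_deg(20, 0, 2))
    rej <- rej + (rayleigh_test(h)$p < 0.05)
  }
  expect_gte(rej / 1000, 0.95)
})

test_that("V test matches its closed forms", {
  h <- heading_set(rep(80, 20))
  v <- v_test(h, target = 80)
  expect_equal(v$v, 1)
  expect_equal(v$u, sqrt(40), tolerance = 1e-12)

  # mean exactly 90 degrees from the target
  h <- heading_set(c(80, 100))        # mean 90
  v <- v_test(h, target = 0)
  expect_equal(v$v, 0, tolerance = 1e-12)
  expect_equal(v$u, 0, tolerance = 1e-12)
})

test_that("mean-direction CI handles degenerate and wrapped cases", {
  h <- heading_set(rep(123, 10))
  ci <- mean_ci_test(h, target = 123)
  expect_equal(ci$ci_lo, 123)
  expect_equal(ci$ci_hi, 123)
  expect_true(ci$contains_target)
  expect_false(mean_ci_test(h, target = 0)$contains_target)

  # wrap-aware inclusion for an interval straddling 0 degrees
  expect_true(angle_in_arc(0, 335.67, 5.01))
  expect_false(angle_in_arc(180, 335.67, 5.01))
  expect_true(angle_in_arc(350, 335.67, 5.01))
})

test_that("Watson-Williams test separates means and nulls", {
  set.seed(7)
  a <- rvonmises_deg(20, 0, 8)
  h1 <- heading_set(a)
  h2 <- heading_set(a)          # identical copy
  w <- watson_williams_test(h1, h2)
  expect_equal(w$f, 0, tolerance = 1e-10)
  expect_gt(w$p, 0.99)

  rej <- 0
  for (i in 1:200) {
    h1 <- heading_set(rvonmises_deg(20, 0, 8))
    h2 <- heading_set(rvonmises_deg(20, 90, 8))
    rej <- rej + (watson_williams_test(h1, h2)$p < 0.01)
  }
  expect_gte(rej / 200, 0.99)
})

test_that("von Mises LRT equals a numeric profile-likelihood oracle", {
  set.seed(15)
  a <- round(rvonmises_deg(10, 40, 2), 3)
  h <- heading_set(a)
  res <- vonmises_lrt(h, target = 0)

  # free fit: profile over kappa at the ML mean; constrained: mu fixed at 0
  mu_hat <- res$mu
  lf <- optimize(function(k) oracle_vm_loglik(a, mu_hat, k), c(0, 100),
                 maximum = TRUE, tol = 1e-10)$objective
  l0 <- optimize(function(k) oracle_vm_loglik(a, 0, k), c(0, 100),
                 maximum = TRUE, tol = 1e-10)$objective
  expect_equal(res$chi2, 2 * (lf - l0), tolerance = 1e-8)
})

test_that("von Mises LRT behaves at the null and under shifts", {
  set.seed(16)
  a <- rvonmises_deg(30, 0, 3)
  h <- heading_set(a)
  res0 <- vonmises_lrt(h, target = vonmises_lrt(h, 0)$mu)
  expect_equal(res0$chi2, 0, tolerance = 1e-8)
  expect_equal(res0$p, 1, tolerance = 1e-6)

  rej <- 0
  for (i in 1:200) {
    h <- heading_set(rvonmises_deg(20, 60, 2))
    rej <- rej + (vonmises_lrt(h, 0)$p < 0.05)
  }
  expect_gte(rej / 200, 0.90)
})

test_that("circular statistics are rotation-equivariant", {
  set.seed(31)
  a <- rvonmises_deg(25, 120, 2)
  h <- heading_set(a)
  r0 <- rayleigh_test(h)
  k0 <- fit_vonmises(h)$kappa
  for (delta in c(13.7, 90, 251.2)) {
    h2 <- heading_set(a + delta)
    r2 <- rayleigh_test(h2)
    expect_equal(r2$rbar, r0$rbar, tolerance = 1e-10)
    expect_equal(r2$z, r0$z, tolerance = 1e-10)
    expect_equal(wrap360(r2$mu - delta), r0$mu, tolerance = 1e-8)
    expect_equal(fit_vonmises(h2)$kappa, k0, tolerance = 1e-8)
  }
})

test_that("final heading follows the nest-relative sign convention", {
  # released 2 m North of the nest; arena of 50 cm around the release point
  mk <- function(hdx, hdy) {
    tx <- c(0, 0, 0, 0); ty <- c(200, 220, 240, 260)
    make_traj(tx, ty, hx = tx + hdx, hy = ty + hdy)
  }
  # head due South on the exit frame -> 0 (facing the nest)
  expect_equal(as.numeric(final_heading(mk(0, -1), c(0, 200), 50)), 0)
  # head due North -> 180
  expect_equal(as.numeric(final_heading(mk(0, 1), c(0, 200), 50)), 180)
  # head due East -> 270
  expect_equal(as.numeric(final_heading(mk(1, 0), c(0, 200), 50)), 270)

  # never leaves the arena: flagged, last frame used
  tr <- make_traj(c(0, 0), c(200, 210))
  fh <- final_heading(tr, c(0, 200), 50)
  expect_false(attr(fh, "exited"))
})
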