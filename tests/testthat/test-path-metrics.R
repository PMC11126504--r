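test_that("convex hull area matches elementary shapes", {
  expect_equal(convex_hull_area(make_traj(c(0, 1, 1, 0), c(0, 0, 1, 1))), 1)
  expect_equal(convex_hull_area(make_traj(c(0, 1, 2), c(0, 0, 0))), 0)
  expect_equal(convex_hull_area(make_traj(c(0, 2, 0), c(0, 0, 2))), 2)
  expect_error(convex_hull_area(make_traj(c(0, 1), c(0, 0))), "3 points")
})

test_that("convex hull area is invariant under permutation and rotation", {
  tr <- random_traj(50, seed = 21)
  a0 <- convex_hull_area(tr)
  set.seed(1)
  perm <- sample.int(50)
  expect_equal(convex_hull_area(make_traj(tr$thorax_x[perm],
                                          tr$thorax_y[perm])), a0,
               tolerance = 1e-9)
  th <- 0.7
  rx <- cos(th) * tr$thorax_x - sin(th) * tr$thorax_y
  ry <- sin(th) * tr$thorax_x + cos(th) * tr$thorax_y
  expect_equal(convex_hull_area(make_traj(rx, ry)), a0, tolerance = 1e-9)
})

test_that("maximum displacement is the farthest thorax distance from the nest", {
  expect_equal(max_displacement(make_traj(c(0, 0, 0), c(0, 3, 1))), 3)
  expect_equal(max_displacement(make_traj(c(0, 0), c(0.5, 0.5))), 0.5)
  lw <- gen_learning_walk(walk_gen_params("learning", loop_radius = 20, seed = 3))
  expect_equal(max_displacement(lw$traj), lw$truth$max_excursion,
               tolerance = 1e-9)
})

test_that("duration is elapsed time over the tracked frames", {
  expect_equal(duration(make_traj(rep(0, 251), seq_len(251))), 10)
  expect_equal(duration(make_traj(c(0, 1), c(0, 0))), 0.04)
})

test_that("mean speed excludes sustained stops", {
  # constant 1 cm/frame at 25 fps
  expect_equal(mean_speed(make_traj(0:100, rep(0, 101))), 25)

  # 100 moving frames at 2 cm/s then 100 motionless frames
  tx <- c(seq(0, by = 0.08, length.out = 101), rep(8, 100))
  expect_equal(mean_speed(make_traj(tx, rep(0, 201))), 2)

  # all frames stopped: 0 with warning
  expect_warning(v <- mean_speed(make_traj(rep(0, 50), rep(0, 50),
                                           hx = rep(1, 50), hy = rep(0, 50))),
                 "stopped")
  expect_equal(v, 0)

  # a commanded 5 cm/s walk with an inserted 1 s stop
  tx <- cumsum(c(0, rep(5 / 25, 100), rep(0, 25), rep(5 / 25, 100)))
  expect_equal(mean_speed(make_traj(tx, rep(0, length(tx)))), 5,
               tolerance = 0.1 / 5)
})

test_that("orientation series is CCW from North and unwrapped", {
  # head always due North of the thorax
  tr <- make_traj(0:10, rep(0, 11))
  expect_equal(orientation_series(tr), rep(0, 11))

  # on-the-spot CCW rotation at 15 deg/frame unwraps without jumps
  ang <- (0:30) * 15
  hx <- 0 + cos((ang + 90) * pi / 180)
  hy <- 0 + sin((ang + 90) * pi / 180)
  tr <- make_traj(rep(0, 31), rep(0, 31), hx = hx, hy = hy)
  o <- orientation_series(tr)
  expect_equal(diff(o), rep(15, 30), tolerance = 1e-9)
  expect_gte(max(o) - min(o), 360)
})

test_that("mean orientation angular velocity uses absolute change", {
  ang <- (0:30) * 15
  hx <- cos((ang + 90) * pi / 180); hy <- sin((ang + 90) * pi / 180)
  tr <- make_traj(rep(0, 31), rep(0, 31), hx = hx, hy = hy)
  expect_equal(mean_orient_angular_velocity(tr), 375, tolerance = 1e-9)

  tr <- make_traj(0:10, rep(0, 11))
  expect_equal(mean_orient_angular_velocity(tr), 0)

  # sinusoidal head oscillation: mean |d orient/dt| = 4 * amplitude * freq
  A <- 20; f <- 1; fps <- 100
  tt <- seq(0, 10, by = 1 / fps)
  ang <- A * sin(2 * pi * f * tt)
  tr <- make_traj(tt, rep(0, length(tt)),
                  hx = tt + cos((ang + 90) * pi / 180),
                  hy = sin((ang + 90) * pi / 180), fps = fps)
  expect_equal(mean_orient_angular_velocity(tr), 4 * A * f,
               tolerance = 0.05 * 4 * A * f)
})

test_that("straightness matches closed forms and is bounded", {
  expect_equal(straightness(make_traj(c(0, 1, 2), c(0, 0, 0))), 1)
  expect_equal(straightness(make_traj(c(0, 1, 1), c(0, 0, 1))), sqrt(2) / 2)
  sq <- make_traj(c(0, 1, 1, 0, 0), c(0, 0, 1, 1, 0))
  expect_equal(straightness(sq), 0)
  expect_error(straightness(make_traj(c(0, 0), c(0, 0),
                                      hx = c(1, 1), hy = c(0, 0))),
               "zero path")
})

test_that("inserting a detour never increases straightness", {
  for (seed in 1:20) {
    tr <- random_traj(15, seed = seed)
    s0 <- straightness(tr)
    k <- 7L
    tx <- append(tr$thorax_x, tr$thorax_x[k] + 2, after = k)
    ty <- append(tr$thorax_y, tr$thorax_y[k] - 3, after = k)
    expect_lte(straightness(make_traj(tx, ty)), s0 + 1e-12)
  }
})

test_that("sinuosity follows the tortuosity formula", {
  # perfectly straight equal steps: limiting value 0
  s <- sinuosity(make_traj(0:10, rep(0, 11)))
  expect_equal(as.numeric(s), 0)
  expect_true(attr(s, "limit"))

  # unit steps alternating +-90 deg turns: p = 1, c = 0, b = 0 -> S = 2
  tx <- c(0, 1, 1, 2, 2, 3, 3)
  ty <- c(0, 0, 1, 1, 2, 2, 3)
  expect_equal(as.numeric(sinuosity(make_traj(tx, ty))), 2, tolerance = 1e-12)
})

test_that("sinuosity and emax equal brute-force oracles on random paths", {
  for (seed in 1:100) {
    tr <- random_traj(50, seed = 1000 + seed)
    expect_equal(as.numeric(sinuosity(tr)),
                 oracle_sinuosity(tr$thorax_x, tr$thorax_y),
                 tolerance = 1e-12)
    expect_equal(as.numeric(emax(tr)),
                 oracle_emax(tr$thorax_x, tr$thorax_y), tolerance = 1e-12)
  }
})

test_that("emax handles its closed forms and the straight-path guard", {
  # beta = 0: alternating +-90 deg turns
  tx <- c(0, 1, 1, 2, 2); ty <- c(0, 0, 1, 1, 2)
  expect_equal(as.numeric(emax(make_traj(tx, ty))), 0, tolerance = 1e-12)

  e <- emax(make_traj(0:5, rep(0, 6)))
  expect_true(is.infinite(e))
  expect_true(attr(e, "infinite"))
})

test_that("metrics obey the coordinate-scale contract", {
  tr <- random_traj(60, seed = 77)
  tr2 <- make_traj(2 * tr$thorax_x, 2 * tr$thorax_y)
  expect_equal(convex_hull_area(tr2), 4 * convex_hull_area(tr),
               tolerance = 1e-9)
  expect_equal(max_displacement(tr2), 2 * max_displacement(tr))
  expect_equal(mean_speed(tr2), 2 * mean_speed(tr))
  expect_equal(straightness(tr2), straightness(tr), tolerance = 1e-12)
  expect_equal(as.numeric(emax(tr2)), as.numeric(emax(tr)), tolerance = 1e-12)
  expect_equal(as.numeric(sinuosity(tr2)),
               as.numeric(sinuosity(tr)) / sqrt(2), tolerance = 1e-12)
})
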