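test_that("generators are deterministic under a fixed seed", {
  p <- walk_gen_params("learning", seed = 44, n_scan_bouts = 2)
  w1 <- gen_learning_walk(p); w2 <- gen_learning_walk(p)
  expect_identical(w1$traj, w2$traj)
  expect_identical(w1$truth, w2$truth)

  e1 <- gen_excavation_trip(walk_gen_params("excavation", seed = 45))
  e2 <- gen_excavation_trip(walk_gen_params("excavation", seed = 45))
  expect_identical(e1$traj, e2$traj)

  h1 <- gen_headings(15, 30, 2, seed = 46)
  h2 <- gen_headings(15, 30, 2, seed = 46)
  expect_identical(h1$angles, h2$angles)
})

test_that("learning walks satisfy their construction contract", {
  for (seed in 1:10) {
    lw <- gen_learning_walk(walk_gen_params("learning", seed = seed))
    tr <- lw$traj
    n <- nrow(tr)
    # starts and ends within 1 cm of the nest
    expect_lt(sqrt(tr$thorax_x[1]^2 + tr$thorax_y[1]^2), 1)
    expect_lt(sqrt(tr$thorax_x[n]^2 + tr$thorax_y[n]^2), 1)
    # confined near the nest, positive hull area
    expect_lte(max_displacement(tr), 30)
    expect_gt(convex_hull_area(tr), 0)
  }
  # without scan bouts, duration tracks loop length / commanded speed
  for (seed in 1:5) {
    lw <- gen_learning_walk(walk_gen_params("learning", seed = seed,
                                            n_scan_bouts = 0))
    expect_equal(duration(lw$traj),
                 lw$truth$path_length / lw$truth$commanded_speed,
                 tolerance = 0.1)
  }
  expect_error(gen_learning_walk(walk_gen_params("learning",
                                                 loop_radius = 40)),
               "exceeds")
})

test_that("excavation trips deposit sand at 5-10 cm and return", {
  dd <- sapply(1:200, function(s)
    gen_excavation_trip(walk_gen_params("excavation", seed = s))$truth$drop_distance)
  expect_true(all(dd >= 5 & dd <= 10))

  for (seed in 1:5) {
    ex <- gen_excavation_trip(walk_gen_params("excavation", seed = seed))
    tr <- ex$traj
    n <- nrow(tr)
    expect_lt(sqrt(tr$thorax_x[n]^2 + tr$thorax_y[n]^2), 1)
    expect_equal(max_displacement(tr), ex$truth$max_excursion)
    # outbound leg is nearly straight
    nf <- ex$truth$outbound_frames
    out <- make_traj(tr$thorax_x[1:nf], tr$thorax_y[1:nf])
    expect_gte(straightness(out), 0.98)
  }
})

test_that("commanded speed is realized on noise-free walks", {
  for (seed in 1:8) {
    lw <- gen_learning_walk(walk_gen_params("learning", seed = seed))
    expect_equal(mean_speed(lw$traj), lw$truth$commanded_speed,
                 tolerance = 0.02)
    ex <- gen_excavation_trip(walk_gen_params("excavation", seed = seed))
    expect_equal(mean_speed(ex$traj), ex$truth$commanded_speed,
                 tolerance = 0.02)
  }
})

test_that("heading generator covers the uniform and concentrated limits", {
  h <- gen_headings(400, 90, 500, seed = 9)
  dev <- abs(((h$angles - 90 + 180) %% 360) - 180)
  expect_true(all(dev <= 10))

  set.seed(77)
  notrej <- 0
  for (i in 1:200) {
    h <- gen_headings(50, 0, 0, seed = 7000 + i)
    notrej <- notrej + (rayleigh_test(h)$p > 0.05)
  }
  expect_gte(notrej / 200, 0.88)
})

test_that("population effect directions match the study design", {
  n <- 25
  lw_m <- t(sapply(1:n, function(s) {
    tr <- gen_learning_walk(walk_gen_params("learning", seed = s))$traj
    c(convex_hull_area(tr), duration(tr), mean_speed(tr))
  }))
  ex_m <- t(sapply(1:n, function(s) {
    tr <- gen_excavation_trip(walk_gen_params("excavation", seed = s))$traj
    c(convex_hull_area(tr), duration(tr), mean_speed(tr))
  }))
  expect_gt(mean(lw_m[, 1]), mean(ex_m[, 1]))   # area
  expect_gt(mean(lw_m[, 2]), mean(ex_m[, 2]))   # duration
  expect_lt(mean(lw_m[, 3]), mean(ex_m[, 3]))   # speed
})

test_that("the experiment bundle writes a complete reproducible file tree", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  b1 <- gen_experiment(d1, n_ants = 4, master_seed = 77, render = FALSE)
  gen_experiment(d2, n_ants = 4, master_seed = 77, render = FALSE)

  files <- list.files(file.path(d1, "trajectories"))
  expect_length(files, 4 * 4)

  # byte-identical re-run under the same master seed
  for (f in files) {
    expect_identical(readLines(file.path(d1, "trajectories", f)),
                     readLines(file.path(d2, "trajectories", f)))
  }
  expect_identical(readLines(file.path(d1, "headings.csv")),
                   readLines(file.path(d2, "headings.csv")))

  gt <- jsonlite::read_json(file.path(d1, "ground_truth.json"))
  expect_length(gt$walks, 16)
  # every inserted scanning bout is listed
  lw_truth <- gt$walks[grepl("_LW$", names(gt$walks))]
  for (w in lw_truth) expect_gte(length(w$bouts), 1)

  # the heading CSV is readable by the displacement pipeline
  hs <- utils::read.csv(file.path(d1, "headings.csv"))
  expect_setequal(unique(hs$condition), c("2mN", "2mE", "4mN", "4mE"))
})
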