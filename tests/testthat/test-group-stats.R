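walk_table <- function(n_ants, means, sd_within, seed) {
  # means: named per-condition population means; within-ant noise sd_within
  set.seed(seed)
  conds <- names(means)
  do.call(rbind, lapply(seq_len(n_ants), function(a)
    data.frame(ant_id = paste0("a", a), condition = conds,
               value = unlist(means) + rnorm(length(conds), 0, sd_within))))
}

test_that("contrast coefficients are orthogonal and zero-sum", {
  m <- helmert_contrasts(c("LW", "E1", "E2", "E3"))
  expect_equal(dim(m), c(3L, 4L))
  expect_equal(rowSums(m), c(contrast1 = 0, contrast2 = 0, contrast3 = 0))
  expect_equal(sum(m[1, ] * m[2, ]), 0)
  expect_equal(sum(m[1, ] * m[3, ]), 0)
  expect_equal(sum(m[2, ] * m[3, ]), 0)
  # contrast 1 is the learning walk against the mean of the excavation trips
  v <- c(LW = 10, E1 = 2, E2 = 4, E3 = 6)
  expect_equal(sum(m[1, ] * v), 10 - mean(c(2, 4, 6)))
  # contrast 3 compares excavation trips 2 and 3
  expect_equal(sum(m[3, ] * v), 4 - 6)
  expect_error(helmert_contrasts(c("a", "b", "c")), "4 levels")
})

test_that("repeated-measures contrasts match per-ant hand arithmetic", {
  tab <- data.frame(
    ant_id = rep(c("a1", "a2", "a3", "a4"), each = 4),
    condition = rep(c("LW", "E1", "E2", "E3"), 4),
    value = c(10, 2, 3, 4,   8, 1, 2, 3,   12, 4, 3, 5,   9, 2, 2, 2))
  cm <- helmert_contrasts()
  r <- repeated_contrast_test(tab, "value", cm[1, ], conditions = colnames(cm))
  hand <- c(10 - 3, 8 - 2, 12 - 4, 9 - 2)
  expect_equal(r$estimate, mean(hand), tolerance = 1e-12)
  tt <- t.test(hand)
  expect_equal(r$t, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(r$p, tt$p.value, tolerance = 1e-10)
  expect_equal(r$f, r$t^2)
  expect_equal(r$df, 3)
})

test_that("identical conditions give a null contrast", {
  tab <- walk_table(10, c(LW = 5, E1 = 5, E2 = 5, E3 = 5), 0, seed = 1)
  r <- repeated_contrast_test(tab, "value", helmert_contrasts()[1, ])
  expect_equal(r$estimate, 0)
  expect_equal(r$p, 1)
})

test_that("ants with incomplete conditions are dropped with a warning", {
  tab <- walk_table(5, c(LW = 5, E1 = 4, E2 = 4, E3 = 4), 0.5, seed = 2)
  tab <- tab[-2, ]   # remove one condition of ant 1
  expect_warning(r <- repeated_contrast_test(tab, "value",
                                             helmert_contrasts()[1, ]),
                 "dropped")
  expect_equal(r$n_ants, 4)
  tiny <- tab[tab$ant_id %in% c("a1", "a2"), ]
  expect_warning(expect_error(
    repeated_contrast_test(tiny, "value", helmert_contrasts()[1, ]),
    "fewer than 3"))
})

test_that("Welch ANOVA matches oneway heteroscedastic theory", {
  g <- list(c(1, 2, 3, 4), c(2, 1, 4, 3), c(3, 4, 1, 2))
  r <- welch_anova(g)   # identical means
  expect_equal(r$f, 0, tolerance = 1e-12)
  expect_equal(r$p, 1, tolerance = 1e-12)

  # k = 2 reduces to the square of the Welch t statistic
  set.seed(5)
  a <- rnorm(15, 0, 1); b <- rnorm(20, 1, 3)
  r2 <- welch_anova(list(a, b))
  wt <- oracle_welch_t(a, b)
  expect_equal(r2$f, wt$t^2, tolerance = 1e-10)
  expect_equal(r2$df2, wt$df, tolerance = 1e-10)

  expect_true(welch_anova(list(c(1, 1, 1), c(1, 2, 3)))$degenerate)
})

test_that("Welch ANOVA type-I error is calibrated under unequal variances", {
  set.seed(99)
  rej <- 0; N <- 2000
  for (i in 1:N) {
    g <- list(rnorm(20, 0, 1), rnorm(20, 0, 3), rnorm(20, 0, 1))
    rej <- rej + (welch_anova(g)$p < 0.05)
  }
  expect_gte(rej / N, 0.03)
  expect_lte(rej / N, 0.07)
})

test_that("Welch t test matches the brute-force formula", {
  set.seed(8)
  a <- rnorm(5, 1, 2); b <- rnorm(5, 0, 0.5)
  r <- welch_t_test(a, b)
  wt <- oracle_welch_t(a, b)
  expect_equal(r$t, wt$t, tolerance = 1e-12)
  expect_equal(r$df, wt$df, tolerance = 1e-12)
  expect_equal(r$p, wt$p, tolerance = 1e-12)

  r0 <- welch_t_test(a, a)
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)

  # equal variances: df approaches n_a + n_b - 2
  x <- c(1, 2, 3, 4, 5); y <- c(2, 3, 4, 5, 6)
  expect_equal(welch_t_test(x, y)$df, 8, tolerance = 1e-10)
})

test_that("Tukey pairwise comparisons are adjusted and well-behaved", {
  tab <- walk_table(8, c(LW = 5, E1 = 5, E2 = 5, E3 = 5), 0, seed = 3)
  r <- tukey_pairwise(tab, "value")
  expect_equal(nrow(r), 6)
  expect_true(all(r$p_adj == 1))

  tab2 <- walk_table(12, c(LW = 8, E1 = 5, E2 = 5, E3 = 5), 1, seed = 4)
  r2 <- tukey_pairwise(tab2, "value")
  unadj <- 2 * pt(abs(r2$t), r2$df, lower.tail = FALSE)
  expect_true(all(r2$p_adj >= unadj - 1e-12))
})

test_that("Tukey comparisons flag only the shifted condition", {
  set.seed(11)
  hits <- 0; N <- 200
  for (i in 1:N) {
    tab <- walk_table(20, c(LW = 3, E1 = 0, E2 = 0, E3 = 0), 1, seed = 900 + i)
    r <- tukey_pairwise(tab, "value")
    lw_pairs <- grepl("LW", r$pair)
    hits <- hits + (all(r$p_adj[lw_pairs] < 0.01) &&
                      all(r$p_adj[!lw_pairs] >= 0.01))
  }
  expect_gte(hits / N, 0.95)
})

test_that("bootstrap mean differences are seeded and consistent", {
  a <- c(1, 2, 3, 4, 5)
  r1 <- bootstrap_mean_diff(a, a, n_boot = 1000, seed = 3)
  expect_lte(r1$ci_lo, 0)
  expect_gte(r1$ci_hi, 0)
  r2 <- bootstrap_mean_diff(a, a, n_boot = 1000, seed = 3)
  expect_identical(r1, r2)
  expect_error(bootstrap_mean_diff(a, a, n_boot = 10), ">= 1000")
})

test_that("bootstrap interval width shrinks with sample size", {
  set.seed(21)
  wins <- 0; N <- 100
  for (i in 1:N) {
    small_a <- rnorm(10); small_b <- rnorm(10)
    big_a <- rnorm(100); big_b <- rnorm(100)
    ws <- with(bootstrap_mean_diff(small_a, small_b, 1000, seed = i),
               ci_hi - ci_lo)
    wb <- with(bootstrap_mean_diff(big_a, big_b, 1000, seed = i),
               ci_hi - ci_lo)
    wins <- wins + (wb < ws)
  }
  expect_gte(wins / N, 0.95)
})

test_that("null contrasts produce uniform p-values", {
  set.seed(55)
  ps <- replicate(2000, {
    tab <- data.frame(ant_id = rep(paste0("a", 1:10), each = 4),
                      condition = rep(c("LW", "E1", "E2", "E3"), 10),
                      value = rnorm(40))
    repeated_contrast_test(tab, "value", helmert_contrasts()[1, ])$p
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})
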