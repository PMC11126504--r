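#' Helmert-style contrast coefficients for four walk conditions
#'
#' The a-priori contrast scheme used to compare a learning walk (LW) with
#' three consecutive excavation trips (E1, E2, E3): contrast 1 compares LW
#' with the mean of all three excavation trips, contrast 2 compares E1 with
#' the mean of E2 and E3, and contrast 3 compares E2 with E3. The rows are
#' mutually orthogonal and each sums to zero.
#'
#' @param levels character vector of exactly 4 ordered condition labels.
#' @return a 3 x 4 matrix of coefficients with the levels as column names.
#' @export
helmert_contrasts <- function(levels = c("LW", "E1", "E2", "E3")) {
  if (length(levels) != 4L)
    stop("exactly 4 levels required", call. = FALSE)
  m <- rbind(c(1, -1/3, -1/3, -1/3),
             c(0, 1, -1/2, -1/2),
             c(0, 0, 1, -1))
  dimnames(m) <- list(paste0("contrast", 1:3), levels)
  m
}

## Reshape a long (ant_id, condition, value) table to a complete wide matrix,
## dropping ants that miss any condition (with a warning).
complete_wide <- function(table, metric, conditions) {
  need <- c("ant_id", "condition", metric)
  if (!all(need %in% names(table)))
    stop("table must have columns ant_id, condition, ", metric, call. = FALSE)
  if (anyDuplicated(table[, c("ant_id", "condition")]))
    stop("more than one row per ant x condition", call. = FALSE)
  ants <- unique(table$ant_id)
  wide <- matrix(NA_real_, length(ants), length(conditions),
                 dimnames = list(as.character(ants), conditions))
  rows <- match(as.character(table$ant_id), as.character(ants))
  cols <- match(as.character(table$condition), conditions)
  ok <- !is.na(cols)
  wide[cbind(rows[ok], cols[ok])] <- table[[metric]][ok]
  complete <- stats::complete.cases(wide)
  if (any(!complete))
    warning(sum(!complete), " ant(s) dropped: incomplete conditions")
  wide[complete, , drop = FALSE]
}

#' Repeated-measures contrast test
#'
#' Exact within-ant contrast test for a complete repeated-measures design:
#' each ant contributes one contrast value (the dot product of the contrast
#' coefficients with its per-condition metric values), and the contrast
#' values are tested against zero with a one-sample t test. F = t^2 is
#' reported alongside. This exploits the complete design (every ant performs
#' every condition) to respect the repeated-measures structure without a
#' mixed-model fit.
#'
#' For metrics bounded in (0, 1) (straightness, sinuosity when treated as
#' bounded) set `logit = TRUE` to contrast logit-transformed values (clamped
#' to `[1e-6, 1 - 1e-6]`).
#'
#' @param table data frame with columns `ant_id`, `condition` and the metric.
#' @param metric name of the metric column.
#' @param contrast numeric contrast coefficients, one per condition; names
#'   (or the `conditions` argument) give the condition order.
#' @param conditions condition labels matching the coefficients; defaults to
#'   `names(contrast)` or the four walk conditions.
#' @param logit apply a logit transform before contrasting.
#' @return a one-row data frame: `contrast_id`, `estimate` (mean within-ant
#'   contrast), `t`, `f`, `df`, `p`, `n_ants`.
#' @export
repeated_contrast_test <- function(table, metric, contrast,
                                   conditions = NULL, logit = FALSE) {
  if (is.null(conditions))
    conditions <- if (!is.null(names(contrast))) names(contrast)
                  else c("LW", "E1", "E2", "E3")
  if (length(contrast) != length(conditions))
    stop("one coefficient per condition required", call. = FALSE)
  wide <- complete_wide(table, metric, conditions)
  if (nrow(wide) < 3L)
    stop("fewer than 3 ants with complete data", call. = FALSE)
  if (logit) {
    wide <- pmin(pmax(wide, 1e-6), 1 - 1e-6)
    wide <- log(wide / (1 - wide))
  }
  vals <- as.numeric(wide %*% contrast)
  n <- length(vals)
  est <- mean(vals)
  s <- stats::sd(vals)
  # guard against floating-point residue of the coefficient arithmetic when
  # every ant has an identical (or exactly proportional) condition profile
  eps <- 1e-10 * max(1, max(abs(wide)))
  if (s <= eps) {
    tstat <- if (abs(est) <= eps) 0 else Inf * sign(est)
    p <- if (abs(est) <= eps) 1 else 0
    est <- if (abs(est) <= eps) 0 else est
  } else {
    tstat <- est / (s / sqrt(n))
    p <- 2 * stats::pt(abs(tstat), n - 1, lower.tail = FALSE)
  }
  data.frame(contrast_id = paste(contrast, collapse = ","),
             estimate = est, t = tstat, f = tstat^2, df = n - 1, p = p,
             n_ants = n)
}

#' Welch's one-way ANOVA
#'
#' Heteroscedasticity-robust one-way comparison of k group means (unequal
#' variances allowed), with Welch-Satterthwaite denominator degrees of
#' freedom. With k = 2 the F statistic equals the square of the Welch t
#' statistic.
#'
#' @param groups a list of numeric samples (each n >= 2, positive variance
#'   expected; zero-variance groups are flagged).
#' @return a one-row data frame: `f`, `df1`, `df2`, `p`, `degenerate`.
#' @export
welch_anova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (any(vapply(groups, length, 0L) < 2L))
    stop("each group needs n >= 2", call. = FALSE)
  degenerate <- any(vapply(groups, stats::var, 0) == 0)
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 0L)))
  if (degenerate) {
    return(data.frame(f = NA_real_, df1 = length(groups) - 1, df2 = NA_real_,
                      p = NA_real_, degenerate = TRUE))
  }
  res <- stats::oneway.test(y ~ g, var.equal = FALSE)
  data.frame(f = unname(res$statistic), df1 = unname(res$parameter[1L]),
             df2 = unname(res$parameter[2L]), p = res$p.value,
             degenerate = FALSE)
}

#' Tukey-adjusted pairwise comparisons across four conditions
#'
#' All six pairwise mean differences between the four walk conditions. For a
#' complete repeated-measures design the differences are computed within
#' ants (paired), the t statistic is the paired-sample t, and p-values are
#' adjusted with the studentized range distribution (q = |t| * sqrt(2),
#' 4 means, n - 1 df), the standard Tukey adjustment for a family of
#' pairwise contrasts.
#'
#' @param table data frame with `ant_id`, `condition` and the metric column.
#' @param metric metric column name.
#' @param conditions the four condition labels.
#' @return a 6-row data frame: `pair`, `estimate`, `t`, `df`, `p_adj`.
#' @export
tukey_pairwise <- function(table, metric,
                           conditions = c("LW", "E1", "E2", "E3")) {
  if (length(conditions) != 4L)
    stop("exactly 4 conditions required", call. = FALSE)
  wide <- complete_wide(table, metric, conditions)
  if (nrow(wide) < 3L)
    stop("fewer than 3 ants with complete data", call. = FALSE)
  n <- nrow(wide)
  pairs <- utils::combn(4L, 2L)
  out <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    d <- wide[, i] - wide[, j]
    est <- mean(d); s <- stats::sd(d)
    tstat <- if (s == 0) { if (est == 0) 0 else Inf * sign(est) }
             else est / (s / sqrt(n))
    p <- stats::ptukey(sqrt(2) * abs(tstat), nmeans = 4, df = n - 1,
                       lower.tail = FALSE)
    data.frame(pair = paste(conditions[i], conditions[j], sep = " - "),
               estimate = est, t = tstat, df = n - 1, p_adj = p)
  })
  do.call(rbind, out)
}

#' Welch two-sample t test
#'
#' Unequal-variance t test with Welch-Satterthwaite degrees of freedom,
#' two-sided.
#'
#' @param a,b numeric samples, each n >= 2.
#' @return a one-row data frame: `estimate` (mean(a) - mean(b)), `t`, `df`,
#'   `p`.
#' @export
welch_t_test <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each sample needs n >= 2", call. = FALSE)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    est <- mean(a) - mean(b)
    return(data.frame(estimate = est, t = if (est == 0) 0 else Inf * sign(est),
                      df = length(a) + length(b) - 2,
                      p = if (est == 0) 1 else 0))
  }
  res <- stats::t.test(a, b, var.equal = FALSE)
  data.frame(estimate = mean(a) - mean(b), t = unname(res$statistic),
             df = unname(res$parameter), p = res$p.value)
}

#' Bootstrapped difference of means
#'
#' Seeded nonparametric bootstrap of mean(a) - mean(b) with a percentile
#' confidence interval, as used to display group differences.
#'
#' @param a,b numeric samples.
#' @param n_boot number of resamples (>= 1000).
#' @param seed integer seed.
#' @param conf confidence level (default 0.95).
#' @return list with `mean_diff`, `ci_lo`, `ci_hi`, `boot` (the resampled
#'   differences).
#' @export
bootstrap_mean_diff <- function(a, b, n_boot = 2000, seed = 1L, conf = 0.95) {
  if (n_boot < 1000) stop("n_boot must be >= 1000", call. = FALSE)
  set.seed(as.integer(seed))
  na <- length(a); nb <- length(b)
  boot <- vapply(seq_len(n_boot), function(i)
    mean(a[sample.int(na, na, replace = TRUE)]) -
    mean(b[sample.int(nb, nb, replace = TRUE)]), 0)
  qs <- stats::quantile(boot, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        names = FALSE)
  list(mean_diff = mean(a) - mean(b), ci_lo = qs[1L], ci_hi = qs[2L],
       boot = boot)
}
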