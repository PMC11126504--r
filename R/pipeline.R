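#' Default run configuration
#'
#' Parameters steering the full analysis: frame rate, stop exclusion and
#' scanning-bout detection, alpha levels (0.01 for the multi-metric walk
#' comparisons, 0.05 for circular tests), and the master seed.
#'
#' @param ... overrides of any default field.
#' @return a named list.
#' @export
run_config <- function(...) {
  cfg <- list(frame_rate = 25, stop_speed_thresh = 0.5, stop_min_dur = 0.2,
              scan_params = NULL, alpha_walks = 0.01, alpha_circular = 0.05,
              arena_radius = 50, seed = 1L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  cfg[names(over)] <- over
  stopifnot(cfg$alpha_walks > 0, cfg$alpha_walks < 1,
            cfg$alpha_circular > 0, cfg$alpha_circular < 1)
  cfg
}

#' Per-walk metrics table for a set of labelled walks
#'
#' @param walks named list of lists: `walks[[ant_id]][[condition]]` is an
#'   [trajectory()] object (or a generator output list with a `traj` field).
#' @param cfg a [run_config()].
#' @return data frame with `ant_id`, `condition` and one column per metric.
#' @export
walk_metrics_table <- function(walks, cfg = run_config()) {
  rows <- list()
  for (ant in names(walks)) {
    for (cond in names(walks[[ant]])) {
      w <- walks[[ant]][[cond]]
      traj <- if (inherits(w, "ant_trajectory")) w else w$traj
      m <- path_metrics(traj, cfg$stop_speed_thresh, cfg$stop_min_dur,
                        cfg$scan_params)
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(ant_id = ant, condition = cond), m)
    }
  }
  do.call(rbind, rows)
}

#' Walk-comparison analysis
#'
#' Computes the per-walk metrics table for learning and excavation walks and
#' runs the condition comparisons: the three a-priori contrasts
#' (learning walk vs all excavation trips; trip 1 vs trips 2-3; trip 2 vs 3)
#' as exact within-ant repeated-measures tests for each metric, Welch's
#' ANOVA across conditions, and Tukey-adjusted pairwise comparisons.
#' Bounded metrics (straightness) are contrasted on the logit scale.
#'
#' @param walks as in [walk_metrics_table()]; conditions must be
#'   `LW, E1, E2, E3`.
#' @param cfg a [run_config()].
#' @param metrics metric columns to analyse.
#' @param out_dir optional directory; when given, `walk_metrics.csv`,
#'   `walk_contrasts.csv`, `walk_pairwise.csv` and `run_metadata.json` are
#'   written there.
#' @return list with `metrics` (per-walk table), `contrasts`, `welch`,
#'   `pairwise`, `skipped` (logical: too few ants for group stats).
#' @export
run_walk_analysis <- function(walks, cfg = run_config(),
                              metrics = c("convex_hull_area",
                                          "max_displacement", "duration",
                                          "mean_speed",
                                          "mean_orient_angular_velocity",
                                          "straightness", "sinuosity",
                                          "emax"),
                              out_dir = NULL) {
  if (!length(walks)) stop("empty input set", call. = FALSE)
  tab <- walk_metrics_table(walks, cfg)
  conds <- c("LW", "E1", "E2", "E3")
  cm <- helmert_contrasts(conds)
  skipped <- length(unique(tab$ant_id)) < 3L
  contrasts <- welch <- pairwise <- NULL
  if (skipped) {
    warning("fewer than 3 ants: group statistics skipped")
  } else {
    res <- list(); wres <- list(); pres <- list()
    for (m in metrics) {
      use_logit <- m %in% "straightness"
      for (ci in 1:3) {
        r <- repeated_contrast_test(tab, m, cm[ci, ], conditions = conds,
                                    logit = use_logit)
        r <- cbind(data.frame(metric = m, contrast = rownames(cm)[ci],
                              logit_scale = use_logit), r)
        res[[length(res) + 1L]] <- r
      }
      groups <- lapply(conds, function(cc) tab[[m]][tab$condition == cc])
      wres[[length(wres) + 1L]] <-
        cbind(data.frame(metric = m), welch_anova(groups))
      pres[[length(pres) + 1L]] <-
        cbind(data.frame(metric = m), tukey_pairwise(tab, m, conds))
    }
    contrasts <- do.call(rbind, res)
    contrasts$alpha <- cfg$alpha_walks
    contrasts$significant <- contrasts$p < cfg$alpha_walks
    welch <- do.call(rbind, wres)
    pairwise <- do.call(rbind, pres)
  }
  out <- list(metrics = tab, contrasts = contrasts, welch = welch,
              pairwise = pairwise, skipped = skipped)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(tab, file.path(out_dir, "walk_metrics.csv"),
                     row.names = FALSE)
    if (!skipped) {
      utils::write.csv(contrasts, file.path(out_dir, "walk_contrasts.csv"),
                       row.names = FALSE)
      utils::write.csv(pairwise, file.path(out_dir, "walk_pairwise.csv"),
                       row.names = FALSE)
      utils::write.csv(welch, file.path(out_dir, "walk_welch.csv"),
                       row.names = FALSE)
    }
    write_run_metadata(out_dir, cfg)
  }
  out
}

#' Displacement-heading analysis
#'
#' Runs the circular test battery (mean vector and CI, Rayleigh, V, von
#' Mises likelihood-ratio tests, all toward the nest direction at 0 degrees)
#' plus 24-wedge histogram counts for each displacement condition.
#' Conditions with fewer than 5 headings are flagged and their tests
#' skipped.
#'
#' @param headings either a named list of [heading_set()]s or a data frame
#'   with columns `ant_id`, `condition`, `angle_deg`.
#' @param cfg a [run_config()].
#' @param out_dir optional output directory (`heading_stats.csv`,
#'   `wedge_histograms.csv`).
#' @return list with `table` (one row per analysed condition),
#'   `histograms` (matrix, 24 columns), `flagged` (conditions with n < 5).
#' @export
run_displacement_analysis <- function(headings, cfg = run_config(),
                                      out_dir = NULL) {
  if (is.data.frame(headings)) {
    stopifnot(all(c("condition", "angle_deg") %in% names(headings)))
    headings <- lapply(split(headings, headings$condition), function(d)
      heading_set(d$angle_deg, d$condition[1L]))
  }
  ok <- vapply(headings, function(h) h$n >= 5L, TRUE)
  flagged <- names(headings)[!ok]
  if (length(flagged))
    warning("condition(s) with n < 5 skipped: ",
            paste(flagged, collapse = ", "))
  rows <- lapply(headings[ok], heading_battery, target = 0, seed = cfg$seed)
  tab <- do.call(rbind, rows)
  if (!is.null(tab)) {
    tab$alpha <- cfg$alpha_circular
    tab$uniform_rejected <- tab$rayleigh_p < cfg$alpha_circular
    rownames(tab) <- NULL
  }
  hist <- do.call(rbind, lapply(headings, wedge_histogram))
  out <- list(table = tab, histograms = hist, flagged = flagged)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(tab))
      utils::write.csv(tab, file.path(out_dir, "heading_stats.csv"),
                       row.names = FALSE)
    utils::write.csv(data.frame(condition = rownames(hist), hist,
                                check.names = FALSE),
                     file.path(out_dir, "wedge_histograms.csv"),
                     row.names = FALSE)
    write_run_metadata(out_dir, cfg)
  }
  out
}

#' Panorama rotIDF analysis
#'
#' Computes the rotational image difference function between a reference
#' (nest) panorama and each test-location panorama, with the per-location
#' summary (minimum, argmin, median, mean, depth) and the best-matching
#' world bearing.
#'
#' @param reference a [panorama()], the nest view.
#' @param tests named list of [panorama()]s at the test locations.
#' @param cfg a [run_config()].
#' @param out_dir optional directory; writes one `rotidf_<location>.csv`
#'   per location and a `rotidf_summary.json`.
#' @return list with `results` (named list of [rotidf()] objects) and
#'   `summary` (data frame: location, min, argmin_deg, median, mean, depth,
#'   best_bearing).
#' @details Before each comparison the reference panorama is rolled so that
#'   its first column faces the same world bearing as the test panorama's
#'   (the nest-ward direction when the panoramas come from the synthetic
#'   experiment); the best-matching rotation is then directly interpretable
#'   as a deviation from the nest-ward direction.
#' @export
run_rotidf_analysis <- function(reference, tests, cfg = run_config(),
                                out_dir = NULL) {
  stopifnot(length(tests) >= 1L)
  results <- lapply(tests, function(p) {
    dcol <- (p$heading_of_col0 - reference$heading_of_col0) /
      reference$azimuth_deg_per_col
    rotidf(roll_panorama(reference, round(dcol)), p)
  })
  summary <- do.call(rbind, lapply(names(results), function(nm) {
    r <- results[[nm]]
    data.frame(location = nm, min = r$min_value, argmin_deg = r$argmin_deg,
               median = r$median_value, mean = r$mean_value, depth = r$depth,
               best_bearing = as.numeric(
                 best_nest_bearing(r, tests[[nm]]$heading_of_col0)))
  }))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(results))
      utils::write.csv(data.frame(shift_deg = results[[nm]]$shift_deg,
                                  discrepancy = results[[nm]]$discrepancy),
                       file.path(out_dir, paste0("rotidf_", nm, ".csv")),
                       row.names = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "rotidf_summary.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
    write_run_metadata(out_dir, cfg)
  }
  list(results = results, summary = summary)
}

## Persist the full parameter set of a run (no hidden defaults).
write_run_metadata <- function(out_dir, cfg) {
  meta <- list(config = cfg,
               package_version = as.character(utils::packageVersion("antwalks")),
               r_version = R.version.string)
  jsonlite::write_json(meta, file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(NULL)
}
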