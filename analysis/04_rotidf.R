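#!/usr/bin/env Rscript

# Rotational image difference functions between the nest panorama and each
# test-site panorama: the full 360-degree discrepancy curve per site, its
# minimum and best-matching bearing, and the depth (mean minus minimum) that
# measures how usable the minimum is for view-based homing.
#
#   Rscript analysis/04_rotidf.R [--in <dir>] [--out <dir>]

suppressMessages(library(antwalks))

args <- commandArgs(trailingOnly = TRUE)
ind <- "results/synthetic_study"; out <- "results/rotidf"
i <- 1L
while (i <= length(args)) {
  if (args[i] == "--in") { ind <- args[i + 1L]; i <- i + 2L }
  else if (args[i] == "--out") { out <- args[i + 1L]; i <- i + 2L }
  else stop("unknown argument: ", args[i])
}

pd <- file.path(ind, "panoramas")
if (!file.exists(file.path(pd, "nest.png")))
  stop("no panoramas under ", ind, " -- run 01_simulate.R first")

# test panoramas were rendered with column 1 facing the nest-ward bearing
positions <- list(`2mN` = c(0, 2), `2mE` = c(2, 0),
                  `4mN` = c(0, 4), `4mE` = c(4, 0))
bearing_to_nest <- function(pos) wrap360(90 - atan2(-pos[2], -pos[1]) * 180 / pi)

nest <- read_panorama(file.path(pd, "nest.png"), heading_of_col0 = 0,
                      normalize = FALSE)
tests <- lapply(names(positions), function(nm)
  read_panorama(file.path(pd, paste0(nm, ".png")),
                heading_of_col0 = bearing_to_nest(positions[[nm]]),
                normalize = FALSE))
names(tests) <- names(positions)

res <- run_rotidf_analysis(nest, tests, out_dir = out)

sm <- res$summary
for (r in seq_len(nrow(sm)))
  cat(sprintf(
    "%s: min %.3f at %3.0f deg, mean %.3f, depth %.3f, best bearing %5.1f (nest at %5.1f)\n",
    sm$location[r], sm$min[r], sm$argmin_deg[r], sm$mean[r], sm$depth[r],
    sm$best_bearing[r], bearing_to_nest(positions[[sm$location[r]]])))
cat("curves and summary written to", out, "\n")
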