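#!/usr/bin/env Rscript

# Per-walk path metrics and walk-condition comparisons for the learning walk
# vs the three excavation trips: convex-hull area, maximum displacement,
# duration, stop-excluded speed, orientation angular velocity, straightness,
# sinuosity, maximum expected displacement, and scanning-bout counts; then
# within-ant contrast tests (LW vs E1-E3; E1 vs E2-E3; E2 vs E3) at alpha =
# 0.01, Welch's ANOVA, and Tukey-adjusted pairwise comparisons.
#
#   Rscript analysis/02_walk_analysis.R [--in <dir>] [--out <dir>]

suppressMessages(library(antwalks))

args <- commandArgs(trailingOnly = TRUE)
ind <- "results/synthetic_study"; out <- "results/walks"
i <- 1L
while (i <= length(args)) {
  if (args[i] == "--in") { ind <- args[i + 1L]; i <- i + 2L }
  else if (args[i] == "--out") { out <- args[i + 1L]; i <- i + 2L }
  else stop("unknown argument: ", args[i])
}

files <- list.files(file.path(ind, "trajectories"), full.names = TRUE)
if (!length(files)) stop("no trajectories found under ", ind,
                         " -- run 01_simulate.R first")

walks <- list()
for (f in files) {
  parts <- strsplit(sub("[.]csv$", "", basename(f)), "_")[[1L]]
  ant <- parts[1L]; cond <- parts[2L]
  tr <- read_trajectory_csv(
    f, label = if (cond == "LW") "learning" else "excavation", ant_id = ant)
  walks[[ant]][[cond]] <- tr
}
walks <- lapply(walks, function(w) w[c("LW", "E1", "E2", "E3")])

res <- run_walk_analysis(walks, out_dir = out)

ct <- res$contrasts
sig1 <- ct$metric[ct$contrast == "contrast1" & ct$significant]
cat("metrics separating the learning walk from the excavation trips",
    "(contrast 1, alpha = 0.01):\n  ", paste(sig1, collapse = ", "), "\n")
cat("contrast 2-3 rejections:",
    sum(ct$significant[ct$contrast != "contrast1"]), "of",
    sum(ct$contrast != "contrast1"), "\n")
lw <- res$metrics[res$metrics$condition == "LW", ]
cat(sprintf("learning walks: area %.1f cm^2, duration %.1f s, %d-%d scan bouts\n",
            mean(lw$convex_hull_area), mean(lw$duration),
            min(lw$n_scan_bouts), max(lw$n_scan_bouts)))
cat("tables written to", out, "\n")
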