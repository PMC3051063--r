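#!/usr/bin/env Rscript

# Two-drug Bliss combination-index maps for D2&D3, D2&D4 and D3&D4.
# Default resolution is the scaled-down 10x10 grid; pass --full for the
# 100x100 scan (about 7 minutes per pair on one CPU).

suppressMessages(library(nfkbdrug))

n_levels <- if ("--full" %in% commandArgs(trailingOnly = TRUE)) 100 else 10
out <- file.path("results", "combinations")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

model <- build_default_model()
ranges <- list(D2 = 4, D3 = 0.02, D4 = 1)
for (pr in combn(names(ranges), 2, simplify = FALSE)) {
  t0 <- proc.time()[["elapsed"]]
  map <- combination_grid(model, pr[1], pr[2],
                          rangeA = ranges[[pr[1]]],
                          rangeB = ranges[[pr[2]]],
                          n_levels = n_levels)
  write_synergy_map(map, out)
  cat(sprintf("%s & %s (%dx%d, %.0f s): ", pr[1], pr[2], n_levels,
              n_levels, proc.time()[["elapsed"]] - t0))
  print(synergy_class_counts(map))
}
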