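#!/usr/bin/env Rscript

# Loewe-additivity isobolograms at 25% and 50% inhibition for the drug
# pairs whose single-agent curves reach the level.

suppressMessages(library(nfkbdrug))

out <- file.path("results", "isobolograms")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

model <- build_default_model()
ranges <- list(D2 = 4, D3 = 0.02, D4 = 1)
curves <- lapply(names(ranges), function(id)
  dose_response_curve(model, id, seq(0, ranges[[id]], length.out = 13)))
names(curves) <- names(ranges)

for (pr in combn(names(ranges), 2, simplify = FALSE)) {
  for (x in c(0.25, 0.5)) {
    cA <- curves[[pr[1]]]
    cB <- curves[[pr[2]]]
    if (max(cA$inhibition) < x || max(cB$inhibition) < x) next
    iso <- loewe_isobole(model, pr[1], pr[2], x, cA, cB)
    p <- file.path(out, sprintf("isobole_%s_%s_x%02d.csv", pr[1], pr[2],
                                round(100 * x)))
    write_isobologram(iso, p)
    interior <- iso$loewe_ci[iso$d1 > 0 & iso$d2 > 0]
    cat(sprintf("%s & %s at x=%.2f: interior Loewe CI %.3f-%.3f\n",
                pr[1], pr[2], x, min(interior), max(interior)))
  }
}
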