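#!/usr/bin/env Rscript

# One-command reproduction: run the packaged end-to-end workflow (build +
# validate, sensitivity scan, single-drug curves, D1 null-effect report,
# the three 10x10 Bliss grids, Loewe isobolograms) into results/pipeline/,
# with a JSON manifest of every artifact. The numbered scripts 01-07 run
# the same stages individually with more verbose reporting.

suppressMessages(library(nfkbdrug))

cfg <- run_config(out_dir = file.path("results", "pipeline"), seed = 1)
manifest <- run_pipeline(cfg)
cat("manifest:", file.path(cfg$out_dir, "manifest.json"), "\n")
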