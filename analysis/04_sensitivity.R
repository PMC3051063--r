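#!/usr/bin/env Rscript

# Local sensitivity analysis: 1% one-at-a-time perturbation of all 39
# kinetic parameters and 11 nonzero initial concentrations against the
# steady nuclear NFkB output.

suppressMessages(library(nfkbdrug))

out <- "results"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

model <- build_default_model()
tab <- sensitivity_scan(model)
write_sensitivity(tab, file.path(out, "sensitivity.csv"))

cat(sprintf("baseline output: %.4f uM\n", attr(tab, "baseline_output")))
cat("ten most sensitive targets:\n")
print(head(tab[, c("target", "kind", "subsystem", "S_mean")], 10))
cat("receptor-subsystem kinetic sensitivities (max |S|):",
    max(abs(tab$S_mean[tab$kind == "kinetic" &
                         tab$subsystem == "receptor"])), "\n")
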