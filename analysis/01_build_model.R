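#!/usr/bin/env Rscript

# Build the canonical 26-species TNFa -> NFkB model, validate its structure
# and conservation laws, and export its definition (reaction table, rate
# constants, initial concentrations, SBML) under results/model/.

suppressMessages(library(nfkbdrug))

out <- file.path("results", "model")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

model <- build_default_model()
v <- validate_model(model)
print(model)
cat("validation ok:", v$ok, "\n")
print(v$counts)
stopifnot(v$ok)

write_reactions(model$reactions, file.path(out, "reactions.csv"))
write_parameters(model$parameters, file.path(out, "parameters.csv"),
                 fixed = model$fixed)
write_initial(model$initial, file.path(out, "initial_concentrations.csv"))
export_sbml(model, file.path(out, "nfkb_pathway.xml"))

cat("NFkB moiety total (uM):",
    moiety_total(model, model$initial, NFKB_MOIETY), "\n")
cat("IKK moiety total (uM):",
    moiety_total(model, model$initial, IKK_MOIETY), "\n")
cat("artifacts written to", out, "\n")
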