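#!/usr/bin/env Rscript

# Single-drug inhibition profiles: D2 (active-IKK binder, 0-4 uM), D3
# (proteasome inhibitor, 0-0.02 uM), D4 (NFkB binder, 0-1 uM), and the D1
# (TNFa binder) null-effect control up to 1000 uM.

suppressMessages(library(nfkbdrug))

out <- file.path("results", "dose_response")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

model <- build_default_model()
ranges <- list(D2 = 4, D3 = 0.02, D4 = 1)
for (id in names(ranges)) {
  doses <- seq(0, ranges[[id]], length.out = 13)
  cr <- dose_response_curve(model, id, doses)
  write.csv(as.data.frame(cr), file.path(out, sprintf("curve_%s.csv", id)),
            row.names = FALSE)
  cat(sprintf("%s: shape %s, max inhibition %.3f at %g uM, IC50 %s\n",
              id, attr(cr, "shape"), max(cr$inhibition), max(doses),
              if (max(cr$inhibition) >= 0.5)
                sprintf("%.4g uM", ic_x(cr, 0.5)) else "not reached"))
}

d1 <- dose_response_curve(model, "D1", c(0, 1, 10, 100, 500, 1000))
write.csv(as.data.frame(d1), file.path(out, "curve_D1.csv"),
          row.names = FALSE)
cat(sprintf("D1 max inhibition over 0-1000 uM: %.2e (null effect)\n",
            max(d1$inhibition)))
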