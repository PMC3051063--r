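# nfkbdrug

Drug inhibition profiling for the TNFa-induced NFkB pathway in multiple
myeloma: a 26-species mass-action ODE model with parameter estimation,
local sensitivity analysis, four mechanistically distinct inhibitors, and
Bliss / Loewe two-drug synergy prediction.

## The science

Constitutive NFkB activity is a survival signal in multiple myeloma, and
several approved drugs act on different stages of the same pathway —
TNFa-neutralizing biologics, IKK-directed small molecules, proteasome
inhibitors, and direct NFkB binders. This package models the canonical
TNFa -> TNFR1 -> TRAFs -> IKKK -> IKK -> IkBa -> NFkB cascade, including
the IkBa negative-feedback loop (NFkB-driven IkBa mRNA synthesis,
translation, nuclear re-capture), as 26 species and 39 irreversible
mass-action reactions in uM / minutes. Everything downstream — dose
response, synergy maps, isobolograms — is computed from one scalar
readout: the steady nuclear NFkB concentration under 0.2 uM TNFa
stimulation, 0.055 uM with the shipped calibrated parameter set.

Four inhibitors are built in:

| id | mechanism | model form |
|----|-----------|------------|
| D1 | TNFa binder (infliximab-like) | reversible sequestration species |
| D2 | active-IKK binder (arsenite-like) | reversible sequestration species |
| D3 | proteasome inhibitor (bortezomib-like) | Hill scaling `1 - D^4/(1e-9 + D^4)` of the IkBa degradation constants |
| D4 | NFkB binder (A238L-like) | reversible sequestration species |

Headline predictions with the calibrated set:

- **D1 is a null-effect control**: inhibition stays below 1e-4 up to
  1000 uM — receptor-level signaling is strongly redundant at 0.2 uM
  TNFa, so neutralizing the ligand barely moves the steady output.
- **D2 & D4 act synergistically** (86 of 100 cells on the 10x10 Bliss
  grid over 0-4 uM x 0-1 uM; the rest additive): both drugs drain the
  same 0.91 uM NFkB pool.
- **D2 & D3 never synergize** (0 synergy, 49 additive, 51 antagonism):
  they block successive stages of one serial IkBa-elimination pipeline.
- **D3 & D4 are mixed** (66 synergy / 30 additive / 4 antagonism).

## Worked example

```r
library(nfkbdrug)

model <- build_default_model()          # 26 species, 39 reactions
validate_model(model)$counts
#>      species    reactions   parameters         free nonzero_init
#>           26           39           39           21           11

steady_state(model)$state[["NFkBn"]]    # steady nuclear NFkB, uM
#> [1] 0.05500

# Proteasome-inhibitor occupancy: half-inhibition at 1e-9^(1/4) uM
uniroot(function(d) hill_inhibition(d) - 0.5, c(1e-4, 1))$root
#> [1] 0.005623

# Single-drug profile: D4 titrates the 0.91 uM NFkB pool
curve_d4 <- dose_response_curve(model, "D4", seq(0, 1, length.out = 11))
max(curve_d4$inhibition)                # 0.965 at 1 uM
ic_x(curve_d4, 0.5)                     # 0.67 uM

# Two-drug Bliss map (10x10; 100 levels reproduces the full scan)
map <- combination_grid(model, "D2", "D4", rangeA = 4, rangeB = 1,
                        n_levels = 10)
synergy_class_counts(map)
#>    synergy   additive antagonism  undefined     failed
#>         86         14          0          0          0

# Sensitivity: the IkBa feedback constants dominate, receptor constants
# are irrelevant to the steady output
sens <- sensitivity_scan(model)
head(sens[, c("target", "kind", "S_mean")], 3)   # t1, t2, g7; |S| ~ 1
```

## Repository layout

This is an analysis-first repository: the package under `R/` + `src/`
provides the building blocks, and the numbered scripts under `analysis/`
are the workflow.

- `analysis/00_run_all.R` — one-command end-to-end run (writes
  `results/pipeline/` with a JSON manifest of every artifact).
- `analysis/01..07_*.R` — the individual stages: model build/export,
  baseline and prior simulations, fitting + recovery experiments,
  sensitivity scan, dose-response curves, Bliss grids
  (`--full` for 100x100), Loewe isobolograms.
- `scripts/acceptance.R` — computes the reference quantities and writes
  them as JSON (see below).
- `vignettes/methods.Rmd` — model structure, reconstruction rationale,
  estimation and synergy methods, limitations.

## Reproduction

```sh
R CMD INSTALL .
Rscript -e 'testthat::test_dir("tests/testthat", package = "nfkbdrug",
                               load_package = "installed")'
Rscript scripts/acceptance.R --seed 1 --out acceptance.json
cd analysis && Rscript 00_run_all.R
```

All randomness flows through explicit seeds; rerunning any script with
the same seed reproduces identical outputs. The full test suite takes
roughly 15 minutes on one CPU (dominated by a deliberately full-scale
100x100 combination map and the multistart recovery experiments).

Two acceptance-level checks fail by design and are kept honest rather
than weakened: refitting from the 6+6 early time points cannot pin down
the steady output or the individual IkBa-feedback constants
(`t1`/`t2`/`g7` are only jointly identifiable). The vignette's section 5
explains why this is a property of the sampling design.

## Notes

- Rate constants are reconstructed (the original study's fitted values
  are not published); absolute potencies are illustrative, the
  qualitative synergy structure is the supported result.
- `inst/extdata/` ships the calibrated (`params_fitted.csv`) and
  oscillatory literature-prior (`params_prior.csv`) parameter sets plus
  the initial concentrations; all are plain CSV.
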