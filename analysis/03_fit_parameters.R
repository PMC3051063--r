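#!/usr/bin/env Rscript

# Parameter estimation study: generate densitometry-like synthetic
# time-course data from the calibrated model, refit the 21 free parameters
# by multistart Hooke-Jeeves, and run the zero-noise and 10%-CV recovery
# experiments.

suppressMessages(library(nfkbdrug))

out <- file.path("results", "fit")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

model <- build_default_model()

dataset <- generate_timecourse_data(model, noise_model(cv = 0.1), seed = 1)
write_dataset(dataset, file.path(out, "synthetic_dataset.csv"))

fit <- multistart_fit(dataset, model, n_starts = 5, seed = 1001,
                      target_error = 0.01, max_evals = 2e4)
write.csv(fit$per_run, file.path(out, "fit_runs.csv"), row.names = FALSE)
write_parameters(with_free_parameters(model, fit$best_params)$parameters,
                 file.path(out, "best_fit_parameters.csv"),
                 fixed = model$fixed)
cat(sprintf("best cost %.4g over %d starts (averaged cost %.4g)\n",
            fit$best_cost, nrow(fit$per_run), fit$averaged_cost))

for (cv in c(0, 0.1)) {
  rec <- parameter_recovery_experiment(
    model, n_starts = 5, noise = noise_model(cv = cv), seed = 1,
    use = "best", target_error = 0.01, max_evals = 2e4)
  tag <- sprintf("cv%02d", round(100 * cv))
  write.csv(data.frame(parameter = names(rec$relative_error),
                       relative_error = unname(rec$relative_error)),
            file.path(out, sprintf("recovery_%s.csv", tag)),
            row.names = FALSE)
  cat(sprintf(paste0("recovery (cv=%g): best cost %.4g, recovered output ",
                     "%.4g uM vs truth %.4g uM (within 5%%: %s)\n"),
              cv, rec$fit$best_cost, rec$recovered_output,
              rec$truth_output, rec$output_within_5pct))
}
cat("artifacts written to", out, "\n")
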