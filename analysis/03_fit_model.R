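#!/usr/bin/env Rscript
# Stage 3 — fit the GUD-Peck model.
#
# One training row per visited tray with a weighed final GUD: measured
# GUD against the tray's total pecks, its total minimum individuals and
# the final-forager species. Reports fit diagnostics and writes the
# coefficients to results/model/gud_peck_fit.json.

suppressPackageStartupMessages(library(gudpeck))

study <- read_study(list(trials = "results/data/trials.csv",
                         pecks = "results/data/pecks.csv",
                         intervals = "results/data/intervals.csv"))
events <- analyze_events(study)
train <- training_table(study, events)
fit <- fit_gud_peck_model(train)

dir.create("results/model", showWarnings = FALSE, recursive = TRUE)
jsonlite::write_json(
  list(beta0 = fit$beta0, beta_pecks = fit$beta_pecks,
       beta_density = fit$beta_density,
       species_effects = as.list(fit$species_effects),
       reference_level = fit$reference_level,
       r_squared = fit$r_squared,
       obs_pred_pearson = fit$obs_pred_pearson, n_train = fit$n_train),
  "results/model/gud_peck_fit.json", auto_unbox = TRUE, digits = NA)

print(fit)
cat(sprintf("\n%d trays entered the fit; %d species appeared as final foragers.\n",
            fit$n_train, length(fit$species_effects)))
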