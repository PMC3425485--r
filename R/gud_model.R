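#' @title The GUD-Peck model
#' @description The linear model at the core of the pipeline: measured
#'   final giving-up density regressed on the tray's total peck count,
#'   forager density (tray-total minimum individuals) and final-forager
#'   species identity. Fitted on final-forager observations (the only
#'   trays where the GUD is actually weighed), it back-estimates the GUD
#'   at every other species' quitting point from the cumulative pecks at
#'   that moment. Assumes all pecks are equally likely to yield food and
#'   yield the same amount across species.
#' @name gud_model
NULL

#' Fit the GUD-Peck model
#'
#' Ordinary least squares of
#' `GUD = beta0 + beta_pecks * P + beta_density * d + species offset`,
#' with categorical species offsets relative to the alphabetically first
#' species as reference. One training row per visited tray with a weighed
#' final GUD: `P` is the tray's total peck count, `d` its total minimum
#' individuals, and the species is the final forager.
#'
#' @param training Data frame with columns `gud` (grams), `pecks`
#'   (count), `species` (final forager code), `density` (count).
#' @return A `gud_peck_fit`: coefficients (`beta0`, `beta_pecks`,
#'   `beta_density`, `species_effects` with the reference at 0),
#'   `reference_level`, `r_squared`, `obs_pred_pearson`, `n_train`.
#' @export
fit_gud_peck_model <- function(training) {
  req <- c("gud", "pecks", "species", "density")
  stopifnot(all(req %in% names(training)))
  training <- training[stats::complete.cases(training[req]), , drop = FALSE]
  training$species <- factor(training$species,
                             levels = sort(unique(training$species)))
  n <- nrow(training)
  p <- 2L + nlevels(training$species)  # intercept+offsets, pecks, density
  if (n < p) {
    stop(sprintf(
      "too few training trays (%d) for %d model parameters", n, p),
      call. = FALSE)
  }
  # a single final-forager species leaves no estimable offsets: the
  # model degrades to intercept + pecks + density
  form <- if (nlevels(training$species) >= 2)
    gud ~ pecks + density + species else gud ~ pecks + density
  fit <- stats::lm(form, data = training)
  co <- stats::coef(fit)
  if (anyNA(co)) {
    stop("rank-deficient design; collinear column(s): ",
         paste(names(co)[is.na(co)], collapse = ", "), call. = FALSE)
  }
  lv <- levels(training$species)
  offsets <- stats::setNames(rep(0, length(lv)), lv)
  extra <- co[grepl("^species", names(co))]
  offsets[sub("^species", "", names(extra))] <- unname(extra)
  pred <- stats::fitted(fit)
  # summary() warns on exact interpolation (noiseless training data);
  # that case is legitimate here
  smry <- suppressWarnings(summary(fit))
  structure(list(
    beta0 = unname(co[["(Intercept)"]]),
    beta_pecks = unname(co[["pecks"]]),
    beta_density = unname(co[["density"]]),
    species_effects = offsets,
    reference_level = lv[1],
    r_squared = smry$r.squared,
    obs_pred_pearson = stats::cor(training$gud, pred),
    n_train = n,
    coef_table = smry$coefficients
  ), class = "gud_peck_fit")
}

#' @export
print.gud_peck_fit <- function(x, ...) {
  cat("GUD-Peck model (OLS), n =", x$n_train, "\n")
  cat(sprintf("  beta0        %8.4f g\n", x$beta0))
  cat(sprintf("  beta_pecks   %8.6f g/peck\n", x$beta_pecks))
  cat(sprintf("  beta_density %8.4f g/individual\n", x$beta_density))
  cat("  species offsets (ref ", x$reference_level, "):\n", sep = "")
  for (s in names(x$species_effects)) {
    cat(sprintf("    %-6s %8.4f\n", s, x$species_effects[[s]]))
  }
  cat(sprintf("  r^2 = %.3f, obs-vs-pred Pearson r = %.3f\n",
              x$r_squared, x$obs_pred_pearson))
  invisible(x)
}

#' Predict a GUD from the fitted model
#'
#' Evaluates the linear predictor at a cumulative peck count, species and
#' tray density. Predictions are not clamped; negative values are handled
#' downstream by the omission rules.
#'
#' @param fit A `gud_peck_fit`.
#' @param cum_pecks Cumulative peck count(s).
#' @param species Species code(s); must appear in the training data.
#' @param density Tray-total minimum individuals.
#' @return Predicted GUD(s) in grams.
#' @export
predict_gud <- function(fit, cum_pecks, species, density) {
  stopifnot(inherits(fit, "gud_peck_fit"))
  unknown <- setdiff(unique(species), names(fit$species_effects))
  if (length(unknown) > 0) {
    stop("species_not_in_model: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  fit$beta0 + fit$beta_pecks * cum_pecks + fit$beta_density * density +
    unname(fit$species_effects[species])
}

#' Estimate a GUD for every species visiting every tray
#'
#' For each species on each tray, the GUD at its quitting point is the
#' model prediction at the cumulative peck count when it quit. The final
#' forager's estimate is evaluated at the tray's total pecks. Estimates
#' are flagged `omitted` when the species had fewer than
#' `config$peck_min_threshold` own pecks (the model performs poorly
#' there) or was never a final forager in training (no species offset).
#' Unvisited trays get `gud_estimate = G0` with `unvisited = TRUE`.
#'
#' @param fit A `gud_peck_fit`.
#' @param quit_points `quit_points` table from [analyze_events()]
#'   (with `tray_id` and `is_final_forager`).
#' @param density `density` table from [analyze_events()].
#' @param trials Trials table (for `G0` and unvisited trays).
#' @param config A [default_config()] list.
#' @return Data frame `tray_id`, `species`, `cum_pecks_at_quit`,
#'   `gud_estimate`, `omitted`, `is_final_forager`, `omission_reason`,
#'   `own_total_pecks`, `unvisited`.
#' @export
estimate_species_guds <- function(fit, quit_points, density, trials,
                                  config = default_config()) {
  tray_dens <- unique(density[c("tray_id", "tray_total_min_individuals")])
  d_of <- stats::setNames(tray_dens$tray_total_min_individuals,
                          tray_dens$tray_id)
  qp <- quit_points
  known <- qp$species %in% names(fit$species_effects)
  est <- rep(NA_real_, nrow(qp))
  if (any(known)) {
    est[known] <- predict_gud(fit, qp$cum_pecks_at_quit[known],
                              qp$species[known],
                              unname(d_of[qp$tray_id[known]]))
  }
  reason <- rep("none", nrow(qp))
  reason[qp$own_total_pecks < config$peck_min_threshold] <- "few_pecks"
  reason[!known] <- "species_not_in_model"
  out <- data.frame(
    tray_id = qp$tray_id,
    species = qp$species,
    cum_pecks_at_quit = qp$cum_pecks_at_quit,
    gud_estimate = est,
    omitted = reason != "none",
    is_final_forager = qp$is_final_forager,
    omission_reason = reason,
    own_total_pecks = qp$own_total_pecks,
    unvisited = rep(FALSE, nrow(qp))
  )
  empty <- setdiff(trials$tray_id, qp$tray_id)
  if (length(empty) > 0) {
    g0 <- trials$initial_seed_mass_g[match(empty, trials$tray_id)]
    out <- rbind(out, data.frame(
      tray_id = empty, species = NA_character_,
      cum_pecks_at_quit = 0L, gud_estimate = g0,
      omitted = FALSE, is_final_forager = FALSE,
      omission_reason = "none", own_total_pecks = 0L,
      unvisited = TRUE))
  }
  rownames(out) <- NULL
  out[order(out$tray_id, out$species, na.last = TRUE), , drop = FALSE]
}

#' Per-species seed-consumption rates
#'
#' Consumption is estimated by entering a species' peck count into the
#' GUD-Peck model: `grams_consumed = G0 - predict_gud(...)`. By default
#' the species' own pecks are entered (`config$consumption_pecks_basis`
#' switches to cumulative pecks at quitting). Rows with fewer own pecks
#' than the threshold, with non-positive estimated consumption (the model
#' estimates negative seed consumed in those regimes), or for species
#' absent from the model are flagged `omitted` with a reason; a zero
#' foraging time with pecks present leaves the rate undefined
#' (`zero_time`). The rate is grams per hour over the summed bout time.
#'
#' @param fit A `gud_peck_fit`.
#' @param quit_points,foraging_times,density Tables from
#'   [analyze_events()].
#' @param trials Trials table (for `G0`).
#' @param config A [default_config()] list.
#' @return Data frame `tray_id`, `species`, `grams_consumed`,
#'   `foraging_time_s`, `rate_g_per_h`, `omitted`, `omission_reason`.
#' @export
consumption_rates <- function(fit, quit_points, foraging_times, density,
                              trials, config = default_config()) {
  qp <- quit_points
  if (nrow(qp) == 0) {
    return(data.frame(tray_id = character(0), species = character(0),
                      grams_consumed = numeric(0),
                      foraging_time_s = numeric(0),
                      rate_g_per_h = numeric(0), omitted = logical(0),
                      omission_reason = character(0)))
  }
  tray_dens <- unique(density[c("tray_id", "tray_total_min_individuals")])
  d_of <- stats::setNames(tray_dens$tray_total_min_individuals,
                          tray_dens$tray_id)
  g0 <- trials$initial_seed_mass_g[match(qp$tray_id, trials$tray_id)]
  pecks_in <- if (config$consumption_pecks_basis == "own")
    qp$own_total_pecks else qp$cum_pecks_at_quit
  known <- qp$species %in% names(fit$species_effects)
  grams <- rep(NA_real_, nrow(qp))
  grams[known] <- g0[known] - predict_gud(
    fit, pecks_in[known], qp$species[known],
    unname(d_of[qp$tray_id[known]]))
  key <- paste(qp$tray_id, qp$species)
  ft <- foraging_times$foraging_time_s[
    match(key, paste(foraging_times$tray_id, foraging_times$species))]
  reason <- rep("none", nrow(qp))
  reason[!is.na(grams) & grams <= 0] <- "negative_consumption"
  reason[qp$own_total_pecks < config$peck_min_threshold] <- "few_pecks"
  reason[!known] <- "species_not_in_model"
  reason[reason == "none" & ft <= 0] <- "zero_time"
  rate <- ifelse(reason == "none", grams / (ft / 3600), NA_real_)
  data.frame(
    tray_id = qp$tray_id, species = qp$species,
    grams_consumed = grams, foraging_time_s = ft,
    rate_g_per_h = rate,
    omitted = reason != "none", omission_reason = reason,
    row.names = NULL
  )
}
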