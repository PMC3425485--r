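#' @title End-to-end pipeline
#' @description Runs the analysis chain in dependency order — load or
#'   simulate a study, derive event summaries, fit the GUD-Peck model,
#'   estimate per-species GUDs and consumption rates, and compute the
#'   yard-type comparisons — writing every stage artifact plus a run
#'   manifest to an output directory.
#' @name cli_pipeline
NULL

#' Assemble the model training table from a study's event summaries
#'
#' One row per visited tray with a weighed final GUD: the response is the
#' measured GUD, predictors are the tray's total pecks, its total minimum
#' individuals, and the final-forager species. Trials with a missing
#' measured GUD are excluded from fitting (they still receive
#' predictions downstream).
#'
#' @param study A `study_dataset`.
#' @param events Output of [analyze_events()].
#' @return Data frame `tray_id`, `gud`, `pecks`, `species`, `density`.
#' @export
training_table <- function(study, events) {
  qp <- events$quit_points
  ff <- qp[qp$is_final_forager, , drop = FALSE]
  dens <- unique(events$density[c("tray_id", "tray_total_min_individuals")])
  out <- data.frame(
    tray_id = ff$tray_id,
    gud = study$trials$final_gud_g[match(ff$tray_id,
                                         study$trials$tray_id)],
    pecks = ff$cum_pecks_at_quit,  # final forager: tray total by identity
    species = ff$species,
    density = dens$tray_total_min_individuals[match(ff$tray_id,
                                                    dens$tray_id)])
  out[!is.na(out$gud), , drop = FALSE]
}

#' Yard-type comparison statistics for one study
#'
#' Pools bush/open trays (mean estimated GUD per species per yard, the
#' pooling the paired microhabitat test justifies when no microhabitat
#' effect is found), then computes: the one-way GUD ANOVA by yard type,
#' the ANCOVA with the yard-level density covariate, paired bush/open
#' t-tests per yard type (with and without G0-imputed unvisited trays),
#' per-species Wilcoxon tests, Kruskal-Wallis on consumption rates, the
#' MRPP on the row-normalized rare-filtered community matrix, and the
#' Pielou evenness ANOVA by yard type.
#'
#' @param study A `study_dataset`.
#' @param events Output of [analyze_events()].
#' @param estimates Output of [estimate_species_guds()].
#' @param rates Output of [consumption_rates()].
#' @param config A [default_config()].
#' @return Named list of results (see details); `NULL` entries where a
#'   statistic is not computable from the data at hand.
#' @export
yard_comparisons <- function(study, events, estimates, rates,
                             config = default_config()) {
  trials <- study$trials
  est <- estimates[!estimates$omitted & !estimates$unvisited &
                     !is.na(estimates$gud_estimate), , drop = FALSE]
  est$yard_id <- trials$yard_id[match(est$tray_id, trials$tray_id)]
  est$yard_type <- trials$yard_type[match(est$tray_id, trials$tray_id)]
  est$microhabitat <- trials$microhabitat[match(est$tray_id,
                                                trials$tray_id)]

  # mean GUD per species per yard (bush/open pooled)
  sp_yard <- stats::aggregate(
    list(gud = est$gud_estimate),
    list(yard_id = est$yard_id, yard_type = est$yard_type,
         species = est$species), mean)

  anova_res <- tryCatch(
    gud_anova(sp_yard$gud, sp_yard$yard_type),
    error = function(e) NULL)

  dens <- unique(events$density[c("tray_id", "tray_total_min_individuals")])
  dens$yard_id <- trials$yard_id[match(dens$tray_id, trials$tray_id)]
  yard_density <- stats::aggregate(
    list(density = dens$tray_total_min_individuals),
    list(yard_id = dens$yard_id), mean)
  sp_yard$density <- yard_density$density[match(sp_yard$yard_id,
                                                yard_density$yard_id)]
  ancova_res <- tryCatch(
    gud_ancova(sp_yard$gud, sp_yard$yard_type, sp_yard$density),
    error = function(e) NULL)

  paired <- list()
  for (yt in c("mesic", "xeric")) {
    p <- est[est$yard_type == yt,
             c("yard_id", "species", "microhabitat", "gud_estimate")]
    names(p)[4] <- "gud"
    g0 <- trials$initial_seed_mass_g[1]
    paired[[yt]] <- list(
      visited_only = tryCatch(paired_microhabitat_test(p, FALSE, g0),
                              error = function(e) NULL),
      with_unvisited = tryCatch(paired_microhabitat_test(p, TRUE, g0),
                                error = function(e) NULL))
  }

  rates_ok <- rates[!rates$omitted & !is.na(rates$rate_g_per_h), ,
                    drop = FALSE]
  rates_ok$yard_type <- trials$yard_type[match(rates_ok$tray_id,
                                               trials$tray_id)]
  ranks <- rank_tests(
    sp_yard[c("species", "yard_type", "gud")],
    rates_ok[c("species", "yard_type", "rate_g_per_h")])

  cm <- community_matrix(events$density, trials)
  mrpp_res <- even_anova <- NULL
  if (nrow(cm$matrix) >= 4 && sum(rowSums(cm$matrix) > 0) >= 4) {
    keep <- rowSums(cm$matrix) > 0
    M <- filter_rare(cm$matrix[keep, , drop = FALSE],
                     config$rare_species_min_prop,
                     config$rare_species_inclusive)
    Mn <- row_normalize(M)
    grp <- cm$yard_type[rownames(Mn)]
    mrpp_res <- tryCatch(
      mrpp(Mn, grp, config$n_permutations, config$seed),
      error = function(e) NULL)
    J <- suppressWarnings(apply(cm$matrix[keep, , drop = FALSE], 1,
                                evenness))
    ok <- !is.na(J)
    even_anova <- tryCatch(
      gud_anova(J[ok], cm$yard_type[names(J)[ok]]),
      error = function(e) NULL)
  }

  list(species_yard_guds = sp_yard, anova = anova_res,
       ancova = ancova_res, paired_microhabitat = paired,
       rank_tests = ranks, community = cm, mrpp = mrpp_res,
       evenness_anova = even_anova)
}

#' Run the full pipeline
#'
#' Stages run in dependency order; any failure aborts with the failing
#' stage named. Artifacts (stage CSVs, fit/stats JSON, manifest) are
#' written under `out_dir`.
#'
#' @param out_dir Output directory.
#' @param config A [default_config()].
#' @param input_dir Directory holding `trials.csv`, `pecks.csv`,
#'   `intervals.csv`; ignored when `simulate = TRUE`.
#' @param simulate Generate the study with the built-in simulator
#'   instead of reading files.
#' @param sim_config_ A [sim_config()] used when simulating.
#' @param quiet Suppress per-stage log lines.
#' @return Invisibly, a list with every stage's in-memory result.
#' @export
run_pipeline <- function(out_dir, config = default_config(),
                         input_dir = NULL, simulate = FALSE,
                         sim_config_ = sim_config(), quiet = FALSE) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  say <- function(stage, msg) {
    if (!quiet) message(sprintf("[%s] %s", stage, msg))
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  input_files <- NULL
  study <- run_stage("load", {
    if (simulate) {
      s <- generate_study(sim_config_, seed = config$seed)
      s$config <- config
      write_study(s, out_dir)
      say("load", sprintf("simulated study: %d trials, %d pecks",
                          nrow(s$trials), nrow(s$pecks)))
      s
    } else {
      if (is.null(input_dir)) {
        stop("input_dir required when simulate = FALSE")
      }
      paths <- list(trials = file.path(input_dir, "trials.csv"),
                    pecks = file.path(input_dir, "pecks.csv"),
                    intervals = file.path(input_dir, "intervals.csv"))
      for (p in paths) {
        if (!file.exists(p)) stop("missing input file: ", p)
      }
      input_files <- unlist(paths)
      s <- read_study(paths, config)
      say("load", sprintf("read study: %d trials, %d pecks",
                          nrow(s$trials), nrow(s$pecks)))
      s
    }
  })

  events <- run_stage("events", analyze_events(study))
  say("events", sprintf("%d bouts, %d quit points, %d density rows",
                        nrow(events$bouts), nrow(events$quit_points),
                        nrow(events$density)))
  write_results(events$bouts, file.path(out_dir, "bouts.csv"))
  write_results(events$quit_points, file.path(out_dir, "quit_points.csv"))
  write_results(events$density, file.path(out_dir, "density.csv"))
  write_results(events$foraging_times,
                file.path(out_dir, "foraging_times.csv"))

  train <- run_stage("fit", training_table(study, events))
  fit <- run_stage("fit", fit_gud_peck_model(train))
  say("fit", sprintf("n_train = %d, r^2 = %.3f, Pearson = %.3f",
                     fit$n_train, fit$r_squared, fit$obs_pred_pearson))
  jsonlite::write_json(
    list(beta0 = fit$beta0, beta_pecks = fit$beta_pecks,
         beta_density = fit$beta_density,
         species_effects = as.list(fit$species_effects),
         reference_level = fit$reference_level,
         r_squared = fit$r_squared,
         obs_pred_pearson = fit$obs_pred_pearson,
         n_train = fit$n_train),
    file.path(out_dir, "gud_peck_fit.json"),
    auto_unbox = TRUE, digits = NA)

  estimates <- run_stage("estimate", estimate_species_guds(
    fit, events$quit_points, events$density, study$trials, config))
  say("estimate", sprintf("%d species-tray estimates (%d omitted)",
                          nrow(estimates), sum(estimates$omitted)))
  write_results(
    estimates[c("tray_id", "species", "cum_pecks_at_quit",
                "gud_estimate", "omitted", "is_final_forager",
                "omission_reason", "own_total_pecks", "unvisited")],
    file.path(out_dir, "species_gud_estimates.csv"))

  rates <- run_stage("rates", consumption_rates(
    fit, events$quit_points, events$foraging_times, events$density,
    study$trials, config))
  say("rates", sprintf("%d rate rows (%d omitted)", nrow(rates),
                       sum(rates$omitted)))
  write_results(rates, file.path(out_dir, "consumption_rates.csv"))

  stats_res <- run_stage("stats", yard_comparisons(
    study, events, estimates, rates, config))
  say("stats", "yard-type comparisons done")
  jsonlite::write_json(
    stats_summary_json(stats_res),
    file.path(out_dir, "yard_stats.json"),
    auto_unbox = TRUE, digits = NA, na = "null")

  manifest <- list(
    tool = "gudpeck",
    version = as.character(utils::packageVersion("gudpeck")),
    seed = config$seed,
    config = unclass(config),
    simulated = simulate,
    input_hashes = if (!is.null(input_files))
      as.list(tools::md5sum(input_files)) else NULL,
    outputs = sort(list.files(out_dir))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(study = study, events = events, fit = fit,
                 estimates = estimates, rates = rates,
                 stats = stats_res))
}

stats_summary_json <- function(s) {
  list(
    anova = if (!is.null(s$anova)) list(
      F = s$anova$F, df1 = s$anova$df1, df2 = s$anova$df2,
      p = s$anova$p_value,
      group_means = stats::setNames(as.list(s$anova$group_stats$mean),
                                    s$anova$group_stats$group),
      group_se = stats::setNames(as.list(s$anova$group_stats$se),
                                 s$anova$group_stats$group)),
    ancova = if (!is.null(s$ancova)) list(
      interaction_t = s$ancova$interaction_t,
      interaction_p = s$ancova$interaction_p,
      interaction_estimate = s$ancova$interaction_estimate),
    paired_microhabitat = lapply(s$paired_microhabitat, function(yt)
      lapply(yt, function(r) if (is.null(r)) NULL else
        list(t = r$t, df = r$df, p = r$p_value, n_pairs = r$n_pairs))),
    wilcoxon = if (!is.null(s$rank_tests$wilcoxon))
      s$rank_tests$wilcoxon,
    kruskal_wallis = if (!is.null(s$rank_tests$kruskal_wallis))
      s$rank_tests$kruskal_wallis,
    mrpp = if (!is.null(s$mrpp)) list(
      A = s$mrpp$A, p = s$mrpp$p_value,
      delta_observed = s$mrpp$delta_observed,
      delta_expected = s$mrpp$delta_expected,
      n_permutations = s$mrpp$n_permutations),
    evenness_anova = if (!is.null(s$evenness_anova)) list(
      F = s$evenness_anova$F, df1 = s$evenness_anova$df1,
      df2 = s$evenness_anova$df2, p = s$evenness_anova$p_value)
  )
}
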