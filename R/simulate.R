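#' @title Mechanistic foraging simulator
#' @description An event-driven optimal-foraging simulator with known
#'   ground truth. Birds arrive at a depletable seed tray as a Poisson
#'   process, peck at a species-specific rate, share one seed ledger, and
#'   quit permanently once the expected yield of the next peck drops
#'   below the species' quitting threshold (its marginal value of
#'   continued foraging). Two depletion modes: `constant_yield` (each
#'   peck removes exactly `y_max` grams until the patch is effectively
#'   empty) and `diminishing_returns` (a peck finds a seed worth `y_max`
#'   with probability `G / G0`, so the expected yield `y_max * G / G0`
#'   falls as the patch depletes and each species has a sharp
#'   theoretical giving-up density `GUD* = G0 * q / y_max`).
#' @name synthetic_data
NULL

#' Define a species' foraging profile
#'
#' @param code 4-letter species code.
#' @param q Quitting threshold in grams per peck: the minimum acceptable
#'   expected yield. In diminishing-returns mode the theoretical GUD is
#'   `G0 * q / y_max`.
#' @param peck_rate Pecks per minute while actively foraging.
#' @param arrival_rate Named vector `c(mesic = , xeric = )`, arrivals
#'   (groups) per hour per tray.
#' @param group_size_probs Probabilities for group sizes 1, 2, ...
#' @param class_probs Named probabilities of demographic class tags
#'   (e.g. male/female; use `"unknown"` for monomorphic species).
#' @param pause_prob Per-peck probability of inserting a pause at least
#'   as long as the bout gap (creates multi-bout visits).
#' @return A `species_profile` list.
#' @export
species_profile <- function(code, q, peck_rate,
                            arrival_rate = c(mesic = 0.3, xeric = 0.3),
                            group_size_probs = 1,
                            class_probs = c(unknown = 1),
                            pause_prob = 0.02) {
  stopifnot(nzchar(code), q > 0, peck_rate > 0,
            all(arrival_rate >= 0),
            abs(sum(group_size_probs) - 1) < 1e-9,
            abs(sum(class_probs) - 1) < 1e-9,
            pause_prob >= 0, pause_prob < 1)
  structure(list(code = code, q = q, peck_rate = peck_rate,
                 arrival_rate = arrival_rate,
                 group_size_probs = group_size_probs,
                 class_probs = class_probs,
                 pause_prob = pause_prob),
            class = "species_profile")
}

#' Default species pool for the two residential yard designs
#'
#' Eight granivorous species spanning the observed range of quitting
#' thresholds and visit structure. Invasive/synanthropic species (house
#' sparrow, Inca dove, mourning dove) arrive far more often in mesic
#' (lush exotic) yards; quail and white-crowned sparrow favour xeric
#' (native/drought-tolerant) yards. Arrival rates are set so a 24 h tray
#' sees on the order of 14 individuals in mesic and 8 in xeric yards
#' (the visitation scale of residential seed-tray studies), which also
#' makes the species pool — and hence the final forager and the tray's
#' final GUD — vary from tray to tray. With the default
#' `y_max = 0.01` g/peck the theoretical mesic GUDs run from 3 g
#' (curve-billed thrasher) to 9 g.
#'
#' @return Named list of [species_profile()] objects.
#' @export
default_species_profiles <- function() {
  list(
    ABTO = species_profile("ABTO", q = 0.0025, peck_rate = 40,
      arrival_rate = c(mesic = 0.050, xeric = 0.045)),
    CBTH = species_profile("CBTH", q = 0.0015, peck_rate = 60,
      arrival_rate = c(mesic = 0.045, xeric = 0.035)),
    HOFI = species_profile("HOFI", q = 0.0030, peck_rate = 45,
      arrival_rate = c(mesic = 0.060, xeric = 0.035),
      group_size_probs = c(0.6, 0.4),
      class_probs = c(male = 0.5, female = 0.5)),
    HOSP = species_profile("HOSP", q = 0.0020, peck_rate = 50,
      arrival_rate = c(mesic = 0.120, xeric = 0.020),
      group_size_probs = c(0.3, 0.4, 0.2, 0.1),
      class_probs = c(male = 0.5, female = 0.5)),
    INDO = species_profile("INDO", q = 0.0035, peck_rate = 35,
      arrival_rate = c(mesic = 0.060, xeric = 0.008)),
    MODO = species_profile("MODO", q = 0.0040, peck_rate = 30,
      arrival_rate = c(mesic = 0.045, xeric = 0.015),
      group_size_probs = c(0.7, 0.3)),
    GAQU = species_profile("GAQU", q = 0.0042, peck_rate = 30,
      arrival_rate = c(mesic = 0.000, xeric = 0.020),
      group_size_probs = c(0.5, 0.3, 0.2)),
    WCSP = species_profile("WCSP", q = 0.0045, peck_rate = 35,
      arrival_rate = c(mesic = 0.010, xeric = 0.035))
  )
}

#' Simulation configuration
#'
#' @param n_yards_per_type Yards per design (default 10 + 10).
#' @param G0 Initial seed mass in grams (default 20, the field
#'   provisioning).
#' @param duration_s Trial length in seconds (default 24 h).
#' @param y_max Grams removed per peck at a full patch (default 0.01, so
#'   a full 20 g tray is ~2000 pecks).
#' @param mode `"diminishing_returns"` (default) or `"constant_yield"`.
#' @param gud_weighing_sd SD of the weighing noise on the measured final
#'   GUD, grams (default 0.05; truncated to `[0, G0]` by clamping).
#' @param bout_gap_s Pause length floor used by the bout-leave mechanism
#'   (matches the analysis bout gap; default 60).
#' @param xeric_q_scale Multiplier on quitting thresholds in xeric yards
#'   (default 2): richer alternative resources there make birds quit at
#'   a higher harvest rate.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_yards_per_type = 10, G0 = 20,
                       duration_s = 86400, y_max = 0.01,
                       mode = c("diminishing_returns", "constant_yield"),
                       gud_weighing_sd = 0.05, bout_gap_s = 60,
                       xeric_q_scale = 2) {
  mode <- match.arg(mode)
  if (y_max <= 0) stop("y_max must be positive", call. = FALSE)
  stopifnot(n_yards_per_type >= 1, G0 > 0, duration_s > 0,
            gud_weighing_sd >= 0, bout_gap_s > 0, xeric_q_scale > 0)
  structure(list(n_yards_per_type = as.integer(n_yards_per_type),
                 G0 = G0, duration_s = duration_s, y_max = y_max,
                 mode = mode, gud_weighing_sd = gud_weighing_sd,
                 bout_gap_s = bout_gap_s, xeric_q_scale = xeric_q_scale),
            class = "sim_config")
}

# expected yield of the next peck at seed mass G; foragers assess this
# (not the realised yield) against their quitting threshold
expected_yield <- function(G, config) {
  if (config$mode == "constant_yield") {
    if (G >= config$y_max) config$y_max else 0
  } else {
    config$y_max * G / config$G0
  }
}

# realised yield of one peck: constant mode removes exactly y_max;
# diminishing mode is a seed find with probability G/G0 (seeds thin out
# in the sand as the patch depletes), so the expectation is y_max*G/G0
realized_yield <- function(G, config) {
  if (config$mode == "constant_yield") {
    config$y_max
  } else if (stats::runif(1) < G / config$G0) {
    min(config$y_max, G)
  } else {
    0
  }
}

#' Simulate one 24 h tray deployment
#'
#' Uses the current RNG stream (seed it, or let [generate_study()] do
#' so). Arrivals per species are Poisson; each arriving group's
#' individuals peck with exponential inter-peck gaps (capped just below
#' the bout gap so that only the explicit pause mechanism breaks bouts),
#' share the seed ledger in global time order, and depart permanently
#' when the expected yield falls below their quitting threshold. Visit
#' intervals start at arrival (first peck within 5 s) and end within
#' 10 s of the final peck, emulating scored on/off-tray times.
#'
#' @param profiles List of [species_profile()]s.
#' @param config A [sim_config()].
#' @param yard_type `"mesic"` or `"xeric"` (selects arrival rates and
#'   threshold scaling).
#' @return List `pecks`, `intervals` (data frames without tray ids),
#'   `measured_final_gud`, and `truth` (exact ledger: final mass,
#'   per-species grams consumed / quit time / GUD at quit, per-class
#'   individual counts, theoretical per-species GUD*).
#' @export
simulate_tray <- function(profiles, config, yard_type = "mesic") {
  stopifnot(inherits(config, "sim_config"),
            yard_type %in% c("mesic", "xeric"))
  qs <- vapply(profiles, function(p) p$q, numeric(1)) *
    if (yard_type == "xeric") config$xeric_q_scale else 1
  if (all(qs >= config$y_max)) {
    stop("no species can forage: every quitting threshold >= y_max",
         call. = FALSE)
  }
  rates <- vapply(profiles, function(p)
    unname(p$arrival_rate[[yard_type]]), numeric(1))
  if (all(rates == 0)) {
    # an empty tray is a legal outcome, not an error
  }
  dur_h <- config$duration_s / 3600

  # --- draw all arrivals -------------------------------------------------
  ind <- list(); k <- 0L
  for (i in seq_along(profiles)) {
    p <- profiles[[i]]
    n_arr <- stats::rpois(1, rates[i] * dur_h)
    if (n_arr == 0) next
    t_arr <- sort(stats::runif(n_arr, 0, config$duration_s))
    for (a in seq_len(n_arr)) {
      gsz <- sample.int(length(p$group_size_probs), 1,
                        prob = p$group_size_probs)
      for (g in seq_len(gsz)) {
        k <- k + 1L
        ind[[k]] <- list(
          species = p$code,
          class_tag = sample(names(p$class_probs), 1,
                             prob = p$class_probs),
          q = qs[i], peck_rate = p$peck_rate,
          pause_prob = p$pause_prob, t_arr = t_arr[a])
      }
    }
  }
  empty_truth <- function(G) list(
    final_mass = G,
    species = data.frame(species = character(0),
                         grams_consumed = numeric(0),
                         t_quit = numeric(0), gud_at_quit = numeric(0)),
    class_counts = data.frame(species = character(0),
                              class_tag = character(0), n = integer(0)),
    gud_star = config$G0 * qs / config$y_max)

  mk_gud <- function(G) {
    g <- G + stats::rnorm(1, 0, config$gud_weighing_sd)
    min(max(g, 0), config$G0)
  }
  if (k == 0L) {
    return(list(
      pecks = data.frame(species = character(0), class_tag = character(0),
                         t_seconds = numeric(0)),
      intervals = data.frame(species = character(0),
                             class_tag = character(0),
                             t_on = numeric(0), t_off = numeric(0)),
      measured_final_gud = mk_gud(config$G0),
      truth = empty_truth(config$G0)))
  }

  # --- event loop over pecks --------------------------------------------
  n_ind <- k
  sp_i <- vapply(ind, `[[`, character(1), "species")
  cl_i <- vapply(ind, `[[`, character(1), "class_tag")
  q_i <- vapply(ind, `[[`, numeric(1), "q")
  rate_i <- vapply(ind, `[[`, numeric(1), "peck_rate") / 60  # per second
  pp_i <- vapply(ind, `[[`, numeric(1), "pause_prob")
  t_on <- vapply(ind, `[[`, numeric(1), "t_arr")
  gap_cap <- 0.9 * config$bout_gap_s

  # next scheduled peck per individual (NA once departed)
  next_t <- t_on + stats::runif(n_ind, 0, 5)
  last_peck <- rep(NA_real_, n_ind)
  t_off <- rep(NA_real_, n_ind)
  G <- config$G0
  consumed <- stats::setNames(rep(0, length(profiles)),
                              vapply(profiles, `[[`, character(1), "code"))
  sp_last_peck <- sp_gud_at_quit <- stats::setNames(
    rep(NA_real_, length(profiles)), names(consumed))

  cap <- as.integer(min(4 * config$G0 / config$y_max + 100 * n_ind, 5e5))
  pk_t <- numeric(cap); pk_i <- integer(cap); n_pk <- 0L

  depart <- function(i, now) {
    # departure 0-10 s after the final peck; arrival-only visits leave fast
    base <- if (is.na(last_peck[i])) t_on[i] + stats::runif(1, 0, 2)
            else last_peck[i] + stats::runif(1, 0, 10)
    t_off[i] <<- min(base, config$duration_s)
    next_t[i] <<- NA_real_
  }

  repeat {
    if (all(is.na(next_t))) break
    i <- which.min(next_t)
    now <- next_t[i]
    if (now > config$duration_s) { depart(i, now); next }
    ey <- expected_yield(G, config)
    if (ey < q_i[i] || ey <= 0) { depart(i, now); next }
    # peck: remove the realised yield, log the event
    y <- realized_yield(G, config)
    G <- G - y
    consumed[sp_i[i]] <- consumed[sp_i[i]] + y
    n_pk <- n_pk + 1L
    if (n_pk > cap) stop("peck buffer overflow (misconfigured simulation)")
    pk_t[n_pk] <- now; pk_i[n_pk] <- i
    last_peck[i] <- now
    sp_last_peck[sp_i[i]] <- now
    sp_gud_at_quit[sp_i[i]] <- G
    dt <- min(stats::rexp(1, rate_i[i]), gap_cap)
    if (stats::runif(1) < pp_i[i]) {
      dt <- dt + config$bout_gap_s + stats::rexp(1, 1 / 30)
    }
    next_t[i] <- now + dt
  }

  seen <- sort(unique(pk_i[seq_len(n_pk)]))
  visited_sp <- unique(sp_i[seen])
  ord <- seq_len(n_pk)
  pecks <- data.frame(species = sp_i[pk_i[ord]],
                      class_tag = cl_i[pk_i[ord]],
                      t_seconds = pk_t[ord])
  # only individuals that actually pecked are observable on video
  intervals <- data.frame(species = sp_i[seen], class_tag = cl_i[seen],
                          t_on = t_on[seen], t_off = t_off[seen])
  cc <- if (length(seen) > 0) {
    stats::aggregate(list(n = seq_along(seen)),
                     list(species = sp_i[seen], class_tag = cl_i[seen]),
                     length)
  } else {
    data.frame(species = character(0), class_tag = character(0),
               n = integer(0))
  }
  truth <- list(
    final_mass = config$G0 - sum(consumed),  # exact ledger identity
    species = data.frame(
      species = visited_sp,
      grams_consumed = unname(consumed[visited_sp]),
      t_quit = unname(sp_last_peck[visited_sp]),
      gud_at_quit = unname(sp_gud_at_quit[visited_sp]),
      row.names = NULL),
    class_counts = cc,
    gud_star = config$G0 * qs / config$y_max)
  list(pecks = pecks, intervals = intervals,
       measured_final_gud = mk_gud(truth$final_mass), truth = truth)
}

#' Generate a full two-design residential study
#'
#' Simulates `n_yards_per_type` yards of each design, each with one tray
#' next to bushes and one in the open (microhabitat labels are
#' behaviourally neutral: the field study found no microhabitat effect),
#' and assembles the result in the study CSV schema with exact ground
#' truth attached.
#'
#' @param config A [sim_config()].
#' @param profiles Species pool (default [default_species_profiles()]).
#' @param seed Integer seed; identical seeds give identical studies.
#' @return A `study_dataset` with an extra `ground_truth` element
#'   (per-tray truth objects keyed by tray id).
#' @export
generate_study <- function(config = sim_config(),
                           profiles = default_species_profiles(),
                           seed = 1L) {
  set.seed(seed)
  trials_l <- list(); pecks_l <- list(); iv_l <- list(); truth <- list()
  for (yt in c("mesic", "xeric")) {
    for (y in seq_len(config$n_yards_per_type)) {
      yard_id <- sprintf("%s%02d", toupper(substr(yt, 1, 1)), y)
      for (mh in c("bush", "open")) {
        tray_id <- paste0(yard_id, "_", toupper(substr(mh, 1, 1)))
        sim <- simulate_tray(profiles, config, yt)
        trials_l[[tray_id]] <- data.frame(
          tray_id = tray_id, yard_id = yard_id, yard_type = yt,
          microhabitat = mh, initial_seed_mass_g = config$G0,
          duration_s = config$duration_s,
          final_gud_g = round(sim$measured_final_gud, 2))
        if (nrow(sim$pecks) > 0) {
          sim$pecks$tray_id <- tray_id
          pecks_l[[tray_id]] <- sim$pecks
        }
        if (nrow(sim$intervals) > 0) {
          sim$intervals$tray_id <- tray_id
          iv_l[[tray_id]] <- sim$intervals
        }
        truth[[tray_id]] <- sim$truth
      }
    }
  }
  bind <- function(l, cols, proto) {
    if (length(l) == 0) return(proto)
    out <- do.call(rbind, c(l, make.row.names = FALSE))
    out[cols]
  }
  study <- structure(list(
    trials = do.call(rbind, c(trials_l, make.row.names = FALSE)),
    pecks = bind(pecks_l, PECKS_COLS, data.frame(
      tray_id = character(0), species = character(0),
      class_tag = character(0), t_seconds = numeric(0))),
    intervals = bind(iv_l, INTERVALS_COLS, data.frame(
      tray_id = character(0), species = character(0),
      class_tag = character(0), t_on = numeric(0), t_off = numeric(0))),
    config = default_config(seed = seed),
    ground_truth = truth
  ), class = "study_dataset")
  study
}
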