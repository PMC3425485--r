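#' Default run configuration
#'
#' Analysis-wide knobs shared by the pipeline stages. Values mirror the
#' field protocol the package models: a one-minute bout gap, the 40-peck
#' omission cut-off for model-based estimates, 999 label permutations for
#' MRPP, and a 5% site-occurrence floor for rare species.
#'
#' @param bout_gap_s Inter-peck gap (seconds) at or above which a foraging
#'   bout ends. Default 60.
#' @param peck_min_threshold Minimum own-species peck count below which a
#'   model-based GUD/consumption estimate is flagged as omitted. Default 40.
#' @param n_permutations Number of random relabelings in MRPP. Default 999.
#' @param rare_species_min_prop Species occurring at strictly less than this
#'   proportion of sites are dropped from the community matrix. Default 0.05.
#' @param rare_species_inclusive If `TRUE` the occurrence rule is
#'   `<=` instead of strict `<` (both readings of "less than 5% of sites"
#'   are supported; strict is the default).
#' @param consumption_pecks_basis Peck count entered into the GUD-Peck model
#'   when computing per-species consumption: `"own"` (that species' pecks,
#'   the default) or `"cumulative"` (all pecks up to its quit point).
#' @param seed Integer RNG seed used by every stochastic stage.
#' @return A named list with class `gudpeck_config`.
#' @export
default_config <- function(bout_gap_s = 60,
                           peck_min_threshold = 40,
                           n_permutations = 999,
                           rare_species_min_prop = 0.05,
                           rare_species_inclusive = FALSE,
                           consumption_pecks_basis = c("own", "cumulative"),
                           seed = 1L) {
  stopifnot(bout_gap_s > 0, peck_min_threshold >= 0, n_permutations >= 1,
            rare_species_min_prop >= 0, rare_species_min_prop < 1)
  cfg <- list(
    bout_gap_s = bout_gap_s,
    peck_min_threshold = peck_min_threshold,
    n_permutations = as.integer(n_permutations),
    rare_species_min_prop = rare_species_min_prop,
    rare_species_inclusive = isTRUE(rare_species_inclusive),
    consumption_pecks_basis = match.arg(consumption_pecks_basis),
    seed = as.integer(seed)
  )
  class(cfg) <- "gudpeck_config"
  cfg
}

#' Read a run configuration from a YAML or JSON file
#'
#' Unknown keys raise an error; missing keys keep their defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `gudpeck_config` list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  defaults <- default_config()
  allowed <- setdiff(names(defaults), character())
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown) > 0) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(default_config, utils::modifyList(unclass(defaults)[
    c("bout_gap_s", "peck_min_threshold", "n_permutations",
      "rare_species_min_prop", "rare_species_inclusive",
      "consumption_pecks_basis", "seed")], raw))
}
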