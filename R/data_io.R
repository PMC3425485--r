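#' @title Study dataset I/O
#' @description Readers and writers for the three CSV tables the pipeline
#'   consumes: peck events, visit intervals and tray trials. All files are
#'   comma-separated UTF-8 with a mandatory header row and "." decimals.
#' @name data_io
NULL

PECKS_COLS     <- c("tray_id", "species", "class_tag", "t_seconds")
INTERVALS_COLS <- c("tray_id", "species", "class_tag", "t_on", "t_off")
TRIALS_COLS    <- c("tray_id", "yard_id", "yard_type", "microhabitat",
                    "initial_seed_mass_g", "duration_s", "final_gud_g")

# fixed output precision for floats (GUDs are weighed to 0.01 g; 4 dp is
# finer than any measured quantity and makes write/read/write idempotent)
FLOAT_DIGITS <- 4L

read_table_checked <- function(path, required, what) {
  if (!file.exists(path)) {
    stop(sprintf("%s file not found: %s", what, path), call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s (%s): missing required column(s): %s",
                 what, path, paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  df[required]
}

num_col <- function(df, col, what) {
  out <- suppressWarnings(as.numeric(df[[col]]))
  bad <- which(is.na(out) & !(df[[col]] %in% c("", "NA")))
  if (length(bad) > 0) {
    stop(sprintf("%s: non-numeric '%s' at data row(s) %s", what, col,
                 paste(utils::head(bad, 5), collapse = ", ")),
         call. = FALSE)
  }
  out
}

#' Read a full study (trials, peck events, visit intervals)
#'
#' Loads and cross-references the three study tables. Every peck and
#' interval must refer to a known tray, peck times must fall within the
#' trial duration, and interval bounds must be ordered. Violations are
#' reported with the offending tray id and row number.
#'
#' @param paths Named list or vector with elements `trials`, `pecks`,
#'   `intervals` giving CSV file paths.
#' @param config A [default_config()] list (kept alongside the data so
#'   later stages share one set of thresholds).
#' @return A `study_dataset`: list with data frames `trials`, `pecks`,
#'   `intervals` and the `config`.
#' @export
read_study <- function(paths, config = default_config()) {
  stopifnot(all(c("trials", "pecks", "intervals") %in% names(paths)))
  trials <- read_table_checked(paths[["trials"]], TRIALS_COLS, "trials")
  pecks <- read_table_checked(paths[["pecks"]], PECKS_COLS, "pecks")
  intervals <- read_table_checked(paths[["intervals"]], INTERVALS_COLS,
                                  "intervals")

  trials$initial_seed_mass_g <- num_col(trials, "initial_seed_mass_g", "trials")
  trials$duration_s <- num_col(trials, "duration_s", "trials")
  trials$final_gud_g <- suppressWarnings(as.numeric(trials$final_gud_g))
  pecks$t_seconds <- num_col(pecks, "t_seconds", "pecks")
  intervals$t_on <- num_col(intervals, "t_on", "intervals")
  intervals$t_off <- num_col(intervals, "t_off", "intervals")

  if (anyDuplicated(trials$tray_id)) {
    stop("trials: duplicated tray_id(s): ",
         paste(unique(trials$tray_id[duplicated(trials$tray_id)]),
               collapse = ", "), call. = FALSE)
  }
  bad_type <- !trials$yard_type %in% c("mesic", "xeric")
  if (any(bad_type)) {
    stop("trials: yard_type must be 'mesic' or 'xeric' (row(s) ",
         paste(which(bad_type), collapse = ", "), ")", call. = FALSE)
  }
  bad_micro <- !trials$microhabitat %in% c("bush", "open")
  if (any(bad_micro)) {
    stop("trials: microhabitat must be 'bush' or 'open' (row(s) ",
         paste(which(bad_micro), collapse = ", "), ")", call. = FALSE)
  }
  if (any(trials$initial_seed_mass_g <= 0)) {
    stop("trials: initial_seed_mass_g must be positive", call. = FALSE)
  }
  gud_hi <- !is.na(trials$final_gud_g) &
    trials$final_gud_g > trials$initial_seed_mass_g + 0.05
  if (any(gud_hi) || any(trials$final_gud_g < 0, na.rm = TRUE)) {
    stop("trials: final_gud_g outside [0, initial mass] (row(s) ",
         paste(which(gud_hi | (!is.na(trials$final_gud_g) &
                                 trials$final_gud_g < 0)), collapse = ", "),
         ")", call. = FALSE)
  }

  check_refs <- function(df, what, tcol) {
    unknown <- !(df$tray_id %in% trials$tray_id)
    if (any(unknown)) {
      stop(sprintf("%s: unknown tray_id '%s' at row %d", what,
                   df$tray_id[which(unknown)[1]], which(unknown)[1]),
           call. = FALSE)
    }
    dur <- trials$duration_s[match(df$tray_id, trials$tray_id)]
    for (col in tcol) {
      out <- df[[col]] < 0 | df[[col]] > dur
      if (any(out)) {
        i <- which(out)[1]
        stop(sprintf(
          "%s: %s = %g outside [0, duration] for tray '%s' at row %d",
          what, col, df[[col]][i], df$tray_id[i], i), call. = FALSE)
      }
    }
  }
  if (nrow(pecks) > 0) check_refs(pecks, "pecks", "t_seconds")
  if (nrow(intervals) > 0) {
    check_refs(intervals, "intervals", c("t_on", "t_off"))
    rev_iv <- intervals$t_on > intervals$t_off
    if (any(rev_iv)) {
      stop("intervals: t_on > t_off at row(s) ",
           paste(which(rev_iv), collapse = ", "), call. = FALSE)
    }
  }
  if (any(pecks$species == "") || any(intervals$species == "")) {
    stop("species codes must be non-empty", call. = FALSE)
  }

  structure(list(trials = trials, pecks = pecks, intervals = intervals,
                 config = config),
            class = "study_dataset")
}

#' Write a pipeline stage result table as CSV
#'
#' Columns are written in their data-frame order; floating-point columns
#' are fixed at 4 decimal places so that re-reading reproduces values to
#' the documented precision and write/read/write is byte-identical.
#'
#' @param results A data frame (an empty one yields a header-only file).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  stopifnot(is.data.frame(results))
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  out <- results
  for (col in names(out)) {
    if (is.double(out[[col]])) {
      v <- out[[col]]
      s <- sprintf(paste0("%.", FLOAT_DIGITS, "f"), v)
      s[is.na(v)] <- "NA"
      out[[col]] <- s
    } else if (is.logical(out[[col]])) {
      out[[col]] <- ifelse(is.na(out[[col]]), "NA",
                           ifelse(out[[col]], "TRUE", "FALSE"))
    }
  }
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA")
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) {
    stop("cannot write results to ", path, ": ", conditionMessage(ok),
         call. = FALSE)
  }
  invisible(path)
}

#' Write a study dataset to a directory as pecks/intervals/trials CSVs
#'
#' @param study A `study_dataset`.
#' @param dir Output directory (created if needed).
#' @return Named vector of the three file paths, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "study_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(trials = file.path(dir, "trials.csv"),
             pecks = file.path(dir, "pecks.csv"),
             intervals = file.path(dir, "intervals.csv"))
  write_results(study$trials[TRIALS_COLS], paths[["trials"]])
  write_results(study$pecks[PECKS_COLS], paths[["pecks"]])
  write_results(study$intervals[INTERVALS_COLS], paths[["intervals"]])
  invisible(paths)
}
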