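#' @title Event-log analysis
#' @description Per-species foraging quantities derived from video-scored
#'   event logs: bout segmentation, minimum residency time, quitting
#'   points with cumulative peck counts, the final forager, and
#'   minimum-individual density from visit concurrency.
#' @name event_analysis
NULL

#' Segment one species' pecks on one tray into foraging bouts
#'
#' A bout starts with the species' first peck and ends once at least
#' `gap` seconds pass without a peck ("at least one minute" is inclusive:
#' a gap of exactly `gap` terminates the bout). Input order is irrelevant;
#' times are sorted internally.
#'
#' @param t Numeric vector of peck times (seconds) for one tray+species.
#' @param gap Bout-terminating gap in seconds (> 0), default 60.
#' @return Data frame with columns `t_start`, `t_end`, `n_pecks`
#'   (zero rows for an empty peck set).
#' @export
segment_bouts <- function(t, gap = 60) {
  stopifnot(is.numeric(gap), length(gap) == 1, gap > 0)
  if (length(t) == 0) {
    return(data.frame(t_start = numeric(0), t_end = numeric(0),
                      n_pecks = integer(0)))
  }
  t <- sort(as.numeric(t))
  new_bout <- c(TRUE, diff(t) >= gap)
  id <- cumsum(new_bout)
  data.frame(
    t_start = as.numeric(tapply(t, id, min)),
    t_end = as.numeric(tapply(t, id, max)),
    n_pecks = as.integer(tapply(t, id, length)),
    row.names = NULL
  )
}

#' Total foraging time from a set of bouts
#'
#' Sums bout lengths `t_end - t_start`. Time on the tray before the first
#' peck and after the last is excluded by construction, so this is a
#' minimum residency time.
#'
#' @param bouts Data frame from [segment_bouts()].
#' @return Seconds (0 for no bouts).
#' @export
foraging_time <- function(bouts) {
  if (nrow(bouts) == 0) return(0)
  sum(bouts$t_end - bouts$t_start)
}

#' Minimum number of individuals from visit concurrency
#'
#' Birds are unmarked, so density can only be bounded from below. Within
#' each distinguishable demographic class (e.g. male/female plumage;
#' `"unknown"` is its own class) the bound is the maximum number of
#' simultaneously present visit intervals; non-overlapping visits within a
#' class are assumed repeat visitors. Distinguishable classes cannot share
#' individuals, so the tray+species minimum is the sum of class-wise
#' maxima. Intervals touching only at an endpoint do not count as
#' simultaneous.
#'
#' @param intervals Data frame with `class_tag`, `t_on`, `t_off` for one
#'   tray+species (empty allowed).
#' @return Integer count (0 for no intervals).
#' @export
min_individuals <- function(intervals) {
  if (nrow(intervals) == 0) return(0L)
  stopifnot(all(intervals$t_on <= intervals$t_off))
  per_class <- vapply(split(intervals, intervals$class_tag),
                      function(d) max_overlap(d$t_on, d$t_off), integer(1))
  sum(per_class)
}

# sweep line: +1 at each t_on, -1 at each t_off; at equal times the
# departure is processed first (open-interval overlap convention)
max_overlap <- function(t_on, t_off) {
  n <- length(t_on)
  if (n == 0) return(0L)
  times <- c(t_on, t_off)
  delta <- c(rep(1L, n), rep(-1L, n))
  # order by time, then departures (-1) before arrivals (+1)
  o <- order(times, delta)
  max(cumsum(delta[o]))
}

#' Minimum-individual density table for a study
#'
#' Applies [min_individuals()] to every tray+species and adds the tray
#' total (the density covariate of the GUD-Peck model).
#'
#' @param study A `study_dataset`.
#' @return Data frame `tray_id`, `species`, `min_individuals`,
#'   `tray_total_min_individuals`.
#' @export
density_table <- function(study) {
  iv <- study$intervals
  keys <- unique(iv[c("tray_id", "species")])
  # trays with no intervals still need a zero-density row downstream
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    d <- iv[iv$tray_id == keys$tray_id[i] & iv$species == keys$species[i], ]
    data.frame(tray_id = keys$tray_id[i], species = keys$species[i],
               min_individuals = min_individuals(d))
  })
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(tray_id = character(0), species = character(0),
               min_individuals = integer(0))
  totals <- tapply(out$min_individuals, out$tray_id, sum)
  out$tray_total_min_individuals <-
    as.integer(totals[out$tray_id])
  out[order(out$tray_id, out$species), , drop = FALSE]
}

#' Quitting points for every species on one tray
#'
#' A species' quitting point is the time of its last peck; the cumulative
#' peck count at quitting includes pecks by all species up to and
#' including that time (earlier and concurrent visitors count, later
#' visitors do not).
#'
#' @param pecks Data frame with `species`, `t_seconds` for one tray.
#' @return Data frame `species`, `t_quit`, `cum_pecks_at_quit`,
#'   `own_total_pecks`, sorted by `t_quit`.
#' @export
quit_points <- function(pecks) {
  if (nrow(pecks) == 0) {
    return(data.frame(species = character(0), t_quit = numeric(0),
                      cum_pecks_at_quit = integer(0),
                      own_total_pecks = integer(0)))
  }
  t_all <- pecks$t_seconds
  sp <- unique(pecks$species)
  t_quit <- vapply(sp, function(s) max(t_all[pecks$species == s]),
                   numeric(1))
  out <- data.frame(
    species = sp,
    t_quit = t_quit,
    cum_pecks_at_quit = vapply(t_quit, function(tq)
      sum(t_all <= tq), integer(1)),
    own_total_pecks = vapply(sp, function(s)
      sum(pecks$species == s), integer(1)),
    row.names = NULL
  )
  out[order(out$t_quit, out$species), , drop = FALSE]
}

#' The final forager on a tray
#'
#' The species delivering the last peck; the seed remaining at that point
#' is the tray's measured GUD. Exact time ties (practically impossible at
#' video-frame resolution) are broken towards the lexicographically
#' smallest species code for determinism.
#'
#' @param pecks Data frame with `species`, `t_seconds` for one tray.
#' @return Species code (length-1 character).
#' @export
final_forager <- function(pecks) {
  if (nrow(pecks) == 0) {
    stop("unvisited tray: no pecks, no final forager", call. = FALSE)
  }
  last_t <- max(pecks$t_seconds)
  cand <- sort(unique(pecks$species[pecks$t_seconds == last_t]))
  cand[1]
}

#' Per-tray, per-species event summaries for a whole study
#'
#' Runs bout segmentation, quitting-point and foraging-time computation
#' over every tray, plus the minimum-individual density table.
#'
#' @param study A `study_dataset`.
#' @return List of data frames: `bouts`, `quit_points` (with
#'   `is_final_forager`), `foraging_times`, `density`.
#' @export
analyze_events <- function(study) {
  gap <- study$config$bout_gap_s
  pecks <- study$pecks
  bouts_l <- list(); qp_l <- list(); ft_l <- list()
  for (tray in unique(study$trials$tray_id)) {
    p <- pecks[pecks$tray_id == tray, , drop = FALSE]
    if (nrow(p) == 0) next
    qp <- quit_points(p)
    qp$tray_id <- tray
    qp$is_final_forager <- qp$species == final_forager(p)
    qp_l[[tray]] <- qp
    for (s in unique(p$species)) {
      b <- segment_bouts(p$t_seconds[p$species == s], gap)
      b$tray_id <- tray; b$species <- s
      bouts_l[[paste(tray, s)]] <- b
      ft_l[[paste(tray, s)]] <- data.frame(
        tray_id = tray, species = s,
        foraging_time_s = foraging_time(b))
    }
  }
  rbind_or <- function(l, proto) if (length(l) > 0) do.call(rbind, l) else proto
  bouts <- rbind_or(bouts_l, data.frame(
    t_start = numeric(0), t_end = numeric(0), n_pecks = integer(0),
    tray_id = character(0), species = character(0)))
  qp <- rbind_or(qp_l, data.frame(
    species = character(0), t_quit = numeric(0),
    cum_pecks_at_quit = integer(0), own_total_pecks = integer(0),
    tray_id = character(0), is_final_forager = logical(0)))
  ft <- rbind_or(ft_l, data.frame(
    tray_id = character(0), species = character(0),
    foraging_time_s = numeric(0)))
  rownames(bouts) <- rownames(qp) <- rownames(ft) <- NULL
  list(
    bouts = bouts[c("tray_id", "species", "t_start", "t_end", "n_pecks")],
    quit_points = qp[c("tray_id", "species", "t_quit",
                       "cum_pecks_at_quit", "own_total_pecks",
                       "is_final_forager")],
    foraging_times = ft,
    density = density_table(study)
  )
}
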