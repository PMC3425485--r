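#' @title Community and yard-type statistics
#' @description Yard-type comparisons: the multi-response permutation
#'   procedure (MRPP) on a Bray-Curtis distance matrix, Pielou evenness,
#'   one-way ANOVA and ANCOVA on GUDs, the paired bush/open microhabitat
#'   test, and the nonparametric rank tests.
#' @name community_stats
NULL

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' `sum(|x - y|) / sum(x + y)`; bounded in [0, 1], 0 for identical
#' vectors and 1 for disjoint supports.
#'
#' @param x,y Non-negative numeric vectors of equal length, not both
#'   all-zero.
#' @return Dissimilarity in [0, 1].
#' @export
bray_curtis <- function(x, y) {
  stopifnot(length(x) == length(y), all(x >= 0), all(y >= 0))
  tot <- sum(x + y)
  if (tot == 0) {
    stop("Bray-Curtis undefined: both vectors all-zero", call. = FALSE)
  }
  sum(abs(x - y)) / tot
}

bray_curtis_matrix <- function(M) {
  n <- nrow(M)
  D <- matrix(0, n, n, dimnames = list(rownames(M), rownames(M)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- bray_curtis(M[i, ], M[j, ])
    }
  }
  D
}

#' Row-normalize a community matrix
#'
#' Divides each site row by its total so rows describe species
#' composition (used when the coefficient of variation of raw densities
#' is high). All-zero rows are dropped with a warning.
#'
#' @param M Non-negative numeric matrix, sites x species.
#' @return Matrix with unit row sums.
#' @export
row_normalize <- function(M) {
  stopifnot(is.matrix(M), all(M >= 0))
  totals <- rowSums(M)
  if (any(totals == 0)) {
    warning("dropping ", sum(totals == 0), " all-zero site row(s)")
    M <- M[totals > 0, , drop = FALSE]
    totals <- totals[totals > 0]
  }
  sweep(M, 1, totals, "/")
}

#' Drop insufficiently sampled (rare) species columns
#'
#' Removes species whose occurrence (proportion of sites with a nonzero
#' cell) is below `min_prop`. The comparison is strict (`<`) by default;
#' `inclusive = TRUE` uses `<=`.
#'
#' @param M Sites x species matrix.
#' @param min_prop Occurrence threshold in [0, 1).
#' @param inclusive Use `<=` instead of `<`.
#' @return Filtered matrix.
#' @export
filter_rare <- function(M, min_prop = 0.05, inclusive = FALSE) {
  stopifnot(is.matrix(M), min_prop >= 0, min_prop < 1)
  occ <- colMeans(M > 0)
  drop <- if (inclusive) occ <= min_prop else occ < min_prop
  if (all(drop)) {
    stop("rare-species filter removed every species column", call. = FALSE)
  }
  M[, !drop, drop = FALSE]
}

mrpp_delta <- function(D, groups) {
  n <- length(groups)
  within <- vapply(split(seq_len(n), groups), function(idx) {
    mean(D[idx, idx][upper.tri(D[idx, idx])])
  }, numeric(1))
  sizes <- tabulate(factor(groups))
  sum(sizes / n * within)
}

#' Multi-response permutation procedure (MRPP)
#'
#' Tests whether sites group by label: the observed weighted mean
#' within-group dissimilarity (group weights `n_g / N`) is compared with
#' its distribution over random relabelings that preserve group sizes.
#' The p-value uses the +1/+1 convention (the observed labeling counts as
#' one permutation); the chance-corrected within-group agreement is
#' `A = 1 - delta_observed / delta_expected` with `delta_expected` the
#' permutation mean.
#'
#' @param M Sites x species matrix (typically row-normalized and
#'   rare-filtered), or a precomputed symmetric distance matrix if
#'   `distance = "precomputed"`.
#' @param groups Group label per row; at least 2 groups of size >= 2.
#' @param n_perm Number of random relabelings (default 999).
#' @param seed RNG seed for the permutations.
#' @param distance `"bray_curtis"` (default) or `"precomputed"`.
#' @return An `mrpp_result` list: `delta_observed`, `delta_expected`,
#'   `A`, `p_value`, `n_permutations`.
#' @export
mrpp <- function(M, groups, n_perm = 999, seed = 1L,
                 distance = c("bray_curtis", "precomputed")) {
  distance <- match.arg(distance)
  groups <- as.character(groups)
  stopifnot(nrow(M) == length(groups))
  sizes <- table(groups)
  if (length(sizes) < 2) stop("MRPP needs >= 2 groups", call. = FALSE)
  if (any(sizes < 2)) {
    stop("MRPP group(s) of size 1: within-group distance undefined",
         call. = FALSE)
  }
  D <- if (distance == "precomputed") M else bray_curtis_matrix(M)
  delta_obs <- mrpp_delta(D, groups)
  # local RNG: restore the caller's stream afterwards
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed",
                                                     .GlobalEnv) else NULL
  set.seed(seed)
  deltas <- vapply(seq_len(n_perm), function(i) {
    mrpp_delta(D, sample(groups))
  }, numeric(1))
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  delta_exp <- mean(deltas)
  structure(list(
    delta_observed = delta_obs,
    delta_expected = delta_exp,
    A = 1 - delta_obs / delta_exp,
    p_value = (sum(deltas <= delta_obs) + 1) / (n_perm + 1),
    n_permutations = as.integer(n_perm)
  ), class = "mrpp_result")
}

#' @export
print.mrpp_result <- function(x, ...) {
  cat("MRPP:", x$n_permutations, "permutations\n")
  cat(sprintf("  delta observed %.5f, expected %.5f\n",
              x$delta_observed, x$delta_expected))
  cat(sprintf("  chance-corrected within-group agreement A = %.6f\n", x$A))
  cat(sprintf("  P = %.4g\n", x$p_value))
  invisible(x)
}

#' Pielou evenness of one site's abundances
#'
#' `J = H' / ln(S)` with Shannon `H'` over positive-abundance species and
#' `S` their count; 1 when all species are equally abundant. Undefined
#' (NA) with fewer than two positive species.
#'
#' @param abundances Non-negative counts/densities for one site.
#' @return J in [0, 1], or `NA` (with a warning) when undefined.
#' @export
evenness <- function(abundances) {
  stopifnot(all(abundances >= 0))
  x <- abundances[abundances > 0]
  s <- length(x)
  if (s < 2) {
    warning("evenness undefined with fewer than 2 positive species")
    return(NA_real_)
  }
  p <- x / sum(x)
  -sum(p * log(p)) / log(s)
}

#' One-way ANOVA of GUDs by yard type
#'
#' @param gud Numeric response (grams).
#' @param group Factor/character with >= 2 levels, >= 2 obs per level.
#' @return List `F`, `df1`, `df2`, `p_value`, `group_stats` (mean, SE, n
#'   per group), `degenerate` flag (no within-group variance anywhere).
#' @export
gud_anova <- function(gud, group) {
  group <- factor(group)
  stopifnot(nlevels(group) >= 2, all(table(group) >= 2))
  fit <- stats::aov(gud ~ group)
  tab <- summary(fit)[[1]]
  gs <- do.call(rbind, lapply(levels(group), function(g) {
    v <- gud[group == g]
    data.frame(group = g, n = length(v), mean = mean(v),
               se = stats::sd(v) / sqrt(length(v)))
  }))
  list(F = tab[1, "F value"], df1 = tab[1, "Df"], df2 = tab[2, "Df"],
       p_value = tab[1, "Pr(>F)"], group_stats = gs,
       degenerate = tab[2, "Sum Sq"] < .Machine$double.eps^0.5)
}

#' ANCOVA of GUD on yard type, density and their interaction
#'
#' OLS of `gud ~ group * density`; the quantity of interest is the
#' group-by-density interaction (do the density slopes differ between
#' yard types?), reported as its t statistic and two-sided p.
#'
#' @param gud Numeric response.
#' @param group Two-or-more-level factor.
#' @param density Numeric covariate (minimum individuals).
#' @return List `coef_table`, `interaction_t`, `interaction_p`,
#'   `interaction_estimate`.
#' @export
gud_ancova <- function(gud, group, density) {
  group <- factor(group)
  if (nlevels(group) < 2) {
    stop("ANCOVA needs >= 2 groups", call. = FALSE)
  }
  fit <- stats::lm(gud ~ group * density)
  if (anyNA(stats::coef(fit))) {
    stop("collinear ANCOVA design: ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "), call. = FALSE)
  }
  ct <- summary(fit)$coefficients
  ix <- grep(":density$", rownames(ct))[1]
  list(coef_table = ct,
       interaction_estimate = ct[ix, "Estimate"],
       interaction_t = ct[ix, "t value"],
       interaction_p = ct[ix, "Pr(>|t|)"])
}

#' Paired bush-vs-open microhabitat test
#'
#' Paired-samples t-test on per-species-per-yard GUD pairs from the two
#' microhabitats. With `include_unvisited = TRUE`, a pair whose missing
#' side comes from an unvisited tray contributes with that side imputed
#' at the initial provisioning `G0` (an unvisited tray's GUD is the full
#' 20 g by definition).
#'
#' @param pairs Data frame with `yard_id`, `species`, `microhabitat`
#'   (`"bush"`/`"open"`), `gud`.
#' @param include_unvisited Impute missing sides at `G0`.
#' @param G0 Initial seed mass in grams (default 20).
#' @return List `t`, `df`, `p_value`, `n_pairs`, `mean_diff`
#'   (bush - open).
#' @export
paired_microhabitat_test <- function(pairs, include_unvisited = FALSE,
                                     G0 = 20) {
  stopifnot(all(c("yard_id", "species", "microhabitat", "gud")
                %in% names(pairs)),
            all(pairs$microhabitat %in% c("bush", "open")))
  key <- interaction(pairs$yard_id, pairs$species, drop = TRUE)
  bush <- open <- rep(NA_real_, nlevels(key))
  bush[match(key[pairs$microhabitat == "bush"], levels(key))] <-
    pairs$gud[pairs$microhabitat == "bush"]
  open[match(key[pairs$microhabitat == "open"], levels(key))] <-
    pairs$gud[pairs$microhabitat == "open"]
  if (include_unvisited) {
    bush[is.na(bush)] <- G0
    open[is.na(open)] <- G0
  }
  keep <- !is.na(bush) & !is.na(open)
  if (sum(keep) < 2) {
    stop("fewer than 2 complete bush/open pairs", call. = FALSE)
  }
  d <- bush[keep] - open[keep]
  n <- length(d)
  if (stats::sd(d) == 0) {
    # constant differences: t is 0/0 when all differences vanish
    t_stat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    p <- if (mean(d) == 0) 1 else 0
    return(list(t = t_stat, df = n - 1, p_value = p, n_pairs = n,
                mean_diff = mean(d)))
  }
  tt <- stats::t.test(d)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, n_pairs = n, mean_diff = mean(d))
}

#' Wilcoxon rank-sum Z statistic and two-sided p
#'
#' Normal approximation with average ranks and the tie-corrected
#' variance; no continuity correction. Reported as Z (the scale the rank
#' tests in this analysis are usually quoted on).
#'
#' @param x,y Numeric samples (>= 2 each).
#' @return List `Z`, `p_value`, `W` (rank sum of `x`), `degenerate`
#'   (all values tied).
#' @export
wilcoxon_z <- function(x, y) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  mu <- n1 * (N + 1) / 2
  ties <- table(r)
  sig2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sig2 <= 0) {
    return(list(Z = NA_real_, p_value = NA_real_, W = W,
                degenerate = TRUE))
  }
  Z <- (W - mu) / sqrt(sig2)
  list(Z = Z, p_value = 2 * stats::pnorm(-abs(Z)), W = W,
       degenerate = FALSE)
}

#' Per-species Wilcoxon and per-yard-type Kruskal-Wallis rank tests
#'
#' For each species observed in both yard types with enough data, a
#' Wilcoxon rank-sum test of its GUDs between yard types; for each yard
#' type, a Kruskal-Wallis test of consumption rates across species.
#'
#' @param species_guds Data frame `species`, `yard_type`, `gud`.
#' @param species_rates Data frame `species`, `yard_type`,
#'   `rate_g_per_h`, or `NULL` to skip.
#' @param min_n Minimum observations per group (default 2).
#' @return List `wilcoxon` (data frame per species) and
#'   `kruskal_wallis` (data frame per yard type).
#' @export
rank_tests <- function(species_guds, species_rates = NULL, min_n = 2) {
  wl <- list()
  for (s in sort(unique(species_guds$species))) {
    d <- species_guds[species_guds$species == s, ]
    m <- d$gud[d$yard_type == "mesic"]
    x <- d$gud[d$yard_type == "xeric"]
    if (length(m) >= min_n && length(x) >= min_n) {
      # Z for xeric vs mesic: positive when xeric GUDs rank higher
      wz <- wilcoxon_z(x, m)
      wl[[s]] <- data.frame(species = s, n_mesic = length(m),
                            n_xeric = length(x), Z = wz$Z,
                            p_value = wz$p_value,
                            degenerate = wz$degenerate)
    }
  }
  kw <- list()
  if (!is.null(species_rates)) {
    for (yt in sort(unique(species_rates$yard_type))) {
      d <- species_rates[species_rates$yard_type == yt &
                           !is.na(species_rates$rate_g_per_h), ]
      ok <- names(which(table(d$species) >= min_n))
      d <- d[d$species %in% ok, ]
      if (length(unique(d$species)) >= 2) {
        k <- stats::kruskal.test(d$rate_g_per_h, factor(d$species))
        kw[[yt]] <- data.frame(
          yard_type = yt, chi_square = unname(k$statistic),
          df = unname(k$parameter), p_value = k$p.value,
          n_species = length(unique(d$species)))
      }
    }
  }
  list(
    wilcoxon = if (length(wl) > 0) do.call(rbind, c(wl,
      make.row.names = FALSE)) else NULL,
    kruskal_wallis = if (length(kw) > 0) do.call(rbind, c(kw,
      make.row.names = FALSE)) else NULL
  )
}

#' Build the yards x species community matrix of minimum individuals
#'
#' Per-yard density for each species is the sum over the yard's trays of
#' the per-tray minimum-individual counts.
#'
#' @param density Density table from [analyze_events()].
#' @param trials Trials table (yard and yard-type lookup).
#' @return List `matrix` (yards x species) and `yard_type` per row.
#' @export
community_matrix <- function(density, trials) {
  yard <- trials$yard_id[match(density$tray_id, trials$tray_id)]
  yards <- sort(unique(trials$yard_id))
  species <- sort(unique(density$species))
  M <- matrix(0L, length(yards), length(species),
              dimnames = list(yards, species))
  if (nrow(density) > 0) {
    agg <- stats::aggregate(density$min_individuals,
                            list(yard = yard, species = density$species),
                            sum)
    M[cbind(match(agg$yard, yards), match(agg$species, species))] <- agg$x
  }
  yt <- trials$yard_type[match(yards, trials$yard_id)]
  list(matrix = M, yard_type = stats::setNames(yt, yards))
}
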