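# Independent oracles and tiny fixture builders used across the suite.

# brute-force maximum simultaneous overlap (open-interval convention:
# touching endpoints are not simultaneous); checks every arrival instant
brute_max_overlap <- function(t_on, t_off) {
  if (length(t_on) == 0) return(0L)
  max(vapply(seq_along(t_on), function(i) {
    sum(t_on <= t_on[i] & t_off > t_on[i])
  }, integer(1)))
}

# weighted mean within-group Bray-Curtis delta, written independently of
# the package (explicit double loop)
oracle_delta <- function(M, groups) {
  n <- nrow(M)
  acc <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    d <- c()
    for (i in idx) for (j in idx) if (i < j) {
      d <- c(d, sum(abs(M[i, ] - M[j, ])) / sum(M[i, ] + M[j, ]))
    }
    acc <- acc + length(idx) / n * mean(d)
  }
  acc
}

# exact MRPP p by exhaustive enumeration of all distinct relabelings
# (two groups, sizes preserved); the observed labeling is one of them
oracle_mrpp_exact_p <- function(M, groups) {
  lv <- unique(groups)
  stopifnot(length(lv) == 2)
  n <- length(groups)
  k <- sum(groups == lv[1])
  obs <- oracle_delta(M, groups)
  combos <- utils::combn(n, k)
  deltas <- apply(combos, 2, function(idx) {
    g <- rep(lv[2], n); g[idx] <- lv[1]
    oracle_delta(M, g)
  })
  mean(deltas <= obs + 1e-12)
}

# exact two-sided rank-sum p by enumeration of all C(N, n1) labelings
oracle_ranksum_exact_p <- function(x, y) {
  N <- length(x) + length(y)
  r <- rank(c(x, y))
  W_obs <- sum(r[seq_along(x)])
  mu <- length(x) * (N + 1) / 2
  combos <- utils::combn(N, length(x))
  W_all <- apply(combos, 2, function(idx) sum(r[idx]))
  mean(abs(W_all - mu) >= abs(W_obs - mu) - 1e-12)
}

# all rank sums over the C(N, n1) labelings of the pooled sample
all_W_of <- function(x, y) {
  r <- rank(c(x, y))
  apply(utils::combn(length(r), length(x)), 2, function(idx) sum(r[idx]))
}

# one-way ANOVA F from explicit sums of squares
oracle_anova_F <- function(y, g) {
  g <- factor(g)
  gm <- mean(y)
  ssb <- sum(tapply(y, g, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
  df1 <- nlevels(g) - 1
  df2 <- length(y) - nlevels(g)
  (ssb / df1) / (ssw / df2)
}

# brute-force numerical least-squares minimizer (BFGS with analytic
# gradient on the explicit design matrix, restarted until the gradient
# vanishes numerically)
oracle_ols_optim <- function(X, y) {
  # unit-norm column scaling conditions the quadratic; coefficients are
  # mapped back to the original scale afterwards
  s <- sqrt(colSums(X^2))
  Xs <- sweep(X, 2, s, "/")
  rss <- function(b) sum((y - Xs %*% b)^2)
  grad <- function(b) as.numeric(-2 * t(Xs) %*% (y - Xs %*% b))
  par <- rep(0, ncol(X))
  for (restart in 1:20) {
    fit <- stats::optim(par, rss, grad, method = "BFGS",
                        control = list(maxit = 10000, reltol = 1e-16))
    par <- fit$par
    if (max(abs(grad(par))) < 1e-12) break
  }
  # steepest-descent polish with exact line search (quadratic objective)
  for (it in 1:2000) {
    g <- grad(par)
    if (max(abs(g)) < 1e-14) break
    Hg <- as.numeric(2 * t(Xs) %*% (Xs %*% g))
    par <- par - sum(g * g) / sum(g * Hg) * g
  }
  par / s
}

# small in-memory study written to CSVs and read back through the
# package reader (the canonical hand fixture: 2 trays, 2 species)
tiny_study_files <- function(dir = withr::local_tempdir(
                               .local_envir = parent.frame())) {
  trials <- data.frame(
    tray_id = c("Y1_B", "Y1_O"), yard_id = "Y1",
    yard_type = "mesic", microhabitat = c("bush", "open"),
    initial_seed_mass_g = 20, duration_s = 86400,
    final_gud_g = c(5.25, NA))
  pecks <- data.frame(
    tray_id = c(rep("Y1_B", 7), rep("Y1_O", 3)),
    species = c("HOSP", "HOSP", "ABTO", "HOSP", "ABTO", "HOSP", "HOSP",
                "CBTH", "CBTH", "CBTH"),
    class_tag = c("male", "male", "unknown", "female", "unknown",
                  "male", "male", rep("unknown", 3)),
    t_seconds = c(10, 20, 30, 40, 100, 150, 151, 5, 6, 7))
  intervals <- data.frame(
    tray_id = c("Y1_B", "Y1_B", "Y1_B", "Y1_O"),
    species = c("HOSP", "HOSP", "ABTO", "CBTH"),
    class_tag = c("male", "female", "unknown", "unknown"),
    t_on = c(5, 35, 25, 0), t_off = c(160, 50, 110, 10))
  paths <- list(trials = file.path(dir, "trials.csv"),
                pecks = file.path(dir, "pecks.csv"),
                intervals = file.path(dir, "intervals.csv"))
  utils::write.csv(trials, paths$trials, row.names = FALSE, na = "NA")
  utils::write.csv(pecks, paths$pecks, row.names = FALSE)
  utils::write.csv(intervals, paths$intervals, row.names = FALSE)
  paths
}

# single-species profile pool for focused simulator checks
one_species_pool <- function(q = 0.002, peck_rate = 60, rate = 0.5,
                             pause_prob = 0) {
  list(SPEC = species_profile("SPEC", q = q, peck_rate = peck_rate,
                              arrival_rate = c(mesic = rate, xeric = rate),
                              pause_prob = pause_prob))
}

# small fast study for cross-module tests
small_sim_config <- function(...) {
  sim_config(n_yards_per_type = 3, duration_s = 21600, ...)
}

# noiseless linear training data generated exactly from known
# coefficients (the interpolation fixture)
exact_training <- function(b0 = 18, bp = -0.008, bd = -0.3,
                           offs = c(ABTO = 0, CBTH = -2, HOSP = 1)) {
  set.seed(99)
  n <- 24
  sp <- rep(names(offs), length.out = n)
  pecks <- sample(50:2000, n)
  dens <- sample(1:12, n, replace = TRUE)
  data.frame(gud = b0 + bp * pecks + bd * dens + offs[sp],
             pecks = pecks, species = sp, density = dens)
}
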