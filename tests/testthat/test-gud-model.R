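test_that("noiseless data generated from known coefficients are recovered exactly", {
  b0 <- 18; bp <- -0.008; bd <- -0.3
  offs <- c(ABTO = 0, CBTH = -2, HOSP = 1)
  train <- exact_training(b0, bp, bd, offs)
  fit <- fit_gud_peck_model(train)
  expect_equal(fit$beta0, b0, tolerance = 1e-8)
  expect_equal(fit$beta_pecks, bp, tolerance = 1e-8)
  expect_equal(fit$beta_density, bd, tolerance = 1e-8)
  expect_equal(fit$species_effects[["CBTH"]], -2, tolerance = 1e-8)
  expect_equal(fit$reference_level, "ABTO")
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_equal(fit$n_train, 24L)
})

test_that("the OLS solution matches a brute-force numerical minimizer", {
  set.seed(21)
  n <- 10
  sp <- factor(rep(c("A", "B"), 5))
  train <- data.frame(pecks = runif(n, 0, 10),
                      density = sample(1:5, n, TRUE),
                      species = sp)
  train$gud <- 12 - 0.6 * train$pecks - 0.2 * train$density +
    (sp == "B") * 1.5 + rnorm(n, 0, 0.3)
  fit <- fit_gud_peck_model(train)
  X <- cbind(1, train$pecks, train$density, as.numeric(sp == "B"))
  par <- oracle_ols_optim(X, train$gud)
  got <- c(fit$beta0, fit$beta_pecks, fit$beta_density,
           fit$species_effects[["B"]])
  expect_lt(max(abs(got - par)), 1e-8)
})

test_that("fit diagnostics match independent formula evaluations", {
  train <- exact_training()
  train$gud <- train$gud + rnorm(nrow(train), 0, 0.5)
  fit <- fit_gud_peck_model(train)
  pred <- predict_gud(fit, train$pecks, train$species, train$density)
  x <- train$gud; y <- pred
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(fit$obs_pred_pearson, r, tolerance = 1e-12)
  expect_true(fit$r_squared >= 0 && fit$r_squared <= 1)
  expect_equal(fit$r_squared, r^2, tolerance = 1e-12)
})

test_that("degenerate designs raise explicit errors", {
  train <- exact_training()
  train$density <- 5  # constant covariate -> collinear with intercept
  expect_error(fit_gud_peck_model(train), "collinear")
  expect_error(fit_gud_peck_model(exact_training()[1:4, ]), "few")
})

test_that("predict_gud is the linear predictor, unclamped and monotone", {
  train <- exact_training()
  fit <- fit_gud_peck_model(train)
  # hand-computed dot product with the coefficient vector
  expect_equal(predict_gud(fit, 500, "CBTH", 4),
               fit$beta0 + fit$beta_pecks * 500 + fit$beta_density * 4 +
                 fit$species_effects[["CBTH"]], tolerance = 1e-12)
  expect_lte(predict_gud(fit, 600, "ABTO", 4),
             predict_gud(fit, 500, "ABTO", 4))
  # large peck counts may predict below zero; no clamping
  expect_lt(predict_gud(fit, 1e5, "ABTO", 4), 0)
  expect_error(predict_gud(fit, 10, "XXXX", 1), "species_not_in_model")
})

test_that("species GUD estimates apply the omission and unvisited rules", {
  train <- exact_training()
  fit <- fit_gud_peck_model(train)
  qp <- data.frame(
    tray_id = c("T1", "T1", "T1"),
    species = c("ABTO", "CBTH", "ZZZZ"),
    t_quit = c(100, 900, 500),
    cum_pecks_at_quit = c(25L, 300L, 60L),
    own_total_pecks = c(25L, 240L, 35L),
    is_final_forager = c(FALSE, TRUE, FALSE))
  dens <- data.frame(tray_id = "T1", species = "ABTO",
                     min_individuals = 3L,
                     tray_total_min_individuals = 3L)
  trials <- data.frame(tray_id = c("T1", "T2"),
                       initial_seed_mass_g = 20)
  est <- estimate_species_guds(fit, qp, dens, trials)

  abto <- est[!is.na(est$species) & est$species == "ABTO", ]
  expect_true(abto$omitted)
  expect_equal(abto$omission_reason, "few_pecks")
  zz <- est[!is.na(est$species) & est$species == "ZZZZ", ]
  expect_true(zz$omitted)
  expect_equal(zz$omission_reason, "species_not_in_model")
  cbth <- est[!is.na(est$species) & est$species == "CBTH", ]
  expect_false(cbth$omitted)
  expect_equal(cbth$gud_estimate, predict_gud(fit, 300, "CBTH", 3))
  expect_true(cbth$is_final_forager)

  # a tray with no pecks gets the full provisioning as its GUD
  t2 <- est[est$tray_id == "T2", ]
  expect_true(t2$unvisited)
  expect_equal(t2$gud_estimate, 20)
})

test_that("consumption rates convert model estimates into grams per hour", {
  train <- exact_training()
  fit <- fit_gud_peck_model(train)
  qp <- data.frame(
    tray_id = "T1", species = c("ABTO", "CBTH"),
    t_quit = c(500, 900), cum_pecks_at_quit = c(400L, 800L),
    own_total_pecks = c(400L, 400L),
    is_final_forager = c(FALSE, TRUE))
  ft <- data.frame(tray_id = "T1", species = c("ABTO", "CBTH"),
                   foraging_time_s = c(1800, 3600))
  dens <- data.frame(tray_id = "T1", species = "ABTO",
                     min_individuals = 2L, tray_total_min_individuals = 2L)
  trials <- data.frame(tray_id = "T1", initial_seed_mass_g = 20)
  r <- consumption_rates(fit, qp, ft, dens, trials)
  expect_equal(r$grams_consumed[1],
               20 - predict_gud(fit, 400, "ABTO", 2))
  # halving foraging time at fixed pecks doubles the rate
  expect_equal(r$rate_g_per_h[1] / (r$grams_consumed[1] / 0.5), 1)

  # zero foraging time with pecks present leaves the rate undefined
  ft$foraging_time_s[2] <- 0
  r2 <- consumption_rates(fit, qp, ft, dens, trials)
  expect_true(r2$omitted[2])
  expect_equal(r2$omission_reason[2], "zero_time")
  expect_true(is.na(r2$rate_g_per_h[2]))

  # below-threshold peck counts are omitted
  qp$own_total_pecks[1] <- 30L
  r3 <- consumption_rates(fit, qp, ft, dens, trials)
  expect_equal(r3$omission_reason[1], "few_pecks")
})

test_that("estimates track the depletion ledger in a constant-yield simulation", {
  cfg <- sim_config(n_yards_per_type = 4, duration_s = 3600,
                    mode = "constant_yield", gud_weighing_sd = 0)
  profiles <- lapply(default_species_profiles(), function(p) {
    p$arrival_rate <- p$arrival_rate * 24
    p
  })
  st <- generate_study(cfg, profiles, seed = 5)
  ev <- analyze_events(st)
  fit <- fit_gud_peck_model(training_table(st, ev))
  # each peck removes exactly y_max, so the slope is -y_max
  expect_equal(fit$beta_pecks, -cfg$y_max, tolerance = 0.05 * cfg$y_max)
  est <- estimate_species_guds(fit, ev$quit_points, ev$density,
                               st$trials, st$config)
  ok <- est[!est$omitted & !est$unvisited, ]
  ledger <- 20 - cfg$y_max * ok$cum_pecks_at_quit
  expect_lt(median(abs(ok$gud_estimate - ledger)), 0.5)
})
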