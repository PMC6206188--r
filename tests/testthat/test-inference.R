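test_that("MCMC posterior matches brute-force enumeration on a tiny instance", {
  # T = 2, M = 3, one trap, centers fixed at the trap, known detection
  traps <- tibble::tibble(trap_id = "T1", x = 0, y = 0, K = 5L)
  S <- state_space(-1, 1, -1, 1)
  det <- tibble::tibble(
    individual_id = c("a", "a", "b"),
    trap_id = "T1", period = c(1L, 2L, 2L), count = c(2L, 1L, 2L)
  )
  lambda0 <- 0.5; sigma_p <- 0.5
  p <- 1 - exp(-lambda0)
  y <- rbind(c(2, 1), c(0, 2), c(0, 0))  # label-sorted: a, b, augmented
  oracle <- enumerate_tiny_posterior(y, K = 5, p = p)

  cfg <- fit_config("constant", S = S, M = 3, n_periods = 2,
                    n_chains = 1, n_iter = 110000, n_burnin = 10000,
                    seed = 31)
  M <- 3
  # M is deliberately tiny here, so the N-at-M flag is expected
  fit <- suppressWarnings(
    fit_open_scr(det, traps, cfg, save_z = TRUE,
                 fix_detection = TRUE, fix_centers = TRUE,
                 fixed = list(lambda0 = lambda0, sigma_p = sigma_p,
                              sx = matrix(0, M, 2), sy = matrix(0, M, 2))))
  enc <- zdraws_to_config(fit$z_draws, M = M)
  mcmc_prob <- tabulate(enc, nbins = nrow(oracle$configs)) / length(enc)
  tv <- 0.5 * sum(abs(mcmc_prob - oracle$prob))
  expect_lt(tv, 0.02)

  # survival posterior mean agrees with the enumerated mixture of Betas
  z_all <- oracle$configs
  phi_means <- apply(z_all, 1, function(cfg_row) {
    z <- oracle_histories[cfg_row, , drop = FALSE]
    nsurv <- sum(z[, 1] == 1 & z[, 2] == 1)
    ndie <- sum(z[, 1] == 1 & z[, 2] == 0)
    (nsurv + 1) / (nsurv + ndie + 2)
  })
  expect_equal(mean(fit$draws$phi), sum(phi_means * oracle$prob),
               tolerance = 0.01)
})

test_that("a dataset with no detections leaves survival at its prior", {
  traps <- make_trap_grid(3, 3, spacing = 1, center = c(0, 0), K = 3)
  S <- make_state_space(traps, buffer = 1)
  det <- tibble::tibble(individual_id = character(), trap_id = character(),
                        period = integer(), count = integer())
  cfg <- fit_config("constant", S = S, M = 20, n_periods = 3,
                    n_chains = 1, n_iter = 4000, n_burnin = 500, seed = 3)
  fit <- suppressWarnings(fit_open_scr(det, traps, cfg))
  expect_equal(fit$n_obs, 0)
  # phi ~ Uniform(0,1): mean 0.5, sd ~ 0.29
  expect_gt(mean(fit$draws$phi), 0.35)
  expect_lt(mean(fit$draws$phi), 0.65)
  expect_gt(sd(fit$draws$phi), 0.2)
})

test_that("posterior summaries are invariant to detection row order", {
  d <- simulate_scenario(sim_config(M = 60, target_N = 15), seed = 21)
  cfg <- quick_fit_config("constant", S = d$S_gen, M = 60, seed = 5)
  f1 <- fit_open_scr(d$detections, d$traps, cfg)
  shuffled <- d$detections[sample.int(nrow(d$detections)), ]
  f2 <- fit_open_scr(shuffled, d$traps, cfg)
  expect_identical(f1$draws, f2$draws)
})

test_that("sampled life histories never revive after death", {
  d <- simulate_scenario(sim_config(M = 50, target_N = 15), seed = 22)
  cfg <- quick_fit_config("independent", S = d$S_gen, M = 50, seed = 6)
  fit <- fit_open_scr(d$detections, d$traps, cfg, save_z = TRUE)
  M <- 50; Tn <- 5
  for (k in seq_len(nrow(fit$z_draws))) {
    z <- matrix(fit$z_draws[k, ], M, Tn)
    expect_error(derived_abundance(z), NA)
  }
  # abundance draws equal the sum of alive indicators
  expect_equal(unname(rowSums(matrix(fit$z_draws[, 1:M], ncol = M))),
               fit$draws$N_1)
})

test_that("too-small augmentation triggers the pile-up warning", {
  # both individuals are detected in period 1, so N_1 = M = 2 in every draw
  traps <- tiny_traps()
  det <- tibble::tibble(individual_id = c("i1", "i2"), trap_id = c("A", "D"),
                        period = 1L, count = c(2L, 3L))
  S <- make_state_space(traps, buffer = 1)
  cfg <- fit_config("constant", S = S, M = 2, n_periods = 2,
                    n_chains = 1, n_iter = 300, n_burnin = 100, seed = 7)
  expect_warning(fit_open_scr(det, traps, cfg), "augmentation limit")
})

test_that("CJS conditions on first capture and recovers limiting cases", {
  # perfect detection, everyone alive throughout: phi posterior near 1
  traps <- make_trap_grid(3, 3, spacing = 1, center = c(0, 0), K = 5)
  S <- make_state_space(traps, buffer = 1)
  det <- tidyr::expand_grid(individual_id = paste0("i", 1:12),
                            trap_id = "T5", period = 1:5) |>
    dplyr::mutate(count = 5L)
  cfg <- fit_config("constant", S = S, M = 12, n_periods = 5,
                    n_chains = 1, n_iter = 2000, n_burnin = 500, seed = 8)
  fit <- fit_cjs(det, traps, cfg)
  expect_gt(mean(fit$draws$phi), 0.85)
  expect_false("gamma_1" %in% names(fit$draws))
  expect_false("N_1" %in% names(fit$draws))

  # individuals first seen in the last period carry no survival information
  det_last <- dplyr::mutate(det, period = 5L) |> dplyr::distinct()
  fit_last <- fit_cjs(det_last, traps, cfg)
  expect_gt(mean(fit_last$draws$phi), 0.35)
  expect_lt(mean(fit_last$draws$phi), 0.65)
  expect_gt(sd(fit_last$draws$phi), 0.2)
})

test_that("interval lengths rescale survival consistently", {
  d <- simulate_scenario(sim_config(M = 80, target_N = 25), seed = 24)
  cfg <- fit_config("constant", S = d$S_gen, M = 80, n_periods = 5,
                    n_chains = 1, n_iter = 3000, n_burnin = 500, seed = 9)
  expect_error(unequal_intervals(cfg, c(1, 1)), "length")
  # all-ones delta is the default path
  cfg_one <- unequal_intervals(cfg, rep(1, 4))
  f_def <- fit_open_scr(d$detections, d$traps, cfg)
  f_one <- fit_open_scr(d$detections, d$traps, cfg_one)
  expect_identical(f_def$draws, f_one$draws)
  # doubling the interval halves survival on the log scale:
  # per-unit phi under delta = 2 should match sqrt(phi) under delta = 1
  cfg_two <- unequal_intervals(cfg, rep(2, 4))
  f_two <- fit_open_scr(d$detections, d$traps, cfg_two)
  expect_equal(mean(f_two$draws$phi), mean(sqrt(f_def$draws$phi)),
               tolerance = 0.02)
})

test_that("fit configuration validates its inputs", {
  S <- state_space(0, 10, 0, 10)
  expect_error(fit_config("constant", S = S, M = 10, n_periods = 5,
                          n_iter = 100, n_burnin = 200), "n_iter")
  expect_error(fit_config("walk", S = S, M = 10, n_periods = 5))
  cfg <- fit_config("markovian", S = S, M = 10, n_periods = 5)
  expect_equal(cfg$sigma_p_max, 10)
  expect_equal(cfg$delta_t, rep(1, 4))
})
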