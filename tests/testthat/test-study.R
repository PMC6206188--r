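test_that("study metrics match hand computations", {
  m <- scr_metrics(c(0.7, 0.8), truth = 0.75)
  expect_equal(m$rel_bias, 0)
  expect_equal(m$rrmse, 0.05 / 0.75, tolerance = 1e-12)
  exact <- scr_metrics(rep(0.75, 4), conf.low = rep(0.7, 4),
                       conf.high = rep(0.8, 4), truth = 0.75)
  expect_equal(exact$rel_bias, 0)
  expect_equal(exact$rrmse, 0)
  expect_equal(exact$coverage, 1)
  cov <- scr_metrics(c(0.7, 0.85), conf.low = c(0.6, 0.8),
                     conf.high = c(0.9, 0.9), truth = 0.75)
  expect_equal(cov$coverage, 0.5)
})

test_that("rRMSE decomposes into bias and spread", {
  set.seed(15)
  for (r in 1:5) {
    est <- rnorm(40, mean = 0.7, sd = 0.08)
    truth <- 0.75
    m <- scr_metrics(est, truth = truth)
    n <- length(est)
    var_pop <- var(est) * (n - 1) / n
    expect_equal(m$rrmse^2, m$rel_bias^2 + var_pop / truth^2, tolerance = 1e-10)
  }
})

test_that("tables arrange movement by buffer with mean and rRMSE", {
  fake <- tidyr::expand_grid(movement_fit = c("constant", "independent"),
                             buffer_mult = c(3, 4, 5)) |>
    dplyr::mutate(movement_gen = movement_fit, parameter = "phi",
                  avg_mean = 0.75, rrmse = 0.06, truth = 0.75,
                  rel_bias = 0, coverage = 0.95, n_reps = 10,
                  mc_se_mean = 0.01, mc_se_rel_bias = 0.013,
                  mc_se_coverage = 0.07)
  tbl <- make_table(list(metrics = fake) |> structure(class = "scr_study"))
  expect_equal(dim(tbl), c(2, 7))
  expect_equal(names(tbl)[1:3], c("movement", "mean_3sigma", "rrmse_3sigma"))
  empty <- make_table(fake[0, ])
  expect_equal(nrow(empty), 0)
  expect_s3_class(autoplot(structure(list(metrics = fake), class = "scr_study")),
                  "ggplot")
})

test_that("tables round-trip through CSV at reporting precision", {
  tbl <- tibble::tibble(movement = "constant", mean_4sigma = 0.754321,
                        rrmse_4sigma = 0.061234)
  path <- tempfile(fileext = ".csv")
  readr::write_csv(tbl, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(round(back$mean_4sigma, 6), round(tbl$mean_4sigma, 6))
})

test_that("single scenarios are deterministic and cover the edge replicate", {
  cfg <- sim_config(M = 50, target_N = 15)
  mcmc <- list(n_chains = 1, n_iter = 300, n_burnin = 100)
  a <- run_scenario(cfg, buffer_mult = 4, n_reps = 1, seed = 3, mcmc = mcmc)
  b <- run_scenario(cfg, buffer_mult = 4, n_reps = 1, seed = 3, mcmc = mcmc)
  expect_identical(a$metrics, b$metrics)
  expect_true(all(a$metrics$coverage %in% c(0, 1)))
  expect_equal(unique(a$metrics$n_reps), 1)
})

test_that("misspecification runs reduce to the matched scenario when gen = fit", {
  cfg <- sim_config(M = 50, target_N = 15)
  mcmc <- list(n_chains = 1, n_iter = 300, n_burnin = 100)
  mis <- run_misspecification(cfg, "constant", "constant", buffer_mult = 4,
                              n_reps = 2, seed = 4, mcmc = mcmc)
  match_ <- run_scenario(sim_config(M = 50, target_N = 15), buffer_mult = 4,
                         n_reps = 2, seed = 4, mcmc = mcmc)
  expect_identical(mis$metrics, match_$metrics)
  # crossed models run end to end, including the jump-mixture generator
  crossed <- run_misspecification(cfg, "markovian_jump", "independent",
                                  buffer_mult = 4, n_reps = 1, seed = 5,
                                  mcmc = mcmc)
  expect_equal(crossed$movement_gen, "markovian_jump")
  expect_equal(crossed$movement_fit, "independent")
  expect_true(all(is.finite(crossed$metrics$avg_mean)))
})
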