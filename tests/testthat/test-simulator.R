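test_that("simulated datasets replay bit-identically under the same seed", {
  a <- simulate_scenario(sim_config(movement = "markovian"), seed = 7)
  b <- simulate_scenario(sim_config(movement = "markovian"), seed = 7)
  expect_identical(a$detections, b$detections)
  expect_identical(a$truth$z, b$truth$z)
  expect_identical(a$truth$s, b$truth$s)
  c <- simulate_scenario(sim_config(movement = "markovian"), seed = 8)
  expect_false(identical(a$detections, c$detections))
})

test_that("population dynamics hold the expected size at the target", {
  cfg <- sim_config()
  set.seed(1)
  # entrance probability follows the shortfall formula
  Ns <- replicate(500, colSums(simulate_dynamics(cfg)$z))
  for (t in 1:5) {
    se <- sd(Ns[t, ]) / sqrt(ncol(Ns))
    expect_lt(abs(mean(Ns[t, ]) - 40), max(3 * se, 1e-9))
  }
  expect_true(all(Ns[1, ] == 40))
})

test_that("life histories never revive after death", {
  cfg <- sim_config(M = 60, target_N = 20)
  set.seed(2)
  for (r in 1:200) {
    dyn <- simulate_dynamics(cfg)
    expect_error(derived_abundance(dyn$z), NA)
    # alpha flags exactly the never-yet-alive
    for (t in 2:cfg$n_periods) {
      never_before <- rowSums(dyn$z[, 1:(t - 1), drop = FALSE]) == 0
      expect_equal(dyn$alpha[, t] == 1L, never_before)
    }
  }
})

test_that("deathless populations need no recruits", {
  cfg <- sim_config(phi = 1 - 1e-12)
  set.seed(3)
  dyn <- simulate_dynamics(cfg)
  expect_true(all(colSums(dyn$z) == 40))
  expect_true(all(dyn$gamma[-1] == 0))
})

test_that("activity centers follow the configured movement model", {
  S <- state_space(0, 10, 0, 10)
  z <- matrix(1L, 50, 5)
  set.seed(4)
  s_const <- simulate_centers(z, "constant", S)
  for (t in 2:5) expect_identical(s_const[, t, ], s_const[, 1, ])
  s_frozen <- simulate_centers(z, "markovian", S, sigma_s = 1e-9)
  expect_equal(s_frozen[, 5, ], s_frozen[, 1, ], tolerance = 1e-6)
  # empirical one-step SD of an interior walk matches sigma_s
  zz <- matrix(1L, 2000, 2)
  Sbig <- state_space(-50, 50, -50, 50)
  sw <- simulate_centers(zz, "markovian", Sbig, sigma_s = 0.5)
  steps <- sw[, 2, ] - sw[, 1, ]
  expect_equal(sd(steps[, 1]), 0.5, tolerance = 0.05)
  expect_equal(sd(steps[, 2]), 0.5, tolerance = 0.05)
  expect_true(all(ss_contains(S, s_const[, 1, 1], s_const[, 1, 2])))
})

test_that("independent-model centers are uniform over the state space", {
  S <- state_space(0, 10, 0, 10)
  z <- matrix(1L, 2000, 5)
  set.seed(5)
  s <- simulate_centers(z, "independent", S)
  x <- as.vector(s[, , 1]); y <- as.vector(s[, , 2])
  bx <- cut(x, seq(0, 10, by = 2)); by <- cut(y, seq(0, 10, by = 2))
  tab <- table(bx, by)
  p <- chisq.test(as.vector(tab))$p.value
  expect_gt(p, 0.01)
})

test_that("detections respect alive states, effort and the Binomial mean", {
  traps <- tibble::tibble(trap_id = "T1", x = 0, y = 0, K = 5L)
  S <- state_space(-2, 2, -2, 2)
  n <- 5000
  z <- cbind(rep(1L, n), rep(0L, n))
  s <- array(0, c(n, 2, 2))  # everyone sitting on the trap
  set.seed(6)
  y <- simulate_detections(s, z, traps, lambda0 = 0.5, sigma_p = 0.5)
  expect_true(all(y[, , 2] == 0))          # dead yields structural zeros
  expect_true(all(y <= 5))
  p0 <- 1 - exp(-0.5)
  expect_equal(mean(y[, 1, 1]), 5 * p0, tolerance = 3 * sqrt(5 * p0 * (1 - p0) / n))
  # zero effort yields zero counts
  traps0 <- tibble::tibble(trap_id = "T1", x = 0, y = 0, K = 0L)
  expect_error(simulate_detections(s, z, traps0, 0.5, 0.5), "effort")
  traps01 <- tibble::tibble(trap_id = c("T1", "T2"), x = c(0, 1), y = c(0, 0),
                            K_1 = c(0L, 5L), K_2 = c(5L, 5L))
  y01 <- simulate_detections(s, z, traps01, 0.5, 0.5)
  expect_true(all(y01[, 1, 1] == 0))
})

test_that("scenario composition strips unobserved individuals but keeps truth", {
  d <- simulate_scenario(sim_config(movement = "independent"), seed = 9)
  expect_s3_class(d$detections, "tbl_df")
  expect_equal(d$n_periods, 5)
  expect_equal(nrow(d$traps), 49)
  expect_equal(ss_area(d$S_gen), 100)
  # every reported individual has at least one detection
  expect_true(all(d$detections$count > 0))
  n_obs <- length(unique(d$detections$individual_id))
  expect_equal(n_obs, length(d$truth$observed))
  expect_true(n_obs >= 30 && n_obs <= 110)   # loose stochastic sanity band
  expect_true(all(d$truth$abundance$N <= 150))
  # counts never exceed effort
  expect_true(all(d$detections$count <= 5))
  # all centers that exist lie inside the generating state space
  sx <- d$truth$s[, , 1]
  expect_true(all(ss_contains(d$S_gen, sx[!is.na(sx)],
                              d$truth$s[, , 2][!is.na(sx)])))
})
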