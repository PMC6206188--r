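test_that("detection probability matches the closed form", {
  expect_equal(detection_prob(0, 0.5, 0.5), 1 - exp(-0.5))
  expect_equal(detection_prob(0.5, 0.5, 0.5), 1 - exp(-0.5 * exp(-0.5)),
               tolerance = 1e-12)
  # far from the trap the hazard vanishes
  expect_lt(detection_prob(100, 0.5, 0.5), 1e-12)
  expect_error(detection_prob(-1, 0.5, 0.5), "finite")
  expect_error(detection_prob(1, 0, 0.5), "lambda0")
})

test_that("detection probability is monotone and bounded on a grid", {
  for (lambda0 in c(0.1, 0.5, 2)) {
    for (sigma_p in c(0.25, 0.5, 1)) {
      d <- seq(0, 5, by = 0.05)
      p <- detection_prob(d, lambda0, sigma_p)
      expect_true(all(p > 0 & p < 1))
      expect_true(all(diff(p) < 0))
    }
  }
  # increasing in lambda0 at fixed distance
  p_by_lambda <- detection_prob(1, c(0.1, 0.5, 1, 5), 0.5)
  expect_true(all(diff(p_by_lambda) > 0))
})

test_that("observation log-pmf handles alive and dead states", {
  expect_identical(observation_logpmf(0, 5, 0, 0.9), 0)
  expect_identical(observation_logpmf(1, 5, 0, 0.9), -Inf)
  expect_identical(observation_logpmf(3, 5, 1, 0), -Inf)
  p <- 1 - exp(-0.5 * exp(-0.5))
  expect_equal(observation_logpmf(2, 5, 1, p),
               log(choose(5, 2) * p^2 * (1 - p)^3), tolerance = 1e-10)
  # brute-force pmf evaluation: log(choose(5,2) * p^2 * (1-p)^3) at p = 0.26166
  expect_equal(round(observation_logpmf(2, 5, 1, 0.26166), 3), -1.289)
  expect_error(observation_logpmf(6, 5, 1, 0.5), "y > K")
})

test_that("alive-state transitions follow the survival/entrance process", {
  expect_equal(transition_prob(1, 0, 0.75, 0.1), 0.75)
  expect_equal(transition_prob(0, 0, 0.75, 0.1), 0)
  expect_equal(transition_prob(0, 1, 0.75, 0.1), 0.1)
  expect_error(transition_prob(1, 1, 0.75, 0.1), "recruitment")
})

test_that("interval survival is exponentiation in the interval length", {
  expect_identical(interval_survival(0.75, 1), 0.75)
  expect_equal(interval_survival(0.75, 2), 0.5625)
  expect_equal(interval_survival(0.9, 0.5), sqrt(0.9), tolerance = 1e-12)
  expect_equal(round(interval_survival(0.9, 0.5), 4), 0.9487)
  expect_error(interval_survival(1.2, 1), "phi_unit")
  expect_error(interval_survival(0.5, 0), "delta_t")
})

test_that("movement log-density covers the three models", {
  S <- state_space(0, 10, 0, 10)
  expect_equal(movement_logdensity(c(5, 5), c(4, 4), "independent", S = S),
               -log(100))
  expect_identical(movement_logdensity(c(5, 5), c(5, 5), "constant", S = S), 0)
  expect_identical(movement_logdensity(c(5, 5), c(4, 4), "constant", S = S), -Inf)
  # interior point far from boundaries: truncation mass ~ 1
  ld <- movement_logdensity(c(5.5, 5), c(5, 5), "markovian", sigma_s = 0.5, S = S)
  expect_equal(ld, log(1 / (2 * pi * 0.25) * exp(-0.5)), tolerance = 1e-6)
  # frozen from independent evaluation: log[(2 pi 0.25)^-1 e^-0.5]
  expect_equal(round(ld, 5), -0.95158)
  # density peaks at the previous center
  at_prev <- movement_logdensity(c(5, 5), c(5, 5), "markovian", sigma_s = 0.1, S = S)
  expect_gt(at_prev, movement_logdensity(c(5.2, 5), c(5, 5), "markovian",
                                         sigma_s = 0.1, S = S))
  expect_error(movement_logdensity(c(11, 5), c(5, 5), "independent", S = S),
               "state space")
})

test_that("markovian movement density integrates to 1 over the state space", {
  S <- state_space(0, 4, 0, 4)
  h <- 0.002
  gx <- seq(S$xmin + h / 2, S$xmax - h / 2, by = h)
  for (case in list(list(s = c(2, 2), sig = 0.5),
                    list(s = c(0.3, 3.8), sig = 0.7),
                    list(s = c(4, 0), sig = 1.2))) {
    # separable integrand: product of two 1-D truncated normals
    fx <- dnorm(gx, case$s[1], case$sig) /
      (pnorm(S$xmax, case$s[1], case$sig) - pnorm(S$xmin, case$s[1], case$sig))
    fy <- dnorm(gx, case$s[2], case$sig) /
      (pnorm(S$ymax, case$s[2], case$sig) - pnorm(S$ymin, case$s[2], case$sig))
    total <- sum(fx) * h * sum(fy) * h
    expect_equal(total, 1, tolerance = 1e-6)
    # and the package's bivariate density matches the product on a spot check
    ld <- movement_logdensity(c(1.5, 2.5), case$s, "markovian",
                              sigma_s = case$sig, S = S)
    ref <- log(dnorm(1.5, case$s[1], case$sig)) + log(dnorm(2.5, case$s[2], case$sig)) -
      log(pnorm(S$xmax, case$s[1], case$sig) - pnorm(S$xmin, case$s[1], case$sig)) -
      log(pnorm(S$ymax, case$s[2], case$sig) - pnorm(S$ymin, case$s[2], case$sig))
    expect_equal(ld, ref, tolerance = 1e-12)
  }
})

test_that("derived abundance counts alive, recruits and per-capita recruitment", {
  z <- rbind(c(1, 1), c(0, 1), c(1, 0))
  ab <- derived_abundance(z)
  expect_equal(ab$N, c(2, 2))
  expect_equal(ab$R, c(2, 1))
  expect_equal(ab$per_capita, c(NA, 0.5))
  ab0 <- derived_abundance(matrix(0, 4, 3))
  expect_equal(ab0$N, c(0, 0, 0))
  expect_equal(ab0$R, c(0, 0, 0))
  one <- derived_abundance(matrix(1, 1, 2))
  expect_equal(one$R, c(1, 0))
  expect_error(derived_abundance(rbind(c(1, 0, 1))), "life history")
})

test_that("density scales abundance by state-space area", {
  S <- state_space(0, 10, 0, 10)
  expect_equal(scr_density(40, S), 0.4)
  expect_equal(scr_density(0, S), 0)
  S2 <- state_space(0, 231.8 / 10, 0, 10)
  expect_equal(round(scr_density(13, S2), 4), 0.0561)     # per unit area
  expect_equal(round(scr_density(13, S2, scale = 100), 2), 5.61)  # per 100 units
  expect_equal(scr_density(13, S2), 13 / 231.8, tolerance = 1e-12)
})
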