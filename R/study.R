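#' Simulation-study summary metrics
#'
#' Given per-replicate point estimates and credible intervals of one
#' parameter, computes the average posterior mean, relative bias
#' `(avg_mean - truth) / truth`, relative RMSE
#' `sqrt(mean((estimates - truth)^2)) / truth`, and 95% interval coverage,
#' together with Monte-Carlo standard errors so reduced-replication runs
#' carry principled uncertainty.
#'
#' @param estimates Numeric vector of per-replicate posterior means.
#' @param conf.low,conf.high Numeric vectors of per-replicate interval
#'   bounds (may be `NULL` to skip coverage).
#' @param truth True parameter value (nonzero for the relative metrics).
#' @return A one-row tibble: `n_reps`, `truth`, `avg_mean`, `rel_bias`,
#'   `rrmse`, `coverage`, `mc_se_mean`, `mc_se_rel_bias`, `mc_se_coverage`.
#' @export
#' @examples
#' scr_metrics(c(0.7, 0.8), truth = 0.75)
scr_metrics <- function(estimates, conf.low = NULL, conf.high = NULL, truth) {
  stopifnot(is.numeric(estimates), length(estimates) >= 1,
            is.numeric(truth), length(truth) == 1, truth != 0)
  n <- length(estimates)
  avg <- mean(estimates)
  rel_bias <- (avg - truth) / truth
  rrmse <- sqrt(mean((estimates - truth)^2)) / truth
  mc_se_mean <- stats::sd(estimates) / sqrt(n)
  coverage <- NA_real_; mc_se_cov <- NA_real_
  if (!is.null(conf.low) && !is.null(conf.high)) {
    stopifnot(length(conf.low) == n, length(conf.high) == n)
    coverage <- mean(conf.low <= truth & truth <= conf.high)
    mc_se_cov <- sqrt(coverage * (1 - coverage) / n)
  }
  tibble::tibble(
    n_reps = n, truth = truth, avg_mean = avg,
    rel_bias = rel_bias, rrmse = rrmse, coverage = coverage,
    mc_se_mean = mc_se_mean,
    mc_se_rel_bias = mc_se_mean / abs(truth),
    mc_se_coverage = mc_se_cov
  )
}

# Default (reduced-scale) MCMC settings for simulation-study fits. The
# random-walk scale sigma_s mixes slowly, so markovian fits run longer.
study_mcmc_defaults <- function(fit_movement = "constant") {
  if (identical(fit_movement, "markovian")) {
    list(n_chains = 1, n_iter = 5000, n_burnin = 1500, thin = 1)
  } else {
    list(n_chains = 1, n_iter = 2000, n_burnin = 500, thin = 1)
  }
}

#' Run one simulation-study scenario
#'
#' Simulates `n_reps` datasets under `gen_config` (generating buffer
#' `gen_buffer_mult * sigma_p`), fits each with the requested movement model
#' and analysis buffer, and accumulates per-parameter recovery metrics.
#' Per-replicate seeds are derived deterministically from `seed`.
#'
#' @param gen_config A [sim_config()] describing the data-generating
#'   process (its `movement` entry is the generating movement model).
#' @param fit_movement Movement model used in the analysis (`"constant"`,
#'   `"independent"`, `"markovian"`); defaults to the generating model.
#' @param buffer_mult Analysis buffer in multiples of `sigma_p`.
#' @param n_reps Number of replicate datasets.
#' @param seed Master seed.
#' @param estimator `"js"` (full Jolly-Seber model, [fit_open_scr()]) or
#'   `"cjs"` (survival-only, [fit_cjs()]).
#' @param mcmc Named list overriding the study MCMC defaults (one chain,
#'   2000 iterations with 500 burn-in; markovian fits use 5000 with 1500
#'   burn-in because the random-walk scale mixes slowly).
#' @return A list of class `scr_scenario`: `metrics` (one row per
#'   parameter, see [scr_metrics()]) and `estimates` (per-replicate posterior
#'   means and 95% intervals), plus the scenario descriptors.
#' @export
run_scenario <- function(gen_config, fit_movement = NULL, buffer_mult = 4,
                         n_reps = 10, seed = 1, estimator = c("js", "cjs"),
                         mcmc = list()) {
  stopifnot(inherits(gen_config, "sim_config"), n_reps >= 1)
  estimator <- match.arg(estimator)
  if (is.null(fit_movement)) {
    fit_movement <- if (gen_config$movement == "markovian_jump") "markovian" else gen_config$movement
  }
  mcmc <- utils::modifyList(study_mcmc_defaults(fit_movement), mcmc)
  Tn <- gen_config$n_periods
  gen_traps <- make_trap_grid(gen_config$grid_nx, gen_config$grid_ny,
                              gen_config$grid_spacing, K = gen_config$K)
  gen_area <- ss_area(make_state_space(
    gen_traps, gen_config$gen_buffer_mult * gen_config$sigma_p))
  reps <- purrr::map_dfr(seq_len(n_reps), function(r) {
    # stay well inside 32-bit integer range for any master seed
    rep_seed <- (seed %% 1000000) * 1000 + (r - 1)
    d <- simulate_scenario(gen_config, seed = rep_seed)
    S_fit <- make_state_space(d$traps, buffer = buffer_mult * gen_config$sigma_p,
                              buffer_mult = buffer_mult)
    cfg <- fit_config(fit_movement, S = S_fit, M = gen_config$M,
                      n_periods = Tn,
                      n_chains = mcmc$n_chains, n_iter = mcmc$n_iter,
                      n_burnin = mcmc$n_burnin, thin = mcmc$thin,
                      seed = rep_seed + 500L)
    fit <- if (estimator == "js") {
      fit_open_scr(d$detections, d$traps, cfg)
    } else {
      fit_cjs(d$detections, d$traps, cfg)
    }
    keep <- c("phi", "lambda0", "sigma_p",
              if (fit_movement == "markovian") "sigma_s",
              if (estimator == "js") paste0("D_", seq_len(Tn)))
    sm <- dplyr::filter(summarize_posterior(fit), .data$parameter %in% keep)
    dplyr::mutate(sm, rep = r, .before = 1)
  })
  truth_D <- gen_config$target_N / gen_area
  truth_map <- c(phi = gen_config$phi, lambda0 = gen_config$lambda0,
                 sigma_p = gen_config$sigma_p, sigma_s = gen_config$sigma_s)
  for (t in seq_len(Tn)) truth_map[paste0("D_", t)] <- truth_D
  metrics <- reps |>
    dplyr::group_by(.data$parameter) |>
    dplyr::group_modify(function(g, key) {
      scr_metrics(g$mean, g$conf.low, g$conf.high,
                  truth = unname(truth_map[key$parameter[1]]))
    }) |>
    dplyr::ungroup()
  structure(
    list(
      movement_gen = gen_config$movement, movement_fit = fit_movement,
      buffer_mult = buffer_mult, estimator = estimator,
      metrics = dplyr::mutate(metrics,
                              movement_gen = gen_config$movement,
                              movement_fit = fit_movement,
                              buffer_mult = buffer_mult, .before = 1),
      estimates = reps, seed = seed
    ),
    class = "scr_scenario"
  )
}

#' Run the factorial state-space x movement simulation study
#'
#' Crosses the movement models (used for both generation and analysis) with
#' the analysis buffer sizes. All datasets are generated with the
#' `gen_buffer_mult` of `base_config` (4 by default), so one buffer matches
#' the generating state space, one is smaller and one larger.
#'
#' @param base_config A [sim_config()]; its `movement` entry is ignored in
#'   favor of `movements`.
#' @param buffers Analysis buffer multipliers (default `c(3, 4, 5)`).
#' @param movements Movement models to cross (default all three).
#' @param n_reps Replicates per scenario.
#' @param seed Master seed; scenario seeds are derived deterministically.
#' @param mcmc MCMC overrides, as in [run_scenario()].
#' @return A list of class `scr_study`: `metrics` (long tibble over all
#'   scenarios) and `scenarios` (list of `scr_scenario`).
#' @export
run_factorial <- function(base_config, buffers = c(3, 4, 5),
                          movements = c("constant", "independent", "markovian"),
                          n_reps = 10, seed = 1, mcmc = list()) {
  stopifnot(inherits(base_config, "sim_config"))
  grid <- tidyr::expand_grid(movement = movements, buffer = buffers)
  scenarios <- purrr::pmap(grid, function(movement, buffer) {
    cfg <- base_config
    cfg$movement <- movement
    scen_seed <- seed + 100 * match(movement, movements) + match(buffer, buffers)
    run_scenario(cfg, fit_movement = movement, buffer_mult = buffer,
                 n_reps = n_reps, seed = scen_seed, mcmc = mcmc)
  })
  metrics <- purrr::map_dfr(scenarios, "metrics")
  structure(list(metrics = metrics, scenarios = scenarios, seed = seed,
                 n_reps = n_reps),
            class = "scr_study")
}

#' Run a movement-misspecification scenario
#'
#' Generates data under one movement model (including the
#' `"markovian_jump"` variant with occasional long-distance moves) and fits
#' under another, to probe the robustness of survival estimation to a
#' misspecified between-period movement model.
#'
#' @inheritParams run_scenario
#' @param gen_movement Generating movement model.
#' @param fit_movement Analysis movement model.
#' @return An `scr_scenario` (see [run_scenario()]).
#' @export
run_misspecification <- function(base_config, gen_movement, fit_movement,
                                 buffer_mult = 4, n_reps = 10, seed = 1,
                                 mcmc = list()) {
  stopifnot(inherits(base_config, "sim_config"))
  cfg <- base_config
  cfg$movement <- gen_movement
  run_scenario(cfg, fit_movement = fit_movement, buffer_mult = buffer_mult,
               n_reps = n_reps, seed = seed, mcmc = mcmc)
}

#' Arrange study results as a movement-by-buffer table
#'
#' One row per movement model, and for each analysis buffer the average
#' posterior mean and relative RMSE of the chosen parameter — the layout
#' conventionally used to report buffer sensitivity of survival.
#'
#' @param study An `scr_study` (or its `metrics` tibble).
#' @param parameter Parameter to tabulate (default `"phi"`).
#' @return A wide tibble with columns `movement` then
#'   `mean_<b>sigma` / `rrmse_<b>sigma` per buffer.
#' @export
make_table <- function(study, parameter = "phi") {
  metrics <- if (inherits(study, "scr_study")) study$metrics else study
  stopifnot(is.data.frame(metrics))
  m <- dplyr::filter(metrics, .data$parameter == !!parameter)
  if (nrow(m) == 0) {
    return(tibble::tibble(movement = character()))
  }
  m |>
    dplyr::transmute(movement = .data$movement_fit,
                     buffer = .data$buffer_mult,
                     mean = .data$avg_mean, rrmse = .data$rrmse) |>
    tidyr::pivot_wider(names_from = "buffer",
                       values_from = c("mean", "rrmse"),
                       names_glue = "{.value}_{buffer}sigma") |>
    dplyr::select("movement", dplyr::all_of(
      as.vector(outer(c("mean", "rrmse"),
                      sort(unique(m$buffer_mult)),
                      function(a, b) paste0(a, "_", b, "sigma")))
    ))
}

#' Plot buffer sensitivity of a study metric
#'
#' @param object An `scr_study`.
#' @param parameter Parameter to display.
#' @param ... Unused.
#' @return A ggplot of average posterior mean (with MC error bars) against
#'   the analysis buffer, one line per movement model; the dashed line marks
#'   the true value.
#' @export
autoplot.scr_study <- function(object, parameter = "phi", ...) {
  m <- dplyr::filter(object$metrics, .data$parameter == !!parameter)
  ggplot2::ggplot(m, ggplot2::aes(.data$buffer_mult, .data$avg_mean,
                                  color = .data$movement_fit)) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$truth),
                        linetype = "dashed", color = "grey40") +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$avg_mean - 2 * .data$mc_se_mean,
      ymax = .data$avg_mean + 2 * .data$mc_se_mean),
      position = ggplot2::position_dodge(width = 0.1)) +
    ggplot2::geom_line(position = ggplot2::position_dodge(width = 0.1)) +
    ggplot2::labs(x = "analysis buffer (multiples of sigma_p)",
                  y = paste("average posterior mean of", parameter),
                  color = "movement") +
    ggplot2::theme_minimal()
}

#' @export
print.scr_scenario <- function(x, ...) {
  cat(sprintf("<scr_scenario> gen: %s, fit: %s, buffer %gsigma, %s estimator\n",
              x$movement_gen, x$movement_fit, x$buffer_mult, toupper(x$estimator)))
  print(x$metrics)
  invisible(x)
}

#' @export
print.scr_study <- function(x, ...) {
  cat(sprintf("<scr_study> %d scenarios x %d replicates\n",
              length(x$scenarios), x$n_reps))
  print(make_table(x))
  invisible(x)
}
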