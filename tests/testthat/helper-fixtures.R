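# Shared fixtures: all inputs are generated in code at test time.

# a tiny detection tibble on a 2x2 grid, hand-checkable
tiny_traps <- function(K = 5) {
  tibble::tibble(
    trap_id = c("A", "B", "C", "D"),
    x = c(0, 1, 0, 1), y = c(0, 0, 1, 1), K = as.integer(K)
  )
}

tiny_detections <- function() {
  tibble::tibble(
    individual_id = c("i1", "i1", "i2"),
    trap_id = c("A", "B", "D"),
    period = c(1L, 2L, 1L),
    count = c(2L, 1L, 3L)
  )
}

# fast MCMC settings for structural tests (not for recovery assertions)
quick_mcmc <- list(n_chains = 1, n_iter = 400, n_burnin = 100, thin = 1)

quick_fit_config <- function(movement, S, M, n_periods = 5, seed = 1, ...) {
  fit_config(movement, S = S, M = M, n_periods = n_periods,
             n_chains = quick_mcmc$n_chains, n_iter = quick_mcmc$n_iter,
             n_burnin = quick_mcmc$n_burnin, thin = quick_mcmc$thin,
             seed = seed, ...)
}
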