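#' Simulation configuration for open SCR data generation
#'
#' Defaults follow the package's reference study design: five annual primary
#' periods, an average population of 40 individuals maintained on a 10 x 10
#' unit state space (a 7 x 7 trap grid with unit spacing, buffered by
#' `4 * sigma_p`), survival 0.75, baseline encounter rate 0.5, detection
#' scale 0.5, random-walk variance 0.25, five occasions per period, and
#' M = 150 potential individuals.
#'
#' @param n_periods Number of primary periods T.
#' @param M Number of potential (augmented) individuals.
#' @param target_N Intended average population size per period.
#' @param phi Per-interval survival probability.
#' @param lambda0 Baseline encounter rate.
#' @param sigma_p Within-period detection scale.
#' @param sigma_s Between-period random-walk SD per axis (markovian models).
#' @param movement One of `"constant"`, `"independent"`, `"markovian"`,
#'   `"markovian_jump"`. The jump variant is a Markovian walk that, with
#'   probability `p_jump`, redraws the center uniformly on the state space
#'   (occasional long-distance movements).
#' @param K Occasions (trap-days) per trap per period.
#' @param grid_nx,grid_ny,grid_spacing Trap grid geometry.
#' @param gen_buffer_mult Data-generating buffer, in multiples of `sigma_p`.
#' @param p_jump Jump probability for `"markovian_jump"`.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_periods = 5, M = 150, target_N = 40,
                       phi = 0.75, lambda0 = 0.5, sigma_p = 0.5, sigma_s = 0.5,
                       movement = c("constant", "independent", "markovian", "markovian_jump"),
                       K = 5, grid_nx = 7, grid_ny = 7, grid_spacing = 1,
                       gen_buffer_mult = 4, p_jump = 0.1) {
  movement <- match.arg(movement)
  stopifnot(n_periods >= 2, M >= 1, target_N >= 1, target_N <= M,
            phi > 0, phi < 1, lambda0 > 0, sigma_p > 0, sigma_s > 0,
            K >= 1, grid_nx >= 1, grid_ny >= 1, grid_spacing > 0,
            gen_buffer_mult >= 0, p_jump >= 0, p_jump <= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate alive states under the conditional-entrance dynamics
#'
#' Period 1 places exactly `target_N` randomly chosen individuals in the
#' population. At each later period survivors are drawn Bernoulli(`phi`) from
#' the currently alive, and the conditional entrance probability is computed
#' as the shortfall from `target_N` divided by the number of never-yet-alive
#' individuals, so that the expected population size stays at `target_N`:
#' \eqn{\gamma_t = (N_{t-1} - \mathrm{survivors}_t) / \mathrm{available}_t},
#' clamped to `[0, 1]`. Recruits are then drawn Bernoulli(\eqn{\gamma_t})
#' from the available pool.
#'
#' @param config A [sim_config()].
#' @return List with binary matrices `z`, `alpha` (`M x T`), the entrance
#'   probabilities `gamma` (length T; `gamma[1] = target_N / M`), and the
#'   first-entry period `f` (NA for never-recruited individuals).
#' @export
simulate_dynamics <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  M <- config$M; Tn <- config$n_periods
  z <- matrix(0L, M, Tn)
  z[sample.int(M, config$target_N), 1] <- 1L
  gamma <- numeric(Tn)
  gamma[1] <- config$target_N / M
  ever <- z[, 1]
  for (t in 2:Tn) {
    alive_prev <- which(z[, t - 1] == 1L)
    survived <- alive_prev[stats::runif(length(alive_prev)) < config$phi]
    z[survived, t] <- 1L
    avail <- which(ever == 0L)
    need <- length(alive_prev) - length(survived)
    if (length(avail) == 0L) {
      if (need > 0) warning("no individuals left to recruit; gamma set to 0")
      gamma[t] <- 0
    } else {
      gamma[t] <- min(max(need / length(avail), 0), 1)
      recruits <- avail[stats::runif(length(avail)) < gamma[t]]
      z[recruits, t] <- 1L
    }
    ever <- pmax(ever, z[, t])
  }
  f <- apply(z, 1, function(h) if (any(h == 1L)) which.max(h) else NA_integer_)
  # alpha[i,t] = 1 iff z[i,tau] = 0 for all tau < t (vacuously true at t = 1),
  # so availability extends through the entry period itself
  alpha <- matrix(0L, M, Tn)
  for (i in seq_len(M)) {
    if (is.na(f[i])) alpha[i, ] <- 1L else alpha[i, seq_len(f[i])] <- 1L
  }
  list(z = z, alpha = alpha, gamma = gamma, f = f)
}

# one truncated-normal random-walk step by rejection against S
.rw_step <- function(s, sigma_s, S) {
  repeat {
    cand <- s + stats::rnorm(2, 0, sigma_s)
    if (ss_contains(S, cand[1], cand[2])) return(cand)
  }
}

#' Simulate activity-center trajectories
#'
#' On first entry, centers are uniform on the state space. Afterwards they
#' stay put (`constant`), are redrawn uniformly each period (`independent`),
#' or follow a Gaussian random walk truncated to `S` (`markovian`;
#' `markovian_jump` additionally redraws uniformly with probability
#' `p_jump` per step).
#'
#' @param z Binary alive matrix (`M x T`), e.g. from [simulate_dynamics()].
#' @param model Movement model string.
#' @param S A [state_space()].
#' @param sigma_s Random-walk SD per axis.
#' @param p_jump Jump probability for `"markovian_jump"`.
#' @return Array `M x T x 2`; `NA` before first entry.
#' @export
simulate_centers <- function(z, model, S, sigma_s = 0.5, p_jump = 0.1) {
  M <- nrow(z); Tn <- ncol(z)
  s <- array(NA_real_, c(M, Tn, 2))
  for (i in seq_len(M)) {
    h <- z[i, ]
    if (!any(h == 1)) next
    f_i <- which.max(h)
    cur <- c(stats::runif(1, S$xmin, S$xmax), stats::runif(1, S$ymin, S$ymax))
    s[i, f_i, ] <- cur
    if (f_i < Tn) {
      for (t in (f_i + 1):Tn) {
        cur <- switch(model,
          constant = cur,
          independent = c(stats::runif(1, S$xmin, S$xmax), stats::runif(1, S$ymin, S$ymax)),
          markovian = .rw_step(cur, sigma_s, S),
          markovian_jump = if (stats::runif(1) < p_jump) {
            c(stats::runif(1, S$xmin, S$xmax), stats::runif(1, S$ymin, S$ymax))
          } else .rw_step(cur, sigma_s, S),
          stop("unknown movement model: ", model, call. = FALSE)
        )
        s[i, t, ] <- cur
      }
    }
  }
  s
}

#' Simulate detection counts
#'
#' Counts are Binomial in the trap's per-period effort with detection
#' probability given by [detection_prob()] at the distance between the
#' individual's current activity center and the trap; dead or not-yet-entered
#' individuals yield structural zeros.
#'
#' @param s Center array (`M x T x 2`) from [simulate_centers()].
#' @param z Alive matrix (`M x T`).
#' @param traps Trap tibble (with `K` or `K_1..K_T` effort columns).
#' @param lambda0,sigma_p Detection parameters.
#' @return Integer array `y` of dimension `M x J x T`.
#' @export
simulate_detections <- function(s, z, traps, lambda0, sigma_p) {
  validate_traps(traps)
  M <- nrow(z); Tn <- ncol(z); J <- nrow(traps)
  Kmat <- effort_matrix(traps, Tn)
  y <- array(0L, c(M, J, Tn))
  for (t in seq_len(Tn)) {
    alive <- which(z[, t] == 1L)
    if (length(alive) == 0) next
    d2 <- outer(s[alive, t, 1], traps$x, "-")^2 + outer(s[alive, t, 2], traps$y, "-")^2
    p <- 1 - exp(-lambda0 * exp(-d2 / (2 * sigma_p^2)))
    counts <- stats::rbinom(length(alive) * J, size = rep(Kmat[, t], each = length(alive)),
                            prob = as.vector(p))
    y[alive, , t] <- as.integer(counts)
  }
  y
}

#' Simulate a complete open SCR dataset
#'
#' Composes [simulate_dynamics()], [simulate_centers()] and
#' [simulate_detections()] under a seeded RNG, strips never-detected
#' individuals from the reported detections (retaining them in the ground
#' truth), and returns a self-describing dataset.
#'
#' @param config A [sim_config()].
#' @param seed Integer RNG seed; identical config + seed replays the dataset
#'   bit-identically.
#' @return An object of class `scr_dataset`: a list with `traps` (tibble),
#'   `S_gen` (generating [state_space()]), `detections` (long tibble
#'   `individual_id, trap_id, period, count`, positive counts only),
#'   `n_periods`, `seed`, `config`, and `truth` (latent states, parameters,
#'   per-period `N` and density `D`).
#' @export
#' @examples
#' d <- simulate_scenario(sim_config(movement = "constant"), seed = 1)
#' d$truth$abundance
simulate_scenario <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  traps <- make_trap_grid(config$grid_nx, config$grid_ny, config$grid_spacing,
                          center = c(0, 0), K = config$K)
  S_gen <- make_state_space(traps, buffer = config$gen_buffer_mult * config$sigma_p,
                            buffer_mult = config$gen_buffer_mult)
  dyn <- simulate_dynamics(config)
  s <- simulate_centers(dyn$z, config$movement, S_gen,
                        sigma_s = config$sigma_s, p_jump = config$p_jump)
  y <- simulate_detections(s, dyn$z, traps, config$lambda0, config$sigma_p)
  observed <- which(apply(y, 1, sum) > 0)
  det <- NULL
  if (length(observed) > 0) {
    idx <- which(y[observed, , , drop = FALSE] > 0, arr.ind = TRUE)
    det <- tibble::tibble(
      individual_id = paste0("ind", observed[idx[, 1]]),
      trap_id = traps$trap_id[idx[, 2]],
      period = as.integer(idx[, 3]),
      count = as.integer(y[observed, , , drop = FALSE][idx])
    )
    det <- dplyr::arrange(det, .data$individual_id, .data$period, .data$trap_id)
  } else {
    det <- tibble::tibble(individual_id = character(), trap_id = character(),
                          period = integer(), count = integer())
  }
  ab <- derived_abundance(dyn$z)
  truth <- list(
    z = dyn$z, alpha = dyn$alpha, s = s, f = dyn$f, gamma = dyn$gamma,
    phi = config$phi, lambda0 = config$lambda0, sigma_p = config$sigma_p,
    sigma_s = config$sigma_s, movement = config$movement,
    abundance = dplyr::mutate(ab, D = scr_density(.data$N, S_gen)),
    observed = observed
  )
  structure(
    list(traps = traps, S_gen = S_gen, detections = det,
         n_periods = config$n_periods, seed = seed, config = config,
         truth = truth),
    class = "scr_dataset"
  )
}

#' @export
print.scr_dataset <- function(x, ...) {
  cat(sprintf("<scr_dataset> %d periods, %d traps, %d observed individuals (movement: %s, seed %s)\n",
              x$n_periods, nrow(x$traps), length(unique(x$detections$individual_id)),
              x$config$movement, format(x$seed)))
  invisible(x)
}
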