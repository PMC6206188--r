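#' Configuration for fitting an open SCR model
#'
#' Collects the analysis choices: movement model, augmentation size,
#' analysis state space, priors, chain settings and seed. Priors follow the
#' relatively-noninformative convention: survival and entrance probabilities
#' are Uniform(0, 1); `lambda0` is Uniform(0, `lambda0_max`); the spatial
#' scales are Uniform(0, longest state-space side) unless overridden.
#'
#' @param movement One of `"constant"`, `"independent"`, `"markovian"`.
#' @param S Analysis [state_space()] (may differ from the generating one).
#' @param M Augmented population size (must be at least the number of
#'   observed individuals).
#' @param n_periods Number of primary periods T.
#' @param n_chains,n_iter,n_burnin,thin MCMC settings; `n_iter` counts all
#'   iterations including burn-in.
#' @param seed Integer seed; chain `c` uses `seed + c`.
#' @param delta_t Interval lengths between consecutive primary periods
#'   (length `T - 1`, default all 1); survival over an interval is
#'   `phi^delta_t`, see [interval_survival()] and [unequal_intervals()].
#' @param lambda0_max,sigma_p_max,sigma_s_max Upper bounds of the uniform
#'   priors; `NULL` uses the longest side of `S` for the spatial scales.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(movement = c("constant", "independent", "markovian"),
                       S, M = 150, n_periods,
                       n_chains = 3, n_iter = 2500, n_burnin = 500, thin = 1,
                       seed = 1, delta_t = NULL,
                       lambda0_max = 10, sigma_p_max = NULL, sigma_s_max = NULL) {
  movement <- match.arg(movement)
  stopifnot(inherits(S, "state_space"), M >= 1, n_periods >= 2,
            n_chains >= 1, n_iter > n_burnin, thin >= 1)
  side <- max(S$xmax - S$xmin, S$ymax - S$ymin)
  if (is.null(sigma_p_max)) sigma_p_max <- side
  if (is.null(sigma_s_max)) sigma_s_max <- side
  if (is.null(delta_t)) delta_t <- rep(1, n_periods - 1)
  if (length(delta_t) != n_periods - 1) {
    stop(sprintf("`delta_t` must have length n_periods - 1 = %d", n_periods - 1),
         call. = FALSE)
  }
  if (any(delta_t <= 0)) stop("`delta_t` must be positive", call. = FALSE)
  structure(
    list(movement = movement, S = S, M = M, n_periods = n_periods,
         n_chains = n_chains, n_iter = n_iter, n_burnin = n_burnin,
         thin = thin, seed = seed, delta_t = delta_t,
         lambda0_max = lambda0_max, sigma_p_max = sigma_p_max,
         sigma_s_max = sigma_s_max),
    class = "fit_config"
  )
}

#' Set unequal primary-period spacing on a fit configuration
#'
#' For studies whose primary periods are not evenly spaced, survival over
#' the interval preceding period `t` is modeled as `phi^delta_t[t]`, and the
#' reported `phi` is per unit interval (e.g. annual).
#'
#' @param config A [fit_config()].
#' @param delta_t Numeric vector of interval lengths, length `n_periods - 1`.
#' @return The modified `fit_config`.
#' @export
unequal_intervals <- function(config, delta_t) {
  stopifnot(inherits(config, "fit_config"))
  if (length(delta_t) != config$n_periods - 1) {
    stop(sprintf("`delta_t` must have length n_periods - 1 = %d",
                 config$n_periods - 1), call. = FALSE)
  }
  if (any(delta_t <= 0)) stop("`delta_t` must be positive", call. = FALSE)
  config$delta_t <- as.numeric(delta_t)
  config
}

# Internal: dense M x J x T count array from a long detection tibble.
# Individuals are label-sorted so posterior summaries are exchangeable under
# relabeling of the input.
build_y_array <- function(detections, traps, n_periods, M) {
  stopifnot(is.data.frame(detections))
  need <- c("individual_id", "trap_id", "period", "count")
  missing <- setdiff(need, names(detections))
  if (length(missing) > 0) {
    stop("detections missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ids <- sort(unique(as.character(detections$individual_id)))
  n_obs <- length(ids)
  if (M < n_obs) {
    stop(sprintf("M = %d is smaller than the %d observed individuals", M, n_obs),
         call. = FALSE)
  }
  J <- nrow(traps)
  Kmat <- effort_matrix(traps, n_periods)
  y <- array(0L, c(M, J, n_periods))
  if (n_obs > 0) {
    i_idx <- match(as.character(detections$individual_id), ids)
    j_idx <- match(as.character(detections$trap_id), traps$trap_id)
    if (anyNA(j_idx)) stop("detections reference unknown trap_id", call. = FALSE)
    t_idx <- as.integer(detections$period)
    if (any(t_idx < 1 | t_idx > n_periods)) {
      stop("detection period outside 1..n_periods", call. = FALSE)
    }
    cnt <- as.integer(detections$count)
    if (any(cnt < 0)) stop("negative detection count", call. = FALSE)
    for (r in seq_along(i_idx)) {
      y[i_idx[r], j_idx[r], t_idx[r]] <- y[i_idx[r], j_idx[r], t_idx[r]] + cnt[r]
    }
    over <- which(apply(y, c(2, 3), max) > Kmat)
    if (length(over) > 0) {
      stop("detection count exceeds trap effort (y > K)", call. = FALSE)
    }
  }
  list(y = y, ids = ids, n_obs = n_obs, Kmat = Kmat)
}

# Internal: initial values per the package's scheme. z starts alive from
# first to last detection (observed) or never entered (augmented); centers
# start at each individual's mean detection location, uniform otherwise.
make_inits <- function(y, traps, S, M, n_periods, movement, sigma_p_guess) {
  first <- rep(0L, M); last <- rep(0L, M)
  per_ind_t <- apply(y, c(1, 3), sum)
  for (i in seq_len(M)) {
    det_t <- which(per_ind_t[i, ] > 0)
    if (length(det_t) > 0) { first[i] <- min(det_t); last[i] <- max(det_t) }
  }
  entry <- ifelse(first > 0, first, 0L)
  death <- ifelse(first > 0, pmin(last + 1L, n_periods + 1L), n_periods + 2L)
  sx <- matrix(stats::runif(M * n_periods, S$xmin, S$xmax), M, n_periods)
  sy <- matrix(stats::runif(M * n_periods, S$ymin, S$ymax), M, n_periods)
  for (i in seq_len(M)) {
    tot <- apply(y[i, , , drop = FALSE], 2, sum)
    if (sum(tot) > 0) {
      mx <- sum(traps$x * tot) / sum(tot)
      my <- sum(traps$y * tot) / sum(tot)
      mx <- min(max(mx, S$xmin), S$xmax)
      my <- min(max(my, S$ymin), S$ymax)
      sx[i, ] <- mx; sy[i, ] <- my
    }
  }
  list(entry = as.integer(entry), death = as.integer(death),
       sx = sx, sy = sy,
       phi = 0.7, lambda0 = 1.0, sigma_p = sigma_p_guess,
       sigma_s = sigma_p_guess,
       gamma = rep(0.2, n_periods))
}

movement_code <- function(movement) {
  match(movement, c("constant", "independent", "markovian")) - 1L
}

run_chains <- function(ybuild, traps, config, cjs, first_det, save_z = FALSE,
                       fix_detection = FALSE, fix_centers = FALSE,
                       fixed = list()) {
  S <- config$S
  Tn <- config$n_periods
  M <- if (cjs) ybuild$n_obs else config$M
  nn_spacing <- if (nrow(traps) > 1) {
    d <- as.matrix(stats::dist(cbind(traps$x, traps$y)))
    diag(d) <- Inf
    stats::median(apply(d, 1, min))
  } else 1
  par_names <- if (cjs) {
    c("phi", "lambda0", "sigma_p", "sigma_s")
  } else {
    c("phi", paste0("gamma_", seq_len(Tn)), "lambda0", "sigma_p", "sigma_s",
      paste0("N_", seq_len(Tn)))
  }
  out <- vector("list", config$n_chains)
  hit_M <- FALSE
  accept <- NULL
  zd <- NULL
  for (ch in seq_len(config$n_chains)) {
    set.seed(config$seed + ch)
    inits <- make_inits(ybuild$y, traps, S, M, Tn, config$movement,
                        sigma_p_guess = max(nn_spacing / 2, 1e-3))
    for (nm in names(fixed)) inits[[nm]] <- fixed[[nm]]
    res <- run_mcmc_cpp(
      y_flat = as.integer(ybuild$y), dims = c(M, nrow(traps), Tn),
      Kmat = ybuild$Kmat,
      trapx = traps$x, trapy = traps$y,
      Sbounds = c(S$xmin, S$xmax, S$ymin, S$ymax),
      movement = movement_code(config$movement), cjs = cjs,
      delta_t = config$delta_t,
      prior_max = c(config$lambda0_max, config$sigma_p_max, config$sigma_s_max),
      n_iter = config$n_iter, n_burnin = config$n_burnin, thin = config$thin,
      inits = inits, fix_detection = fix_detection, fix_centers = fix_centers,
      save_z = save_z, first_det_in = as.integer(first_det)
    )
    draws <- res$draws
    colnames(draws) <- par_names
    tb <- tibble::as_tibble(as.data.frame(draws))
    tb <- dplyr::mutate(tb, .chain = ch, .iteration = dplyr::row_number(),
                        .before = 1)
    if (!cjs) {
      area <- ss_area(S)
      for (t in seq_len(Tn)) tb[[paste0("D_", t)]] <- tb[[paste0("N_", t)]] / area
    }
    out[[ch]] <- tb
    hit_M <- hit_M || isTRUE(res$hit_M)
    accept <- res$accept
    if (save_z) zd <- rbind(zd, res$z_draws)
  }
  draws <- dplyr::bind_rows(out)
  if (config$movement != "markovian") draws$sigma_s <- NULL
  list(draws = draws, hit_M = hit_M, accept = accept, z_draws = zd)
}

#' Fit the open-population SCR model by MCMC
#'
#' Jolly-Seber-type open spatial capture-recapture model with data
#' augmentation: alive states follow the survival/conditional-entrance
#' process, activity centers follow the configured movement model, and
#' counts are Binomial in trap effort with a hazard half-normal detection
#' function. Sampling is Metropolis-within-Gibbs with an exact joint update
#' of each individual's life history (all entry/death period combinations
#' enumerated), random-walk MH for activity centers (with exact
#' truncated-normal constants under the Markovian model), conjugate Beta
#' draws for survival and entrance probabilities, and adaptive log-scale MH
#' for the detection and movement scales.
#'
#' @param detections Long detection tibble with columns
#'   `individual_id, trap_id, period, count` (positive counts only is fine).
#' @param traps Trap tibble with `trap_id, x, y` and effort (`K` or
#'   `K_1..K_T`).
#' @param config A [fit_config()].
#' @param save_z Keep per-iteration alive indicators (memory-heavy; intended
#'   for small validation instances).
#' @param fix_detection,fix_centers Hold detection parameters / activity
#'   centers fixed at their initial values (validation tool).
#' @param fixed Named list overriding initial values (e.g.
#'   `list(lambda0 = 0.5, sx = ..., sy = ...)`), used with the `fix_*` flags.
#' @return An object of class `open_scr_fit` with elements `draws` (tibble,
#'   one row per retained iteration with `.chain`, `.iteration`, `phi`,
#'   `gamma_t`, `lambda0`, `sigma_p`, `sigma_s` (markovian), `N_t`, `D_t`),
#'   `config`, `n_obs`, and `flags` (e.g. `hit_M` when the posterior of N
#'   piles up at M, a sign the augmentation is too small).
#' @seealso [fit_cjs()], [tidy.open_scr_fit()], [gelman_rubin()]
#' @export
#' @examples
#' \donttest{
#' d <- simulate_scenario(sim_config(movement = "constant"), seed = 1)
#' cfg <- fit_config("constant", S = d$S_gen, M = 150, n_periods = 5,
#'                   n_chains = 1, n_iter = 600, n_burnin = 200)
#' fit <- fit_open_scr(d$detections, d$traps, cfg)
#' tidy(fit)
#' }
fit_open_scr <- function(detections, traps, config, save_z = FALSE,
                         fix_detection = FALSE, fix_centers = FALSE,
                         fixed = list()) {
  stopifnot(inherits(config, "fit_config"))
  validate_traps(traps)
  ybuild <- build_y_array(detections, traps, config$n_periods, config$M)
  res <- run_chains(ybuild, traps, config, cjs = FALSE,
                    first_det = rep(0L, config$M), save_z = save_z,
                    fix_detection = fix_detection, fix_centers = fix_centers,
                    fixed = fixed)
  if (res$hit_M) {
    warning("posterior of N reached the augmentation limit M; increase M",
            call. = FALSE)
  }
  structure(
    list(draws = res$draws, config = config, n_obs = ybuild$n_obs,
         individual_ids = ybuild$ids, model = "js",
         flags = list(hit_M = res$hit_M), accept = res$accept,
         z_draws = res$z_draws),
    class = "open_scr_fit"
  )
}

#' Fit the survival-only (Cormack-Jolly-Seber) open SCR model
#'
#' Conditions on each individual's first capture: the alive state is fixed
#' to 1 at the first detection period, only the subsequent survival process
#' is modeled, and there is no recruitment and no data augmentation.
#' Movement and detection are as in [fit_open_scr()]. Estimates survival
#' (and detection/movement parameters) but not abundance.
#'
#' @inheritParams fit_open_scr
#' @return An `open_scr_fit` with draws of `phi`, `lambda0`, `sigma_p` and
#'   (markovian) `sigma_s` only.
#' @export
fit_cjs <- function(detections, traps, config, save_z = FALSE,
                    fix_detection = FALSE, fix_centers = FALSE,
                    fixed = list()) {
  stopifnot(inherits(config, "fit_config"))
  validate_traps(traps)
  n_obs <- length(unique(as.character(detections$individual_id)))
  if (n_obs == 0) stop("CJS fit requires at least one observed individual", call. = FALSE)
  ybuild <- build_y_array(detections, traps, config$n_periods, n_obs)
  per_ind_t <- apply(ybuild$y, c(1, 3), sum)
  first_det <- apply(per_ind_t, 1, function(v) which(v > 0)[1])
  res <- run_chains(ybuild, traps, config, cjs = TRUE,
                    first_det = first_det, save_z = save_z,
                    fix_detection = fix_detection, fix_centers = fix_centers,
                    fixed = fixed)
  structure(
    list(draws = res$draws, config = config, n_obs = ybuild$n_obs,
         individual_ids = ybuild$ids, model = "cjs",
         flags = list(hit_M = FALSE), accept = res$accept,
         z_draws = res$z_draws),
    class = "open_scr_fit"
  )
}

#' @export
print.open_scr_fit <- function(x, ...) {
  cat(sprintf("<open_scr_fit> %s model, movement: %s, %d observed individuals\n",
              toupper(x$model), x$config$movement, x$n_obs))
  cat(sprintf("  %d chains x %d retained draws\n",
              x$config$n_chains, nrow(x$draws) / x$config$n_chains))
  print(tidy(x), n = 8)
  invisible(x)
}
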