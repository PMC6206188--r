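#' Per-occasion detection probability
#'
#' Complementary log-log (hazard) form of the half-normal detection function:
#' an individual with activity center at distance `d` from a trap is detected
#' on one occasion with probability
#' \deqn{p = 1 - \exp\{-\lambda_0 \exp(-d^2 / 2\sigma_p^2)\}.}
#' `lambda0` is the baseline encounter rate (at `d = 0`) and `sigma_p` sets
#' the rate at which detection declines with distance.
#'
#' @param d Distance(s) from activity center to trap, `>= 0`.
#' @param lambda0 Baseline encounter rate, `> 0`.
#' @param sigma_p Spatial scale of detection, `> 0`.
#' @return Detection probability in (0, 1), vectorized over `d`.
#' @export
#' @examples
#' detection_prob(0, 0.5, 0.5)       # 1 - exp(-0.5)
#' detection_prob(0:3, 0.5, 0.5)
detection_prob <- function(d, lambda0, sigma_p) {
  if (!all(is.finite(d)) || any(d < 0)) stop("`d` must be finite and >= 0", call. = FALSE)
  if (!all(is.finite(lambda0)) || any(lambda0 <= 0)) stop("`lambda0` must be finite and > 0", call. = FALSE)
  if (!all(is.finite(sigma_p)) || any(sigma_p <= 0)) stop("`sigma_p` must be finite and > 0", call. = FALSE)
  # -expm1 keeps p strictly positive when the hazard underflows
  -expm1(-lambda0 * exp(-d^2 / (2 * sigma_p^2)))
}

#' Log-probability of an encounter count
#'
#' Observation model: counts are Binomial in the trap's effort when the
#' individual is alive, and structurally zero otherwise:
#' \eqn{y_{ijt} \mid z_{it} \sim \mathrm{Binomial}(K_{jt}, p\, z_{it})}.
#'
#' @param y Non-negative integer count of detections.
#' @param K Number of occasions (trap-days) of effort, `y <= K`.
#' @param z Binary alive indicator.
#' @param p Per-occasion detection probability.
#' @return Log-probability; `0` for a dead individual with `y = 0`,
#'   `-Inf` for a dead individual with `y > 0`.
#' @export
observation_logpmf <- function(y, K, z, p) {
  stopifnot(length(y) == 1, length(K) == 1, length(z) == 1, length(p) == 1)
  if (y < 0 || K < 0 || y != round(y) || K != round(K)) {
    stop("`y` and `K` must be non-negative integers", call. = FALSE)
  }
  if (y > K) stop("invalid data: count exceeds effort (y > K)", call. = FALSE)
  if (!z %in% c(0, 1)) stop("`z` must be 0 or 1", call. = FALSE)
  if (z == 0) {
    return(if (y == 0) 0 else -Inf)
  }
  stats::dbinom(y, size = K, prob = p, log = TRUE)
}

#' Alive-state transition probability
#'
#' Probability that an individual is alive at `t` given its state at `t - 1`:
#' \eqn{z_t \sim \mathrm{Bernoulli}(\phi z_{t-1} + \gamma_t \alpha_t)}.
#' A currently alive individual survives with probability `phi_interval`; an
#' individual never alive before (`alpha = 1`) enters with the conditional
#' entrance probability `gamma_t`; an individual that has died stays dead.
#'
#' @param z_prev Binary alive indicator at `t - 1`.
#' @param alpha Binary recruitment-availability indicator at `t`.
#' @param phi_interval Survival probability over the interval (already raised
#'   to the interval length, see [interval_survival()]).
#' @param gamma_t Conditional entrance probability at `t`.
#' @return Probability that `z_t = 1`.
#' @export
transition_prob <- function(z_prev, alpha, phi_interval, gamma_t) {
  stopifnot(z_prev %in% c(0, 1), alpha %in% c(0, 1))
  if (z_prev == 1 && alpha == 1) {
    stop("an alive individual cannot also be available for recruitment", call. = FALSE)
  }
  phi_interval * z_prev + gamma_t * alpha
}

#' Survival over an arbitrary interval
#'
#' For unevenly spaced primary periods, survival over an interval of length
#' `delta_t` (in the units of the per-unit survival) is \eqn{\phi^{\Delta t}}.
#'
#' @param phi_unit Per-unit-interval survival probability in (0, 1).
#' @param delta_t Interval length, `> 0`.
#' @return Interval survival probability; equals `phi_unit` when `delta_t = 1`.
#' @export
interval_survival <- function(phi_unit, delta_t) {
  if (any(phi_unit <= 0 | phi_unit >= 1)) stop("`phi_unit` must be in (0, 1)", call. = FALSE)
  if (any(delta_t <= 0)) stop("`delta_t` must be > 0", call. = FALSE)
  phi_unit^delta_t
}

# 1-D truncated-normal log normalizing mass on [lo, hi]
.trunc_mass_log <- function(mean, sd, lo, hi) {
  log(stats::pnorm(hi, mean, sd) - stats::pnorm(lo, mean, sd))
}

#' Between-period movement log-density of an activity center
#'
#' Log-density of `s_t` given `s_prev` under the three activity-center
#' movement models:
#' * `"constant"`: point mass at `s_prev` (0 if equal, `-Inf` otherwise);
#' * `"independent"`: uniform over the state space, `-log(area(S))`;
#' * `"markovian"`: bivariate Gaussian random walk centered at `s_prev` with
#'   per-axis SD `sigma_s`, truncated to the rectangle `S`. The normalizing
#'   constant is the product of the two 1-D truncated-normal masses, so the
#'   density is proper.
#'
#' @param s_t,s_prev Length-2 numeric vectors `(x, y)` inside `S`.
#' @param model One of `"constant"`, `"independent"`, `"markovian"`.
#' @param sigma_s Random-walk SD per axis (markovian only), `> 0`.
#' @param S A [state_space()].
#' @return Log-density.
#' @export
#' @examples
#' S <- state_space(0, 10, 0, 10)
#' movement_logdensity(c(5, 5), c(4, 4), "independent", S = S)  # -log(100)
movement_logdensity <- function(s_t, s_prev, model = c("constant", "independent", "markovian"),
                                sigma_s = NULL, S) {
  model <- match.arg(model)
  stopifnot(length(s_t) == 2, length(s_prev) == 2, inherits(S, "state_space"))
  if (!ss_contains(S, s_t[1], s_t[2]) || !ss_contains(S, s_prev[1], s_prev[2])) {
    stop("activity centers must lie inside the state space", call. = FALSE)
  }
  switch(model,
    constant = if (isTRUE(all(s_t == s_prev))) 0 else -Inf,
    independent = -log(ss_area(S)),
    markovian = {
      if (is.null(sigma_s) || !is.finite(sigma_s) || sigma_s <= 0) {
        stop("`sigma_s` must be > 0 for the markovian model", call. = FALSE)
      }
      stats::dnorm(s_t[1], s_prev[1], sigma_s, log = TRUE) +
        stats::dnorm(s_t[2], s_prev[2], sigma_s, log = TRUE) -
        .trunc_mass_log(s_prev[1], sigma_s, S$xmin, S$xmax) -
        .trunc_mass_log(s_prev[2], sigma_s, S$ymin, S$ymax)
    }
  )
}

#' Derived abundance, recruits and per-capita recruitment
#'
#' From a matrix of alive indicators, abundance is
#' \eqn{N_t = \sum_i z_{it}}, recruits \eqn{R_t} are the individuals alive at
#' `t` that were never alive before, and per-capita recruitment is
#' \eqn{R_t / N_{t-1}} (undefined at `t = 1`).
#'
#' @param z Binary matrix, individuals in rows, primary periods in columns.
#' @return A tibble with columns `period`, `N`, `R`, `per_capita`.
#' @export
#' @examples
#' z <- rbind(c(1, 1), c(0, 1), c(1, 0))
#' derived_abundance(z)
derived_abundance <- function(z) {
  z <- as.matrix(z)
  if (!all(z %in% c(0, 1))) stop("`z` must be binary", call. = FALSE)
  # no revival after death: once 1 -> 0, all later entries must be 0
  if (ncol(z) >= 2) {
    ever <- t(apply(z, 1, cummax))
    if (nrow(z) == 1) ever <- matrix(ever, nrow = 1)
    dead <- ever == 1 & z == 0
    revived <- vapply(seq_len(nrow(z)), function(i) {
      any(dead[i, -ncol(z)] & z[i, -1] == 1)
    }, logical(1))
    if (any(revived)) stop("invalid life history: individual alive after death", call. = FALSE)
  }
  Tn <- ncol(z)
  N <- colSums(z)
  first <- apply(z, 1, function(h) if (any(h == 1)) which.max(h) else NA_integer_)
  R <- vapply(seq_len(Tn), function(t) sum(first == t, na.rm = TRUE), numeric(1))
  per_capita <- c(NA_real_, R[-1] / N[-Tn])
  tibble::tibble(period = seq_len(Tn), N = N, R = R, per_capita = per_capita)
}

#' Population density over a state space
#'
#' @param N_t Abundance (count or vector of counts).
#' @param S A [state_space()].
#' @param scale Reporting scale factor, e.g. `100` for individuals per
#'   100 squared units. Default 1.
#' @return Density `N_t / area(S) * scale`.
#' @export
scr_density <- function(N_t, S, scale = 1) {
  stopifnot(inherits(S, "state_space"), all(N_t >= 0))
  N_t / ss_area(S) * scale
}
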