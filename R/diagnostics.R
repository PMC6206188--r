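#' Gelman-Rubin potential scale reduction factor
#'
#' Plain (non-split, non-rank) PSRF comparing between- and within-chain
#' variance: \eqn{\hat R = \sqrt{\hat V / W}} with
#' \eqn{\hat V = (n-1)/n \, W + B/n}. Values near 1 indicate the chains
#' agree; values above ~1.1 indicate non-convergence.
#'
#' @param x An `open_scr_fit` or a draws tibble with a `.chain` column.
#' @param pars Optional character vector of parameters to diagnose.
#' @return A tibble with columns `parameter` and `rhat`.
#' @export
gelman_rubin <- function(x, pars = NULL) {
  draws <- if (inherits(x, "open_scr_fit")) x$draws else x
  stopifnot(is.data.frame(draws), ".chain" %in% names(draws))
  chains <- unique(draws$.chain)
  if (length(chains) < 2) stop("Gelman-Rubin requires at least 2 chains", call. = FALSE)
  par_cols <- setdiff(names(draws), c(".chain", ".iteration"))
  if (!is.null(pars)) par_cols <- intersect(par_cols, pars)
  n <- min(table(draws$.chain))
  rhat_one <- function(v, ch) {
    mat <- vapply(chains, function(c) v[ch == c][seq_len(n)], numeric(n))
    W <- mean(apply(mat, 2, stats::var))
    B_n <- stats::var(colMeans(mat))          # B / n
    if (W == 0) return(1)
    sqrt(((n - 1) / n * W + B_n) / W)
  }
  tibble::tibble(
    parameter = par_cols,
    rhat = unname(vapply(par_cols, function(p) rhat_one(draws[[p]], draws$.chain),
                         numeric(1)))
  )
}

#' Summarize posterior draws
#'
#' Per-parameter posterior mean, SD, median and central 95% credible
#' interval (2.5% and 97.5% quantiles), plus the Gelman-Rubin \eqn{\hat R}
#' when at least two chains are available.
#'
#' @param x An `open_scr_fit` or a draws tibble with `.chain`/`.iteration`.
#' @param pars Optional character vector of parameters to keep.
#' @param conf_level Credible-interval mass (default 0.95).
#' @return A tibble with columns `parameter`, `mean`, `sd`, `median`,
#'   `conf.low`, `conf.high` and (multi-chain) `rhat`.
#' @export
summarize_posterior <- function(x, pars = NULL, conf_level = 0.95) {
  draws <- if (inherits(x, "open_scr_fit")) x$draws else x
  stopifnot(is.data.frame(draws))
  par_cols <- setdiff(names(draws), c(".chain", ".iteration"))
  if (!is.null(pars)) par_cols <- intersect(par_cols, pars)
  a <- (1 - conf_level) / 2
  out <- purrr::map_dfr(par_cols, function(p) {
    v <- draws[[p]]
    tibble::tibble(
      parameter = p, mean = mean(v), sd = stats::sd(v),
      median = stats::median(v),
      conf.low = unname(stats::quantile(v, a)),
      conf.high = unname(stats::quantile(v, 1 - a))
    )
  })
  if (".chain" %in% names(draws) && length(unique(draws$.chain)) >= 2) {
    out <- dplyr::left_join(out, gelman_rubin(draws, pars = par_cols),
                            by = "parameter")
  }
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy posterior summaries of an open SCR fit
#'
#' @param x An `open_scr_fit`.
#' @param conf_level Credible-interval mass.
#' @param ... Unused.
#' @return A tibble, one row per scalar parameter (see
#'   [summarize_posterior()]).
#' @export
tidy.open_scr_fit <- function(x, conf_level = 0.95, ...) {
  summarize_posterior(x, conf_level = conf_level)
}

#' One-row model overview of an open SCR fit
#'
#' @param x An `open_scr_fit`.
#' @param ... Unused.
#' @return A one-row tibble: model, movement, chains, draws, observed
#'   individuals, max `rhat` (NA for single-chain runs), and whether the
#'   posterior of N hit the augmentation limit.
#' @export
glance.open_scr_fit <- function(x, ...) {
  max_rhat <- if (x$config$n_chains >= 2) max(gelman_rubin(x)$rhat) else NA_real_
  tibble::tibble(
    model = x$model, movement = x$config$movement,
    n_chains = x$config$n_chains,
    n_draws = nrow(x$draws),
    n_obs = x$n_obs,
    max_rhat = max_rhat,
    hit_M = isTRUE(x$flags$hit_M)
  )
}

#' Plot posterior draws of an open SCR fit
#'
#' @param object An `open_scr_fit`.
#' @param pars Parameters to plot (default: scalar demographic and
#'   detection parameters).
#' @param type `"trace"` or `"density"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.open_scr_fit <- function(object, pars = NULL, type = c("trace", "density"), ...) {
  type <- match.arg(type)
  if (is.null(pars)) {
    pars <- intersect(c("phi", "lambda0", "sigma_p", "sigma_s"),
                      names(object$draws))
  }
  long <- tidyr::pivot_longer(
    dplyr::select(object$draws, dplyr::all_of(c(".chain", ".iteration", pars))),
    cols = dplyr::all_of(pars), names_to = "parameter", values_to = "value"
  )
  if (type == "trace") {
    ggplot2::ggplot(long, ggplot2::aes(.data$.iteration, .data$value,
                                       color = factor(.data$.chain))) +
      ggplot2::geom_line(linewidth = 0.3) +
      ggplot2::facet_wrap(~parameter, scales = "free_y") +
      ggplot2::labs(x = "iteration", y = NULL, color = "chain") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(long, ggplot2::aes(.data$value, color = factor(.data$.chain))) +
      ggplot2::geom_density() +
      ggplot2::facet_wrap(~parameter, scales = "free") +
      ggplot2::labs(x = NULL, color = "chain") +
      ggplot2::theme_minimal()
  }
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
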