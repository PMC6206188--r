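# Brute-force posterior enumeration for a tiny open SCR instance:
# T = 2 periods, one trap, all activity centers fixed at the trap location,
# known detection parameters. Each individual's life history is one of
# (z1, z2) in {(0,0) never, (1,0), (1,1), (0,1)}; survival and the two
# entrance probabilities carry independent Uniform(0,1) priors, integrated
# in closed form via Beta functions. Independent of the MCMC code path.

oracle_histories <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1), ncol = 2, byrow = TRUE)

# y: M x 2 matrix of counts at the single trap; K occasions per period;
# p: known per-occasion detection probability.
# Returns the posterior probability of each of the 4^M configurations.
enumerate_tiny_posterior <- function(y, K, p) {
  M <- nrow(y)
  configs <- as.matrix(expand.grid(rep(list(1:4), M)))
  w <- apply(configs, 1, function(cfg) {
    z <- oracle_histories[cfg, , drop = FALSE]
    # observation likelihood
    lik <- 1
    for (i in seq_len(M)) {
      for (t in 1:2) {
        lik <- lik * if (z[i, t] == 1) {
          stats::dbinom(y[i, t], K, p)
        } else {
          as.numeric(y[i, t] == 0)
        }
      }
    }
    if (lik == 0) return(0)
    r1 <- sum(z[, 1] == 1)                       # entered at t = 1
    avail2 <- M - r1                             # never alive before t = 2
    r2 <- sum(z[, 1] == 0 & z[, 2] == 1)         # entered at t = 2
    nsurv <- sum(z[, 1] == 1 & z[, 2] == 1)
    ndie <- sum(z[, 1] == 1 & z[, 2] == 0)
    lik *
      beta(r1 + 1, M - r1 + 1) *                 # integral over gamma_1
      beta(r2 + 1, avail2 - r2 + 1) *            # integral over gamma_2
      beta(nsurv + 1, ndie + 1)                  # integral over phi
  })
  list(configs = configs, prob = w / sum(w))
}

# Map saved z draws (draws x (M*T) matrix, column i + (t-1)*M) to the
# config index used by enumerate_tiny_posterior.
zdraws_to_config <- function(zd, M) {
  z1 <- zd[, 1:M, drop = FALSE]
  z2 <- zd[, M + (1:M), drop = FALSE]
  hist_idx <- matrix(0L, nrow(zd), M)
  for (i in seq_len(M)) {
    hist_idx[, i] <- 1L + z1[, i] * 1L + (z1[, i] & z2[, i]) * 1L +
      ((!z1[, i]) & z2[, i]) * 3L
  }
  # encode as index into expand.grid(rep(list(1:4), M)) ordering
  enc <- rep(1L, nrow(zd))
  mult <- 1L
  for (i in seq_len(M)) {
    enc <- enc + (hist_idx[, i] - 1L) * mult
    mult <- mult * 4L
  }
  enc
}
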