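# Independent brute-force oracles for the exact tests, plus small fixture
# builders. The oracles enumerate; the package routes go through the
# implementation under test.

# Mann-Whitney U and exact two-sided p by full enumeration of all
# C(m+n, m) group assignments of the pooled values (no ties assumed).
mw_enum_oracle <- function(x, y) {
  m <- length(x)
  n <- length(y)
  pooled <- c(x, y)
  u_obs <- sum(outer(x, y, ">"))
  combos <- utils::combn(m + n, m)
  u_all <- apply(combos, 2, function(ix) {
    sum(outer(pooled[ix], pooled[-ix], ">"))
  })
  p_le <- mean(u_all <= u_obs)
  p_ge <- mean(u_all >= u_obs)
  list(U = u_obs, p = min(1, 2 * min(p_le, p_ge)))
}

# Fisher exact two-sided p for a 2x2 table by hypergeometric enumeration:
# sum of the probabilities of all tables (fixed margins) no more probable
# than the observed one.
fisher2x2_enum_oracle <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); N <- sum(tab)
  a_range <- max(0, r1 + c1 - N):min(r1, c1)
  probs <- stats::dhyper(a_range, c1, N - c1, r1)
  p_obs <- stats::dhyper(tab[1, 1], c1, N - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Freeman-Halton p for a 2xk table by full enumeration of all tables with
# the observed margins (multivariate hypergeometric null).
freeman_halton_enum_oracle <- function(tab) {
  col_tot <- colSums(tab)
  r1 <- sum(tab[1, ])
  N <- sum(tab)
  k <- ncol(tab)
  log_prob <- function(a) {
    sum(lchoose(col_tot, a)) - lchoose(N, r1)
  }
  p_obs <- exp(log_prob(tab[1, ]))
  total <- 0
  recurse <- function(j, a, left) {
    if (j == k) {
      if (left <= col_tot[k]) {
        p <- exp(log_prob(c(a, left)))
        if (p <= p_obs * (1 + 1e-7)) total <<- total + p
      }
      return(invisible())
    }
    for (v in 0:min(col_tot[j], left)) recurse(j + 1, c(a, v), left - v)
  }
  recurse(1, integer(0), r1)
  total
}

# Event table with the six canonical channels from a few named columns;
# unspecified channels are filled with a constant.
make_table <- function(n, fill = 10, meta = list(), ...) {
  cols <- list(...)
  m <- matrix(fill, nrow = n, ncol = 6,
              dimnames = list(NULL, phagoflow::PF_CHANNELS))
  for (nm in names(cols)) m[, nm] <- cols[[nm]]
  phagoflow::event_table(m, meta = meta)
}

# Three-cluster scatter configuration with no debris (clean agreement case)
three_cluster_config <- function(seed = 1L, n_events = 10000, ...) {
  phagoflow::synth_config(
    seed = seed, n_events = n_events,
    populations = data.frame(
      name = c("debris", "lymphocyte", "monocyte", "granulocyte"),
      fraction = c(0, 0.35, 0.15, 0.50),
      fsc_mean = c(30, 250, 450, 480), fsc_sd = c(10, 25, 30, 40),
      ssc_mean = c(30, 80, 220, 500), ssc_sd = c(10, 20, 30, 45)
    ),
    ...
  )
}
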