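# Independent brute-force oracles. These re-derive expected values by the
# most literal route available (explicit loops, exhaustive enumeration,
# stats::quantile) and must stay independent of the implementation paths
# they check.

# literal re-evaluation of the knee losses: for each candidate c, the 99th
# percentile (stats::quantile, type 7) of the top-c totals, the count of
# barcodes strictly above a tenth of it, and the loss (obs - c)^2 / c
oracle_ordmag <- function(totals, candidates) {
  sorted <- sort(totals, decreasing = TRUE)
  m_k <- numeric(length(candidates))
  observed <- numeric(length(candidates))
  losses <- numeric(length(candidates))
  for (i in seq_along(candidates)) {
    c_e <- candidates[i]
    m_k[i] <- unname(stats::quantile(sorted[1:c_e], 0.99, type = 7))
    observed[i] <- sum(sorted > m_k[i] / 10)
    losses[i] <- (observed[i] - c_e)^2 / c_e
  }
  best <- which(losses == min(losses))
  expected <- min(candidates[best])  # smallest candidate on ties
  list(m_k = m_k, observed = observed, losses = losses,
       expected_cells = expected)
}

# direct BH step-up formula: min over j >= i of p_(j) * m / j, clipped at 1
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- pmin(1, rev(cummin(rev(ps * m / seq_len(m)))))
  out <- numeric(m)
  out[o] <- adj
  out
}

# exhaustive multinomial null on 2 genes at a fixed total: p-value of a
# count vector = total probability of outcomes with log-likelihood <= its
# own (ties included)
oracle_exhaustive_pvalue <- function(obs, total, profile) {
  ks <- 0:total
  probs <- stats::dbinom(ks, total, profile[1])
  ll <- log(probs)
  obs_ll <- log(stats::dbinom(obs[1], total, profile[1]))
  min(1, sum(probs[ll <= obs_ll + 1e-12]))
}

# all count vectors over 2 genes at a fixed total
enumerate_2gene <- function(total) {
  t(vapply(0:total, function(k) c(k, total - k), numeric(2)))
}
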