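# Independent brute-force oracles and table builders shared across tests.

# table with given (pmin, pmax) per row: p1 carries the min, p2 the max
table_from_min_max <- function(pmin, pmax) {
  stopifnot(all(pmin <= pmax))
  pvalue_table(p1 = pmin, p2 = pmax)
}

random_table <- function(m, prop_signal = 0.3, snr = 2.5) {
  z1 <- rnorm(m) + ifelse(runif(m) < prop_signal, snr, 0)
  z2 <- rnorm(m) + ifelse(runif(m) < prop_signal, snr, 0)
  pvalue_table(p1 = pnorm(-z1), p2 = pnorm(-z2))
}

# exhaustive scan of the threshold grid {budget/j : j = m..1} (capped at 1):
# largest grid value whose estimated per-family error is within budget
brute_force_grid_threshold <- function(pmin_vec, budget) {
  m <- length(pmin_vec)
  grid <- pmin(budget / (m:1), 1)
  ok <- vapply(grid, function(cc) cc * sum(pmin_vec <= cc) <= budget + 1e-12,
               logical(1))
  max(grid[ok])
}

# Monte-Carlo estimate of P(pmax <= u | pmin <= c) for a pair with one
# uniform and one Gaussian-shift component
mc_cond_cdf_mixed <- function(u, c, snr, n = 1e6) {
  p_null <- runif(n)
  p_alt <- pnorm(-(rnorm(n) + snr))
  keep <- pmin(p_null, p_alt) <= c
  list(est = mean(pmax(p_null, p_alt)[keep] <= u), n_kept = sum(keep))
}

binom_se <- function(p, n) sqrt(p * (1 - p) / n)
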