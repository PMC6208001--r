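# Independent oracles used across the suite.

# Brute-force Benjamini-Hochberg step-up: adjusted p_(i) =
# min over j >= i of min(1, p_(j) * n / j), mapped back to input order.
bh_bruteforce <- function(p) {
  n <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- numeric(n)
  for (i in seq_len(n)) {
    adj[i] <- min(1, min(ps[i:n] * n / (i:n)))
  }
  out <- numeric(n)
  out[ord] <- adj
  out
}

# Closed-form simple OLS of y on (1, x): coefficients, residuals, and the
# two-sided t-test p-value of the slope, via normal equations only.
ols_hand <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  beta <- sum((x - mean(x)) * (y - mean(y))) / sxx
  alpha <- mean(y) - beta * mean(x)
  res <- y - alpha - beta * x
  se <- sqrt(sum(res^2) / (n - 2) / sxx)
  tstat <- beta / se
  list(alpha = alpha, beta = beta, residuals = res, se = se,
       p = 2 * pt(-abs(tstat), df = n - 2))
}

# One small default-condition replicate set, computed lazily and shared by
# the property-style tests (SVR fits are the expensive step).
.rep_cache <- new.env(parent = emptyenv())
shared_replicates <- function(n_reps = 5, seed0 = 42) {
  key <- sprintf("reps_%d_%d", n_reps, seed0)
  if (is.null(.rep_cache[[key]])) {
    .rep_cache[[key]] <- lapply(seq_len(n_reps), function(r) {
      run_replicate(sim_config(), seed = seed0 + r)
    })
  }
  .rep_cache[[key]]
}
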