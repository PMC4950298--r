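# Independent oracles used across the suite. These re-derive expected
# values by brute force or closed form, independently of the package's
# implementation path.

# Direct algebraic one-generation update of the four-cytotype model,
# written as explicit sums over the 16 crosses (no mating-table object).
oracle_step <- function(x, l, mu, fa, fb, tau, alpha = 0, beta = 0) {
  conv <- alpha * beta
  xa <- x[1:2] * (1 - conv)
  xb <- x[3:4] + conv * x[1:2]
  pa <- sum(xa); pb <- sum(xb)
  out <- numeric(4)
  for (h in 1:2) {
    out[h]     <- out[h] + fa * xa[h] * pa
    out[h]     <- out[h] + fa * (1 - l) * xa[h] * pb * (1 - tau)
    out[2 + h] <- out[2 + h] + fa * (1 - l) * xa[h] * pb * tau
    out[2 + h] <- out[2 + h] + fb * xb[h] * pa * (1 - mu)
    out[h]     <- out[h] + fb * xb[h] * pa * mu
    out[2 + h] <- out[2 + h] + fb * xb[h] * pb * ((1 - mu) + mu * tau)
    out[h]     <- out[h] + fb * xb[h] * pb * mu * (1 - tau)
  }
  out / sum(out)
}

# Exact two-sided Fisher p by exhaustive enumeration over the
# hypergeometric support of a 2x2 table with fixed margins.
oracle_fisher_p <- function(tab) {
  r <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  support <- max(0L, r + c1 - n):min(r, c1)
  probs <- stats::dhyper(support, c1, n - c1, r)
  p_obs <- stats::dhyper(tab[1, 1], c1, n - c1, r)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Random normalized cytotype state.
random_state <- function() {
  x <- stats::runif(4)
  x <- x / sum(x)
  cytotype_state(x[1], x[2], x[3], x[4])
}
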