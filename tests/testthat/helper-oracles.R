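# Independent pmf-enumeration oracles for the exact binomial machinery.

oracle_limits <- function(n, p0, alpha) {
  pmf <- dbinom(0:n, n, p0)
  cdf <- cumsum(pmf)                       # cdf[j+1] = P(X <= j)
  sf <- rev(cumsum(rev(pmf)))              # sf[j+1]  = P(X >= j)
  half <- alpha / 2
  ks <- 0:n
  ok_lo <- c(TRUE, cdf[1:n] <= half)       # k = 0 always allowed
  k_lo <- max(ks[ok_lo])
  ok_up <- c(sf[2:(n + 1)] <= half, TRUE)  # P(X >= k+1) <= half; k = n always
  k_up <- min(ks[ok_up])
  c(lower = k_lo / n, upper = k_up / n)
}

oracle_two_sided <- function(k, n, p0) {
  pmf <- dbinom(0:n, n, p0)
  min(1, 2 * min(sum(pmf[1:(k + 1)]), sum(pmf[(k + 1):(n + 1)])))
}
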