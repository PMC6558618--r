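# Independent Saltelli-type Monte Carlo estimator of first-order Sobol
# indices for a function on uniform [-1, 1]^d. Used as the oracle against
# the coefficient-based indices; deliberately shares no code with the
# package implementation.
#
# Estimator (Saltelli et al. 2010): V_i ~ mean( f(B) * (f(A_B^i) - f(A)) ),
# where A_B^i is A with column i replaced by B's. Standard errors come from
# the sample variance of the elementary products.
saltelli_first_order <- function(f, d, n, seed) {
  set.seed(seed)
  A <- matrix(stats::runif(n * d, -1, 1), n, d)
  B <- matrix(stats::runif(n * d, -1, 1), n, d)
  fA <- f(A)
  fB <- f(B)
  V <- stats::var(c(fA, fB))
  S <- numeric(d)
  SE <- numeric(d)
  for (i in seq_len(d)) {
    ABi <- A
    ABi[, i] <- B[, i]
    g <- fB * (f(ABi) - fA)
    S[i] <- mean(g) / V
    SE[i] <- stats::sd(g) / sqrt(n) / V
  }
  list(S = S, se = SE, total_variance = V)
}
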