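# Independent brute-force oracles used across test files. These stay
# deliberately naive (double loops, direct summation) so they share no code
# with the implementation they check.

# direct causal convolution: y[n] = sum_m k[m] x[n - m], zero-padded past
brute_convolve <- function(k, x) {
  n <- length(x)
  y <- numeric(n)
  for (i in seq_len(n)) {
    for (m in seq_along(k)) {
      j <- i - (m - 1L)
      if (j >= 1L) y[i] <- y[i] + k[m] * x[j]
    }
  }
  y
}

# Laguerre regressor by explicit double loop (NA burn-in like the package)
brute_regressor <- function(x, B) {
  n <- length(x)
  M <- ncol(B)
  out <- matrix(NA_real_, n, nrow(B))
  for (j in seq_len(nrow(B))) {
    for (i in M:n) {
      acc <- 0
      for (m in seq_len(M)) acc <- acc + B[j, m] * x[i - m + 1L]
      out[i, j] <- acc
    }
  }
  out
}

# random stable test system with matching-structure kernels
random_sys <- function(seed, alpha = 0.5, L = 3L, dt = 1, M = 50L) {
  withr::with_seed(seed, {
    true_model(alpha_p = alpha, alpha_c = alpha,
               coeff_p = rnorm(L, sd = 0.4),
               coeff_c = c(0.8, rnorm(L - 1L, sd = 0.3)),
               dt = dt, M = M)
  })
}
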