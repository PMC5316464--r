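# Independent brute-force oracles used across the suite.  These deliberately
# avoid the package's own code paths.

# circular convolution by explicit double loop: y[n] = sum_k taps[k] x[n-k]
naive_circ_conv <- function(x, taps) {
  n <- length(x)
  y <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (k in seq_along(taps)) {
      acc <- acc + taps[k] * x[((i - 1L) - (k - 1L)) %% n + 1L]
    }
    y[i] <- acc
  }
  y
}

# O(N^2) direct DFT power at frequency bin k (mean-removed)
naive_dft_power <- function(x, k) {
  n <- length(x)
  xc <- x - mean(x)
  t <- 0:(n - 1L)
  re <- sum(xc * cos(2 * pi * k * t / n))
  im <- sum(xc * sin(2 * pi * k * t / n))
  (re^2 + im^2) / n
}

# element-by-element forward pass of the three-layer sigmoid perceptron
naive_mlp_forward <- function(w, b, z) {
  m <- nrow(z); Q <- ncol(w); tau <- ncol(b)
  out <- matrix(0, m, tau)
  for (r in seq_len(m)) {
    y <- numeric(Q)
    for (j in seq_len(Q)) {
      s <- 0
      for (i in seq_len(nrow(w))) s <- s + w[i, j] * z[r, i]
      y[j] <- 1 / (1 + exp(-s))
    }
    for (h in seq_len(tau)) out[r, h] <- sum(b[, h] * y)
  }
  out
}

# least squares via heavily-checked ridge limit (normal equations with a
# vanishing ridge), as an oracle for residuals of rank-deficient fits
ridge_ls_fit <- function(z, targets, lambda = 1e-10) {
  solve(crossprod(z) + diag(lambda, ncol(z)), crossprod(z, targets))
}

# seeded random series of a given length on the scale of weekly counts
random_count_series <- function(n, seed, level = 1000) {
  set.seed(seed)
  level + cumsum(rnorm(n, 0, 5)) + rnorm(n, 0, 20)
}
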