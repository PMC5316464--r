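#' Orthonormal Daubechies filter pair
#'
#' Closed-form scaling (low-pass) coefficients for Daubechies wavelets of
#' order 1-3 under the orthonormal convention (taps sum to sqrt(2)); the
#' wavelet (high-pass) filter follows by the quadrature-mirror rule
#' `g[i] = (-1)^i h[L-1-i]`.
#'
#' @param wavelet One of `"db1"`, `"db2"`, `"db3"`.
#' @return List with `h` (low-pass) and `g` (high-pass) numeric vectors.
#' @keywords internal
daubechies_filters <- function(wavelet = "db2") {
  h <- switch(wavelet,
    db1 = c(1, 1) / sqrt(2),
    db2 = c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2)),
    db3 = {
      a <- sqrt(5 + 2 * sqrt(10))
      c(1 + sqrt(10) + a, 5 + sqrt(10) + 3 * a, 10 - 2 * sqrt(10) + 2 * a,
        10 - 2 * sqrt(10) - 2 * a, 5 + sqrt(10) - 3 * a, 1 + sqrt(10) - a) /
        (16 * sqrt(2))
    },
    stop(sprintf("unsupported wavelet '%s'; supported: db1, db2, db3", wavelet),
         call. = FALSE)
  )
  L <- length(h)
  g <- (-1)^(0:(L - 1L)) * rev(h)
  list(h = h, g = g)
}

#' Build the a trous filter bank
#'
#' Constructs the per-level analysis filters of the stationary (undecimated)
#' wavelet transform: the level-(j+1) filter is the level-j filter upsampled
#' by inserting `2^(j-1) - 1` zeros between adjacent taps, so no decimation is
#' ever applied and every coefficient sequence keeps the signal's length.
#' Analysis filters carry a 1/sqrt(2) factor per level; synthesis applies the
#' same filters in adjoint (correlation) order, which makes
#' analysis-plus-synthesis an exact inverse (for orthonormal pairs
#' `|H|^2 + |G|^2 = 2`, and the two 1/sqrt(2) factors absorb the 2).
#'
#' @param wavelet Daubechies order as `"db1"`, `"db2"` (default) or `"db3"`.
#' @param J Number of decomposition levels, >= 1.
#' @return Object of class `"swt_bank"`: list with `wavelet`, `J`, and
#'   per-level upsampled `low_pass` / `high_pass` filters.
#' @examples
#' bank <- swt_filter_bank("db2", 3)
#' length(bank$low_pass[[3]])  # 4 taps with zero-gaps of 3
#' @export
swt_filter_bank <- function(wavelet = "db2", J = 3L) {
  stopifnot(J >= 1L)
  f <- daubechies_filters(wavelet)
  upsample <- function(v) {
    out <- numeric(2L * length(v) - 1L)
    out[seq(1L, length(out), by = 2L)] <- v
    out
  }
  low <- vector("list", J)
  high <- vector("list", J)
  low[[1L]] <- f$h / sqrt(2)
  high[[1L]] <- f$g / sqrt(2)
  if (J >= 2L) {
    for (j in 2:J) {
      low[[j]] <- upsample(low[[j - 1L]])
      high[[j]] <- upsample(high[[j - 1L]])
    }
  }
  structure(list(wavelet = wavelet, J = J, low_pass = low, high_pass = high),
            class = "swt_bank")
}

# circular filtering; analysis is convolution y[n] = sum_i f[i] x[n - i],
# synthesis the adjoint correlation y[n] = sum_i f[i] x[n + i] (0-based taps)
circ_filter <- function(x, taps, adjoint = FALSE) {
  n <- length(x)
  idx0 <- seq_along(taps) - 1L
  out <- numeric(n)
  for (k in seq_along(taps)) {
    if (taps[k] == 0) next
    shift <- idx0[k]
    pos <- if (adjoint) (seq_len(n) - 1L + shift) %% n + 1L
           else         (seq_len(n) - 1L - shift) %% n + 1L
    out <- out + taps[k] * x[pos]
  }
  out
}

#' Stationary wavelet decomposition
#'
#' Runs the a trous cascade: the signal is circularly convolved with the
#' level-1 low- and high-pass filters to give the first approximation and
#' detail sequences, then each approximation is filtered with the next
#' (upsampled) filter pair.  All sequences keep length N.
#'
#' @param x Numeric series; its length must be an integer multiple of `2^J`
#'   (pad first otherwise, see [swt_components()]).
#' @param bank Filter bank from [swt_filter_bank()].
#' @return Object of class `"swt"`: list with `a` (approximations, levels
#'   1..J), `d` (details), `J`, `n`, `wavelet`.
#' @export
swt_decompose <- function(x, bank) {
  x <- check_series(x, min_length = 2L)
  stopifnot(inherits(bank, "swt_bank"))
  n <- length(x)
  J <- bank$J
  if (n %% 2L^J != 0L) {
    stop(sprintf(
      "series length %d is not a multiple of 2^J = %d; pad the series first",
      n, 2L^J), call. = FALSE)
  }
  a <- vector("list", J)
  d <- vector("list", J)
  cur <- x
  for (j in seq_len(J)) {
    a[[j]] <- circ_filter(cur, bank$low_pass[[j]])
    d[[j]] <- circ_filter(cur, bank$high_pass[[j]])
    cur <- a[[j]]
  }
  structure(list(a = a, d = d, J = J, n = n, wavelet = bank$wavelet),
            class = "swt")
}

#' Inverse stationary wavelet transform
#'
#' Reconstructs a series from SWT coefficients by applying the analysis
#' operations in reverse order with the adjoint (time-reversed) filters.
#' Subbands can be selectively kept: with everything kept the original
#' series is recovered exactly; zeroing subbands reconstructs only the
#' retained contributions, and by linearity the per-subband reconstructions
#' sum to the full signal.
#'
#' @param coeffs `"swt"` object from [swt_decompose()].
#' @param bank The same filter bank used for analysis.
#' @param keep_approx Keep the level-J approximation? (default TRUE)
#' @param keep_details Integer vector of detail levels to keep
#'   (default all `1..J`).
#' @return Numeric series of length N.
#' @export
iswt_reconstruct <- function(coeffs, bank, keep_approx = TRUE,
                             keep_details = seq_len(coeffs$J)) {
  stopifnot(inherits(coeffs, "swt"), inherits(bank, "swt_bank"))
  if (bank$J != coeffs$J || bank$wavelet != coeffs$wavelet) {
    stop("filter bank does not match the coefficients (levels or wavelet differ)",
         call. = FALSE)
  }
  J <- coeffs$J
  zero <- numeric(coeffs$n)
  cur <- if (keep_approx) coeffs$a[[J]] else zero
  for (j in J:1) {
    dj <- if (j %in% keep_details) coeffs$d[[j]] else zero
    cur <- circ_filter(cur, bank$low_pass[[j]], adjoint = TRUE) +
           circ_filter(dj,  bank$high_pass[[j]], adjoint = TRUE)
  }
  cur
}

#' Pad a series to a multiple of a block size by symmetric reflection
#'
#' Appends the mirror image of the series tail (half-point symmetric,
#' boundary value repeated) until the length is the next multiple of `m`.
#'
#' @param x Numeric series.
#' @param m Positive integer block size.
#' @return List with `x` (padded series) and `n` (original length).
#' @export
pad_to_multiple <- function(x, m) {
  stopifnot(is.numeric(x), m >= 1L)
  n <- length(x)
  p <- (m - n %% m) %% m
  if (p > 0L) {
    if (p > n) stop("series too short to pad by reflection", call. = FALSE)
    x <- c(x, rev(x[(n - p + 1L):n]))
  }
  list(x = x, n = n)
}

#' Low/high-frequency split by stationary wavelet transform
#'
#' The wavelet counterpart of [msvd()]: decomposes the series to depth `J`,
#' reconstructs the level-J approximation alone as the low-frequency
#' component `c_L`, and sums the reconstructions of all detail subbands into
#' the high-frequency component `c_H`; the two add back to the input.
#' Series whose length is not a multiple of `2^J` are padded by symmetric
#' reflection, transformed, and the components truncated back to N.
#'
#' @param x Numeric series.
#' @param J Decomposition depth (default 3, suited to fluctuation periods of
#'   roughly 8-16 samples).
#' @param wavelet Daubechies filter, default `"db2"`.
#' @return Object of class `"swt_components"`: list with `c_L`, `c_H`, `J`,
#'   `wavelet`, and the achieved `coeffs` on the (possibly padded) series.
#' @examples
#' t <- 1:260
#' x <- 50 + 10 * sin(2 * pi * t / 26)
#' sc <- swt_components(x)
#' max(abs(sc$c_L + sc$c_H - x))
#' @export
swt_components <- function(x, J = 3L, wavelet = "db2") {
  x <- check_series(x)
  bank <- swt_filter_bank(wavelet, J)
  padded <- pad_to_multiple(x, 2L^J)
  coeffs <- swt_decompose(padded$x, bank)
  c_L <- iswt_reconstruct(coeffs, bank, keep_approx = TRUE,
                          keep_details = integer(0))
  c_H <- iswt_reconstruct(coeffs, bank, keep_approx = FALSE)
  structure(list(c_L = c_L[seq_len(padded$n)], c_H = c_H[seq_len(padded$n)],
                 J = J, wavelet = wavelet, coeffs = coeffs),
            class = "swt_components")
}

#' @export
print.swt_components <- function(x, ...) {
  cat(sprintf("Stationary wavelet component split (%s, J = %d, N = %d)\n",
              x$wavelet, x$J, length(x$c_L)))
  cat(sprintf("  sd(c_L) = %.4g, sd(c_H) = %.4g\n",
              stats::sd(x$c_L), stats::sd(x$c_H)))
  invisible(x)
}
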