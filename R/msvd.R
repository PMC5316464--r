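#' @keywords internal
check_series <- function(x, min_length = 3L, arg = "x") {
  if (!is.numeric(x)) {
    stop(sprintf("`%s` must be a numeric series", arg), call. = FALSE)
  }
  x <- as.numeric(x)
  if (length(x) < min_length) {
    stop(sprintf("series too short: `%s` has %d values, at least %d are required",
                 arg, length(x), min_length), call. = FALSE)
  }
  bad <- which(!is.finite(x))
  if (length(bad) > 0L) {
    stop(sprintf("`%s` contains a non-finite value at index %d", arg, bad[1L]),
         call. = FALSE)
  }
  x
}

#' Embed a series in a 2 x (N-1) Hankel matrix
#'
#' Builds the trajectory matrix with window length 2: the first row holds
#' `x[1..N-1]`, the second row `x[2..N]`, so every anti-diagonal is constant.
#' This fixed-window embedding is the first step of the multilevel SVD
#' decomposition.
#'
#' @param x Numeric series of length N >= 3, all values finite.
#' @return A `2 x (N-1)` numeric matrix.
#' @seealso [hankelize()] for the inverse mapping, [msvd()] for the full
#'   decomposition.
#' @examples
#' embed_hankel(c(1, 2, 3, 4))
#' @export
embed_hankel <- function(x) {
  x <- check_series(x)
  n <- length(x)
  rbind(x[-n], x[-1L])
}

#' Closed-form SVD of a two-row matrix
#'
#' Computes the exact singular value decomposition of a `2 x m` matrix from
#' the eigendecomposition of the 2 x 2 symmetric matrix `H %*% t(H)`:
#' the squared singular values are its eigenvalues
#' `(tr +/- sqrt(tr^2 - 4 det)) / 2`, and the right singular vectors follow
#' as `t(H) %*% u / lambda`.
#'
#' @param H Numeric matrix with exactly 2 rows.
#' @return List with `d` (singular values, descending), `u` (`2 x 2` left
#'   singular vectors in columns), `v` (`m x 2` right singular vectors).
#'   `H` equals `d[1] u1 v1' + d[2] u2 v2'` to machine precision.
#' @examples
#' svd_rank2(matrix(c(1, 3, 2, 4), 2, 2))
#' @export
svd_rank2 <- function(H) {
  if (!is.matrix(H) || nrow(H) != 2L) {
    stop("`H` must be a matrix with exactly 2 rows", call. = FALSE)
  }
  if (!all(is.finite(H))) stop("`H` contains non-finite values", call. = FALSE)
  m <- ncol(H)
  A <- H %*% t(H)                      # 2x2 symmetric PSD
  tr <- A[1L, 1L] + A[2L, 2L]
  # guard tiny negative discriminants / eigenvalues from rounding
  disc <- sqrt(max((A[1L, 1L] - A[2L, 2L])^2 + 4 * A[1L, 2L]^2, 0))
  ev1 <- (tr + disc) / 2
  ev2 <- max((tr - disc) / 2, 0)
  d <- sqrt(c(max(ev1, 0), ev2))

  eigvec <- function(lam) {
    # (A - lam I) u = 0; pick the better-conditioned row
    r1 <- c(A[1L, 1L] - lam, A[1L, 2L])
    r2 <- c(A[2L, 1L], A[2L, 2L] - lam)
    u <- if (sum(r1^2) >= sum(r2^2)) c(-r1[2L], r1[1L]) else c(-r2[2L], r2[1L])
    nu <- sqrt(sum(u^2))
    if (nu == 0) c(1, 0) else u / nu
  }
  u1 <- eigvec(ev1)
  # enforce orthogonality exactly; handles the degenerate ev1 == ev2 case
  u2 <- c(-u1[2L], u1[1L])
  u <- cbind(u1, u2, deparse.level = 0L)

  v <- matrix(0, m, 2L)
  for (k in 1:2) {
    if (d[k] > 0) {
      v[, k] <- drop(t(H) %*% u[, k]) / d[k]
    }
  }
  list(d = d, u = u, v = v)
}

#' Map a two-row matrix back to a series by anti-diagonal averaging
#'
#' The diagonal-averaging (Hankelization) step standard in singular spectrum
#' analysis: entry `k` of the output is the mean of all matrix entries on the
#' k-th anti-diagonal.  For a true Hankel matrix this inverts
#' [embed_hankel()] exactly, and the map is linear, so the SVD's elementary
#' matrices turn into additive series components.
#'
#' @param M Numeric matrix with 2 rows and m columns.
#' @return Numeric series of length `m + 1`.
#' @examples
#' hankelize(embed_hankel(c(1, 5, 2, 8)))  # recovers the input
#' @export
hankelize <- function(M) {
  if (!is.matrix(M) || nrow(M) != 2L) {
    stop("`M` must be a matrix with exactly 2 rows", call. = FALSE)
  }
  m <- ncol(M)
  n <- m + 1L
  s <- numeric(n)
  s[1L] <- M[1L, 1L]
  s[n] <- M[2L, m]
  if (n > 2L) {
    k <- 2:(n - 1L)
    s[k] <- (M[1L, k] + M[2L, k - 1L]) / 2
  }
  s
}

#' One level of the Hankel-SVD decomposition
#'
#' Embeds the series ([embed_hankel()]), takes the exact rank-2 SVD
#' ([svd_rank2()]), and Hankelizes the two elementary matrices back into a
#' low-frequency component (leading singular triple) and a high-frequency
#' component (second triple).  By linearity the two components add back to
#' the input.  The relative energy of the leading singular value,
#' `R = lambda1 / (lambda1 + lambda2)`, always lies in `[0.5, 1]` and equals
#' 1 exactly when the Hankel matrix has rank <= 1; an all-zero input takes
#' `R = 1` by convention.
#'
#' @param x Numeric series, length >= 3.
#' @return List with `c_low`, `c_high` (series of the input's length),
#'   `lambda1`, `lambda2`, and `R`.
#' @export
msvd_level <- function(x) {
  H <- embed_hankel(x)
  s <- svd_rank2(H)
  c_low <- s$d[1L] * hankelize(tcrossprod(s$u[, 1L], s$v[, 1L]))
  c_high <- s$d[2L] * hankelize(tcrossprod(s$u[, 2L], s$v[, 2L]))
  tot <- s$d[1L] + s$d[2L]
  R <- if (tot > 0) s$d[1L] / tot else 1
  list(c_low = c_low, c_high = c_high,
       lambda1 = s$d[1L], lambda2 = s$d[2L], R = R)
}

#' Multilevel SVD decomposition of a series
#'
#' Decomposes a series into an additive low-frequency component `c_L` and
#' high-frequency component `c_H` by recursing the window-2 Hankel-SVD
#' ([msvd_level()]) on the low-frequency branch, pyramid style: each level's
#' `c_low` is the next level's input, and the per-level `c_high` terms
#' accumulate into `c_H`.  The recursion depth J is chosen by the singular
#' spectrum rate `deltaR_j = R_j / R_{j+1}`: decomposition stops at the first
#' level where `|deltaR_j - 1| <= tol`, i.e. where the relative leading-value
#' energy has reached its asymptote.  One level beyond the candidate stopping
#' level is always computed so the rate is available at the decision point.
#'
#' @param x Numeric series of length N >= 3, all finite.
#' @param tol Stopping tolerance on `|deltaR - 1|` (default `1e-4`).  The
#'   rate approaches 1 from below as the pyramid deepens; on series whose
#'   mean level dominates the Hankel spectrum a loose tolerance (say 0.01)
#'   stops after one or two levels and the split degenerates to
#'   `c_L ~ x`, so the default is chosen tight enough that realistic weekly
#'   count series decompose to depths in the tens.
#' @param max_levels Depth cap (default 32).  Reaching it without meeting the
#'   tolerance is not an error; the result is flagged unconverged and a
#'   warning is raised.
#' @return An object of class `"msvd"`: a list with
#'   \describe{
#'     \item{c_L, c_H}{the two components, each of length N, summing to `x`;}
#'     \item{J}{achieved depth;}
#'     \item{R}{per-level leading-energy ratios `R_1..R_{J+1}` (one past the
#'       stopping level when available);}
#'     \item{delta_R}{the rate sequence `R_j / R_{j+1}`;}
#'     \item{levels}{per-level records (`c_low`, `c_high`, `lambda1`,
#'       `lambda2`, `R`);}
#'     \item{converged}{whether the tolerance was met before `max_levels`.}
#'   }
#' @examples
#' t <- 1:256
#' x <- 100 + sin(2 * pi * t / 26) * 10 + cos(2 * pi * t / 7) * 2
#' dec <- msvd(x)
#' max(abs(dec$c_L + dec$c_H - x))  # additive to machine precision
#' @export
msvd <- function(x, tol = 1e-4, max_levels = 32L) {
  x <- check_series(x)
  stopifnot(tol > 0, max_levels >= 1L)
  levels <- vector("list", max_levels + 1L)
  R <- numeric(0)
  current <- x
  J <- NA_integer_
  converged <- FALSE

  # compute eagerly one level past the candidate so deltaR_j = R_j / R_{j+1}
  # is defined when level j is tested
  for (j in seq_len(max_levels + 1L)) {
    lv <- msvd_level(current)
    levels[[j]] <- lv
    R[j] <- lv$R
    if (j >= 2L) {
      dR <- R[j - 1L] / R[j]
      if (abs(dR - 1) <= tol) {
        J <- j - 1L
        converged <- TRUE
        break
      }
    }
    if (j == max_levels + 1L) break
    current <- lv$c_low
  }
  if (!converged) {
    J <- max_levels
    warning(sprintf(
      "singular spectrum rate did not reach 1 +/- %g within %d levels",
      tol, max_levels), call. = FALSE)
  }
  levels <- levels[seq_len(min(J + 1L, length(R)))]
  delta_R <- if (length(R) >= 2L) R[-length(R)] / R[-1L] else numeric(0)

  c_H <- Reduce(`+`, lapply(levels[seq_len(J)], `[[`, "c_high"))
  c_L <- levels[[J]]$c_low
  structure(list(c_L = c_L, c_H = c_H, J = J, R = R, delta_R = delta_R,
                 levels = levels, converged = converged, tol = tol,
                 n = length(x)),
            class = "msvd")
}

#' @export
print.msvd <- function(x, ...) {
  cat(sprintf("Multilevel Hankel-SVD decomposition (N = %d)\n", x$n))
  cat(sprintf("  depth J = %d (%s, tol = %g on |deltaR - 1|)\n", x$J,
              if (x$converged) "converged" else "max depth reached", x$tol))
  if (length(x$delta_R) > 0) {
    k <- length(x$delta_R)
    cat(sprintf("  deltaR at stopping level: %.6f\n", x$delta_R[k]))
  }
  cat(sprintf("  level-1 energy ratio R1 = %.4f\n", x$R[1L]))
  invisible(x)
}
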