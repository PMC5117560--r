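# Exact linear algebra over stoichiometric matrices.
#
# Conservation vectors are integer objects, so rank decisions must not depend
# on a floating-point tolerance. Rank is computed over the rationals by
# Gaussian elimination modulo a set of primes just below 2^26: the rank modulo
# any prime is a lower bound on the rational rank, with equality unless the
# prime divides a fixed nonzero maximal minor. Taking the maximum over enough
# primes that their product exceeds the Hadamard bound on any minor therefore
# gives the exact rational rank, while every intermediate product stays below
# 2^53 and is exact in double arithmetic.

# primes just below 2^26; p^2 < 2^53 so modular products are exact doubles
.MOD_PRIMES <- c(
  67108859, 67108837, 67108819, 67108777, 67108763, 67108757,
  67108693, 67108669, 67108667, 67108661, 67108649, 67108633
)

# continued-fraction rationalisation of a double, denominator capped
.as_rational <- function(x, max_den = 1e6, tol = 1e-9) {
  if (!is.finite(x)) stop("non-finite matrix entry")
  sign <- if (x < 0) -1 else 1
  x <- abs(x)
  h0 <- 0; h1 <- 1; k0 <- 1; k1 <- 0
  r <- x
  repeat {
    a <- floor(r)
    h <- a * h1 + h0; k <- a * k1 + k0
    if (k > max_den) break
    h0 <- h1; h1 <- h; k0 <- k1; k1 <- k
    if (abs(x - h1 / k1) < tol * max(1, x)) break
    if (r - a < 1e-12) break
    r <- 1 / (r - a)
  }
  if (abs(x - h1 / k1) > tol * max(1, x)) {
    stop("matrix entry ", sign * x, " is not a small rational; exact rank undefined")
  }
  c(num = sign * h1, den = k1)
}

# scale each column by the lcm of its entry denominators (rank-invariant)
.integerise_columns <- function(M) {
  M <- as.matrix(M)
  if (length(M) == 0) return(M)
  if (all(M == round(M))) return(round(M))
  gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)
  for (j in seq_len(ncol(M))) {
    rats <- vapply(M[, j], .as_rational, numeric(2))
    dens <- rats["den", ]
    l <- 1
    for (d in dens) l <- l * d / gcd2(l, d)
    M[, j] <- round(rats["num", ] * (l / dens))
  }
  M
}

.powmod <- function(a, e, p) {
  r <- 1; a <- a %% p
  while (e > 0) {
    if (e %% 2 == 1) r <- (r * a) %% p
    a <- (a * a) %% p
    e <- e %/% 2
  }
  r
}

.rank_mod_p <- function(M, p) {
  M <- M %% p
  m <- nrow(M); n <- ncol(M)
  rank <- 0; row <- 1
  for (col in seq_len(n)) {
    if (row > m) break
    piv <- which(M[row:m, col] != 0)
    if (length(piv) == 0) next
    piv <- piv[1] + row - 1
    if (piv != row) M[c(row, piv), ] <- M[c(piv, row), ]
    inv <- .powmod(M[row, col], p - 2, p)
    M[row, ] <- (M[row, ] * inv) %% p
    for (i in seq_len(m)) {
      if (i != row && M[i, col] != 0) {
        M[i, ] <- (M[i, ] - M[i, col] * M[row, ]) %% p
      }
    }
    rank <- rank + 1; row <- row + 1
  }
  rank
}

#' Exact rank of an integer (or small-rational) matrix
#'
#' Computes the rank of the rational row space by exact modular elimination,
#' with no floating-point tolerance. Entries must be integers or small
#' rationals (e.g. fractional exchange coefficients); each column is scaled to
#' integers first, which leaves the rank unchanged.
#'
#' @param M a numeric matrix with finite entries.
#' @return the rank as a nonnegative integer.
#' @examples
#' exact_rank(diag(3))
#' exact_rank(matrix(0, 2, 2))
#' @export
exact_rank <- function(M) {
  M <- as.matrix(M)
  if (length(M) == 0 || all(M == 0)) return(0L)
  M <- .integerise_columns(M)
  if (max(abs(M)) >= 2^53) stop("entries too large for exact arithmetic")
  # Hadamard bound on any minor (log scale), to choose enough primes
  log_norms <- log(pmax(1, sqrt(colSums(M^2))))
  k_minor <- min(nrow(M), ncol(M))
  log_bound <- sum(sort(log_norms, decreasing = TRUE)[seq_len(k_minor)])
  n_primes <- min(length(.MOD_PRIMES),
                  max(2L, ceiling(log_bound / log(min(.MOD_PRIMES))) + 1L))
  max(vapply(.MOD_PRIMES[seq_len(n_primes)],
             function(p) .rank_mod_p(M, p), numeric(1)))
}

#' Dimension of the left null space of a matrix
#'
#' For an internal stoichiometric matrix `N` with `m` metabolite rows this is
#' the number of linearly independent conservation vectors of the closed
#' network, `m - exact_rank(N)`.
#'
#' @param M a numeric matrix (rows are metabolites).
#' @return `nrow(M) - exact_rank(M)`.
#' @export
left_nullspace_dim <- function(M) {
  M <- as.matrix(M)
  nrow(M) - exact_rank(M)
}

#' Test whether a vector is a conservation vector of N
#'
#' True iff `t(N) %*% v` is exactly zero under integer arithmetic.
#'
#' @param N internal stoichiometric matrix, metabolites in rows.
#' @param v integer vector of length `nrow(N)`.
#' @return logical scalar.
#' @export
is_conservation_vector <- function(N, v) {
  N <- as.matrix(N)
  if (length(v) != nrow(N)) stop("dimension mismatch: length(v) != nrow(N)")
  all(crossprod(N, v) == 0)
}
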