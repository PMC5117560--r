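# Downstream uses of moiety vectors and graphs: moiety subnetworks (row
# scaling of S by a moiety vector) and atom- versus moiety-resolution
# isotopomer counting for stable-isotope flux analysis.

#' Moiety subnetwork of a stoichiometric matrix
#'
#' `S_k = diag(l_k) %*% S`: the subnetwork restricted to one moiety's flow.
#' Rows with `l_k[i] == 0` are zero. The result reports whether the pruned
#' internal part is a graph (every nonzero internal column connects exactly
#' one substrate metabolite to one product metabolite, magnitudes ignored) or
#' a hypergraph.
#'
#' @param S total stoichiometric matrix (m x n), or a `metabolic_network`.
#' @param l_k nonnegative integer vector of length m.
#' @param u number of internal reactions (first `u` columns); taken from the
#'   network when `S` is a `metabolic_network`.
#' @return a `moiety_subnetwork`: `S_k`, `active_rows`, `active_cols`,
#'   `is_graph`.
#' @export
moiety_subnetwork <- function(S, l_k, u = NULL) {
  if (inherits(S, "metabolic_network")) {
    u <- S$u
    S <- S$S
  }
  S <- as.matrix(S)
  if (length(l_k) != nrow(S)) stop("dimension mismatch")
  if (is.null(u)) u <- ncol(S)
  S_k <- diag(as.numeric(l_k), nrow = nrow(S)) %*% S
  dimnames(S_k) <- dimnames(S)
  active_cols <- which(colSums(S_k != 0) > 0)
  internal_active <- intersect(active_cols, seq_len(u))
  is_graph <- all(vapply(internal_active, function(j) {
    sum(S_k[, j] < 0) == 1 && sum(S_k[, j] > 0) == 1
  }, logical(1)))
  structure(
    list(S_k = S_k, u = u,
         active_rows = which(rowSums(S_k != 0) > 0),
         active_cols = active_cols, is_graph = is_graph),
    class = "moiety_subnetwork"
  )
}

#' Per-reaction moiety balance of a subnetwork
#'
#' For each internal column `j`, the signed sum of `S_k[, j]` (equivalently
#' `l_k' N[, j]`); all sums are zero iff the scaling vector is a conservation
#' vector of `N`. Only moiety vectors are guaranteed to yield mass-balanced
#' subnetworks.
#'
#' @param sub a `moiety_subnetwork`.
#' @return named numeric vector over internal reactions.
#' @export
subnetwork_mass_balance <- function(sub) {
  stopifnot(inherits(sub, "moiety_subnetwork"))
  cols <- seq_len(sub$u)
  stats::setNames(colSums(sub$S_k[, cols, drop = FALSE]),
                  colnames(sub$S_k)[cols])
}

# --- exact big-integer counters --------------------------------------------
# Isotopomer totals overflow doubles for genome-scale networks (~1e23), so
# counts are kept as little-endian base-1e7 digit vectors.

.BIGBASE <- 1e7

.big <- function(n) {
  stopifnot(n >= 0, n == round(n), n < 2^53)
  d <- numeric(0)
  repeat {
    d <- c(d, n %% .BIGBASE)
    n <- n %/% .BIGBASE
    if (n == 0) break
  }
  structure(list(d = d), class = "bigcount")
}

.big_add <- function(a, b) {
  la <- length(a$d); lb <- length(b$d)
  n <- max(la, lb)
  d <- c(a$d, numeric(n - la)) + c(b$d, numeric(n - lb))
  carry <- 0
  for (i in seq_len(n)) {
    d[i] <- d[i] + carry
    carry <- d[i] %/% .BIGBASE
    d[i] <- d[i] %% .BIGBASE
  }
  while (carry > 0) {
    d <- c(d, carry %% .BIGBASE)
    carry <- carry %/% .BIGBASE
  }
  structure(list(d = d), class = "bigcount")
}

.big_pow2 <- function(n) {
  x <- .big(1)
  while (n > 0) {
    take <- min(n, 25)   # digit * 2^25 + carry stays well below 2^53
    mult <- 2^take
    d <- x$d * mult
    carry <- 0
    for (i in seq_along(d)) {
      d[i] <- d[i] + carry
      carry <- d[i] %/% .BIGBASE
      d[i] <- d[i] %% .BIGBASE
    }
    while (carry > 0) {
      d <- c(d, carry %% .BIGBASE)
      carry <- carry %/% .BIGBASE
    }
    x <- structure(list(d = d), class = "bigcount")
    n <- n - take
  }
  x
}

.big_cmp <- function(a, b) {
  da <- a$d; db <- b$d
  while (length(da) && da[length(da)] == 0) da <- da[-length(da)]
  while (length(db) && db[length(db)] == 0) db <- db[-length(db)]
  if (length(da) != length(db)) return(sign(length(da) - length(db)))
  for (i in rev(seq_along(da))) {
    if (da[i] != db[i]) return(sign(da[i] - db[i]))
  }
  0
}

#' @exportS3Method base::format
format.bigcount <- function(x, ...) {
  d <- rev(x$d)
  paste0(sub("^0+(?=.)", "", paste0(sprintf("%07.0f", d), collapse = ""),
             perl = TRUE))
}

#' @exportS3Method base::print
print.bigcount <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @exportS3Method base::as.numeric
as.numeric.bigcount <- function(x, ...) {
  sum(x$d * .BIGBASE^(seq_along(x$d) - 1))
}

#' Atom-resolution isotopomer count for one element
#'
#' Sums `2^(atom count of the element)` over the metabolites that contain at
#' least one atom of the element. Counts are exact big integers (genome-scale
#' totals exceed the integer range of doubles).
#'
#' @param net a `metabolic_network` with formulas.
#' @param element element symbol, e.g. `"C"`.
#' @return a `bigcount`; use `as.numeric()` for small values.
#' @export
atom_isotopomer_count <- function(net, element) {
  stopifnot(inherits(net, "metabolic_network"))
  .require_formulas(net)
  counts <- vapply(net$formulas[net$metabolites$id], function(f) {
    if (!is.null(f) && element %in% names(f)) f[[element]] else 0L
  }, numeric(1))
  total <- .big(0)
  for (n in counts[counts > 0]) total <- .big_add(total, .big_pow2(n))
  total
}

#' Moiety-resolution isotopomer count for one element
#'
#' A moiety is labelled if any of its atoms is labelled, so a metabolite with
#' `n` element-bearing moiety instances has `2^n` moiety isotopomers. Sums
#' over metabolites containing at least one such instance, counting
#' multiplicity from the moiety matrix.
#'
#' @param L moiety matrix (m x r).
#' @param compositions list of named element-count vectors, one per column of
#'   `L`.
#' @param element element symbol.
#' @return list with `isotopomers` (a `bigcount`), `n_instances` (total
#'   element-bearing moiety instances over all metabolites).
#' @export
moiety_isotopomer_count <- function(L, compositions, element) {
  L <- as.matrix(L)
  bearing <- vapply(compositions, function(comp) {
    element %in% names(comp) && comp[[element]] > 0
  }, logical(1))
  inst <- rowSums(L[, bearing, drop = FALSE])
  total <- .big(0)
  for (n in inst[inst > 0]) total <- .big_add(total, .big_pow2(n))
  list(isotopomers = total, n_instances = sum(inst))
}
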