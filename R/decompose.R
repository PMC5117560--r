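# Decomposition of composite conservation vectors. A nonnegative integer
# conservation vector l of N is decomposable if it splits as l = x + y with
# both parts nonzero nonnegative integer conservation vectors. The split is
# found by an exact integer program:
#
#   min 1'x  s.t.  N'x = 0,  x integer,  0 <= x <= l,  1 <= 1'x <= 1'l - 1
#
# solved by bundled branch-and-bound over the finite box 0 <= x <= l
# (variables are bounded by l, so the search space is finite and the solver
# is exact). Among minimum-objective solutions the lexicographically smallest
# x in metabolite order is returned, so output is deterministic.

# branch-and-bound: assign x[i] in metabolite order, ascending values, with
# two prunings: (1) the partial residual r = N'x restricted to assigned rows
# must remain reconcilable by the remaining rows' min/max contributions;
# (2) the partial objective must not exceed the best known (strictly), which
# preserves the first-found = lex-smallest optimum.
.bnb_min_split <- function(N, l) {
  N <- as.matrix(N)
  m <- nrow(N); u <- ncol(N)
  total <- sum(l)
  if (total < 2) return(NULL)  # no nonzero proper split can exist
  # remaining min/max contribution to each reaction residual from rows > i
  rem_min <- matrix(0, m + 1, u); rem_max <- matrix(0, m + 1, u)
  for (i in m:1) {
    rem_min[i, ] <- rem_min[i + 1, ] + pmin(0, N[i, ] * l[i])
    rem_max[i, ] <- rem_max[i + 1, ] + pmax(0, N[i, ] * l[i])
  }
  rem_sum <- rev(cumsum(rev(l)))          # sum of l[i..m]
  rem_sum <- c(rem_sum, 0)
  best <- new.env(parent = emptyenv())
  best$sum <- Inf; best$x <- NULL
  x <- numeric(m)
  recurse <- function(i, r, s) {
    # s = partial objective, r = partial residual over reactions
    if (s > best$sum) return()
    if (s > total - 1) return()
    if (i > m) {
      if (all(r == 0) && s >= 1 && s < best$sum) {
        best$sum <- s; best$x <- x
      }
      return()
    }
    # objective lower bound: must still be able to reach >= 1
    if (s + rem_sum[i] < 1) return()
    for (v in 0:l[i]) {
      r2 <- r + v * N[i, ]
      if (all(r2 + rem_min[i + 1, ] <= 0) &&
          all(r2 + rem_max[i + 1, ] >= 0)) {
        x[i] <<- v
        recurse(i + 1, r2, s + v)
      }
    }
    x[i] <<- 0
  }
  recurse(1, numeric(u), 0)
  if (is.null(best$x)) NULL else best$x
}

#' Decompose a conservation vector into two nonzero conservation parts
#'
#' Solves the integer program above. On success returns `x` (objective-
#' minimal, lexicographic tie-break) and `y = l - x`, both nonzero
#' nonnegative integer conservation vectors of `N`; if no split exists the
#' vector is certified nondecomposable.
#'
#' @param N internal stoichiometric matrix (m x u).
#' @param l nonnegative integer conservation vector of `N`.
#' @return `list(x = , y = )` or `NULL` (infeasible: `l` is nondecomposable).
#' @export
decompose_vector <- function(N, l) {
  N <- as.matrix(N)
  l <- as.numeric(l)
  if (length(l) != nrow(N)) stop("dimension mismatch")
  if (any(l < 0) || any(l != round(l))) {
    stop("l must be a nonnegative integer vector")
  }
  if (!is_conservation_vector(N, l)) {
    stop("l is not a conservation vector of N")
  }
  x <- .bnb_min_split(N, l)
  if (is.null(x)) return(NULL)
  nm <- rownames(N)
  names(x) <- nm
  list(x = x, y = stats::setNames(l - x, nm))
}

#' Brute-force nondecomposability oracle
#'
#' Exhaustively enumerates every integer vector `0 <= x <= l` componentwise
#' (excluding `0` and `l`) and tests `N'x == 0`. Independent of the
#' branch-and-bound path; used to certify its answers on small vectors. Any
#' decomposition into positive integer multiples of two conservation vectors
#' yields such a unit split, so enumerating splits is equivalent for
#' certification.
#'
#' @param N internal stoichiometric matrix.
#' @param l nonnegative integer conservation vector.
#' @param cap maximum `sum(l)` accepted for tractability (default 64).
#' @return list with `nondecomposable` (logical) and, when decomposable, a
#'   `witness` list `(x, y)`.
#' @export
brute_force_nondecomposable <- function(N, l, cap = 64) {
  N <- as.matrix(N)
  l <- as.numeric(l)
  if (sum(l) > cap) stop("sum(l) exceeds cap (", cap, ")")
  m <- length(l)
  x <- numeric(m)
  repeat {
    # mixed-radix increment over the box
    i <- 1
    while (i <= m) {
      if (x[i] < l[i]) { x[i] <- x[i] + 1; break }
      x[i] <- 0; i <- i + 1
    }
    if (i > m) break  # wrapped: enumeration done
    if (sum(x) == 0 || all(x == l)) next
    if (all(crossprod(N, x) == 0)) {
      nm <- rownames(N)
      return(list(nondecomposable = FALSE,
                  witness = list(x = stats::setNames(x, nm),
                                 y = stats::setNames(l - x, nm))))
    }
  }
  list(nondecomposable = TRUE, witness = NULL)
}

#' Fully decompose a matrix of conservation vectors
#'
#' Iterates the split until every column is certified nondecomposable:
#' initialise the working set with the columns of `L`; repeatedly replace any
#' decomposable column by its two parts; terminate when the program is
#' infeasible for every remaining column (each split strictly reduces the
#' atom total of at least one part, so the iteration terminates). Identical
#' output columns are deduplicated in `D`; provenance keeps multiplicity.
#'
#' @param N internal stoichiometric matrix.
#' @param L matrix whose columns are nonnegative integer conservation
#'   vectors of `N`.
#' @return list with `D` (m x t matrix of distinct nondecomposable columns),
#'   `provenance` (per input column, a data frame tree of splits), and
#'   `leaves` (the full multiset of output columns before deduplication).
#' @export
fully_decompose <- function(N, L) {
  N <- as.matrix(N)
  L <- as.matrix(L)
  for (k in seq_len(ncol(L))) {
    if (!is_conservation_vector(N, L[, k])) {
      stop("column ", k, " is not a conservation vector of N")
    }
  }
  prov <- list()
  leaves <- list()
  for (k in seq_len(ncol(L))) {
    events <- list()
    # queue of vectors still to certify, all descended from input column k
    queue <- list(L[, k])
    while (length(queue)) {
      l <- queue[[1]]; queue <- queue[-1]
      split <- decompose_vector(N, l)
      if (is.null(split)) {
        leaves[[length(leaves) + 1]] <- l
        events[[length(events) + 1]] <-
          data.frame(vector = paste(l, collapse = ","), action = "kept")
      } else {
        queue <- c(queue, list(split$x), list(split$y))
        events[[length(events) + 1]] <-
          data.frame(vector = paste(l, collapse = ","), action = "split")
      }
    }
    prov[[k]] <- do.call(rbind, events)
  }
  leaf_mat <- do.call(cbind, leaves)
  rownames(leaf_mat) <- rownames(L)
  keys <- apply(leaf_mat, 2, paste, collapse = ",")
  D <- leaf_mat[, !duplicated(keys), drop = FALSE]
  colnames(D) <- sprintf("D%02d", seq_len(ncol(D)))
  names(prov) <- colnames(L)
  list(D = D, provenance = prov, leaves = leaf_mat)
}

#' Decompose a general conservation matrix (elemental matrix, electron vector)
#'
#' Applies [fully_decompose()] after checking the conservation precondition
#' columnwise; supports nonnegative integer factorisation of the elemental
#' matrix and of the electron vector of a balanced network.
#'
#' @param N internal stoichiometric matrix.
#' @param M nonnegative integer matrix (or vector) whose columns are
#'   conservation vectors of `N`.
#' @return as [fully_decompose()].
#' @export
decompose_matrix <- function(N, M) {
  M <- as.matrix(M)
  for (k in seq_len(ncol(M))) {
    if (!is_conservation_vector(N, M[, k])) {
      stop("column ", k, " of M is not conserved by N ",
           "(is the network elementally balanced?)")
    }
  }
  fully_decompose(N, M)
}
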