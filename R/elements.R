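# Elemental bookkeeping: the metabolite-by-element matrix, electron counts and
# per-reaction balance reports. Columns of the elemental matrix of a balanced
# network are themselves conservation vectors of N.

# atomic numbers for the elements that occur in metabolic formulas
.ATOMIC_NUMBER <- c(
  H = 1, He = 2, Li = 3, Be = 4, B = 5, C = 6, N = 7, O = 8, F = 9, Ne = 10,
  Na = 11, Mg = 12, Al = 13, Si = 14, P = 15, S = 16, Cl = 17, Ar = 18,
  K = 19, Ca = 20, Mn = 25, Fe = 26, Co = 27, Ni = 28, Cu = 29, Zn = 30,
  Se = 34, Br = 35, Mo = 42, I = 53, W = 74
)

# fixed element order for reproducible output: C, H, O, N, then alphabetical
.element_order <- function(elements) {
  lead <- c("C", "H", "O", "N")
  c(intersect(lead, elements), sort(setdiff(elements, lead)))
}

# Hill convention for composition strings: C, H, then alphabetical
.hill_order <- function(elements) {
  lead <- c("C", "H")
  c(intersect(lead, elements), sort(setdiff(elements, lead)))
}

.require_formulas <- function(net) {
  missing <- setdiff(net$metabolites$id, names(net$formulas))
  if (is.null(net$formulas) || length(missing)) {
    stop("missing formula for metabolite(s): ",
         paste(if (is.null(net$formulas)) net$metabolites$id else missing,
               collapse = ", "))
  }
}

#' Elemental matrix of a metabolic network
#'
#' Entry `(i, element)` is the atom count of that element in metabolite `i`.
#' Column order is C, H, O, N, then remaining elements alphabetically.
#' A metabolite with an empty formula (a massless placeholder such as a
#' photon) yields an all-zero row; such rows are flagged in the balance
#' report, not here.
#'
#' @param net a `metabolic_network` whose metabolites all carry formulas.
#' @return an m x (#elements) nonnegative integer matrix.
#' @export
elemental_matrix <- function(net) {
  stopifnot(inherits(net, "metabolic_network"))
  .require_formulas(net)
  elements <- .element_order(unique(unlist(lapply(net$formulas, names))))
  E <- matrix(0L, nrow(net$metabolites), length(elements),
              dimnames = list(net$metabolites$id, elements))
  for (id in net$metabolites$id) {
    f <- net$formulas[[id]]
    if (length(f)) E[id, names(f)] <- as.integer(f)
  }
  E
}

#' Electron count vector of a metabolic network
#'
#' `e_i` is the total number of electrons in metabolite `i`: the sum over its
#' formula of atomic number times atom count, minus its charge.
#'
#' @param net a `metabolic_network` with formulas and charges for every
#'   metabolite.
#' @return a length-m named nonnegative integer vector.
#' @export
electron_vector <- function(net) {
  stopifnot(inherits(net, "metabolic_network"))
  .require_formulas(net)
  if (any(is.na(net$metabolites$charge))) {
    stop("electron counts require a charge for every metabolite")
  }
  e <- vapply(seq_len(nrow(net$metabolites)), function(i) {
    id <- net$metabolites$id[i]
    f <- net$formulas[[id]]
    unknown <- setdiff(names(f), names(.ATOMIC_NUMBER))
    if (length(unknown)) stop("unknown element symbol: ",
                              paste(unknown, collapse = ", "))
    sum(.ATOMIC_NUMBER[names(f)] * f) - net$metabolites$charge[i]
  }, numeric(1))
  if (any(e < 0)) {
    stop("negative electron count for: ",
         paste(net$metabolites$id[e < 0], collapse = ", "),
         " (check formula/charge)")
  }
  names(e) <- net$metabolites$id
  e
}

#' Elemental and charge balance report for internal reactions
#'
#' For each internal reaction the signed sum of coefficient times atom count
#' is reported per element, plus the signed charge sum. A reaction is
#' balanced iff all sums are zero. Exchange reactions do not conserve mass or
#' charge and are exempt. Imbalance is reported, not raised.
#'
#' @param net a `metabolic_network` with formulas (and charges, if charge
#'   balance is wanted) present.
#' @return a data frame with one row per internal reaction: `reaction_id`,
#'   one column per element, `charge`, and logical `balanced`; attribute
#'   `massless` lists metabolites with empty formulas.
#' @export
check_elemental_balance <- function(net) {
  stopifnot(inherits(net, "metabolic_network"))
  .require_formulas(net)
  E <- elemental_matrix(net)
  massless <- rownames(E)[rowSums(E) == 0]
  internal <- net$reactions$id[net$reactions$kind == "internal"]
  charge <- net$metabolites$charge
  charge[is.na(charge)] <- 0
  rows <- lapply(internal, function(rid) {
    coef <- net$S[, rid]
    sums <- as.numeric(crossprod(E, coef))
    names(sums) <- colnames(E)
    csum <- sum(coef * charge)
    data.frame(reaction_id = rid, t(sums), charge = csum,
               balanced = all(sums == 0) && csum == 0,
               stringsAsFactors = FALSE, check.names = FALSE)
  })
  report <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(reaction_id = character(0), charge = numeric(0),
               balanced = logical(0))
  }
  rownames(report) <- NULL
  attr(report, "massless") <- massless
  report
}
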