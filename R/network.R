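# Data model for metabolic networks: metabolites with element-count formulas
# and charges, reactions split into internal (mass balanced) and exchange
# (boundary) columns, and the total stoichiometric matrix S = [N, B].

#' Construct a metabolic network
#'
#' @param metabolites data frame with columns `id`, `name` (optional) and
#'   `charge` (optional, integer elementary charges). Row order defines the
#'   row order of the stoichiometric matrix.
#' @param formulas named list, one entry per metabolite id, each a named
#'   nonnegative integer vector of element counts (e.g. `c(C = 9, H = 11)`).
#'   May be `NULL` for networks used without balance checking.
#' @param reactions data frame with columns `id` and `kind`
#'   (`"internal"` or `"exchange"`). Column order defines reaction order.
#' @param stoichiometry named list, one entry per reaction id, each a named
#'   numeric vector over metabolite ids: negative for substrates, positive
#'   for products in the designated forward direction.
#' @return an object of class `metabolic_network` with elements `metabolites`,
#'   `formulas`, `reactions`, `S` (m x n matrix), `u` (number of internal
#'   reactions) and `permutation` (the column permutation applied, if any, to
#'   put internal reactions before exchange reactions).
#' @export
metabolic_network <- function(metabolites, reactions, stoichiometry,
                              formulas = NULL) {
  metabolites <- as.data.frame(metabolites)
  reactions <- as.data.frame(reactions)
  if (nrow(reactions) == 0) stop("empty reaction list")
  if (nrow(metabolites) == 0) stop("empty metabolite list")
  if (anyDuplicated(metabolites$id)) stop("duplicate metabolite id")
  if (anyDuplicated(reactions$id)) stop("duplicate reaction id")
  if (!all(reactions$kind %in% c("internal", "exchange"))) {
    stop("reaction kind must be 'internal' or 'exchange'")
  }
  if (!setequal(names(stoichiometry), reactions$id) ||
      length(stoichiometry) != nrow(reactions)) {
    stop("stoichiometry must have exactly one entry per reaction id")
  }
  m <- nrow(metabolites)

  # internal-before-exchange column convention, permutation recorded
  ord <- order(match(reactions$kind, c("internal", "exchange")))
  permutation <- if (identical(ord, seq_len(nrow(reactions)))) NULL else ord
  reactions <- reactions[ord, , drop = FALSE]
  rownames(reactions) <- NULL

  S <- matrix(0, m, nrow(reactions),
              dimnames = list(metabolites$id, reactions$id))
  for (rid in reactions$id) {
    coef <- stoichiometry[[rid]]
    if (length(coef) == 0) stop("reaction ", rid, " has empty stoichiometry")
    bad <- setdiff(names(coef), metabolites$id)
    if (length(bad)) {
      stop("reaction ", rid, " references unknown metabolite(s): ",
           paste(bad, collapse = ", "))
    }
    kind <- reactions$kind[reactions$id == rid]
    if (kind == "internal") {
      if (any(coef != round(coef))) {
        stop("internal reaction ", rid, " has non-integer coefficients")
      }
      if (!any(coef < 0) || !any(coef > 0)) {
        stop("internal reaction ", rid,
             " must have at least one substrate and one product")
      }
    }
    S[names(coef), rid] <- coef
  }
  u <- sum(reactions$kind == "internal")

  if (!is.null(formulas)) {
    bad <- setdiff(names(formulas), metabolites$id)
    if (length(bad)) stop("formulas given for unknown metabolite(s): ",
                          paste(bad, collapse = ", "))
    for (f in formulas) {
      if (length(f) && (any(f < 0) || any(f != round(f)))) {
        stop("formula counts must be nonnegative integers")
      }
    }
  }

  structure(
    list(metabolites = metabolites, formulas = formulas,
         reactions = reactions, S = S, u = u, permutation = permutation),
    class = "metabolic_network"
  )
}

#' @exportS3Method base::print
print.metabolic_network <- function(x, ...) {
  cat("<metabolic_network> ", nrow(x$S), " metabolites, ",
      ncol(x$S), " reactions (", x$u, " internal)\n", sep = "")
  invisible(x)
}

#' Split the total stoichiometric matrix into internal and exchange blocks
#'
#' Returns the internal stoichiometric matrix `N` (m x u) and the exchange
#' block `B` (m x (n-u)); their horizontal concatenation reproduces `S`
#' entry for entry.
#'
#' @param net a `metabolic_network`.
#' @return list with elements `N` and `B`.
#' @export
split_matrices <- function(net) {
  stopifnot(inherits(net, "metabolic_network"))
  n <- ncol(net$S)
  list(N = net$S[, seq_len(net$u), drop = FALSE],
       B = net$S[, setdiff(seq_len(n), seq_len(net$u)), drop = FALSE])
}

#' Read a metabolic network from the native JSON dialect or a TSV matrix
#'
#' The JSON dialect is
#' `{"metabolites":[{"id","name","formula":{"C":9,...},"charge"},...],`
#' `"reactions":[{"id","kind":"internal|exchange","stoichiometry":{...}},...]}`.
#' The TSV alternative is a matrix with metabolite-id row labels and
#' reaction-id column labels plus a sidecar file listing internal reaction
#' ids, one per line.
#'
#' @param path path to a `.json` network file or a `.tsv` matrix.
#' @param internal_ids for TSV input, path to the sidecar of internal reaction
#'   ids or a character vector of ids.
#' @return a `metabolic_network`. Row/column order is preserved as given,
#'   except that internal reactions are moved before exchange reactions with
#'   the permutation recorded in the result.
#' @export
load_network <- function(path, internal_ids = NULL) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    mets <- data.frame(
      id = vapply(doc$metabolites, function(m) m$id, character(1)),
      name = vapply(doc$metabolites, function(m) {
        if (is.null(m$name)) NA_character_ else m$name
      }, character(1)),
      charge = vapply(doc$metabolites, function(m) {
        if (is.null(m$charge)) NA_real_ else as.numeric(m$charge)
      }, numeric(1)),
      stringsAsFactors = FALSE
    )
    formulas <- lapply(doc$metabolites, function(m) {
      if (is.null(m$formula)) NULL else unlist(m$formula)
    })
    names(formulas) <- mets$id
    formulas <- formulas[!vapply(formulas, is.null, logical(1))]
    if (length(formulas) == 0) formulas <- NULL
    if (length(doc$reactions) == 0) stop("empty reaction list")
    rxns <- data.frame(
      id = vapply(doc$reactions, function(r) r$id, character(1)),
      kind = vapply(doc$reactions, function(r) r$kind, character(1)),
      stringsAsFactors = FALSE
    )
    stoich <- lapply(doc$reactions, function(r) unlist(r$stoichiometry))
    names(stoich) <- rxns$id
    metabolic_network(mets, rxns, stoich, formulas)
  } else {
    mat <- utils::read.delim(path, row.names = 1, check.names = FALSE)
    mat <- as.matrix(mat)
    if (is.character(internal_ids) && length(internal_ids) == 1 &&
        file.exists(internal_ids)) {
      internal_ids <- readLines(internal_ids)
      internal_ids <- internal_ids[nzchar(internal_ids)]
    }
    if (is.null(internal_ids)) stop("TSV input requires internal reaction ids")
    mets <- data.frame(id = rownames(mat), name = NA_character_,
                       charge = NA_real_, stringsAsFactors = FALSE)
    rxns <- data.frame(
      id = colnames(mat),
      kind = ifelse(colnames(mat) %in% internal_ids, "internal", "exchange"),
      stringsAsFactors = FALSE
    )
    stoich <- lapply(colnames(mat), function(j) {
      v <- mat[, j]
      v[v != 0]
    })
    names(stoich) <- colnames(mat)
    metabolic_network(mets, rxns, stoich)
  }
}
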