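# Atom transition network assembly. Nodes are individual metabolite atoms
# (one node per atom of the network, shared by every reaction that touches
# it); directed edges are substrate-to-product atom transitions of internal
# reactions, with direction fixed by each reaction's designated forward
# direction.

#' Build an atom transition network
#'
#' Creates one node per (metabolite, element, index) over metabolites that
#' possess atoms of the included element(s), and one directed transition per
#' mapping row surviving the element filter. Transitions from different
#' instances of a repeated metabolite within one reaction attach to the same
#' nodes: nodes are per metabolite atom, not per instance. The incidence
#' matrix `A` has one column per transition with -1 at the source row and +1
#' at the target row. Node order is deterministic: metabolites in network
#' order, elements in the fixed element order (C, H, O, N, then alphabetical),
#' index ascending; transitions follow reaction order then table order.
#'
#' @param net a `metabolic_network` with formulas for every metabolite.
#' @param maps an `atom_mapping_set` covering every internal reaction.
#' @param element_filter a single element symbol, or `"all"`.
#' @return an object of class `atom_transition_network` with elements
#'   `nodes` (data frame: metabolite, element, index), `transitions`
#'   (data frame: reaction_id, source, target row positions), `A` (sparse
#'   incidence matrix in \{-1,0,1\}^(p x q)), `element_filter`, `net`, and a
#'   `report` listing p, q and any self-transitions (atoms of a metabolite
#'   written on both sides), which are retained in `A` as flagged zero
#'   columns and dropped from the simple graph.
#' @export
build_atn <- function(net, maps, element_filter = "all") {
  stopifnot(inherits(net, "metabolic_network"),
            inherits(maps, "atom_mapping_set"))
  .require_formulas(net)
  internal <- net$reactions$id[net$reactions$kind == "internal"]
  missing <- setdiff(internal, names(maps))
  if (length(missing)) {
    stop("internal reaction(s) missing from atom mappings: ",
         paste(missing, collapse = ", "))
  }

  # node table: every atom of every included element, in canonical order
  node_rows <- list()
  for (id in net$metabolites$id) {
    f <- net$formulas[[id]]
    if (length(f) == 0) next  # massless placeholder: excluded from the ATN
    elements <- .element_order(names(f)[f > 0])
    if (!identical(element_filter, "all")) {
      elements <- intersect(elements, element_filter)
    }
    for (e in elements) {
      node_rows[[length(node_rows) + 1]] <-
        data.frame(metabolite = id, element = e, index = seq_len(f[[e]]),
                   stringsAsFactors = FALSE)
    }
  }
  nodes <- if (length(node_rows)) do.call(rbind, node_rows) else {
    data.frame(metabolite = character(0), element = character(0),
               index = integer(0))
  }
  rownames(nodes) <- NULL
  node_key <- paste(nodes$metabolite, nodes$element, nodes$index)
  node_pos <- stats::setNames(seq_along(node_key), node_key)

  trans_rows <- list()
  for (rid in internal) {
    tab <- maps[[rid]]
    if (!identical(element_filter, "all")) {
      tab <- tab[tab$element %in% element_filter, , drop = FALSE]
    }
    coef <- net$S[, rid]
    # completeness: per element, transitions must cover every substrate copy
    elems <- if (identical(element_filter, "all")) {
      unique(unlist(lapply(net$formulas[names(coef)[coef != 0]], names)))
    } else element_filter
    for (e in elems) {
      expect <- sum(vapply(names(coef)[coef < 0], function(id) {
        f <- net$formulas[[id]]
        abs(coef[[id]]) * if (e %in% names(f)) f[[e]] else 0
      }, numeric(1)))
      got <- sum(tab$element == e)
      if (got != expect) {
        stop("reaction ", rid, ": ", got, " transition(s) for element ", e,
             " but stoichiometry implies ", expect)
      }
    }
    if (nrow(tab) == 0) next
    skey <- paste(tab$sub_met, tab$element, tab$sub_index)
    pkey <- paste(tab$prod_met, tab$element, tab$prod_index)
    bad <- c(skey[!skey %in% node_key], pkey[!pkey %in% node_key])
    if (length(bad)) {
      stop("reaction ", rid, ": atom index exceeds formula count for ",
           paste(unique(bad), collapse = "; "))
    }
    trans_rows[[length(trans_rows) + 1]] <- data.frame(
      reaction_id = rid, source = unname(node_pos[skey]),
      target = unname(node_pos[pkey]), stringsAsFactors = FALSE
    )
  }
  transitions <- if (length(trans_rows)) do.call(rbind, trans_rows) else {
    data.frame(reaction_id = character(0), source = integer(0),
               target = integer(0))
  }
  rownames(transitions) <- NULL

  p <- nrow(nodes); q <- nrow(transitions)
  self <- transitions$source == transitions$target
  A <- Matrix::sparseMatrix(
    i = c(transitions$source[!self], transitions$target[!self]),
    j = rep(which(!self), 2),
    x = rep(c(-1, 1), each = sum(!self)),
    dims = c(p, q)
  )
  structure(
    list(nodes = nodes, transitions = transitions, A = A,
         element_filter = element_filter, net = net,
         report = list(p = p, q = q, self_transitions = which(self))),
    class = "atom_transition_network"
  )
}

#' @exportS3Method base::print
print.atom_transition_network <- function(x, ...) {
  cat("<atom_transition_network> p = ", x$report$p, " atoms, q = ",
      x$report$q, " transitions (element filter: ", x$element_filter,
      ")\n", sep = "")
  invisible(x)
}

#' Undirected simple graph underlying an atom transition network
#'
#' Parallel transitions collapse to a single undirected edge and
#' self-transitions are dropped; connectivity analyses run on this graph.
#'
#' @param atn an `atom_transition_network`.
#' @return an undirected simple `igraph` graph over the ATN's nodes.
#' @export
underlying_simple_graph <- function(atn) {
  stopifnot(inherits(atn, "atom_transition_network"))
  tr <- atn$transitions
  tr <- tr[tr$source != tr$target, , drop = FALSE]
  g <- igraph::graph_from_edgelist(cbind(tr$source, tr$target),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nrow(atn$nodes) - igraph::vcount(g)))
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}
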