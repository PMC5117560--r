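# Conserved moiety identification: connected components of the atom
# transition network, atom conservation vectors, isomorphism classes, merged
# moiety graphs, the moiety matrix, classification and chemical composition.
#
# A conserved moiety is a maximal set of equivalent atoms: atoms that follow
# identical paths through the network. Components are isomorphic exactly when
# they contain the same number of atoms from each metabolite (equality of
# atom conservation vectors); a stricter structural audit double-checks that
# shortcut on demand.

#' Connected components of an atom transition network
#'
#' Components of the underlying simple undirected graph (edge directions
#' ignored); they partition the ATN's nodes. Each component carries its
#' incidence matrix `C`, its m x x atom-to-metabolite mapping matrix `M`, and
#' its atom conservation vector `a` (the column sum of `M`: `a[i]` counts the
#' component's atoms in metabolite `i`). Components are ordered by their
#' smallest node position.
#'
#' @param atn an `atom_transition_network`.
#' @return list of `component` objects, each with `nodes` (row positions in
#'   the ATN), `transitions` (data frame subset), `C`, `M`, `a`.
#' @export
connected_components <- function(atn) {
  stopifnot(inherits(atn, "atom_transition_network"))
  g <- underlying_simple_graph(atn)
  memb <- igraph::components(g)$membership
  met_ids <- atn$net$metabolites$id
  m <- length(met_ids)
  # order components by smallest node position
  comp_ids <- unique(memb[order(seq_along(memb))])
  lapply(seq_along(comp_ids), function(h) {
    nodes <- which(memb == comp_ids[h])
    tr_idx <- which(atn$transitions$source %in% nodes |
                    atn$transitions$target %in% nodes)
    tr <- atn$transitions[tr_idx, , drop = FALSE]
    x <- length(nodes); y <- nrow(tr)
    C <- matrix(0L, x, y)
    if (y) {
      src <- match(tr$source, nodes); tgt <- match(tr$target, nodes)
      for (j in seq_len(y)) {
        C[src[j], j] <- C[src[j], j] - 1L
        C[tgt[j], j] <- C[tgt[j], j] + 1L
      }
    }
    M <- matrix(0L, m, x, dimnames = list(met_ids, NULL))
    met_of <- atn$nodes$metabolite[nodes]
    for (g2 in seq_len(x)) M[met_of[g2], g2] <- 1L
    a <- as.integer(rowSums(M))
    names(a) <- met_ids
    structure(list(id = h, nodes = nodes, transitions = tr, C = C, M = M,
                   a = a),
              class = "atn_component")
  })
}

#' Atom conservation vector of a component
#'
#' @param comp a component from [connected_components()].
#' @return named integer vector over metabolites: the number of the
#'   component's atoms in each metabolite.
#' @export
atom_conservation_vector <- function(comp) {
  stopifnot(inherits(comp, "atn_component"))
  comp$a
}

#' Group components into isomorphism classes
#'
#' Two components are isomorphic iff their atom conservation vectors are
#' equal. Classes are ordered by descending atoms per instance (component
#' node count), then lexicographically by the conservation vector, so class
#' order is reproducible.
#'
#' @param components list of components over a common network.
#' @return list of classes, each an integer vector of component indices.
#' @export
group_isomorphic <- function(components) {
  if (length(components) == 0) return(list())
  A <- vapply(components, function(c) c$a,
              integer(length(components[[1]]$a)))
  A <- matrix(A, ncol = length(components))  # columns = components
  key <- apply(A, 2, paste, collapse = ",")
  classes <- split(seq_along(components), factor(key, levels = unique(key)))
  # atoms per instance = number of member components (one atom each)
  sizes <- lengths(classes)
  reps <- vapply(classes, function(k) k[1], integer(1))
  ord <- do.call(order, c(list(-sizes),
                          as.data.frame(t(A[, reps, drop = FALSE]))))
  unname(classes[ord])
}

#' Strict structural isomorphism audit between two components
#'
#' Checks, beyond equality of atom conservation vectors, that a metabolite-
#' identity-preserving vertex bijection can exist: per-metabolite node counts
#' agree and, per reaction, the multisets of (source-metabolite,
#' target-metabolite) transition pairs agree. Used as an audit of the
#' conservation-vector shortcut; chemistry guarantees agreement on real
#' networks but hand-made pathological inputs can violate it.
#'
#' @param c1,c2 components with equal atom conservation vectors.
#' @return logical scalar.
#' @export
verify_isomorphism_strict <- function(c1, c2) {
  stopifnot(inherits(c1, "atn_component"), inherits(c2, "atn_component"))
  if (!identical(c1$a, c2$a)) return(FALSE)
  edge_key <- function(comp) {
    tr <- comp$transitions
    # metabolite of each endpoint, via the mapping matrix
    met_of <- rownames(comp$M)[apply(comp$M, 2, which.max)]
    paste(tr$reaction_id,
          met_of[match(tr$source, comp$nodes)],
          met_of[match(tr$target, comp$nodes)])
  }
  k1 <- sort(edge_key(c1)); k2 <- sort(edge_key(c2))
  identical(k1, k2)
}

#' Merge an isomorphism class into a moiety graph
#'
#' The merged graph equals the common incidence structure of the class (the
#' representative's, after verifying equality): nodes are moiety instances,
#' each annotated with the member atoms mapped to it (one per member
#' component); the moiety vector is the common atom conservation vector.
#'
#' @param components full component list.
#' @param K integer vector of component indices forming one class.
#' @param atn the parent `atom_transition_network` (for atom annotations).
#' @param audit if `TRUE` (default) run [verify_isomorphism_strict()] against
#'   the representative and downgrade failures to a warning naming the
#'   components.
#' @return a `moiety_graph`: `G` (incidence matrix), `instances` (data frame
#'   metabolite/instance), `edges` (reaction-labelled instance pairs),
#'   `atoms` (list per instance of member atom node positions), `l` (moiety
#'   vector), `composition` (named element counts per instance).
#' @export
merge_to_moiety_graph <- function(components, K, atn, audit = TRUE) {
  stopifnot(length(K) >= 1)
  rep_c <- components[[K[1]]]
  if (audit && length(K) > 1) {
    for (h in K[-1]) {
      if (!verify_isomorphism_strict(rep_c, components[[h]])) {
        warning("components ", K[1], " and ", h,
                " share an atom conservation vector but differ structurally")
      }
    }
  }
  met_ids <- atn$net$metabolites$id
  # instances: representative's atoms grouped per metabolite, in node order
  met_of <- rownames(rep_c$M)[apply(rep_c$M, 2, which.max)]
  inst_within <- stats::ave(seq_along(met_of), met_of, FUN = seq_along)
  instances <- data.frame(metabolite = met_of, instance = inst_within,
                          stringsAsFactors = FALSE)
  # atoms per instance: position g of every member component, matched by
  # (metabolite, within-metabolite rank) so equivalent atoms align
  atoms <- vector("list", nrow(instances))
  for (h in K) {
    comp <- components[[h]]
    met_h <- rownames(comp$M)[apply(comp$M, 2, which.max)]
    rank_h <- stats::ave(seq_along(met_h), met_h, FUN = seq_along)
    pos <- match(paste(met_h, rank_h),
                 paste(instances$metabolite, instances$instance))
    for (g in seq_along(pos)) {
      atoms[[pos[g]]] <- c(atoms[[pos[g]]], comp$nodes[g])
    }
  }
  tr <- rep_c$transitions
  edges <- data.frame(
    reaction_id = tr$reaction_id,
    from = match(tr$source, rep_c$nodes),
    to = match(tr$target, rep_c$nodes),
    stringsAsFactors = FALSE
  )
  l <- rep_c$a
  comp_elements <- atn$nodes$element[vapply(components[K],
                                            function(c) c$nodes[1],
                                            integer(1))]
  composition <- table(comp_elements)
  composition <- stats::setNames(as.integer(composition), names(composition))
  composition <- composition[.hill_order(names(composition))]
  structure(
    list(G = rep_c$C, instances = instances, edges = edges, atoms = atoms,
         l = l, composition = composition, members = K),
    class = "moiety_graph"
  )
}

#' @exportS3Method base::print
print.moiety_graph <- function(x, ...) {
  cat("<moiety_graph> ", nrow(x$instances), " instance(s), composition ",
      format_composition(x$composition), "\n", sep = "")
  invisible(x)
}

#' Chemical composition of a moiety
#'
#' Element counts of one instance's constituent atoms; identical across
#' instances by construction (each member component contributes one atom of a
#' single element per instance), asserted against the atom annotations.
#'
#' @param g a `moiety_graph`.
#' @param atn the parent `atom_transition_network`.
#' @return named integer vector of element counts.
#' @export
moiety_composition <- function(g, atn) {
  stopifnot(inherits(g, "moiety_graph"))
  per_instance <- lapply(g$atoms, function(nodes) {
    tab <- table(atn$nodes$element[nodes])
    stats::setNames(as.integer(tab), names(tab))[order(names(tab))]
  })
  for (ci in per_instance) {
    if (!identical(ci, per_instance[[1]])) {
      stop("instance composition mismatch: isomorphism grouping bug")
    }
  }
  g$composition
}

#' Format an element-count vector as a formula string
#' @param composition named integer vector (e.g. `c(C = 9, H = 13)`).
#' @return a string such as `"C9H13N5O3"`.
#' @export
format_composition <- function(composition) {
  paste0(names(composition), ifelse(composition == 1, "", composition),
         collapse = "")
}

#' Identify conserved moieties in an atom transition network
#'
#' Orchestrates the pipeline: connected components, isomorphism classes,
#' merged moiety graphs, and the moiety matrix `L` whose column `k` counts
#' instances of moiety `k` per metabolite. Columns follow class order;
#' moieties are named `M01`, `M02`, ... in that order.
#'
#' @param atn an `atom_transition_network`.
#' @param audit passed to [merge_to_moiety_graph()].
#' @return list with `graphs` (list of `moiety_graph`), `L` (m x r integer
#'   matrix), `compositions` (named list), `components` (the component list).
#' @export
identify_moieties <- function(atn, audit = TRUE) {
  comps <- connected_components(atn)
  classes <- group_isomorphic(comps)
  graphs <- lapply(classes, function(K) {
    merge_to_moiety_graph(comps, K, atn, audit = audit)
  })
  names(graphs) <- sprintf("M%02d", seq_along(graphs))
  m <- nrow(atn$net$metabolites)
  L <- matrix(0L, m, length(graphs),
              dimnames = list(atn$net$metabolites$id, names(graphs)))
  for (k in seq_along(graphs)) L[, k] <- graphs[[k]]$l
  compositions <- lapply(graphs, moiety_composition, atn = atn)
  list(graphs = graphs, L = L, compositions = compositions,
       components = comps)
}

#' Classify moiety vectors as internal, transitive or integrative
#'
#' A moiety is internal iff it is conserved in the open network
#' (`t(S) %*% l == 0`). Metabolites carrying any internal moiety are
#' secondary; a non-internal moiety is transitive if its support lies only on
#' primary metabolites and integrative if it spans both.
#'
#' @param L moiety matrix (m x r, metabolite rows).
#' @param net the `metabolic_network` providing the total matrix `S`.
#' @return character vector of class labels per column of `L`.
#' @export
classify_moieties <- function(L, net) {
  stopifnot(inherits(net, "metabolic_network"))
  L <- as.matrix(L)
  internal <- vapply(seq_len(ncol(L)), function(k) {
    all(crossprod(net$S, L[, k]) == 0)
  }, logical(1))
  secondary <- rowSums(L[, internal, drop = FALSE] != 0) > 0
  vapply(seq_len(ncol(L)), function(k) {
    if (internal[k]) return("internal")
    support_secondary <- secondary[L[, k] != 0]
    if (any(support_secondary)) "integrative" else "transitive"
  }, character(1))
}
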