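# End-to-end orchestration and on-disk artefacts: moiety matrix TSV,
# per-moiety GraphML, ATN exports and a versioned summary JSON. All orderings
# are canonical and no wall-clock content enters data files, so repeated runs
# are byte-identical.

#' Write a moiety matrix as TSV
#'
#' Metabolite rows, moiety columns; the header carries class and composition
#' strings such as `"M01|transitive|C9H13N5O3"`.
#'
#' @param L moiety matrix.
#' @param classes character vector of per-column classes.
#' @param compositions list of per-column element-count vectors.
#' @param path output path.
#' @export
write_moiety_matrix <- function(L, classes, compositions, path) {
  header <- vapply(seq_len(ncol(L)), function(k) {
    paste(colnames(L)[k], classes[k],
          format_composition(compositions[[k]]), sep = "|")
  }, character(1))
  out <- as.data.frame(L)
  names(out) <- header
  utils::write.table(cbind(metabolite = rownames(L), out), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a moiety graph as GraphML
#'
#' Instance nodes carry metabolite, instance index and the constituent atom
#' annotation (one atom per member component, as
#' `metabolite:element:index` strings).
#'
#' @param g a `moiety_graph`.
#' @param atn the parent `atom_transition_network`.
#' @param path output path.
#' @export
write_moiety_graphml <- function(g, atn, path) {
  ig <- igraph::graph_from_data_frame(
    data.frame(from = g$edges$from, to = g$edges$to,
               reaction = g$edges$reaction_id),
    directed = TRUE,
    vertices = data.frame(
      name = seq_len(nrow(g$instances)),
      metabolite = g$instances$metabolite,
      instance = g$instances$instance,
      atoms = vapply(g$atoms, function(nodes) {
        paste(atn$nodes$metabolite[nodes], atn$nodes$element[nodes],
              atn$nodes$index[nodes], sep = ":", collapse = ";")
      }, character(1))
    )
  )
  igraph::write_graph(ig, path, format = "graphml")
  invisible(path)
}

#' Export an atom transition network
#'
#' Writes a TSV edge list (`reaction_id, sub_met, element, sub_index,
#' prod_met, prod_index`), the incidence matrix as sparse triplet TSV
#' (`row, col, value`), and GraphML.
#'
#' @param atn an `atom_transition_network`.
#' @param dir output directory.
#' @export
write_atn <- function(atn, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tr <- atn$transitions
  edges <- data.frame(
    reaction_id = tr$reaction_id,
    sub_met = atn$nodes$metabolite[tr$source],
    element = atn$nodes$element[tr$source],
    sub_index = atn$nodes$index[tr$source],
    prod_met = atn$nodes$metabolite[tr$target],
    prod_index = atn$nodes$index[tr$target]
  )
  utils::write.table(edges, file.path(dir, "atn_edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  A <- methods::as(atn$A, "TsparseMatrix")
  trip <- data.frame(row = A@i + 1, col = A@j + 1, value = A@x)
  trip <- trip[order(trip$col, trip$row), ]
  utils::write.table(trip, file.path(dir, "atn_incidence.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ig <- igraph::graph_from_data_frame(
    data.frame(from = tr$source, to = tr$target,
               reaction = tr$reaction_id),
    directed = TRUE,
    vertices = data.frame(name = seq_len(nrow(atn$nodes)),
                          metabolite = atn$nodes$metabolite,
                          element = atn$nodes$element,
                          index = atn$nodes$index)
  )
  igraph::write_graph(ig, file.path(dir, "atn.graphml"), format = "graphml")
  invisible(dir)
}

#' Run the full identification pipeline and write its artefact bundle
#'
#' Loads a network and mappings, builds the atom transition network,
#' identifies and classifies moieties, optionally fully decomposes the moiety
#' matrix, and writes the moiety matrix TSV, per-moiety GraphML files, ATN
#' exports and a summary JSON
#' (`{schema, p, q, components, moieties, rank_L, leftnull_dim, classes}`).
#'
#' @param network a `metabolic_network` or path to a network JSON.
#' @param mappings an `atom_mapping_set` or path to a mapping TSV.
#' @param out_dir output directory.
#' @param element element filter symbol or `"all"`.
#' @param audit enable the strict isomorphism audit.
#' @param decompose also compute the fully decomposed matrix `D`.
#' @return the summary list, invisibly; artefacts on disk.
#' @export
run_identify <- function(network, mappings, out_dir, element = "all",
                         audit = TRUE, decompose = FALSE) {
  net <- if (inherits(network, "metabolic_network")) network else {
    load_network(network)
  }
  maps <- if (inherits(mappings, "atom_mapping_set")) mappings else {
    parse_mapping_table(mappings, net)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  atn <- build_atn(net, maps, element)
  res <- identify_moieties(atn, audit = audit)
  classes <- classify_moieties(res$L, net)
  NB <- split_matrices(net)
  write_moiety_matrix(res$L, classes, res$compositions,
                      file.path(out_dir, "moiety_matrix.tsv"))
  for (k in seq_along(res$graphs)) {
    write_moiety_graphml(res$graphs[[k]], atn,
                         file.path(out_dir,
                                   paste0(names(res$graphs)[k], ".graphml")))
  }
  write_atn(atn, file.path(out_dir, "atn"))
  summary <- list(
    schema = 1,
    element_filter = element,
    p = atn$report$p, q = atn$report$q,
    components = length(res$components),
    moieties = ncol(res$L),
    rank_L = exact_rank(res$L),
    leftnull_dim = left_nullspace_dim(NB$N),
    classes = stats::setNames(as.list(classes), colnames(res$L))
  )
  if (decompose) {
    dec <- fully_decompose(NB$N, res$L)
    utils::write.table(
      cbind(metabolite = rownames(dec$D), as.data.frame(dec$D)),
      file.path(out_dir, "decomposed_matrix.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    summary$decomposed <- ncol(dec$D)
  }
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(summary)
}
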