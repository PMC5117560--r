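# Packaged dopamine-pathway fixtures. DAS is a small human dopamine synthesis
# network: 11 metabolites, four internal reactions (phenylalanine
# hydroxylase; tyrosine hydroxylase; DOPA decarboxylase; a composite of
# formate dehydrogenase and dihydropteridine reductase) and seven exchanges.
# Atom mappings are the canonical transition conventions that reproduce the
# network's published aggregate structure (170 atoms, 176 transitions, 57
# components, seven moieties); the hydrogen conventions in R1/R2 are a fixture
# convention, not a biochemical claim. The two symmetric oxygen atoms of O2
# admit four mapping combinations across R1 and R2 (variants a, b, d, e);
# variants d/e make the O2-to-water atom differ between the two reactions and
# merge two oxygen moieties into one composite moiety.

.map_rows <- function(reaction_id = NULL, sub_met, element, sub_index,
                      prod_met, prod_index) {
  n <- max(length(sub_index), length(prod_index))
  data.frame(sub_met = sub_met, sub_instance = 1L, element = element,
             sub_index = as.integer(sub_index), prod_met = prod_met,
             prod_instance = 1L, prod_index = as.integer(prod_index),
             stringsAsFactors = FALSE)
}

# identity transfer of a whole formula block from one metabolite to another
.identity_block <- function(sub_met, prod_met, counts) {
  do.call(rbind, lapply(names(counts), function(e) {
    .map_rows(sub_met = sub_met, element = e, sub_index = seq_len(counts[[e]]),
              prod_met = prod_met, prod_index = seq_len(counts[[e]]))
  }))
}

.das_network <- function() {
  mets <- data.frame(
    id = c("Phe", "Tyr", "L-DOPA", "DA", "CO2", "Formate", "BH4", "BH2",
           "O2", "H2O", "H+"),
    name = c("L-phenylalanine", "L-tyrosine", "levodopa", "dopamine",
             "carbon dioxide", "formate", "tetrahydrobiopterin",
             "dihydrobiopterin", "dioxygen", "water", "hydrogen ion"),
    charge = c(0, 0, 0, 1, 0, -1, 0, 0, 0, 0, 1),
    stringsAsFactors = FALSE
  )
  formulas <- list(
    "Phe" = c(C = 9, H = 11, N = 1, O = 2),
    "Tyr" = c(C = 9, H = 11, N = 1, O = 3),
    "L-DOPA" = c(C = 9, H = 11, N = 1, O = 4),
    "DA" = c(C = 8, H = 12, N = 1, O = 2),
    "CO2" = c(C = 1, O = 2),
    "Formate" = c(C = 1, H = 1, O = 2),
    "BH4" = c(C = 9, H = 15, N = 5, O = 3),
    "BH2" = c(C = 9, H = 13, N = 5, O = 3),
    "O2" = c(O = 2),
    "H2O" = c(H = 2, O = 1),
    "H+" = c(H = 1)
  )
  rxns <- data.frame(
    id = c("R1", "R2", "R3", "R4", paste0("E", 1:7)),
    kind = c(rep("internal", 4), rep("exchange", 7)),
    stringsAsFactors = FALSE
  )
  stoich <- list(
    R1 = c("Phe" = -1, "BH4" = -1, "O2" = -1,
           "Tyr" = 1, "BH2" = 1, "H2O" = 1),
    R2 = c("Tyr" = -1, "BH4" = -1, "O2" = -1,
           "L-DOPA" = 1, "BH2" = 1, "H2O" = 1),
    R3 = c("L-DOPA" = -1, "H+" = -1, "DA" = 1, "CO2" = 1),
    R4 = c("BH2" = -1, "Formate" = -1, "H+" = -1, "BH4" = 1, "CO2" = 1),
    E1 = c("O2" = 1), E2 = c("Phe" = 1), E3 = c("H2O" = -1),
    E4 = c("DA" = -1), E5 = c("CO2" = -1), E6 = c("Formate" = 1),
    E7 = c("H+" = 1)
  )
  metabolic_network(mets, rxns, stoich, formulas)
}

# BH4 -> BH2 hydride-carrier block shared by R1 and R2: the biopterin core
# keeps its 30 atoms, H14/H15 leave to the new water molecule
.bh4_block <- function() {
  rbind(
    .identity_block("BH4", "BH2", c(C = 9, H = 13, N = 5, O = 3)),
    .map_rows(sub_met = "BH4", element = "H", sub_index = 14,
              prod_met = "H2O", prod_index = 1),
    .map_rows(sub_met = "BH4", element = "H", sub_index = 15,
              prod_met = "H2O", prod_index = 2)
  )
}

# oxygen mapping of the hydroxylase reactions; `water_atom` is the O2 atom
# index that becomes the water oxygen, the other becomes the new hydroxyl
.o2_rows <- function(water_atom, hydroxyl_met, hydroxyl_index) {
  rbind(
    .map_rows(sub_met = "O2", element = "O", sub_index = water_atom,
              prod_met = "H2O", prod_index = 1),
    .map_rows(sub_met = "O2", element = "O",
              sub_index = setdiff(1:2, water_atom),
              prod_met = hydroxyl_met, prod_index = hydroxyl_index)
  )
}

.r3_map <- function() {
  rbind(
    .map_rows(sub_met = "L-DOPA", element = "C", sub_index = 1:8,
              prod_met = "DA", prod_index = 1:8),
    .map_rows(sub_met = "L-DOPA", element = "C", sub_index = 9,
              prod_met = "CO2", prod_index = 1),
    .map_rows(sub_met = "L-DOPA", element = "H", sub_index = 1:11,
              prod_met = "DA", prod_index = 1:11),
    .map_rows(sub_met = "L-DOPA", element = "N", sub_index = 1,
              prod_met = "DA", prod_index = 1),
    .map_rows(sub_met = "L-DOPA", element = "O", sub_index = 1:2,
              prod_met = "CO2", prod_index = 1:2),
    .map_rows(sub_met = "L-DOPA", element = "O", sub_index = 3:4,
              prod_met = "DA", prod_index = 1:2),
    .map_rows(sub_met = "H+", element = "H", sub_index = 1,
              prod_met = "DA", prod_index = 12)
  )
}

#' The DAS dopamine synthesis fixture
#'
#' Returns the 11-metabolite dopamine synthesis network, its canonical atom
#' mapping set, and the expected analysis results. The `oxygen_variant`
#' selects which of the two symmetric O2 atoms maps to water in each of the
#' two hydroxylase reactions: in variants `"a"` and `"b"` the same atom maps
#' to water in both reactions (seven nondecomposable moieties); in `"d"` and
#' `"e"` the atom differs between reactions, merging the two oxygen moieties
#' into one composite moiety (six moieties).
#'
#' @param oxygen_variant one of `"a"`, `"b"`, `"d"`, `"e"`.
#' @return list with `network`, `mappings` (an `atom_mapping_set`) and
#'   `expected` (moiety matrix columns, compositions, classes, p, q,
#'   component count).
#' @export
das_fixture <- function(oxygen_variant = c("a", "b", "d", "e")) {
  oxygen_variant <- match.arg(oxygen_variant)
  net <- .das_network()
  # O2 atom feeding water in (R1, R2) per variant
  water_atom <- switch(oxygen_variant,
                       a = c(1, 1), b = c(2, 2), d = c(1, 2), e = c(2, 1))
  r1 <- rbind(
    .identity_block("Phe", "Tyr", c(C = 9, H = 11, N = 1, O = 2)),
    .bh4_block(),
    .o2_rows(water_atom[1], "Tyr", 3)
  )
  r2 <- rbind(
    .identity_block("Tyr", "L-DOPA", c(C = 9, H = 11, N = 1, O = 3)),
    .bh4_block(),
    .o2_rows(water_atom[2], "L-DOPA", 4)
  )
  r4 <- rbind(
    .identity_block("BH2", "BH4", c(C = 9, H = 13, N = 5, O = 3)),
    .map_rows(sub_met = "Formate", element = "C", sub_index = 1,
              prod_met = "CO2", prod_index = 1),
    .map_rows(sub_met = "Formate", element = "O", sub_index = 1:2,
              prod_met = "CO2", prod_index = 1:2),
    .map_rows(sub_met = "Formate", element = "H", sub_index = 1,
              prod_met = "BH4", prod_index = 14),
    .map_rows(sub_met = "H+", element = "H", sub_index = 1,
              prod_met = "BH4", prod_index = 15)
  )
  mappings <- atom_mapping_set(list(R1 = r1, R2 = r2, R3 = .r3_map(),
                                    R4 = r4))

  mets <- net$metabolites$id
  col <- function(...) stats::setNames(c(...), mets)
  l1 <- col(1, 1, 1, 1, 0, 0, 0, 0, 0, 0, 0)
  l2 <- col(1, 1, 1, 0, 1, 1, 0, 0, 0, 0, 0)
  l3 <- col(0, 0, 0, 0, 0, 0, 1, 1, 0, 0, 0)
  l4 <- col(0, 0, 0, 1, 0, 0, 1, 0, 0, 1, 1)
  l5 <- col(0, 0, 0, 0, 0, 1, 1, 0, 0, 1, 0)
  l6 <- col(0, 1, 2, 2, 0, 0, 0, 0, 1, 0, 0)
  l7 <- col(0, 0, 0, 0, 0, 0, 0, 0, 1, 1, 0)
  l8 <- l6 + l7
  expected <- if (oxygen_variant %in% c("a", "b")) {
    list(L_columns = list(l1 = l1, l2 = l2, l3 = l3, l4 = l4, l5 = l5,
                          l6 = l6, l7 = l7),
         n_moieties = 7L)
  } else {
    list(L_columns = list(l1 = l1, l2 = l2, l3 = l3, l4 = l4, l5 = l5,
                          l8 = l8),
         n_moieties = 6L)
  }
  expected$compositions <- list(
    l1 = c(C = 8, H = 11, N = 1), l2 = c(C = 1, O = 2),
    l3 = c(C = 9, H = 13, N = 5, O = 3), l4 = c(H = 1), l5 = c(H = 1)
  )
  expected$p <- 170L
  expected$q <- 176L
  expected$n_components <- if (oxygen_variant %in% c("a", "b")) 57L else 56L
  expected$classes <- c(l1 = "transitive", l2 = "transitive", l3 = "internal",
                        l4 = "integrative", l5 = "integrative",
                        l6 = "transitive", l7 = "transitive")
  list(network = net, mappings = mappings, expected = expected)
}

#' The DOPA decarboxylase example fixture
#'
#' A single internal reaction (levodopa + H+ -> dopamine + CO2) with source
#' exchanges for the substrates and sinks for the products. The reaction
#' conserves three moieties: the dopamine moiety (levodopa, dopamine), the
#' CO2 moiety (levodopa, CO2), and a hydrogen moiety (H+, dopamine).
#'
#' @return list with `network`, `mappings`, `expected` (the three moiety
#'   vectors and their compositions).
#' @export
dopa_decarboxylase_fixture <- function() {
  mets <- data.frame(
    id = c("L-DOPA", "H+", "DA", "CO2"),
    name = c("levodopa", "hydrogen ion", "dopamine", "carbon dioxide"),
    charge = c(0, 1, 1, 0),
    stringsAsFactors = FALSE
  )
  formulas <- list(
    "L-DOPA" = c(C = 9, H = 11, N = 1, O = 4),
    "H+" = c(H = 1),
    "DA" = c(C = 8, H = 12, N = 1, O = 2),
    "CO2" = c(C = 1, O = 2)
  )
  rxns <- data.frame(
    id = c("R1", "E1", "E2", "E3", "E4"),
    kind = c("internal", rep("exchange", 4)),
    stringsAsFactors = FALSE
  )
  stoich <- list(
    R1 = c("L-DOPA" = -1, "H+" = -1, "DA" = 1, "CO2" = 1),
    E1 = c("L-DOPA" = 1), E2 = c("H+" = 1),
    E3 = c("DA" = -1), E4 = c("CO2" = -1)
  )
  net <- metabolic_network(mets, rxns, stoich, formulas)
  mappings <- atom_mapping_set(list(R1 = .r3_map()))
  col <- function(...) stats::setNames(c(...), mets$id)
  expected <- list(
    L_columns = list(l1 = col(1, 0, 1, 0), l2 = col(1, 0, 0, 1),
                     l3 = col(0, 1, 1, 0)),
    # in the standalone reaction the catechol oxygens travel with the
    # dopamine moiety (in full DAS they trace back to O2 instead)
    compositions = list(l1 = c(C = 8, H = 11, N = 1, O = 2),
                        l2 = c(C = 1, O = 2), l3 = c(H = 1))
  )
  list(network = net, mappings = mappings, expected = expected)
}

#' Write a fixture to disk as network JSON plus mapping TSV
#'
#' @param fixture a fixture list from [das_fixture()],
#'   [dopa_decarboxylase_fixture()] or [planted_moiety_generator()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  net <- fixture$network
  doc <- list(
    metabolites = lapply(seq_len(nrow(net$metabolites)), function(i) {
      id <- net$metabolites$id[i]
      out <- list(id = id, name = net$metabolites$name[i])
      f <- net$formulas[[id]]
      if (length(f)) out$formula <- as.list(f)
      if (!is.na(net$metabolites$charge[i])) {
        out$charge <- net$metabolites$charge[i]
      }
      out
    }),
    reactions = lapply(seq_len(nrow(net$reactions)), function(j) {
      rid <- net$reactions$id[j]
      coef <- net$S[, rid]
      list(id = rid, kind = net$reactions$kind[j],
           stoichiometry = as.list(coef[coef != 0]))
    })
  )
  jsonlite::write_json(doc, file.path(dir, "network.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_mapping_table(fixture$mappings, file.path(dir, "mappings.tsv"))
  if (!is.null(fixture$expected)) {
    exp_json <- fixture$expected
    if (!is.null(exp_json$L_columns)) {
      exp_json$L_columns <- lapply(exp_json$L_columns, unname)
    }
    if (!is.null(exp_json$L)) exp_json$L <- NULL
    jsonlite::write_json(exp_json, file.path(dir, "expected.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(dir)
}
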