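# Component finding, isomorphism classes, moiety graphs, the moiety matrix,
# classification and composition.

test_that("DAS carbon network has 18 components in 3 classes", {
  res <- das_result("a", "C")
  expect_length(res$components, 18)
  expect_length(res$graphs, 3)
  expect_setequal(vapply(res$graphs, function(g) length(g$members),
                         integer(1)),
                  c(8L, 1L, 9L))
})

test_that("full DAS network has 57 components in 7 classes", {
  res <- das_result("a", "all")
  expect_length(res$components, 57)
  expect_equal(ncol(res$L), 7)
})

test_that("components partition the nodes and carry consistent vectors", {
  atn <- das_atn()
  comps <- das_result()$components
  all_nodes <- sort(unlist(lapply(comps, function(c) c$nodes)))
  expect_equal(all_nodes, seq_len(atn$report$p))
  for (comp in comps[1:5]) {
    expect_equal(atom_conservation_vector(comp),
                 stats::setNames(as.integer(rowSums(comp$M)),
                                 rownames(comp$M)))
    expect_equal(sum(comp$a), length(comp$nodes))
  }
})

test_that("singleton components give unit conservation vectors", {
  net <- metabolic_network(
    data.frame(id = c("A", "B"), name = NA, charge = 0),
    data.frame(id = "E1", kind = "exchange"),
    list(E1 = c(A = -1)),
    list(A = c(C = 1), B = c(N = 2)))
  atn <- build_atn(net, atom_mapping_set(stats::setNames(list(), character(0))))
  comps <- connected_components(atn)
  expect_length(comps, 3)
  expect_equal(unname(comps[[1]]$a), c(1L, 0L))
  expect_equal(unname(comps[[2]]$a), c(0L, 1L))
})

test_that("DAS moiety matrix equals the published seven vectors", {
  res <- das_result("a")
  expect_equal(col_set(res$L), col_set(table4_L()))
  N <- das_N()
  expect_true(all(crossprod(N, res$L) == 0))
  expect_equal(exact_rank(res$L), 7)
})

test_that("oxygen-variant b gives the same vectors; d and e merge two", {
  expect_equal(col_set(das_result("b")$L), col_set(das_result("a")$L))
  for (v in c("d", "e")) {
    res <- das_result(v)
    expect_equal(ncol(res$L), 6)
    l8 <- c(0, 1, 2, 2, 0, 0, 0, 0, 2, 1, 0)
    expect_true(paste(l8, collapse = ",") %in% col_set(res$L))
    # one composite column: rank drops to 6 of the 7-dimensional null space
    expect_equal(exact_rank(res$L), 6)
    expect_length(res$components, 56)
  }
})

test_that("DOPA decarboxylase yields its three published moiety vectors", {
  res <- dopa_result()
  fx <- dopa()
  expect_equal(col_set(res$L), col_set(do.call(cbind, fx$expected$L_columns)))
  comps <- vapply(res$compositions, format_composition, character(1))
  expect_setequal(unname(comps), c("C8H11NO2", "CO2", "H"))
})

test_that("moiety compositions match the published formulas", {
  res <- das_result("a")
  comp_str <- vapply(res$compositions, format_composition, character(1))
  key <- apply(res$L, 2, paste, collapse = ",")
  want <- c("1,1,1,1,0,0,0,0,0,0,0" = "C8H11N",
            "1,1,1,0,1,1,0,0,0,0,0" = "CO2",
            "0,0,0,0,0,0,1,1,0,0,0" = "C9H13N5O3",
            "0,0,0,1,0,0,1,0,0,1,1" = "H",
            "0,0,0,0,0,1,1,0,0,1,0" = "H",
            "0,1,2,2,0,0,0,0,1,0,0" = "O",
            "0,0,0,0,0,0,0,0,1,1,0" = "O")
  expect_equal(unname(comp_str), unname(want[key]))
})

test_that("atoms are exhaustively and disjointly assigned to moieties", {
  # partition identity: compositions weighted by L reproduce the elemental
  # matrix on the mapped elements
  for (variant in c("a", "d")) {
    res <- das_result(variant)
    E <- elemental_matrix(das(variant)$network)
    for (e in colnames(E)) {
      weights <- vapply(res$compositions, function(cc) {
        if (e %in% names(cc)) cc[[e]] else 0L
      }, numeric(1))
      expect_equal(as.numeric(res$L %*% weights), unname(E[, e]))
    }
  }
})

test_that("classes agree within each isomorphism class", {
  res <- das_result("a")
  for (g in res$graphs) {
    comps <- res$components[g$members]
    sizes <- vapply(comps, function(c) length(c$nodes), integer(1))
    expect_equal(length(unique(sizes)), 1)
    for (c2 in comps[-1]) {
      expect_true(verify_isomorphism_strict(comps[[1]], c2))
    }
  }
})

test_that("strict audit rejects equal-count but structurally different pairs", {
  # two hand-made 2-atom components with identical conservation vectors but
  # edges from different reactions
  mk <- function(rid) {
    M <- matrix(c(1L, 0L, 0L, 1L), 2, 2, dimnames = list(c("A", "B"), NULL))
    structure(list(
      id = 1, nodes = c(1L, 2L),
      transitions = data.frame(reaction_id = rid, source = 1L, target = 2L),
      C = matrix(c(-1L, 1L), 2, 1), M = M,
      a = stats::setNames(c(1L, 1L), c("A", "B"))
    ), class = "atn_component")
  }
  c1 <- mk("R1"); c2 <- mk("R2")
  expect_true(verify_isomorphism_strict(c1, c1))
  expect_false(verify_isomorphism_strict(c1, c2))
  fake_atn <- list(
    nodes = data.frame(metabolite = c("A", "B"), element = "C", index = 1),
    net = list(metabolites = data.frame(id = c("A", "B"))))
  expect_warning(
    merge_to_moiety_graph(list(c1, c2), c(1, 2), fake_atn, audit = TRUE),
    "differ structurally")
})

test_that("classification matches the published schema on DAS", {
  res <- das_result("a")
  classes <- classify_moieties(res$L, das()$network)
  key <- apply(res$L, 2, paste, collapse = ",")
  want <- c("1,1,1,1,0,0,0,0,0,0,0" = "transitive",   # l1
            "1,1,1,0,1,1,0,0,0,0,0" = "transitive",   # l2
            "0,0,0,0,0,0,1,1,0,0,0" = "internal",     # l3 (biopterin)
            "0,0,0,1,0,0,1,0,0,1,1" = "integrative",  # l4
            "0,0,0,0,0,1,1,0,0,1,0" = "integrative",  # l5
            "0,1,2,2,0,0,0,0,1,0,0" = "transitive",   # l6
            "0,0,0,0,0,0,0,0,1,1,0" = "transitive")   # l7
  expect_equal(classes, unname(want[key]))
})

test_that("a sink for every metabolite leaves no internal moieties", {
  fx <- dopa()
  net <- fx$network
  extra <- metabolic_network(
    net$metabolites,
    rbind(net$reactions,
          data.frame(id = paste0("S", 1:4), kind = "exchange")),
    c(stats::setNames(lapply(net$reactions$id, function(r) {
        v <- net$S[, r]; v[v != 0]
      }), net$reactions$id),
      stats::setNames(lapply(net$metabolites$id, function(m) {
        stats::setNames(-1, m)
      }), paste0("S", 1:4))),
    net$formulas)
  classes <- classify_moieties(dopa_result()$L, extra)
  expect_false(any(classes == "internal"))
})

test_that("identification is idempotent on re-encoded moiety graphs", {
  res <- das_result("a")
  for (k in c(2, 7)) {  # a multi-instance and a two-instance moiety
    g <- res$graphs[[k]]
    fx2 <- moiety_graph_as_fixture(g, das()$network)
    res2 <- identify_moieties(build_atn(fx2$network, fx2$mappings))
    expect_equal(ncol(res2$L), 1)
    expect_equal(unname(res2$L[, 1]), unname(g$l))
  }
})
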