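# Network data model and exact linear algebra over stoichiometric matrices.

test_that("DAS and DOPA decarboxylase networks load with the right shape", {
  net <- das()$network
  expect_equal(nrow(net$S), 11)
  expect_equal(ncol(net$S), 11)
  expect_equal(net$u, 4)

  dn <- dopa()$network
  expect_equal(dim(dn$S), c(4, 5))
  expect_equal(dn$u, 1)

  NB <- split_matrices(dn)
  expect_equal(unname(NB$N[, 1]), c(-1, -1, 1, 1))
  expect_equal(cbind(NB$N, NB$B), dn$S, ignore_attr = TRUE)
})

test_that("network JSON round-trips through load_network", {
  path <- system.file("extdata/das_a/network.json", package = "moietyr")
  net <- load_network(path)
  ref <- das()$network
  expect_equal(net$S, ref$S)
  expect_equal(net$u, ref$u)
  expect_equal(net$formulas[ref$metabolites$id], ref$formulas)
})

test_that("TSV matrix input needs a sidecar and reorders internal first", {
  net <- das()$network
  tsv <- tempfile(fileext = ".tsv")
  # write with exchange columns first to exercise the recorded permutation
  perm <- c(5:11, 1:4)
  utils::write.table(
    cbind(metabolite = rownames(net$S), as.data.frame(net$S[, perm])),
    tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  loaded <- load_network(tsv, internal_ids = c("R1", "R2", "R3", "R4"))
  expect_equal(loaded$u, 4)
  expect_equal(colnames(loaded$S)[1:4], c("R1", "R2", "R3", "R4"))
  expect_equal(loaded$S[, colnames(net$S)], net$S, ignore_attr = TRUE)
  expect_false(is.null(loaded$permutation))
  expect_error(load_network(tsv), "internal reaction ids")
})

test_that("constructor rejects malformed networks", {
  mets <- data.frame(id = c("A", "B"), name = NA, charge = 0)
  expect_error(
    metabolic_network(mets, data.frame(id = character(0),
                                       kind = character(0)), list()),
    "empty reaction list")
  expect_error(
    metabolic_network(mets, data.frame(id = "R1", kind = "internal"),
                      list(R1 = c(A = -1, C = 1))),
    "unknown metabolite")
  expect_error(
    metabolic_network(rbind(mets, mets[1, ]),
                      data.frame(id = "R1", kind = "internal"),
                      list(R1 = c(A = -1, B = 1))),
    "duplicate metabolite")
  expect_error(
    metabolic_network(mets, data.frame(id = "R1", kind = "sideways"),
                      list(R1 = c(A = -1, B = 1))),
    "kind")
  expect_error(
    metabolic_network(mets, data.frame(id = "R1", kind = "internal"),
                      list(R1 = c(A = -0.5, B = 0.5))),
    "non-integer")
})

test_that("exact rank and left null space dimensions match the networks", {
  expect_equal(exact_rank(das_N()), 4)
  expect_equal(left_nullspace_dim(das_N()), 7)
  dopa_N <- split_matrices(dopa()$network)$N
  expect_equal(exact_rank(dopa_N), 1)
  expect_equal(left_nullspace_dim(dopa_N), 3)
  expect_equal(exact_rank(matrix(0, 3, 3)), 0)
  expect_equal(left_nullspace_dim(diag(5)), 0)
  # open-network inequality: closing a network can only add conservation
  expect_gte(left_nullspace_dim(das_N()),
             left_nullspace_dim(das()$network$S))
  expect_equal(left_nullspace_dim(dopa()$network$S), 0)
})

test_that("exact rank agrees with floating SVD rank on random matrices", {
  set.seed(42)
  for (i in 1:25) {
    m <- sample(2:20, 1); n <- sample(2:20, 1)
    M <- matrix(sample(-3:3, m * n, replace = TRUE), m, n)
    d <- svd(M)$d
    float_rank <- sum(d > 1e-9 * max(d, 1))
    expect_equal(exact_rank(M), float_rank)
  }
})

test_that("exact rank handles small-rational exchange coefficients", {
  M <- cbind(c(1, 2, 3), c(0.5, 1, 1.5), c(1 / 3, 0, 1))
  expect_equal(exact_rank(M), 2)
})

test_that("conservation vector test is exact and validates dimensions", {
  N <- das_N()
  for (l in das("a")$expected$L_columns) {
    expect_true(is_conservation_vector(N, l))
  }
  expect_true(is_conservation_vector(N, l9_vector()))
  expect_true(is_conservation_vector(N, rep(0, 11)))
  expect_false(is_conservation_vector(N, c(1, rep(0, 10))))
  expect_error(is_conservation_vector(N, 1:3), "dimension mismatch")
})

test_that("l9 identity holds entry-wise", {
  cols <- das("a")$expected$L_columns
  expect_equal(unname(l9_vector()),
               c(0, 1, 2, 0, 2, 2, 0, 0, 1, 0, 0))
  expect_equal(l9_vector(), cols$l6 + 2 * (cols$l2 - cols$l1))
})

test_that("elemental matrix follows the fixed element order", {
  E <- elemental_matrix(dopa()$network)
  expect_equal(colnames(E)[1:4], c("C", "H", "O", "N"))
  expect_equal(unname(E["L-DOPA", c("C", "H", "O", "N")]), c(9, 11, 4, 1))
  expect_equal(unname(E["H+", c("C", "H", "O", "N")]), c(0, 1, 0, 0))
  expect_equal(unname(E["DA", c("C", "H", "O", "N")]), c(8, 12, 2, 1))
  expect_equal(unname(E["CO2", c("C", "H", "O", "N")]), c(1, 0, 2, 0))
})

test_that("elemental columns are conservation vectors of a balanced network", {
  net <- das()$network
  E <- elemental_matrix(net)
  expect_true(all(check_elemental_balance(net)$balanced))
  N <- das_N()
  for (j in seq_len(ncol(E))) {
    expect_true(is_conservation_vector(N, E[, j]))
  }
})

test_that("electron counts come from atomic numbers minus charge", {
  net <- dopa()$network
  e <- electron_vector(net)
  expect_equal(unname(e["H+"]), 0)
  tiny <- metabolic_network(
    data.frame(id = c("H2O", "O2"), name = NA, charge = c(0, 0)),
    data.frame(id = "E1", kind = "exchange"),
    list(E1 = c(H2O = -1)),
    list(H2O = c(H = 2, O = 1), O2 = c(O = 2)))
  expect_equal(unname(electron_vector(tiny)), c(10, 16))
})

test_that("imbalance is reported, not raised", {
  # drop the proton from the decarboxylase reaction: H and charge go to -1
  net <- metabolic_network(
    dopa()$network$metabolites,
    data.frame(id = c("R1", "E1"), kind = c("internal", "exchange")),
    list(R1 = c("L-DOPA" = -1, "DA" = 1, "CO2" = 1), E1 = c("DA" = -1)),
    dopa()$network$formulas)
  rep <- check_elemental_balance(net)
  expect_false(rep$balanced[1])
  expect_equal(rep$H[1], 1)       # extra product hydrogen, unmatched
  expect_equal(rep$charge[1], 1)
  # exchange-only network gives an empty report
  ex_only <- metabolic_network(
    data.frame(id = "A", name = NA, charge = 0),
    data.frame(id = "E1", kind = "exchange"),
    list(E1 = c(A = -1)), list(A = c(C = 1)))
  expect_equal(nrow(check_elemental_balance(ex_only)), 0)
})
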