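# Integer-programming decomposition of composite conservation vectors and
# the brute-force certification oracle.

test_that("the composite oxygen vector splits into exactly its two parts", {
  N <- das_N()
  cols <- das("a")$expected$L_columns
  l8 <- cols$l6 + cols$l7
  split <- decompose_vector(N, l8)
  expect_false(is.null(split))
  expect_equal(split$x + split$y, l8)
  got <- list(unname(split$x), unname(split$y))
  want <- list(unname(cols$l6), unname(cols$l7))
  expect_true(setequal(lapply(got, paste, collapse = ","),
                       lapply(want, paste, collapse = ",")))
  expect_true(is_conservation_vector(N, split$x))
  expect_true(is_conservation_vector(N, split$y))
})

test_that("published nondecomposable vectors are certified infeasible", {
  N <- das_N()
  for (l in das("a")$expected$L_columns) {
    expect_null(decompose_vector(N, l))
  }
  # the zero vector has no nonzero proper split
  expect_null(decompose_vector(N, rep(0, 11)))
  expect_error(decompose_vector(N, c(1, rep(0, 10))),
               "not a conservation vector")
})

test_that("brute-force oracle certifies the single-reaction cases", {
  N_dopa <- split_matrices(dopa()$network)$N
  dec <- brute_force_nondecomposable(N_dopa, c(1, 1, 1, 1))
  expect_false(dec$nondecomposable)
  w <- dec$witness
  expect_equal(unname(w$x + w$y), c(1, 1, 1, 1))
  expect_true(is_conservation_vector(N_dopa, w$x))
  expect_true(is_conservation_vector(N_dopa, w$y))
  expect_true(brute_force_nondecomposable(N_dopa,
                                          c(1, 0, 1, 0))$nondecomposable)
  l8 <- c(0, 1, 2, 2, 0, 0, 0, 0, 2, 1, 0)
  expect_false(brute_force_nondecomposable(das_N(), l8)$nondecomposable)
  expect_error(brute_force_nondecomposable(das_N(), l8, cap = 3), "cap")
})

test_that("integer program agrees with the oracle on small vectors", {
  N <- das_N()
  cols <- das("a")$expected$L_columns
  candidates <- c(cols, list(l8 = cols$l6 + cols$l7, l9 = l9_vector()))
  # all pairwise sums of the published columns (conservation closed set)
  for (i in seq_along(cols)) {
    for (j in seq(i, length(cols))) {
      candidates[[length(candidates) + 1]] <- cols[[i]] + cols[[j]]
    }
  }
  dopa_N <- split_matrices(dopa()$network)$N
  dopa_cols <- dopa()$expected$L_columns
  for (l in candidates) {
    if (sum(l) > 20) next
    milp <- decompose_vector(N, l)
    oracle <- brute_force_nondecomposable(N, l)
    expect_equal(is.null(milp), oracle$nondecomposable,
                 label = paste("vector", paste(l, collapse = ",")))
  }
  for (l in c(dopa_cols, list(c(1, 1, 1, 1), c(2, 1, 1, 2)))) {
    milp <- decompose_vector(dopa_N, l)
    oracle <- brute_force_nondecomposable(dopa_N, l)
    expect_equal(is.null(milp), oracle$nondecomposable)
  }
})

test_that("full decomposition of the variant-d matrix recovers all seven", {
  N <- das_N()
  cols <- das("a")$expected$L_columns
  L5 <- do.call(cbind, c(cols[c("l1", "l2", "l3", "l4", "l5")],
                         list(l8 = cols$l6 + cols$l7)))
  dec <- fully_decompose(N, L5)
  expect_equal(ncol(dec$D), 7)
  expect_equal(col_set(dec$D), col_set(table4_L()))
  # every output column is oracle-certified nondecomposable
  for (j in seq_len(ncol(dec$D))) {
    expect_true(brute_force_nondecomposable(N, dec$D[, j])$nondecomposable)
  }
  # provenance: l8 split, the others kept
  acts <- vapply(dec$provenance, function(p) p$action[1], character(1))
  expect_equal(sum(acts == "split"), 1)
})

test_that("an already nondecomposable matrix passes through unchanged", {
  dec <- fully_decompose(das_N(), table4_L())
  expect_equal(col_set(dec$D), col_set(table4_L()))
  expect_equal(ncol(dec$D), 7)
})

test_that("duplicated input columns deduplicate with provenance intact", {
  cols <- das("a")$expected$L_columns
  L <- cbind(a = cols$l1, b = cols$l1)
  dec <- fully_decompose(das_N(), L)
  expect_equal(ncol(dec$D), 1)
  expect_equal(ncol(dec$leaves), 2)
  expect_length(dec$provenance, 2)
})

test_that("decomposition is deterministic across runs", {
  N <- das_N()
  cols <- das("a")$expected$L_columns
  L5 <- do.call(cbind, c(cols[1:5], list(l8 = cols$l6 + cols$l7)))
  d1 <- fully_decompose(N, L5)
  d2 <- fully_decompose(N, L5)
  expect_identical(d1$D, d2$D)
})

test_that("elemental matrix decomposition spans the conservation relations", {
  net <- das()$network
  N <- das_N()
  dec <- decompose_matrix(N, elemental_matrix(net))
  expect_equal(ncol(dec$D), 7)
  for (j in seq_len(ncol(dec$D))) {
    expect_true(is_conservation_vector(N, dec$D[, j]))
  }
  expect_equal(exact_rank(dec$D), 7)
  # the oxygen column yields the alternate optimum in place of l6
  expect_true(paste(l9_vector(), collapse = ",") %in% col_set(dec$D))
  # DOPA decarboxylase elemental matrix: all outputs conserved
  dopa_N <- split_matrices(dopa()$network)$N
  dec2 <- decompose_matrix(dopa_N, elemental_matrix(dopa()$network))
  for (j in seq_len(ncol(dec2$D))) {
    expect_true(is_conservation_vector(dopa_N, dec2$D[, j]))
  }
})

test_that("electron vectors decompose like any conservation vector", {
  net <- dopa()$network
  e <- electron_vector(net)
  N <- split_matrices(net)$N
  expect_true(is_conservation_vector(N, e))
  dec <- decompose_matrix(N, matrix(e, ncol = 1))
  for (j in seq_len(ncol(dec$D))) {
    expect_true(is_conservation_vector(N, dec$D[, j]))
  }
  # a nondecomposable vector is returned unchanged
  single <- matrix(c(1, 0, 1, 0), ncol = 1)
  dec1 <- decompose_matrix(N, single)
  expect_equal(unname(dec1$D[, 1]), c(1, 0, 1, 0))
  expect_error(decompose_matrix(N, matrix(c(1, 0, 0, 0), ncol = 1)),
               "not conserved")
})
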