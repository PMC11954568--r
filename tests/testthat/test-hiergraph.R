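# Hierarchical graph construction: drug graphs from SMILES, protein graphs
# from contact maps, similarity blocks and the high-level adjacency.

test_that("build_drug_graph parses simple molecules correctly", {
  g <- build_drug_graph("CC")
  expect_equal(g$m, 2)
  expect_equal(sum(g$A) / 2, 1)
  expect_symmetric(g$A)
  expect_equal(diag(g$A), c(0, 0))

  benzene <- build_drug_graph("c1ccccc1")
  expect_equal(benzene$m, 6)
  expect_equal(sum(benzene$A) / 2, 6)
  expect_equal(as.vector(rowSums(benzene$A)), rep(2, 6))
  # aromatic bit is the last feature column
  expect_equal(benzene$X[, ncol(benzene$X)], rep(1, 6))
})

test_that("unparsable SMILES are rejected with the offending string", {
  expect_error(build_drug_graph("C("), "C\\(")
  expect_error(build_drug_graph(""), "non-empty")
})

test_that("equivalent SMILES yield isomorphic graphs", {
  for (pair in list(c("CCO", "OCC"), c("c1ccccc1", "C1=CC=CC=C1"),
                    c("CC(C)O", "OC(C)C"))) {
    g1 <- build_drug_graph(pair[1])
    g2 <- build_drug_graph(pair[2])
    expect_equal(g1$m, g2$m)
    expect_equal(sort(as.vector(rowSums(g1$A))),
                 sort(as.vector(rowSums(g2$A))))
    expect_equal(sort(g1$symbols), sort(g2$symbols))
  }
})

test_that("contact-map binarization thresholds at 0.5 and keeps backbone", {
  A0 <- binarize_contact_map(matrix(0, 3, 3))
  expect_equal(A0, matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3, 3))

  P <- matrix(0, 3, 3); P[1, 3] <- P[3, 1] <- 0.6
  expect_equal(binarize_contact_map(P)[1, 3], 1)
  P[1, 3] <- P[3, 1] <- 0.4
  expect_equal(binarize_contact_map(P)[1, 3], 0)

  # asymmetric input is symmetrized before thresholding
  P2 <- matrix(0, 3, 3); P2[1, 3] <- 1  # (1 + 0)/2 = 0.5 >= 0.5
  expect_equal(binarize_contact_map(P2)[3, 1], 1)

  expect_error(binarize_contact_map(matrix(0, 2, 3)), "square")
  expect_error(binarize_contact_map(matrix(2, 2, 2)), "\\[0, 1\\]")
})

test_that("protein graphs validate dimensions and separate features from adjacency", {
  g <- build_protein_graph("p", "ACD", matrix(0, 3, 3))
  expect_equal(g$n, 3)
  expect_equal(dim(g$X), c(3, 27))
  expect_equal(which(g$A == 1, arr.ind = TRUE)[, 1],
               c(2, 1, 3, 2), ignore_attr = TRUE)

  expect_error(build_protein_graph("p", "ACDEF", matrix(0, 4, 4)),
               "dimension mismatch.*5.*4x4")

  # permuting feature columns changes X but not A
  g2 <- build_protein_graph("p", "ACD", matrix(0, 3, 3),
                            features = g$X[, rev(seq_len(27))])
  expect_equal(g2$A, g$A)
  expect_false(isTRUE(all.equal(g2$X, g$X)))
})

test_that("common-neighbor similarity counts strictly above theta", {
  A <- matrix(1, 2, 2)
  expect_equal(common_neighbor_similarity(A, 1)$SD,
               matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(common_neighbor_similarity(A, 2)$SD, matrix(0, 2, 2))

  A2 <- diag(2)
  s <- common_neighbor_similarity(A2, 0)
  expect_equal(s$SD, matrix(0, 2, 2))
  expect_equal(s$SP, matrix(0, 2, 2))

  A3 <- matrix(c(1, 1, 1, 0), 2, 2)
  expect_equal(common_neighbor_similarity(A3, 0)$SD,
               matrix(c(0, 1, 1, 0), 2, 2))

  expect_error(common_neighbor_similarity(A, -1), "nonnegative")
})

test_that("similarity agrees with a brute-force double loop", {
  set.seed(42)
  for (theta in 0:3) {
    A <- matrix(rbinom(80, 1, 0.4), 10, 8)
    s <- common_neighbor_similarity(A, theta)
    SD_ref <- matrix(0, 10, 10)
    for (i in 1:10) for (j in 1:10) {
      if (i != j && sum(A[i, ] * A[j, ]) > theta) SD_ref[i, j] <- 1
    }
    SP_ref <- matrix(0, 8, 8)
    for (i in 1:8) for (j in 1:8) {
      if (i != j && sum(A[, i] * A[, j]) > theta) SP_ref[i, j] <- 1
    }
    expect_equal(s$SD, SD_ref)
    expect_equal(s$SP, SP_ref)
  }
})

test_that("high-level adjacency has the block layout and round-trips", {
  expect_equal(assemble_high_level_adjacency(matrix(1, 1, 1)),
               matrix(c(0, 1, 1, 0), 2, 2))

  A <- matrix(c(1, 1), 2, 1)
  SD <- matrix(c(0, 1, 1, 0), 2, 2)
  Ah <- assemble_high_level_adjacency(A, SD, matrix(0, 1, 1))
  expect_equal(dim(Ah), c(3, 3))
  expect_equal(Ah[1, 2], 1)  # SD edge
  expect_equal(Ah[1, 3], 1)  # DTI edge
  expect_equal(Ah[2, 3], 1)

  set.seed(1)
  A <- matrix(rbinom(12, 1, 0.5), 3, 4)
  SD <- random_adjacency(3); SP <- random_adjacency(4)
  Ah <- assemble_high_level_adjacency(A, SD, SP)
  expect_symmetric(Ah)
  # block round trip
  expect_equal(Ah[1:3, 1:3], SD)
  expect_equal(Ah[1:3, 4:7], A)
  expect_equal(Ah[4:7, 1:3], t(A))
  expect_equal(Ah[4:7, 4:7], SP)
  # similarity switched off zeroes SD/SP only
  Ah0 <- assemble_high_level_adjacency(A, SD, SP, include_similarity = FALSE)
  expect_equal(Ah0[1:3, 1:3], matrix(0, 3, 3))
  expect_equal(Ah0[1:3, 4:7], A)

  expect_error(assemble_high_level_adjacency(A, SP, SD), "shape mismatch")
})

test_that("adjacency normalization matches hand-computed values", {
  expect_equal(normalize_adjacency(matrix(0, 1, 1)), matrix(1, 1, 1))
  expect_equal(normalize_adjacency(matrix(c(0, 1, 1, 0), 2, 2)),
               matrix(0.5, 2, 2))

  path3 <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3, 3)
  Ah <- normalize_adjacency(path3)
  expect_equal(Ah[1, 2], 1 / sqrt(6))
  expect_equal(Ah[2, 2], 1 / 3)

  # isolated node row is a standard basis vector
  A <- matrix(0, 3, 3); A[1, 2] <- A[2, 1] <- 1
  expect_equal(normalize_adjacency(A)[3, ], c(0, 0, 1))

  expect_error(normalize_adjacency(matrix(c(0, 1, 0, 0), 2, 2)),
               "symmetric")
})

test_that("normalized adjacency has spectral radius at most one", {
  set.seed(7)
  for (i in 1:20) {
    A <- random_adjacency(sample(2:9, 1))
    ev <- eigen(normalize_adjacency(A), only.values = TRUE)$values
    expect_lte(max(abs(ev)), 1 + 1e-10)
  }
})

test_that("hetero graph constructor wires blocks and orders drugs first", {
  corpus <- small_corpus(4, 3)
  A <- corpus$latent$A_full
  hg <- hetero_dti_graph(corpus$drugs, corpus$proteins, A, theta = 0)
  expect_equal(hg$M, 4); expect_equal(hg$N, 3)
  expect_equal(hg$Ah[1:4, 5:7], A)
  expect_symmetric(hg$Ah)
  expect_error(hetero_dti_graph(corpus$drugs, corpus$proteins, t(A)),
               "drugs")
})
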