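# Shared fixture builders: everything is generated in code at test time.

# A tiny protein graph with a hand-set contact map.
tiny_protein <- function(id = "p1", sequence = "ACDEF", extra = NULL) {
  n <- nchar(sequence)
  P <- matrix(0, n, n)
  if (!is.null(extra)) {
    for (e in extra) {
      P[e[1], e[2]] <- e[3]
      P[e[2], e[1]] <- e[3]
    }
  }
  build_protein_graph(id, sequence, P)
}

# A small corpus with planted structure, cheap enough for unit tests.
small_corpus <- function(M = 10, N = 8, seed = 3) {
  synth_corpus(synth_config(n_drugs = M, n_proteins = N, rank = 2,
                            mol_size_range = c(4, 10),
                            protein_length_range = c(12, 25),
                            seed = seed))
}

# Random symmetric 0/1 adjacency with zero diagonal.
random_adjacency <- function(n, p = 0.4) {
  A <- matrix(0, n, n)
  up <- which(upper.tri(A))
  A[up] <- rbinom(length(up), 1, p)
  A + t(A)
}

expect_symmetric <- function(x, tol = 1e-12) {
  testthat::expect_lt(max(abs(x - t(x))), tol)
}
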