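# Synthetic corpus generator.

test_that("generated molecules are connected, valence-capped and seeded", {
  g1 <- gen_molecule(1, seed = 1)
  expect_equal(g1$m, 1)
  expect_equal(g1$A, matrix(0, 1, 1))

  caps <- c(C = 4, N = 3, O = 2)
  for (seed in 1:15) {
    g <- gen_molecule(sample(2:20, 1), seed = seed)
    expect_symmetric(g$A)
    expect_true(all(rowSums(g$A) <= caps[g$symbols]))
    # connectivity via reachability over powers of (A + I)
    reach <- diag(g$m) + g$A
    for (k in seq_len(g$m)) reach <- sign(reach %*% (diag(g$m) + g$A))
    expect_true(all(reach > 0))
  }
  expect_identical(gen_molecule(12, seed = 9), gen_molecule(12, seed = 9))
})

test_that("generated SMILES reparse to an isomorphic molecule", {
  for (seed in c(2, 5, 8, 13)) {
    g <- gen_molecule(10, seed = seed)
    expect_false(is.na(g$smiles))
    g2 <- build_drug_graph(g$smiles)
    expect_equal(g2$m, g$m)
    expect_equal(sum(g2$A), sum(g$A))
    expect_equal(sort(g2$symbols), sort(g$symbols))
    expect_equal(sort(as.vector(rowSums(g2$A))),
                 sort(as.vector(rowSums(g$A))))
  }
})

test_that("generated proteins have backbone contacts and symmetric maps", {
  p <- gen_protein(2, seed = 1)
  expect_equal(p$contact_probs, matrix(c(0, 1, 1, 0), 2, 2))

  p2 <- gen_protein(40, seed = 3)
  expect_symmetric(p2$contact_probs)
  expect_true(all(diag(p2$contact_probs) == 0))
  expect_true(all(p2$contact_probs[abs(row(p2$contact_probs) -
                                         col(p2$contact_probs)) == 1] == 1))
  expect_equal(nchar(p2$sequence), 40)
  expect_equal(dim(p2$features), c(40, 27))
})

test_that("long-range contact rate matches the configured mean", {
  cfg <- list(long_range_rate = 0.05, contact_decay = 20)
  rates <- vapply(1:50, function(s) {
    p <- gen_protein(120, contact_cfg = cfg, seed = 1000 + s)
    sep <- abs(row(p$contact_probs) - col(p$contact_probs))
    long <- p$contact_probs[sep >= 2 & upper.tri(p$contact_probs)]
    mean(long >= 0.5)
  }, 0)
  expect_lt(abs(mean(rates) - cfg$long_range_rate),
            0.2 * cfg$long_range_rate)
})

test_that("planted labels follow the logistic low-rank model", {
  # scale zero: pure coin flips, rate about one half
  p0 <- plant_interactions(60, 40, rank = 4, scale = 0, noise = 0,
                           seed = 2)
  se <- sqrt(0.25 / (60 * 40))
  expect_lt(abs(mean(p0$A) - 0.5), 3 * se)

  # saturated scale, no noise: labels equal the sign of u.v
  ps <- plant_interactions(20, 15, rank = 3, scale = 1e4, noise = 0,
                           seed = 3)
  expect_equal(ps$A, (ps$U %*% t(ps$V) > 0) * 1, ignore_attr = TRUE)

  # positive rate matches the analytic sigmoid expectation
  pm <- plant_interactions(60, 40, rank = 4, scale = 3, noise = 0,
                           seed = 4)
  expect_lt(abs(mean(pm$A) - mean(pm$prob)), 4 * sqrt(0.25 / (60 * 40)))

  expect_identical(plant_interactions(10, 8, 2, seed = 5),
                   plant_interactions(10, 8, 2, seed = 5))
})

test_that("the whole corpus is deterministic under a fixed seed", {
  c1 <- synth_corpus(synth_config(n_drugs = 6, n_proteins = 5, rank = 2,
                                  protein_length_range = c(10, 20),
                                  seed = 21))
  c2 <- synth_corpus(synth_config(n_drugs = 6, n_proteins = 5, rank = 2,
                                  protein_length_range = c(10, 20),
                                  seed = 21))
  expect_identical(c1$drugs, c2$drugs)
  expect_identical(c1$proteins, c2$proteins)
  expect_identical(c1$pairs, c2$pairs)
  expect_identical(c1$latent, c2$latent)
})
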