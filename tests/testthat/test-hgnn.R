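# High-level encoder: feature encoder, graph encoder and SAIF fusion.

test_that("feature encoder applies leaky-ReLU layers", {
  X <- matrix(c(-1, 2), 1, 2)
  id_params <- list(W = list(diag(2)), b = list(c(0, 0)), slope = 0.01)
  expect_equal(feature_encoder(X, id_params), matrix(c(-0.01, 2), 1, 2))
  nn <- matrix(c(0.5, 3), 1, 2)
  expect_equal(feature_encoder(nn, id_params), nn)
  zero <- list(W = list(matrix(0, 2, 3)), b = list(numeric(3)))
  expect_equal(feature_encoder(X, zero), matrix(0, 1, 3))
  expect_error(feature_encoder(X, list(W = list(matrix(0, 3, 2)),
                                       b = list(numeric(2)))),
               "width")
})

test_that("graph encoder is a tanh graph convolution with bounded output", {
  # single isolated node: Ahat = 1, one layer with scalar weight 1
  out <- graph_encoder(matrix(1), matrix(1), list(W = list(matrix(1))))
  expect_equal(out[1, 1], tanh(1), tolerance = 1e-6)
  expect_equal(graph_encoder(matrix(5), matrix(1),
                             list(W = list(matrix(0)))), matrix(0))
  set.seed(2)
  Ahat <- normalize_adjacency(random_adjacency(6))
  X <- matrix(rnorm(6 * 4, sd = 10), 6, 4)
  Z <- graph_encoder(X, Ahat, list(W = list(matrix(rnorm(4 * 3), 4, 3))))
  expect_lt(max(abs(Z)), 1)
})

test_that("SAIF combination is the stated linear mix and affine in alpha", {
  expect_equal(saif_combine(matrix(2), matrix(0), 0.5), matrix(1))
  ZFE <- matrix(rnorm(12), 4, 3); ZGE <- matrix(rnorm(12), 4, 3)
  expect_equal(saif_combine(ZFE, ZGE, 1), ZFE)
  expect_equal(saif_combine(ZFE, ZGE, 0), ZGE)
  # affine: Z(0.3) = 0.6 * Z(0.5) + 0.4 * Z(0)
  expect_equal(saif_combine(ZFE, ZGE, 0.3),
               0.6 * saif_combine(ZFE, ZGE, 0.5) +
                 0.4 * saif_combine(ZFE, ZGE, 0))
})

test_that("local enhancement is plain propagation", {
  expect_equal(saif_local(matrix(c(1, 3), 2, 1), matrix(0.5, 2, 2)),
               matrix(2, 2, 1))
  ZI <- matrix(rnorm(8), 4, 2)
  expect_equal(saif_local(ZI, diag(4)), ZI)
  expect_equal(saif_local(matrix(0, 4, 2), normalize_adjacency(random_adjacency(4))),
               matrix(0, 4, 2))
})

test_that("self-correlation is a row-stochastic softmax of the Gram matrix", {
  expect_equal(self_correlation(matrix(0, 3, 2)), matrix(1 / 3, 3, 3))
  expect_equal(self_correlation(matrix(2, 1, 1)), matrix(1))
  S <- self_correlation(matrix(c(1, 0), 2, 1))
  expect_equal(S, matrix(c(exp(1), 0.5, 1, 0.5) / c(exp(1) + 1, 1, exp(1) + 1, 1),
                         2, 2), tolerance = 1e-4)
  expect_equal(S[1, 1], 0.7311, tolerance = 1e-4)
  expect_equal(S[2, 1], 0.5)
})

test_that("self-correlation rows sum to one over many random draws", {
  set.seed(8)
  for (i in 1:1000) {
    ZL <- matrix(rnorm(5 * 3, sd = runif(1, 0.1, 20)), 5, 3)
    S <- self_correlation(ZL)
    expect_lt(max(abs(rowSums(S) - 1)), 1e-6)
    expect_true(all(S > 0))
  }
})

test_that("softmax rows are invariant to a per-row constant in the logits", {
  set.seed(9)
  ZL <- matrix(rnorm(12), 4, 3)
  C <- ZL %*% t(ZL)
  S1 <- hierdti:::row_softmax(C)
  C2 <- C; C2[2, ] <- C2[2, ] + 57
  S2 <- hierdti:::row_softmax(C2)
  expect_lt(max(abs(S1[2, ] - S2[2, ])), 1e-6)
  expect_equal(S1[-2, ], S2[-2, ])
})

test_that("saif_fuse applies the scaled skip connection", {
  ZL <- matrix(rnorm(6), 3, 2)
  S <- self_correlation(ZL)
  expect_equal(saif_fuse(ZL, S, 0), ZL)
  expect_equal(saif_fuse(matrix(2, 1, 1), matrix(1), 0.7), matrix(3.4))
  expect_equal(saif_fuse(matrix(c(1, 3), 2, 1), matrix(0.5, 2, 2), 0.7),
               matrix(c(2.4, 4.4), 2, 1))
})

test_that("hgnn_forward chains the stages with the right shape", {
  set.seed(3)
  n <- 6; d1 <- 5; d2 <- 2
  Xh <- matrix(rnorm(n * d1), n, d1)
  Ahat <- normalize_adjacency(random_adjacency(n))
  fe <- list(W = list(matrix(rnorm(d1 * 3), d1, 3),
                      matrix(rnorm(3 * d2), 3, d2)),
             b = list(numeric(3), numeric(d2)), slope = 0.01)
  ge <- list(W = list(matrix(rnorm(d1 * 3), d1, 3),
                      matrix(rnorm(3 * d2), 3, d2)))
  saif <- list(alpha = 0.5, beta = 0.7)
  Z <- hgnn_forward(Xh, Ahat, fe, ge, saif)
  expect_equal(dim(Z), c(n, d2))
  expect_identical(Z, hgnn_forward(Xh, Ahat, fe, ge, saif))
  # zero weights in both encoders give a zero embedding
  fe0 <- list(W = lapply(fe$W, function(w) w * 0), b = fe$b, slope = 0.01)
  ge0 <- list(W = lapply(ge$W, function(w) w * 0))
  expect_equal(hgnn_forward(Xh, Ahat, fe0, ge0, saif),
               matrix(0, n, d2))
})

test_that("the engine gradient of alpha matches finite differences", {
  corpus <- small_corpus(5, 4)
  ctl <- hierdti_control(epochs = 1, d1 = 6, d2 = 3, hidden = 4, seed = 1)
  drug_ids <- vapply(corpus$drugs, function(g) g$drug_id, "")
  prot_ids <- vapply(corpus$proteins, function(g) g$protein_id, "")
  pairs <- hierdti:::normalize_pairs(corpus$pairs, drug_ids, prot_ids)
  A <- matrix(0, 5, 4)
  A[as.matrix(pairs[pairs$label == 1, 1:2])] <- 1
  hg <- hetero_dti_graph(corpus$drugs, corpus$proteins, A)
  st <- hierdti:::build_engine_state(hg, as.matrix(pairs[, 1:2]),
                                     pairs$label, ctl, "full")
  params <- withr::with_seed(4, hierdti:::init_params(28, 27, ctl, "full"))
  cache <- hierdti:::engine_forward(st, params, keep = TRUE)
  grads <- hierdti:::engine_backward(st, params, cache)
  h <- 1e-5
  p1 <- params; p1$alpha <- p1$alpha + h
  p2 <- params; p2$alpha <- p2$alpha - h
  fd <- (hierdti:::engine_forward(st, p1, keep = FALSE)$loss -
           hierdti:::engine_forward(st, p2, keep = FALSE)$loss) / (2 * h)
  expect_lt(abs(grads$alpha - fd), 1e-4)
})
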