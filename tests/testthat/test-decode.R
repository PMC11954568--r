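# Decoder, reconstruction and the masked cross-entropy.

test_that("graph decoder matches hand evaluation and stays bounded", {
  out <- graph_decoder(matrix(0.5), matrix(1), list(W = list(matrix(1))))
  expect_equal(out[1, 1], tanh(0.5), tolerance = 1e-6)
  expect_equal(graph_decoder(matrix(3), matrix(1),
                             list(W = list(matrix(0)))), matrix(0))
  set.seed(4)
  Z <- matrix(rnorm(12, sd = 30), 4, 3)
  Ahat <- normalize_adjacency(random_adjacency(4))
  D <- graph_decoder(Z, Ahat, list(W = list(matrix(rnorm(9), 3, 3))))
  expect_lt(max(abs(D)), 1)
})

test_that("reconstruction is a sigmoid Gram matrix", {
  r <- reconstruct(matrix(0, 3, 2))
  expect_equal(r$yhat, matrix(0.5, 3, 3))
  r1 <- reconstruct(matrix(2, 1, 1))
  expect_equal(r1$yhat[1, 1], 1 / (1 + exp(-4)), tolerance = 1e-5)
  expect_equal(r1$yhat[1, 1], 0.98201, tolerance = 1e-4)
})

test_that("reconstruction symmetry, range and diagonal hold over random draws", {
  set.seed(6)
  for (i in 1:1000) {
    Z <- matrix(rnorm(5 * 3, sd = runif(1, 0.1, 5)), 5, 3)
    r <- reconstruct(Z, M = 3, N = 2)
    expect_symmetric(r$yhat, tol = 1e-6)
    expect_true(all(r$yhat > 0 & r$yhat < 1))
    expect_true(all(diag(r$yhat) >= 0.5))
    expect_equal(r$ydp, r$yhat[1:3, 4:5])
  }
})

test_that("masked BCE matches its closed forms", {
  y <- matrix(0.5, 3, 3)
  mask <- cbind(c(1, 2, 3), c(1, 2, 3))
  expect_equal(masked_bce(y, c(1, 0, 1), mask), log(2), tolerance = 1e-6)

  yhat <- matrix(0, 2, 2); yhat[1, 1] <- 1; yhat[2, 2] <- 0
  expect_lt(masked_bce(yhat, c(1, 0), cbind(c(1, 2), c(1, 2))), 1e-6)

  expect_equal(masked_bce(matrix(0.9), 1, cbind(1, 1)), -log(0.9),
               tolerance = 1e-6)

  expect_error(masked_bce(y, numeric(0), mask[0, , drop = FALSE]),
               "empty mask")
  expect_error(masked_bce(y, c(1, 2, 0), mask), "0 or 1")
})

test_that("masked BCE equals an independent scalar-loop oracle", {
  set.seed(10)
  for (rep in 1:20) {
    M <- 4; N <- 5
    ydp <- matrix(runif(M * N), M, N)
    k <- sample(2:8, 1)
    mask <- cbind(sample(M, k, replace = TRUE), sample(N, k, replace = TRUE))
    labels <- rbinom(k, 1, 0.5)
    acc <- 0
    for (r in seq_len(k)) {
      p <- min(max(ydp[mask[r, 1], mask[r, 2]], 1e-7), 1 - 1e-7)
      acc <- acc - labels[r] * log(p) - (1 - labels[r]) * log(1 - p)
    }
    expect_lt(abs(masked_bce(ydp, labels, mask) - acc / k), 1e-8)
  }
})

test_that("the loss strictly increases when correct scores drift toward 0.5", {
  labels <- c(1, 1, 0)
  mask <- cbind(1:3, 1:3)
  good <- matrix(0.5, 3, 3); good[cbind(1:3, 1:3)] <- c(0.95, 0.9, 0.05)
  worse <- matrix(0.5, 3, 3); worse[cbind(1:3, 1:3)] <- c(0.8, 0.75, 0.2)
  expect_lt(masked_bce(good, labels, mask), masked_bce(worse, labels, mask))
})

test_that("pair prediction is order-invariant and rejects unknown entities", {
  corpus <- small_corpus(6, 5)
  fit <- hierdti(corpus, control = hierdti_control(epochs = 3, seed = 2,
                                                   d1 = 8, d2 = 4,
                                                   hidden = 6))
  q <- data.frame(drug = c("D002", "D001", "D002"),
                  protein = c("P001", "P002", "P001"))
  s <- predict(fit, q)
  expect_true(all(s > 0 & s < 1))
  expect_equal(s[1], s[3])  # duplicate queries agree
  s_rev <- predict(fit, q[c(2, 1, 3), ])
  expect_equal(s_rev[2], s[1])
  expect_error(predict(fit, data.frame(drug = "nope", protein = "P001")),
               "unknown ids")
})

test_that("new entities can be appended and scored at masked positions", {
  corpus <- small_corpus(6, 5)
  fit <- hierdti(corpus, control = hierdti_control(epochs = 3, seed = 2,
                                                   d1 = 8, d2 = 4,
                                                   hidden = 6))
  extra <- gen_molecule(7, seed = 77, drug_id = "Dnew")
  s <- predict(fit, data.frame(drug = "Dnew", protein = "P001"),
               newdrugs = list(extra))
  expect_length(s, 1)
  expect_true(s > 0 && s < 1)
})
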