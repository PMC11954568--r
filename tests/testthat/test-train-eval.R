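# Splits, negative sampling, metrics, training behavior.

test_that("entity splits follow the 4:1 protocol and are seeded", {
  ids_d <- sprintf("d%02d", 1:10)
  ids_p <- sprintf("p%02d", 1:8)
  pairs <- expand.grid(drug = ids_d, protein = ids_p,
                       stringsAsFactors = FALSE)
  pairs$label <- rbinom(nrow(pairs), 1, 0.5)

  sp <- make_split(ids_d, ids_p, pairs, "S1", seed = 1)
  expect_equal(length(sp$train_drugs), 8)
  expect_equal(length(sp$test_drugs), 2)
  expect_equal(length(sp$train_proteins), 8)  # all proteins train side

  sp2 <- make_split(ids_d, ids_p, pairs, "S1", seed = 1)
  expect_identical(sp, sp2)

  expect_true(all(sp$test_pairs$drug %in% sp$test_drugs))
  expect_false(any(sp$train_pairs$drug %in% sp$test_drugs))
})

test_that("S3 splits have zero entity overlap across 100 random draws", {
  ids_d <- sprintf("d%02d", 1:12)
  ids_p <- sprintf("p%02d", 1:10)
  set.seed(0)
  pairs <- expand.grid(drug = ids_d, protein = ids_p,
                       stringsAsFactors = FALSE)
  pairs$label <- rbinom(nrow(pairs), 1, 0.5)
  for (seed in 1:100) {
    sp <- make_split(ids_d, ids_p, pairs, "S3", seed = seed)
    expect_equal(length(intersect(sp$test_pairs$drug, sp$train_pairs$drug)), 0)
    expect_equal(length(intersect(sp$test_pairs$protein,
                                  sp$train_pairs$protein)), 0)
    expect_true(all(sp$test_pairs$drug %in% sp$test_drugs))
    expect_true(all(sp$test_pairs$protein %in% sp$test_proteins))
  }
})

test_that("negative sampling is exact, disjoint and seeded", {
  set.seed(2)
  pos <- unique(cbind(sample(10, 60, TRUE), sample(12, 60, TRUE)))
  out <- sample_negatives(pos, 10, 12, ratio = 1, seed = 5)
  expect_equal(sum(out$label == 0), nrow(pos))
  key <- paste(out$drug, out$protein)
  expect_equal(anyDuplicated(key), 0)
  out2 <- sample_negatives(pos, 10, 12, ratio = 1, seed = 5)
  expect_identical(out, out2)
  # requesting more negatives than unknown pairs exist fails
  expect_error(sample_negatives(cbind(1, 1), 1, 2, ratio = 5, seed = 1),
               "unknown pairs")
})

test_that("metrics match hand-computed confusion and ranking values", {
  m <- evaluate_scores(c(0.9, 0.4, 0.6, 0.1), c(1, 1, 0, 0))
  expect_equal(m[["acc"]], 0.5)
  expect_equal(m[["precision"]], 0.5)
  expect_equal(m[["recall"]], 0.5)
  expect_equal(m[["f1"]], 0.5)

  perfect <- evaluate_scores(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(perfect[["auc"]], 1)
  expect_equal(perfect[["aupr"]], 1)

  expect_equal(evaluate_scores(c(0.4, 0.6), c(1, 0))[["auc"]], 0)
  expect_error(evaluate_scores(c(0.1, 0.2), c(1, 1)), "one positive")
})

test_that("rank AUC equals the brute-force pairwise comparison oracle", {
  set.seed(13)
  for (rep in 1:200) {
    n <- sample(6:30, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))  # both classes present
    scores <- round(runif(n), sample(c(1, 2, 6), 1))  # induce ties
    auc <- evaluate_scores(scores, labels)[["auc"]]
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    expect_lt(abs(auc - mean(cmp)), 1e-10)
  }
})

test_that("F1 is consistent with precision and recall", {
  set.seed(14)
  for (rep in 1:50) {
    n <- 40
    labels <- c(0, 1, rbinom(n - 2, 1, 0.4))
    m <- evaluate_scores(runif(n), labels)
    p <- m[["precision"]]; r <- m[["recall"]]
    f_ref <- if (p + r > 0) 2 * p * r / (p + r) else 0
    expect_lt(abs(m[["f1"]] - f_ref), 1e-9)
  }
})

test_that("training descends, moves alpha, and is seed-deterministic", {
  corpus <- small_corpus(8, 6)
  ctl <- hierdti_control(epochs = 25, seed = 3, d1 = 10, d2 = 4,
                         hidden = 6)
  fit <- hierdti(corpus, control = ctl)
  expect_lt(fit$train_loss, fit$history$loss[1])
  expect_true(all(is.finite(fit$history$loss)))
  expect_gt(abs(utils::tail(fit$history$alpha, 1) - 0.5), 0)

  fit2 <- hierdti(corpus, control = ctl)
  expect_identical(fit$history, fit2$history)
  expect_identical(fit$params, fit2$params)
})

test_that("dataset pair arithmetic follows the two labeling rules", {
  bal <- dti_dataset_stats(6647, 4294, 17511, "sampled", ratio = 1)
  expect_equal(bal$negatives, 17511)
  expect_equal(bal$interactions, 35022)

  aff <- dti_dataset_stats(68, 379, 7320, "all_unknown")
  expect_equal(aff$all_pairs, 25772)
  expect_equal(aff$negatives, 18452)
  expect_equal(aff$interactions, 25772)

  expect_error(dti_dataset_stats(2, 2, 5, "sampled"), "more positives")
})

test_that("planted structure is recovered well above a permutation control", {
  corpus <- synth_corpus(synth_config())
  fit <- hierdti(corpus, control = hierdti_control(seed = 7))
  auc <- fit$test_metrics[["auc"]]

  ctrl_corpus <- corpus
  A_perm <- withr::with_seed(7, matrix(sample(corpus$latent$A_full), 60, 40))
  pos <- which(A_perm == 1, arr.ind = TRUE)
  ctrl_corpus$pairs <- data.frame(drug = sprintf("D%03d", pos[, 1]),
                                  protein = sprintf("P%03d", pos[, 2]),
                                  label = 1)
  ctrl_fit <- hierdti(ctrl_corpus, control = hierdti_control(seed = 7))
  control_auc <- ctrl_fit$test_metrics[["auc"]]

  expect_gte(auc, 0.65)
  expect_lt(abs(control_auc - 0.5), 0.1)
  expect_gte(auc - control_auc, 0.15)
})
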