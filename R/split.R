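#' Sample negative drug-protein pairs
#'
#' Draws negatives uniformly without replacement from the pairs not listed
#' as positives, \code{floor(ratio * n_positives)} of them, and returns the
#' combined labeled pair set (positives labeled 1, sampled negatives 0).
#'
#' @param positives two-column matrix/data frame of (drug index, protein
#'   index) positive pairs, 1-based.
#' @param M,N numbers of drugs and proteins.
#' @param ratio negatives per positive (default 1).
#' @param seed integer seed.
#' @return data frame with columns \code{drug}, \code{protein},
#'   \code{label}.
#' @export
sample_negatives <- function(positives, M, N, ratio = 1, seed = 1L) {
  positives <- as.matrix(positives)[, 1:2, drop = FALSE]
  storage.mode(positives) <- "integer"
  if (any(positives[, 1L] < 1 | positives[, 1L] > M |
            positives[, 2L] < 1 | positives[, 2L] > N))
    stop("positive pair indices out of range", call. = FALSE)
  pos_lin <- unique((positives[, 2L] - 1L) * M + positives[, 1L])
  n_neg <- floor(ratio * length(pos_lin))
  avail <- M * N - length(pos_lin)
  if (n_neg > avail)
    stop(sprintf("requested %d negatives but only %d unknown pairs exist",
                 n_neg, avail), call. = FALSE)
  unknown <- setdiff(seq_len(M * N), pos_lin)
  neg_lin <- withr::with_seed(seed, sample(unknown, n_neg))
  rbind(
    data.frame(drug = ((pos_lin - 1L) %% M) + 1L,
               protein = ((pos_lin - 1L) %/% M) + 1L, label = 1),
    data.frame(drug = ((neg_lin - 1L) %% M) + 1L,
               protein = ((neg_lin - 1L) %/% M) + 1L, label = 0))
}

#' Cold-start train/test split
#'
#' Entity-level partitioning for the three cold-start protocols:
#' \describe{
#'   \item{S1 (new drug)}{drugs are split 4:1; training pairs are those of
#'     the training drugs (against all targets), test pairs those of the
#'     held-out drugs.}
#'   \item{S2 (new target)}{same with proteins.}
#'   \item{S3 (both)}{both entity sets are split; training pairs connect
#'     training drugs to training targets only, test pairs connect test
#'     drugs to test targets only (mixed pairs are dropped).}
#' }
#'
#' @param drug_ids,protein_ids character vectors of entity identifiers.
#' @param pairs data frame with columns \code{drug}, \code{protein} (ids or
#'   1-based indices) and \code{label}.
#' @param mode \code{"S1"}, \code{"S2"} or \code{"S3"}.
#' @param test_fraction held-out fraction of entities (default 0.2 = 4:1).
#' @param seed integer seed; the same seed reproduces the same split.
#' @return an object of class \code{"split_spec"} with the entity index
#'   partitions and the train/test pair tables (indices into
#'   \code{drug_ids}/\code{protein_ids}).
#' @export
make_split <- function(drug_ids, protein_ids, pairs,
                       mode = c("S1", "S2", "S3"), test_fraction = 0.2,
                       seed = 1L) {
  mode <- match.arg(mode)
  M <- length(drug_ids); N <- length(protein_ids)
  pairs <- normalize_pairs(pairs, drug_ids, protein_ids)

  split_entities <- function(n, sub_seed) {
    n_test <- round(test_fraction * n)
    if (n_test < 1 || n_test >= n)
      stop(sprintf("cannot hold out %d of %d entities", n_test, n),
           call. = FALSE)
    test <- sort(withr::with_seed(sub_seed, sample.int(n, n_test)))
    list(train = setdiff(seq_len(n), test), test = test)
  }

  train_drugs <- seq_len(M); test_drugs <- integer()
  train_proteins <- seq_len(N); test_proteins <- integer()
  if (mode %in% c("S1", "S3")) {
    sd <- split_entities(M, derive_seed(seed, 1L))
    train_drugs <- sd$train; test_drugs <- sd$test
  }
  if (mode %in% c("S2", "S3")) {
    sp <- split_entities(N, derive_seed(seed, 2L))
    train_proteins <- sp$train; test_proteins <- sp$test
  }

  in_train <- pairs$drug %in% train_drugs & pairs$protein %in% train_proteins
  in_test <- switch(mode,
    S1 = pairs$drug %in% test_drugs,
    S2 = pairs$protein %in% test_proteins,
    S3 = pairs$drug %in% test_drugs & pairs$protein %in% test_proteins)

  structure(list(mode = mode, seed = as.integer(seed),
                 train_drugs = train_drugs, test_drugs = test_drugs,
                 train_proteins = train_proteins,
                 test_proteins = test_proteins,
                 train_pairs = pairs[in_train, , drop = FALSE],
                 test_pairs = pairs[in_test, , drop = FALSE]),
            class = "split_spec")
}

# Accept id-based or index-based pair tables; return integer indices.
normalize_pairs <- function(pairs, drug_ids, protein_ids) {
  pairs <- as.data.frame(pairs)
  if (!all(c("drug", "protein") %in% names(pairs)))
    names(pairs)[1:2] <- c("drug", "protein")
  if (is.null(pairs$label)) pairs$label <- 1
  if (is.character(pairs$drug) || is.factor(pairs$drug)) {
    di <- match(as.character(pairs$drug), drug_ids)
    pi_ <- match(as.character(pairs$protein), protein_ids)
    bad <- is.na(di) | is.na(pi_)
    if (any(bad))
      stop("pairs reference unknown ids: ",
           paste(unique(c(as.character(pairs$drug)[is.na(di)],
                          as.character(pairs$protein)[is.na(pi_)])),
                 collapse = ", "), call. = FALSE)
    pairs$drug <- di; pairs$protein <- pi_
  }
  if (any(pairs$drug < 1 | pairs$drug > length(drug_ids) |
            pairs$protein < 1 | pairs$protein > length(protein_ids)))
    stop("pair indices out of range", call. = FALSE)
  if (!all(pairs$label %in% c(0, 1)))
    stop("pair labels must be 0/1", call. = FALSE)
  rownames(pairs) <- NULL
  pairs[, c("drug", "protein", "label")]
}

#' @export
print.split_spec <- function(x, ...) {
  cat(sprintf("Cold-start split %s (seed %d)\n", x$mode, x$seed))
  cat(sprintf("  drugs: %d train / %d test | proteins: %d train / %d test\n",
              length(x$train_drugs), length(x$test_drugs),
              length(x$train_proteins), length(x$test_proteins)))
  cat(sprintf("  pairs: %d train / %d test\n", nrow(x$train_pairs),
              nrow(x$test_pairs)))
  invisible(x)
}
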