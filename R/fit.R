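#' Fit the hierarchical heterogeneous DTI model
#'
#' End-to-end training of the two-level model: low-level GCN encoders turn
#' every drug molecular graph and protein residue graph into a
#' \code{d1}-dimensional vector; the high-level encoder (feature encoder +
#' graph encoder + SAIF fusion) produces a consensus embedding over the
#' bipartite DTI network; a symmetric graph decoder and an inner-product
#' reconstruction score every drug-protein pair; the masked binary
#' cross-entropy over the labeled training pairs is minimized with Adam.
#' Training is transductive: all entities are present in the high-level
#' graph, but interaction edges of held-out pairs are zeroed (masked), and
#' predictions are read at the masked positions.
#'
#' @param corpus a \code{dti_corpus}: list with \code{drugs} (list of
#'   \code{\link{build_drug_graph}}), \code{proteins} (list of
#'   \code{\link{build_protein_graph}}) and \code{pairs} (data frame
#'   \code{drug}, \code{protein}, \code{label}; ids or 1-based indices).
#'   If the pair table has no negatives, negatives are sampled at
#'   \code{control$negative_ratio} per positive.
#' @param split a \code{\link{make_split}} object, or \code{NULL} to create
#'   one from \code{control} (\code{mode}, \code{test_fraction},
#'   \code{seed}).
#' @param control a \code{\link{hierdti_control}}.
#' @param variant model variant: \code{"full"}, or an ablation —
#'   \code{"-L"} (sequence label-encoding + linear projection instead of
#'   the low-level GCNs), \code{"-F"} (graph encoder only: no feature
#'   encoder, no fusion), \code{"-W"} (fusion coefficient frozen at 0.5).
#' @return an object of class \code{"hierdti"} with the learned parameters,
#'   per-epoch \code{history} (loss and fusion coefficient), the split, the
#'   heterogeneous graph (with encoded \code{Xh}), the full bipartite score
#'   matrix, and train/test metric reports.
#' @seealso \code{\link{predict.hierdti}}, \code{\link{evaluate_scores}},
#'   \code{\link{synth_corpus}}
#' @examples
#' \donttest{
#' corpus <- synth_corpus(synth_config(n_drugs = 12, n_proteins = 8,
#'                                     seed = 1))
#' fit <- hierdti(corpus, control = hierdti_control(epochs = 5, seed = 1))
#' fit
#' }
#' @export
hierdti <- function(corpus, split = NULL, control = hierdti_control(),
                    variant = c("full", "-L", "-F", "-W")) {
  variant <- match.arg(variant)
  stopifnot(inherits(control, "hierdti_control"))
  corpus <- as_dti_corpus(corpus)
  drug_ids <- vapply(corpus$drugs, function(g) g$drug_id, "")
  protein_ids <- vapply(corpus$proteins, function(g) g$protein_id, "")
  M <- length(drug_ids); N <- length(protein_ids)

  pairs <- normalize_pairs(corpus$pairs, drug_ids, protein_ids)
  if (all(pairs$label == 1)) {
    n_unknown <- M * N - nrow(unique(pairs[, c("drug", "protein")]))
    ratio <- control$negative_ratio
    if (floor(ratio * nrow(pairs)) > n_unknown) {
      warning(sprintf(paste0("only %d unknown pairs available for negative",
                             " sampling; using all of them"), n_unknown),
              call. = FALSE)
      ratio <- n_unknown / nrow(pairs)
    }
    pairs <- sample_negatives(pairs[, c("drug", "protein")], M, N,
                              ratio = ratio,
                              seed = derive_seed(control$seed, 3L))
  }
  if (is.null(split)) {
    split <- make_split(drug_ids, protein_ids, pairs, mode = control$mode,
                        test_fraction = control$test_fraction,
                        seed = control$seed)
  }
  stopifnot(inherits(split, "split_spec"))
  if (nrow(split$train_pairs) == 0)
    stop("split has no training pairs", call. = FALSE)

  # masked interaction adjacency: training positives only
  A_train <- matrix(0, M, N)
  tp <- split$train_pairs
  A_train[cbind(tp$drug, tp$protein)[tp$label == 1, , drop = FALSE]] <- 1
  hg <- hetero_dti_graph(corpus$drugs, corpus$proteins, A_train)
  if (control$include_similarity && !is.null(control$theta)) {
    # similarity source: training-only DTIs (leak-free default), or the
    # full known positive table ("all": held-out entities keep edges)
    A_sim <- A_train
    if (identical(control$similarity_from, "all")) {
      A_sim <- matrix(0, M, N)
      A_sim[cbind(pairs$drug, pairs$protein)[pairs$label == 1, ,
                                             drop = FALSE]] <- 1
    }
    sim <- common_neighbor_similarity(A_sim, control$theta)
    hg$SD <- sim$SD
    hg$SP <- sim$SP
    hg$Ah <- assemble_high_level_adjacency(A_train, sim$SD, sim$SP)
  }

  st <- build_engine_state(hg, mask = as.matrix(tp[, c("drug", "protein")]),
                           labels = tp$label, control, variant)
  mu1 <- if (variant == "-L") NA_integer_ else ncol(corpus$drugs[[1]]$X)
  mu2 <- if (variant == "-L") NA_integer_ else ncol(corpus$proteins[[1]]$X)
  params <- withr::with_seed(derive_seed(control$seed, 4L),
                             init_params(mu1, mu2, control, variant))

  trained <- train_engine(st, params, control)
  sc <- engine_scores(st, trained$params)
  hg$Xh <- sc$Xh

  train_metrics <- tryCatch(
    evaluate_scores(sc$ydp[as.matrix(tp[, c("drug", "protein")])],
                    tp$label, control$threshold),
    error = function(e) NULL)
  test_metrics <- NULL
  if (nrow(split$test_pairs) > 0) {
    te <- split$test_pairs
    test_metrics <- tryCatch(
      evaluate_scores(sc$ydp[as.matrix(te[, c("drug", "protein")])],
                      te$label, control$threshold),
      error = function(e) NULL)
  }

  structure(list(params = trained$params, control = control,
                 variant = variant, split = split, hg = hg,
                 history = trained$history, ydp = sc$ydp,
                 train_loss = utils::tail(trained$history$loss, 1L),
                 train_metrics = train_metrics,
                 test_metrics = test_metrics,
                 drug_ids = drug_ids, protein_ids = protein_ids,
                 call = match.call()),
            class = "hierdti")
}

as_dti_corpus <- function(corpus) {
  if (inherits(corpus, "dti_corpus")) return(corpus)
  if (is.list(corpus) && all(c("drugs", "proteins", "pairs") %in%
                               names(corpus))) {
    class(corpus) <- c("dti_corpus", class(corpus))
    return(corpus)
  }
  stop("'corpus' must be a dti_corpus (drugs, proteins, pairs)",
       call. = FALSE)
}

#' @export
print.hierdti <- function(x, ...) {
  cat("Hierarchical heterogeneous DTI model",
      if (x$variant != "full") paste0("(variant ", x$variant, ")"), "\n")
  cat(sprintf("  %d drugs x %d proteins | split %s | %d epochs\n",
              x$hg$M, x$hg$N, x$split$mode, x$control$epochs))
  cat(sprintf("  final training loss %.5f", x$train_loss))
  a <- utils::tail(x$history$alpha, 1L)
  if (!is.na(a)) cat(sprintf(" | fusion alpha %.4f", a))
  cat("\n")
  if (!is.null(x$test_metrics)) {
    cat("  held-out: "); print(x$test_metrics)
  }
  invisible(x)
}

#' @export
summary.hierdti <- function(object, ...) {
  s <- list(variant = object$variant, control = object$control,
            split = object$split, history = object$history,
            train_loss = object$train_loss,
            train_metrics = object$train_metrics,
            test_metrics = object$test_metrics)
  class(s) <- "summary.hierdti"
  s
}

#' @export
print.summary.hierdti <- function(x, ...) {
  cat("Hierarchical heterogeneous DTI model",
      if (x$variant != "full") paste0("(variant ", x$variant, ")"), "\n\n")
  print(x$split)
  cat(sprintf("\nTraining: %d epochs, Adam lr %g, d1 = %d, d2 = %d, beta = %g\n",
              x$control$epochs, x$control$lr, x$control$d1, x$control$d2,
              x$control$beta))
  cat(sprintf("Loss: %.5f (epoch 1) -> %.5f (final)\n",
              x$history$loss[1L], x$train_loss))
  a <- utils::tail(x$history$alpha, 1L)
  if (!is.na(a))
    cat(sprintf("Fusion alpha: %.4f -> %.4f\n", x$history$alpha[1L], a))
  if (!is.null(x$train_metrics)) {
    cat("\nTraining pairs:  "); print(x$train_metrics)
  }
  if (!is.null(x$test_metrics)) {
    cat("Held-out pairs:  "); print(x$test_metrics)
  }
  invisible(x)
}

#' Extract learned parameters
#'
#' Returns the model parameters grouped by component (low-level drug and
#' protein GCN weights, feature-encoder weights and biases, graph-encoder
#' weights, decoder weights, and the fusion scalars), with the flat named
#' list attached as attribute \code{"flat"}.
#'
#' @param object a fitted \code{\link{hierdti}} model.
#' @param ... unused.
#' @export
coef.hierdti <- function(object, ...) {
  out <- params_as_components(object$params, object$control)
  attr(out, "flat") <- object$params
  out
}

#' Predict interaction scores
#'
#' Reads reconstruction scores at drug-protein pairs.  With no arguments,
#' the full bipartite score matrix of the fitted graph is returned.  A pair
#' table (entity ids or indices) selects individual scores; duplicate
#' queries return identical scores and the result is invariant to query
#' order.  Genuinely new entities can be appended via \code{newdrugs} /
#' \code{newproteins}: they join the high-level graph with all their
#' interaction entries masked (zero), the trained encoders embed them, and
#' their scores are read at the masked positions.
#'
#' @param object a fitted \code{\link{hierdti}} model.
#' @param pairs optional data frame with columns \code{drug},
#'   \code{protein} (ids or indices).
#' @param newdrugs,newproteins optional lists of
#'   \code{\link{build_drug_graph}} / \code{\link{build_protein_graph}}
#'   objects to append.
#' @param ... unused.
#' @return numeric vector of scores in (0, 1), or the full score matrix
#'   when \code{pairs} is \code{NULL}.
#' @export
predict.hierdti <- function(object, pairs = NULL, newdrugs = NULL,
                            newproteins = NULL, ...) {
  drug_ids <- object$drug_ids
  protein_ids <- object$protein_ids
  ydp <- object$ydp

  if (!is.null(newdrugs) || !is.null(newproteins)) {
    hg2 <- extend_hetero_graph(object$hg, newdrugs, newproteins)
    st <- build_engine_state(hg2, mask = matrix(1L, 1, 2), labels = 1,
                             object$control, object$variant)
    ydp <- engine_scores(st, object$params)$ydp
    drug_ids <- hg2$drug_ids
    protein_ids <- hg2$protein_ids
  }
  if (is.null(pairs)) {
    dimnames(ydp) <- list(drug_ids, protein_ids)
    return(ydp)
  }
  p <- normalize_pairs(pairs, drug_ids, protein_ids)
  ydp[cbind(p$drug, p$protein)]
}

extend_hetero_graph <- function(hg, newdrugs, newproteins) {
  drugs <- c(hg$drugs, newdrugs %||% list())
  proteins <- c(hg$proteins, newproteins %||% list())
  A <- matrix(0, length(drugs), length(proteins))
  A[seq_len(hg$M), seq_len(hg$N)] <- hg$A
  SD <- matrix(0, length(drugs), length(drugs))
  SD[seq_len(hg$M), seq_len(hg$M)] <- hg$SD
  SP <- matrix(0, length(proteins), length(proteins))
  SP[seq_len(hg$N), seq_len(hg$N)] <- hg$SP
  out <- hetero_dti_graph(drugs, proteins, A, include_similarity = FALSE)
  out$SD <- SD; out$SP <- SP
  out$Ah <- assemble_high_level_adjacency(A, SD, SP)
  out
}

#' @export
fitted.hierdti <- function(object, ...) {
  tp <- object$split$train_pairs
  object$ydp[as.matrix(tp[, c("drug", "protein")])]
}

#' Training-pair residuals
#'
#' Raw residuals \code{label - score} over the labeled training pairs.
#'
#' @param object a fitted \code{\link{hierdti}} model.
#' @param ... unused.
#' @export
residuals.hierdti <- function(object, ...) {
  object$split$train_pairs$label - fitted(object)
}

#' Plot training diagnostics
#'
#' Training loss per epoch and, for variants that learn it, the trajectory
#' of the fusion coefficient.
#'
#' @param x a fitted \code{\link{hierdti}} model.
#' @param ... passed to \code{plot}.
#' @export
plot.hierdti <- function(x, ...) {
  h <- x$history
  has_alpha <- !all(is.na(h$alpha))
  old <- graphics::par(mfrow = c(1L, 1L + has_alpha))
  on.exit(graphics::par(old))
  plot(h$epoch, h$loss, type = "l", xlab = "epoch",
       ylab = "masked BCE loss", main = "training loss", ...)
  if (has_alpha)
    plot(h$epoch, h$alpha, type = "l", xlab = "epoch",
         ylab = expression(alpha), main = "fusion coefficient", ...)
  invisible(x)
}

#' Simulate interaction labels from the fitted model
#'
#' Draws Bernoulli interaction matrices from the fitted pairwise
#' probabilities.
#'
#' @param object a fitted \code{\link{hierdti}} model.
#' @param nsim number of matrices to draw.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return list of \code{M x N} 0/1 matrices.
#' @export
simulate.hierdti <- function(object, nsim = 1, seed = NULL, ...) {
  draw <- function() {
    matrix(stats::rbinom(length(object$ydp), 1L, object$ydp),
           nrow(object$ydp), ncol(object$ydp))
  }
  if (!is.null(seed))
    withr::with_seed(seed, replicate(nsim, draw(), simplify = FALSE))
  else replicate(nsim, draw(), simplify = FALSE)
}
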