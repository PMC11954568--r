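# Network layer primitives.  Each function is a pure map used both by the
# user-facing encoders and by the training engine (which re-runs them with
# cached intermediates for backpropagation).

#' One graph-convolution layer
#'
#' \code{ReLU(Ahat \%*\% H \%*\% W)} where \code{Ahat} is the symmetric
#' normalized adjacency with self-loops (see
#' \code{\link{normalize_adjacency}}).  No bias term.
#'
#' @param H node-feature matrix (\code{m x f}).
#' @param Ahat normalized adjacency (\code{m x m}).
#' @param W weight matrix (\code{f x f'}).
#' @return \code{m x f'} matrix with nonnegative entries.
#' @export
gcn_layer <- function(H, Ahat, W) {
  check_matrix(H, "H"); check_matrix(Ahat, "Ahat"); check_matrix(W, "W")
  if (ncol(Ahat) != nrow(H) || ncol(H) != nrow(W))
    stop(sprintf("shape mismatch: Ahat %dx%d, H %dx%d, W %dx%d",
                 nrow(Ahat), ncol(Ahat), nrow(H), ncol(H),
                 nrow(W), ncol(W)), call. = FALSE)
  pmax(Ahat %*% H %*% W, 0)
}

#' Global mean pooling
#'
#' Column-wise mean of the node embedding matrix: one fixed-length vector
#' per graph, invariant to node ordering.
#'
#' @param H node embedding matrix (\code{m x d}), \code{m >= 1}.
#' @return \code{1 x d} matrix.
#' @export
global_mean_pool <- function(H) {
  check_matrix(H, "H")
  if (nrow(H) < 1) stop("cannot pool an empty graph", call. = FALSE)
  matrix(colMeans(H), 1L)
}

#' Feature encoder (stacked leaky-ReLU dense layers)
#'
#' Applies \code{LeakyReLU(Z \%*\% W + b)} for each layer.  Weights are
#' stored samples-as-rows (input width times output width), mathematically
#' identical to the column-vector convention.
#'
#' @param X input matrix, rows are entities.
#' @param params list with \code{W} (list of weight matrices), \code{b}
#'   (list of bias vectors) and \code{slope} (leaky negative-branch slope,
#'   default 0.01).
#' @return encoded matrix.
#' @export
feature_encoder <- function(X, params) {
  check_matrix(X, "X")
  slope <- params$slope %||% 0.01
  Z <- X
  for (l in seq_along(params$W)) {
    W <- params$W[[l]]
    if (ncol(Z) != nrow(W))
      stop(sprintf("feature encoder layer %d: input width %d != %d",
                   l, ncol(Z), nrow(W)), call. = FALSE)
    P <- Z %*% W
    P <- sweep(P, 2L, params$b[[l]], `+`)
    Z <- ifelse(P >= 0, P, slope * P)
  }
  Z
}

#' Graph encoder (stacked tanh graph convolutions)
#'
#' Applies \code{tanh(Ahat \%*\% Z \%*\% W)} per layer over the high-level
#' normalized adjacency; no biases.  All outputs lie in \code{(-1, 1)}.
#'
#' @param X input matrix, rows are high-level nodes.
#' @param Ahat normalized high-level adjacency.
#' @param params list with \code{W}, a list of weight matrices.
#' @return encoded matrix.
#' @export
graph_encoder <- function(X, Ahat, params) {
  check_matrix(X, "X"); check_matrix(Ahat, "Ahat")
  Z <- X
  for (l in seq_along(params$W)) {
    W <- params$W[[l]]
    if (ncol(Z) != nrow(W) || ncol(Ahat) != nrow(Z))
      stop(sprintf("graph encoder layer %d: shape mismatch", l),
           call. = FALSE)
    Z <- tanh(Ahat %*% Z %*% W)
  }
  # keep the open-interval range contract despite tanh saturating to
  # exactly +/-1 in floating point for |x| > ~19
  sign(Z) * pmin(abs(Z), 1 - 1e-12)
}

#' Linear combination of feature- and graph-encoder embeddings
#'
#' \code{alpha * ZFE + (1 - alpha) * ZGE}; \code{alpha} is the learnable
#' fusion coefficient (initialized at 0.5 during training).
#'
#' @param ZFE,ZGE equally shaped embedding matrices.
#' @param alpha scalar mixing coefficient.
#' @export
saif_combine <- function(ZFE, ZGE, alpha) {
  check_matrix(ZFE, "ZFE"); check_matrix(ZGE, "ZGE")
  if (!all(dim(ZFE) == dim(ZGE)))
    stop("ZFE and ZGE must have identical shapes", call. = FALSE)
  alpha * ZFE + (1 - alpha) * ZGE
}

#' Local structure enhancement
#'
#' One unweighted message-passing step \code{Ahat \%*\% ZI} smoothing the
#' fused embedding over the high-level graph.
#'
#' @param ZI fused embedding.
#' @param Ahat normalized high-level adjacency.
#' @export
saif_local <- function(ZI, Ahat) {
  check_matrix(ZI, "ZI"); check_matrix(Ahat, "Ahat")
  if (ncol(Ahat) != nrow(ZI))
    stop("shape mismatch between Ahat and ZI", call. = FALSE)
  Ahat %*% ZI
}

#' Normalized self-correlation matrix
#'
#' Row-softmax of the Gram matrix \code{ZL \%*\% t(ZL)}, computed with
#' per-row max subtraction for numerical stability.  Every row sums to 1 and
#' every entry is strictly positive.
#'
#' @param ZL locally enhanced embedding.
#' @return row-stochastic square matrix.
#' @export
self_correlation <- function(ZL) {
  check_matrix(ZL, "ZL")
  row_softmax(ZL %*% t(ZL))
}

#' Global recombination with skip connection
#'
#' \code{beta * S \%*\% ZL + ZL}: recombines the embedding through the
#' self-correlation coefficients and keeps a skip connection so information
#' passes smoothly through the fusion mechanism.
#'
#' @param ZL locally enhanced embedding.
#' @param S row-stochastic self-correlation matrix.
#' @param beta fixed scale parameter (0.7 by default in training).
#' @export
saif_fuse <- function(ZL, S, beta) {
  check_matrix(ZL, "ZL"); check_matrix(S, "S")
  if (ncol(S) != nrow(ZL) || nrow(S) != nrow(ZL))
    stop("shape mismatch between S and ZL", call. = FALSE)
  beta * (S %*% ZL) + ZL
}

#' High-level encoder forward pass
#'
#' Chains the feature encoder, graph encoder and the structure-and-attribute
#' information fusion (SAIF) steps into the consensus embedding.
#'
#' @param Xh high-level node features (rows: drugs then proteins).
#' @param Ahat normalized high-level adjacency.
#' @param fe feature-encoder parameters (see \code{\link{feature_encoder}}).
#' @param ge graph-encoder parameters (see \code{\link{graph_encoder}}).
#' @param saif list with scalars \code{alpha} and \code{beta}.
#' @return consensus embedding matrix \code{(M+N) x d2}.
#' @export
hgnn_forward <- function(Xh, Ahat, fe, ge, saif) {
  ZFE <- feature_encoder(Xh, fe)
  ZGE <- graph_encoder(Xh, Ahat, ge)
  ZI <- saif_combine(ZFE, ZGE, saif$alpha)
  ZL <- saif_local(ZI, Ahat)
  S <- self_correlation(ZL)
  saif_fuse(ZL, S, saif$beta)
}

#' Graph decoder (symmetric to the graph encoder)
#'
#' Stacked \code{tanh(Ahat \%*\% Z \%*\% W)} layers widening the consensus
#' embedding back out before link reconstruction.
#'
#' @param Z consensus embedding.
#' @param Ahat normalized high-level adjacency.
#' @param params list with \code{W}, a list of weight matrices.
#' @export
graph_decoder <- function(Z, Ahat, params) {
  graph_encoder(Z, Ahat, params)
}

#' Inner-product link reconstruction
#'
#' Scores every node pair as the sigmoid of the embedding Gram matrix,
#' \code{sigmoid(Z \%*\% t(Z))}.  The result is symmetric with entries
#' strictly in \code{(0, 1)} and diagonal at least 0.5.
#'
#' @param Z final decoder embedding (\code{(M+N) x d}).
#' @param M,N optional drug/protein counts; when supplied, the bipartite
#'   \code{M x N} view is attached.
#' @return an object of class \code{"dti_prediction"} with fields
#'   \code{yhat} (full matrix) and \code{ydp} (bipartite block or
#'   \code{NULL}).
#' @export
reconstruct <- function(Z, M = NULL, N = NULL) {
  check_matrix(Z, "Z")
  # clamp away from 0/1 so the strict range contract survives floating
  # point saturation of the sigmoid at |score| > ~37
  yhat <- pmin(pmax(sigmoid(Z %*% t(Z)), 1e-12), 1 - 1e-12)
  ydp <- NULL
  if (!is.null(M) && !is.null(N)) {
    if (M + N != nrow(Z))
      stop("M + N must equal nrow(Z)", call. = FALSE)
    ydp <- yhat[seq_len(M), M + seq_len(N), drop = FALSE]
  }
  structure(list(yhat = yhat, ydp = ydp), class = "dti_prediction")
}

#' @export
print.dti_prediction <- function(x, ...) {
  cat("DTI reconstruction:", nrow(x$yhat), "x", ncol(x$yhat),
      "score matrix\n")
  if (!is.null(x$ydp))
    cat("  bipartite block:", nrow(x$ydp), "x", ncol(x$ydp), "\n")
  invisible(x)
}

#' Masked binary cross-entropy
#'
#' Mean of \code{-y log(p) - (1-y) log(1-p)} over the labeled training
#' pairs inside the drug-by-protein score block.  Scores are clamped to
#' \code{[eps, 1-eps]} before the logarithms.
#'
#' @param ydp \code{M x N} score matrix (bipartite block).
#' @param labels 0/1 vector, one per masked pair.
#' @param mask two-column integer matrix of (drug row, protein column)
#'   indices selecting the labeled pairs.
#' @param eps clamp width, default \code{1e-7}.
#' @return scalar loss.
#' @export
masked_bce <- function(ydp, labels, mask, eps = 1e-7) {
  check_matrix(ydp, "ydp")
  mask <- as.matrix(mask)
  if (nrow(mask) == 0) stop("empty mask", call. = FALSE)
  if (ncol(mask) != 2) stop("'mask' must have two columns", call. = FALSE)
  if (length(labels) != nrow(mask))
    stop("'labels' length must match the mask", call. = FALSE)
  if (!all(labels %in% c(0, 1)))
    stop("labels must be 0 or 1", call. = FALSE)
  p <- pmin(pmax(ydp[mask], eps), 1 - eps)
  mean(-labels * log(p) - (1 - labels) * log(1 - p))
}
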