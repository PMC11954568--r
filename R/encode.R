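#' Encode one entity graph into its fixed-length vector
#'
#' Runs the low-level GCN encoder: \code{K} stacked
#' \code{\link{gcn_layer}} applications over the entity's normalized
#' adjacency, then \code{\link{global_mean_pool}}.  The result is invariant
#' to node relabeling (adjacency and features permuted consistently).
#'
#' @param graph a \code{\link{build_drug_graph}} or
#'   \code{\link{build_protein_graph}} object.
#' @param weights list of GCN weight matrices (first input width must equal
#'   the graph's feature width; last output width is \code{d1}).
#' @return \code{1 x d1} matrix.
#' @export
encode_entity <- function(graph, weights) {
  if (!inherits(graph, c("drug_graph", "protein_graph")))
    stop("'graph' must be a drug_graph or protein_graph", call. = FALSE)
  stopifnot(is.list(weights), length(weights) >= 1)
  if (ncol(graph$X) != nrow(weights[[1L]]))
    stop(sprintf("feature width %d does not match first weight matrix (%d rows)",
                 ncol(graph$X), nrow(weights[[1L]])), call. = FALSE)
  Ahat <- normalize_adjacency(graph$A)
  H <- graph$X
  for (k in seq_along(weights)) H <- gcn_layer(H, Ahat, weights[[k]])
  global_mean_pool(H)
}

#' Encode every entity of a heterogeneous DTI graph
#'
#' Applies the drug branch of the low-level encoder to every drug graph and
#' the protein branch to every protein graph, stacks the vectors into the
#' high-level node feature matrix \code{Xh} (drug rows first), and stores
#' it on the graph object.
#'
#' @param hg a \code{\link{hetero_dti_graph}}.
#' @param params list with \code{lgnn_drug} and \code{lgnn_protein} weight
#'   lists (as produced during fitting; see
#'   \code{\link[=coef.hierdti]{coef}}).
#' @return the graph with its \code{Xh} slot filled
#'   (\code{(M+N) x d1} matrix).
#' @export
encode_all_entities <- function(hg, params) {
  stopifnot(inherits(hg, "hetero_dti_graph"))
  rows_d <- lapply(hg$drugs, encode_entity, weights = params$lgnn_drug)
  rows_p <- lapply(hg$proteins, encode_entity,
                   weights = params$lgnn_protein)
  hg$Xh <- do.call(rbind, c(rows_d, rows_p))
  hg
}
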