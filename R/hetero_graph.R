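#' Common-neighbor similarity graphs over the DTI bipartite adjacency
#'
#' Two drugs are deemed similar when they share strictly more than
#' \code{theta} interacting proteins; two proteins when they share strictly
#' more than \code{theta} interacting drugs.  Both outputs are symmetric 0/1
#' matrices with zero diagonals.
#'
#' @param A \code{M x N} binary drug-protein interaction matrix.
#' @param theta nonnegative integer common-neighbor threshold.
#' @return list with components \code{SD} (\code{M x M}) and \code{SP}
#'   (\code{N x N}).
#' @examples
#' A <- matrix(c(1, 1, 1, 1), 2, 2)
#' common_neighbor_similarity(A, theta = 1)$SD
#' @export
common_neighbor_similarity <- function(A, theta) {
  check_binary_matrix(A, "A")
  if (length(theta) != 1 || is.na(theta) || theta < 0 ||
      theta != floor(theta))
    stop("'theta' must be a nonnegative integer", call. = FALSE)
  SD <- (A %*% t(A) > theta) * 1
  SP <- (t(A) %*% A > theta) * 1
  diag(SD) <- 0
  diag(SP) <- 0
  list(SD = SD, SP = SP)
}

#' Assemble the high-level block adjacency
#'
#' Lays out the \code{(M+N) x (M+N)} heterogeneous adjacency
#' \code{rbind(cbind(SD, A), cbind(t(A), SP))}: drugs occupy rows/columns
#' \code{1..M}, proteins \code{M+1..M+N}.  With \code{include_similarity =
#' FALSE} only the known interactions form edges and the SD/SP blocks are
#' zero (the configuration used when the entity sets are large).
#'
#' @param A \code{M x N} bipartite interaction matrix.
#' @param SD,SP optional drug/protein similarity blocks; zero when omitted.
#' @param include_similarity keep the SD/SP blocks (default \code{TRUE}).
#' @return symmetric \code{(M+N) x (M+N)} 0/1 matrix.
#' @export
assemble_high_level_adjacency <- function(A, SD = NULL, SP = NULL,
                                          include_similarity = TRUE) {
  check_binary_matrix(A, "A")
  M <- nrow(A); N <- ncol(A)
  if (is.null(SD) || !include_similarity) SD <- matrix(0, M, M)
  if (is.null(SP) || !include_similarity) SP <- matrix(0, N, N)
  check_binary_matrix(SD, "SD"); check_binary_matrix(SP, "SP")
  if (nrow(SD) != M || ncol(SD) != M || nrow(SP) != N || ncol(SP) != N)
    stop(sprintf("shape mismatch: A is %dx%d but SD is %dx%d and SP is %dx%d",
                 M, N, nrow(SD), ncol(SD), nrow(SP), ncol(SP)),
         call. = FALSE)
  rbind(cbind(SD, A), cbind(t(A), SP))
}

#' Symmetric GCN normalization with self-loops
#'
#' Computes \code{D^{-1/2} (A + I) D^{-1/2}} where \code{D} is the diagonal
#' degree matrix of \code{A + I}.  Rows of isolated nodes come out as the
#' corresponding standard basis vector (self-loop only).
#'
#' @param A square symmetric 0/1 matrix.
#' @return symmetric normalized adjacency of the same dimension.
#' @examples
#' normalize_adjacency(matrix(c(0, 1, 1, 0), 2, 2))  # all entries 0.5
#' @export
normalize_adjacency <- function(A) {
  check_binary_matrix(A, "A")
  check_symmetric(A, "A")
  At <- A + diag(nrow(A))
  dinv <- 1 / sqrt(rowSums(At))
  At * outer(dinv, dinv)
}

#' Construct the two-level heterogeneous DTI graph
#'
#' Bundles drug molecular graphs, protein residue graphs and the bipartite
#' interaction matrix into the high-level heterogeneous graph.  Optional
#' drug/drug and protein/protein similarity edges come from
#' \code{\link{common_neighbor_similarity}} applied to a (possibly masked)
#' interaction matrix — pass the training-only adjacency there to avoid
#' label leakage.
#'
#' @param drugs list of \code{\link{build_drug_graph}} objects (length M).
#' @param proteins list of \code{\link{build_protein_graph}} objects
#'   (length N).
#' @param A \code{M x N} binary interaction matrix (typically with held-out
#'   entries already zeroed).
#' @param theta common-neighbor threshold for the similarity blocks;
#'   \code{NULL} disables them.
#' @param include_similarity keep similarity blocks in \code{Ah}.
#' @return an object of class \code{"hetero_dti_graph"}: the entity lists,
#'   id vectors, \code{A}, \code{SD}, \code{SP}, the assembled block
#'   adjacency \code{Ah}, counts \code{M}, \code{N}, and an \code{Xh} slot
#'   (\code{NULL} until filled by \code{\link{encode_all_entities}}).
#' @export
hetero_dti_graph <- function(drugs, proteins, A, theta = NULL,
                             include_similarity = !is.null(theta)) {
  stopifnot(is.list(drugs), is.list(proteins))
  if (!all(vapply(drugs, inherits, TRUE, "drug_graph")))
    stop("'drugs' must be a list of drug_graph objects", call. = FALSE)
  if (!all(vapply(proteins, inherits, TRUE, "protein_graph")))
    stop("'proteins' must be a list of protein_graph objects", call. = FALSE)
  M <- length(drugs); N <- length(proteins)
  check_binary_matrix(A, "A")
  if (nrow(A) != M || ncol(A) != N)
    stop(sprintf("A is %dx%d but there are %d drugs and %d proteins",
                 nrow(A), ncol(A), M, N), call. = FALSE)
  if (include_similarity && !is.null(theta)) {
    sim <- common_neighbor_similarity(A, theta)
    SD <- sim$SD; SP <- sim$SP
  } else {
    SD <- matrix(0, M, M); SP <- matrix(0, N, N)
  }
  Ah <- assemble_high_level_adjacency(A, SD, SP,
                                      include_similarity = include_similarity)
  structure(list(drugs = drugs, proteins = proteins,
                 drug_ids = vapply(drugs, function(g) g$drug_id, ""),
                 protein_ids = vapply(proteins, function(g) g$protein_id, ""),
                 A = A, SD = SD, SP = SP, Ah = Ah, M = M, N = N, Xh = NULL),
            class = "hetero_dti_graph")
}

#' @export
print.hetero_dti_graph <- function(x, ...) {
  cat("Heterogeneous DTI graph:", x$M, "drugs x", x$N, "proteins\n")
  cat("  known interactions:", sum(x$A),
      "| similarity edges:", sum(x$SD) / 2, "drug,", sum(x$SP) / 2,
      "protein\n")
  cat("  Xh:", if (is.null(x$Xh)) "not encoded" else
    paste(dim(x$Xh), collapse = " x "), "\n")
  invisible(x)
}
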