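#' Threshold a residue contact-probability map into a 0/1 adjacency
#'
#' Symmetrizes the probability matrix as \code{(P + t(P))/2}, sets an edge
#' wherever the symmetrized probability is at least \code{threshold}
#' (off-diagonal only), and always includes the sequence backbone
#' (\code{|i - j| == 1}) so the residue graph is connected and message
#' passing reaches every node.
#'
#' @param contact_probs square numeric matrix with entries in \code{[0, 1]}.
#' @param threshold contact probability cut-off, default 0.5.
#' @return symmetric 0/1 matrix with zero diagonal.
#' @examples
#' P <- matrix(0, 3, 3); P[1, 3] <- P[3, 1] <- 0.6
#' binarize_contact_map(P)
#' @export
binarize_contact_map <- function(contact_probs, threshold = 0.5) {
  check_matrix(contact_probs, "contact_probs")
  if (nrow(contact_probs) != ncol(contact_probs))
    stop("'contact_probs' must be square", call. = FALSE)
  if (min(contact_probs) < 0 || max(contact_probs) > 1)
    stop("'contact_probs' entries must lie in [0, 1]", call. = FALSE)
  n <- nrow(contact_probs)
  P <- (contact_probs + t(contact_probs)) / 2
  A <- (P >= threshold) * 1
  diag(A) <- 0
  if (n > 1) {
    idx <- cbind(seq_len(n - 1L), 2:n)
    A[idx] <- 1
    A[idx[, 2:1, drop = FALSE]] <- 1
  }
  A
}

#' Build a protein residue graph
#'
#' Combines an amino-acid sequence, a residue-residue contact-probability
#' map and a per-residue descriptor matrix (e.g. a PSSM) into a residue
#' graph.  The adjacency comes from \code{\link{binarize_contact_map}}; the
#' descriptor matrix is stored unchanged.  When no descriptors are supplied,
#' the deterministic built-in \code{\link{residue_features}} stand-in is
#' computed from the sequence.
#'
#' @param protein_id identifier stored with the graph.
#' @param sequence amino-acid string of length \code{n}.
#' @param contact_probs \code{n x n} contact-probability matrix.
#' @param features optional \code{n x mu2} per-residue descriptor matrix.
#' @param threshold contact cut-off passed to
#'   \code{\link{binarize_contact_map}}.
#' @return an object of class \code{"protein_graph"} with fields
#'   \code{protein_id}, \code{sequence}, \code{n}, \code{X} and \code{A}.
#' @examples
#' g <- build_protein_graph("p1", "ACD", matrix(0, 3, 3))
#' g$A  # backbone edges only
#' @export
build_protein_graph <- function(protein_id, sequence, contact_probs,
                                features = NULL, threshold = 0.5) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  n <- nchar(sequence)
  if (is.null(features)) features <- residue_features(sequence)
  check_matrix(features, "features")
  if (n != nrow(contact_probs) || n != nrow(features))
    stop(sprintf(paste0("dimension mismatch for protein '%s': sequence ",
                        "length %d, contact map %dx%d, features %d rows"),
                 protein_id, n, nrow(contact_probs), ncol(contact_probs),
                 nrow(features)), call. = FALSE)
  A <- binarize_contact_map(contact_probs, threshold)
  structure(list(protein_id = protein_id, sequence = sequence, n = n,
                 X = features, A = A, contact_probs = contact_probs),
            class = "protein_graph")
}

#' @export
print.protein_graph <- function(x, ...) {
  cat("Protein graph", x$protein_id, "\n")
  cat("  ", x$n, " residues, ", sum(x$A) / 2, " contacts, feature width ",
      ncol(x$X), "\n", sep = "")
  invisible(x)
}
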