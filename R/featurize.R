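#' Atom featurizer
#'
#' Defines the per-atom descriptor vector used to populate the feature matrix
#' \code{Xd} of a drug molecular graph.  The descriptor is the concatenation
#' of a one-hot element symbol (over a fixed vocabulary plus a catch-all
#' \emph{other} slot), a one-hot heavy-atom degree, a one-hot total hydrogen
#' count, a one-hot implicit valence, and a single aromaticity bit.  The
#' output width is fixed once the featurizer is constructed and the mapping
#' is deterministic: the same atom always yields the same vector.
#'
#' @param symbols ordered element vocabulary for the one-hot block; a final
#'   catch-all \code{"other"} slot is always appended.
#' @param degree_max largest heavy-atom degree with its own slot (one-hot
#'   over \code{0:degree_max}, values above clip to the last slot).
#' @param hydrogens_max largest total hydrogen count with its own slot.
#' @param valence_max largest implicit valence with its own slot.
#' @param aromatic include the aromaticity bit.
#' @return an object of class \code{"atom_featurizer"} with a \code{$width}
#'   field giving the descriptor dimension.
#' @examples
#' fz <- atom_featurizer()
#' fz$width
#' @export
atom_featurizer <- function(symbols = c("C", "N", "O", "S", "F", "P",
                                        "Cl", "Br", "I"),
                            degree_max = 5L, hydrogens_max = 4L,
                            valence_max = 5L, aromatic = TRUE) {
  stopifnot(length(symbols) >= 1, degree_max >= 0, hydrogens_max >= 0,
            valence_max >= 0)
  fz <- list(symbols = as.character(symbols),
             degree_max = as.integer(degree_max),
             hydrogens_max = as.integer(hydrogens_max),
             valence_max = as.integer(valence_max),
             aromatic = isTRUE(aromatic))
  fz$width <- (length(fz$symbols) + 1L) + (fz$degree_max + 1L) +
    (fz$hydrogens_max + 1L) + (fz$valence_max + 1L) +
    as.integer(fz$aromatic)
  class(fz) <- "atom_featurizer"
  fz
}

#' @export
print.atom_featurizer <- function(x, ...) {
  cat("Atom featurizer: width", x$width, "\n")
  cat("  symbols:", paste(c(x$symbols, "other"), collapse = " "), "\n")
  cat("  degree 0:", x$degree_max, " hydrogens 0:", x$hydrogens_max,
      " valence 0:", x$valence_max,
      if (x$aromatic) " + aromatic bit" else "", "\n", sep = "")
  invisible(x)
}

one_hot <- function(value, n_slots) {
  v <- numeric(n_slots)
  v[min(value, n_slots - 1L) + 1L] <- 1
  v
}

# Vectorized featurization of a set of atoms.
featurize_atoms <- function(fz, symbols, degrees, hydrogens, valences,
                            aromatic_flags) {
  stopifnot(inherits(fz, "atom_featurizer"))
  m <- length(symbols)
  out <- matrix(0, m, fz$width)
  nsym <- length(fz$symbols) + 1L
  for (i in seq_len(m)) {
    idx <- match(symbols[i], fz$symbols)
    sym <- numeric(nsym)
    sym[if (is.na(idx)) nsym else idx] <- 1
    row <- c(sym,
             one_hot(max(0L, degrees[i]), fz$degree_max + 1L),
             one_hot(max(0L, hydrogens[i]), fz$hydrogens_max + 1L),
             one_hot(max(0L, valences[i]), fz$valence_max + 1L))
    if (fz$aromatic) row <- c(row, as.numeric(isTRUE(aromatic_flags[i])))
    out[i, ] <- row
  }
  out
}

# Default valences of the elements the package generates or commonly meets;
# used to infer implicit hydrogen counts from the heavy-atom bond order sum.
.default_valence <- c(C = 4, N = 3, O = 2, S = 2, F = 1, P = 3,
                      Cl = 1, Br = 1, I = 1, B = 3, Si = 4, Se = 2)

#' Built-in residue descriptors
#'
#' Deterministic stand-in for an evolutionary profile (PSSM) when none is
#' supplied with a protein: a 20-dimensional one-hot amino-acid encoding
#' concatenated with seven fixed physicochemical scales (Kyte-Doolittle
#' hydropathy, residue mass, net side-chain charge at pH 7, polarity flag,
#' aromaticity flag, van der Waals volume, and flexibility), each scaled to
#' order-one magnitude.  Unknown residue letters map to an all-zero one-hot
#' with average property values.
#'
#' @param sequence amino-acid string (one-letter codes).
#' @return numeric matrix with \code{nchar(sequence)} rows and 27 columns.
#' @examples
#' dim(residue_features("ACDEFG"))
#' @export
residue_features <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1, nchar(sequence) >= 1)
  aa <- strsplit(toupper(sequence), "")[[1]]
  tab <- .aa_properties
  n <- length(aa)
  out <- matrix(0, n, 20L + ncol(tab))
  idx <- match(aa, rownames(tab))
  prop_mean <- colMeans(tab)
  for (i in seq_len(n)) {
    if (!is.na(idx[i])) {
      out[i, idx[i]] <- 1
      out[i, 20L + seq_len(ncol(tab))] <- tab[idx[i], ]
    } else {
      out[i, 20L + seq_len(ncol(tab))] <- prop_mean
    }
  }
  out
}

# hydropathy (KD / 4.5), mass (Da / 100), charge at pH 7, polar flag,
# aromatic flag, van der Waals volume (A^3 / 100), flexibility index.
.aa_properties <- local({
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  hydro <- c(1.8, 2.5, -3.5, -3.5, 2.8, -0.4, -3.2, 4.5, -3.9, 3.8,
             1.9, -3.5, -1.6, -3.5, -4.5, -0.8, -0.7, 4.2, -0.9, -1.3) / 4.5
  mass <- c(89.1, 121.2, 133.1, 147.1, 165.2, 75.1, 155.2, 131.2, 146.2,
            131.2, 149.2, 132.1, 115.1, 146.2, 174.2, 105.1, 119.1, 117.1,
            204.2, 181.2) / 100
  charge <- c(0, 0, -1, -1, 0, 0, 0.1, 0, 1, 0, 0, 0, 0, 0, 1, 0, 0, 0, 0, 0)
  polar <- c(0, 0, 1, 1, 0, 0, 1, 0, 1, 0, 0, 1, 0, 1, 1, 1, 1, 0, 0, 1)
  arom <- c(0, 0, 0, 0, 1, 0, 1, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 1, 1)
  volume <- c(67, 86, 91, 109, 135, 48, 118, 124, 135, 124, 124, 96, 90,
              114, 148, 73, 93, 105, 163, 141) / 100
  flex <- c(0.36, 0.35, 0.51, 0.50, 0.31, 0.54, 0.32, 0.46, 0.47, 0.37,
            0.30, 0.46, 0.51, 0.49, 0.53, 0.51, 0.44, 0.39, 0.31, 0.42)
  m <- cbind(hydro, mass, charge, polar, arom, volume, flex)
  rownames(m) <- aa
  m
})
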