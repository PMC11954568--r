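#' Build a drug molecular graph from a SMILES string
#'
#' Parses a SMILES string into a heavy-atom molecular graph: one node per
#' non-hydrogen atom, an undirected edge per chemical bond.  Node descriptors
#' follow the supplied \code{\link{atom_featurizer}}; hydrogens are implicit,
#' inferred from default valences.  The string is canonicalized (OpenBabel
#' canonical SMILES) before the final parse so that the same molecule written
#' two different ways yields the same atom ordering.
#'
#' @param smiles a single SMILES string.
#' @param featurizer an \code{\link{atom_featurizer}}; default descriptor set
#'   gives one row of width \code{featurizer$width} per atom.
#' @param drug_id identifier stored with the graph (default: the input string).
#' @param canonicalize canonicalize before parsing (default \code{TRUE}).
#' @return an object of class \code{"drug_graph"} with fields
#'   \code{drug_id}, \code{smiles} (canonical form), \code{m} (atom count),
#'   \code{symbols}, \code{X} (\code{m x mu1} feature matrix) and \code{A}
#'   (symmetric 0/1 bond adjacency with zero diagonal).
#' @examples
#' g <- build_drug_graph("c1ccccc1")  # benzene: 6 atoms, 6 ring bonds
#' g$m
#' sum(g$A) / 2
#' @export
build_drug_graph <- function(smiles, featurizer = atom_featurizer(),
                             drug_id = smiles, canonicalize = TRUE) {
  if (!is.character(smiles) || length(smiles) != 1 || is.na(smiles) ||
      !nzchar(trimws(smiles)))
    stop("'smiles' must be a single non-empty string", call. = FALSE)
  smiles <- trimws(smiles)

  sdf <- parse_smiles_checked(smiles)
  if (canonicalize) {
    can <- tryCatch(
      trimws(ChemmineOB::convertFormat("SMI", "CAN", source = smiles)),
      error = function(e) "")
    can <- sub("\\s.*$", "", can)
    if (nzchar(can)) {
      sdf2 <- tryCatch(parse_smiles_checked(can), error = function(e) NULL)
      if (!is.null(sdf2)) {
        sdf <- sdf2
        smiles <- can
      }
    }
  }

  mol <- sdf[[1]]
  ab <- ChemmineR::atomblock(mol)
  m <- nrow(ab)
  if (m < 1L)
    stop(sprintf("SMILES '%s' yields a molecule with zero atoms", smiles),
         call. = FALSE)
  symbols <- sub("_\\d+$", "", rownames(ab))

  A <- matrix(0, m, m)
  bond_order <- numeric(m)
  bb <- tryCatch(ChemmineR::bondblock(mol), error = function(e) NULL)
  if (!is.null(bb) && nrow(bb) > 0) {
    for (r in seq_len(nrow(bb))) {
      i <- bb[r, 1L]; j <- bb[r, 2L]; ord <- bb[r, 3L]
      A[i, j] <- 1; A[j, i] <- 1
      # aromatic bond code 4 counts as order 1.5 toward the valence sum
      o <- if (ord == 4) 1.5 else ord
      bond_order[i] <- bond_order[i] + o
      bond_order[j] <- bond_order[j] + o
    }
  }

  arom <- aromatic_atoms(mol, m)
  degrees <- as.integer(rowSums(A))
  val <- .default_valence[symbols]
  val[is.na(val)] <- ceiling(bond_order[is.na(val)])
  hydrogens <- pmax(0L, as.integer(round(val - bond_order)))

  X <- featurize_atoms(featurizer, symbols, degrees, hydrogens, hydrogens,
                       arom)
  structure(list(drug_id = drug_id, smiles = smiles, m = m,
                 symbols = symbols, X = X, A = A),
            class = "drug_graph")
}

# Parse with ChemmineR and turn its "invalid SDF" warning into a hard error
# naming the offending string.
parse_smiles_checked <- function(smiles) {
  bad <- FALSE
  sdf <- withCallingHandlers(
    tryCatch(ChemmineR::smiles2sdf(smiles),
             error = function(e) {
               stop(sprintf("unparsable SMILES: '%s' (%s)", smiles,
                            conditionMessage(e)), call. = FALSE)
             }),
    warning = function(w) {
      bad <<- TRUE
      invokeRestart("muffleWarning")
    })
  ok <- !bad && length(sdf) >= 1 && tryCatch({
    ab <- ChemmineR::atomblock(sdf[[1]])
    nrow(ab) >= 1 && !anyNA(ab[, 1:2])
  }, error = function(e) FALSE)
  if (!ok)
    stop(sprintf("unparsable SMILES: '%s'", smiles), call. = FALSE)
  sdf
}

# Atoms belonging to at least one aromatic ring.
aromatic_atoms <- function(mol, m) {
  flags <- rep(FALSE, m)
  rr <- tryCatch(
    suppressWarnings(ChemmineR::rings(mol, type = "all", arom = TRUE,
                                      inner = FALSE)),
    error = function(e) NULL)
  if (!is.null(rr) && length(rr$RINGS) > 0) {
    for (k in seq_along(rr$RINGS)) {
      if (isTRUE(rr$AROMATIC[[k]])) {
        idx <- as.integer(sub("^[A-Za-z]+_", "", rr$RINGS[[k]]))
        flags[idx] <- TRUE
      }
    }
  }
  flags
}

#' @export
print.drug_graph <- function(x, ...) {
  cat("Drug graph", x$drug_id, "\n")
  cat("  ", x$m, " atoms, ", sum(x$A) / 2, " bonds, feature width ",
      ncol(x$X), "\n", sep = "")
  invisible(x)
}
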