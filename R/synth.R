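# Synthetic hierarchical DTI corpus with planted low-rank interaction
# structure: valence-plausible molecular graphs, protein sequences with
# banded + long-range contact maps, per-residue descriptors, and labels
# drawn from a logistic low-rank latent model whose factors are also
# injected into the node features so the signal is learnable from inputs.

#' Synthetic corpus configuration
#'
#' @param n_drugs,n_proteins entity counts (default benchmark: 60 x 40).
#' @param mol_size_range inclusive atom-count range for generated
#'   molecules.
#' @param protein_length_range inclusive residue-count range.
#' @param rank latent factor rank of the planted interaction model.
#' @param scale positive logit scale: \code{P(y=1) = sigmoid(scale * u.v)}.
#' @param noise label flip probability, in \code{[0, 0.5)}.
#' @param long_range_rate mean contact probability over long-range residue
#'   pairs (\code{|i-j| >= 2}).
#' @param contact_decay decay length (in residues) of the long-range
#'   contact rate with sequence separation.
#' @param feature_shift amplitude of the latent-factor shift added to the
#'   node feature means (order-one: comparable to the one-hot descriptor
#'   scale).
#' @param seed integer seed; every artifact is byte-identical under the
#'   same seed.
#' @return an object of class \code{"synth_config"}.
#' @export
synth_config <- function(n_drugs = 60L, n_proteins = 40L,
                         mol_size_range = c(4L, 20L),
                         protein_length_range = c(30L, 120L),
                         rank = 4L, scale = 3, noise = 0.05,
                         long_range_rate = 0.03, contact_decay = 20,
                         feature_shift = 2, seed = 7L) {
  stopifnot(n_drugs >= 2, n_proteins >= 2,
            mol_size_range[1] >= 1, mol_size_range[2] >= mol_size_range[1],
            protein_length_range[1] >= 2,
            rank >= 1, rank <= min(n_drugs, n_proteins),
            noise >= 0, noise < 0.5, long_range_rate >= 0,
            long_range_rate < 1, contact_decay > 0)
  structure(list(n_drugs = as.integer(n_drugs),
                 n_proteins = as.integer(n_proteins),
                 mol_size_range = as.integer(mol_size_range),
                 protein_length_range = as.integer(protein_length_range),
                 rank = as.integer(rank), scale = scale, noise = noise,
                 long_range_rate = long_range_rate,
                 contact_decay = contact_decay,
                 feature_shift = feature_shift, seed = as.integer(seed)),
            class = "synth_config")
}

# element valence caps used by the molecule generator
.gen_elements <- c(C = 4L, N = 3L, O = 2L)

#' Generate a random valence-plausible molecular graph
#'
#' Builds a random spanning tree over atoms drawn from \{C, N, O\}
#' respecting valence caps (C:4, N:3, O:2), then adds ring-closure edges
#' between non-adjacent atoms that still have spare valence.  The graph is
#' connected and symmetric by construction.  A SMILES serialization of the
#' graph (single bonds only) is attached when the graph is writable.
#'
#' @param size atom count (>= 1).
#' @param seed integer seed.
#' @param featurizer an \code{\link{atom_featurizer}} for the node
#'   descriptors.
#' @param drug_id identifier for the resulting graph.
#' @return a \code{drug_graph} with a \code{$smiles} field.
#' @export
gen_molecule <- function(size, seed = 1L, featurizer = atom_featurizer(),
                         drug_id = paste0("D", seed)) {
  stopifnot(size >= 1)
  withr::with_seed(seed, {
    elements <- names(.gen_elements)
    symbols <- sample(elements, size, replace = TRUE,
                      prob = c(0.7, 0.15, 0.15))
    caps <- .gen_elements[symbols]
    A <- matrix(0, size, size)
    deg <- integer(size)
    if (size > 1) {
      for (i in 2:size) {
        open <- which(deg[seq_len(i - 1L)] < caps[seq_len(i - 1L)])
        if (length(open) == 0) {
          # no spare valence among placed atoms: promote one to carbon
          j <- sample.int(i - 1L, 1L)
          symbols[j] <- "C"; caps[j] <- 4L
          open <- j
        }
        j <- if (length(open) == 1L) open else sample(open, 1L)
        A[i, j] <- A[j, i] <- 1
        deg[i] <- deg[i] + 1L; deg[j] <- deg[j] + 1L
      }
      # optional ring closures
      n_rings <- sample(0:max(0L, size %/% 6L), 1L)
      for (r in seq_len(n_rings)) {
        cand <- which(deg < caps)
        if (length(cand) < 2) break
        pair <- sample(cand, 2L)
        u <- pair[1L]; v <- pair[2L]
        if (A[u, v] == 0) {
          A[u, v] <- A[v, u] <- 1
          deg[u] <- deg[u] + 1L; deg[v] <- deg[v] + 1L
        }
      }
    }
  })
  hyd <- as.integer(caps - rowSums(A))
  X <- featurize_atoms(featurizer, symbols, as.integer(rowSums(A)), hyd,
                       hyd, rep(FALSE, size))
  smiles <- tryCatch(graph_to_smiles(symbols, A), error = function(e) NA)
  structure(list(drug_id = drug_id, smiles = smiles, m = size,
                 symbols = symbols, X = X, A = A),
            class = "drug_graph")
}

# Serialize a connected single-bond molecular graph as SMILES via DFS with
# ring-closure digits.
graph_to_smiles <- function(symbols, A) {
  n <- length(symbols)
  if (n == 1L) return(symbols[1L])
  visited <- rep(FALSE, n)
  parent <- rep(NA_integer_, n)
  order_ <- integer(0)
  stack <- 1L
  # iterative DFS for tree edges
  children <- vector("list", n)
  while (length(stack)) {
    u <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (visited[u]) next
    visited[u] <- TRUE
    order_ <- c(order_, u)
    nb <- which(A[u, ] == 1)
    nb <- nb[!visited[nb]]
    for (v in rev(nb)) {
      if (is.na(parent[v]) && v != 1L) parent[v] <- u
      stack <- c(stack, v)
    }
  }
  if (!all(visited)) stop("graph is not connected", call. = FALSE)
  # tree edges: (parent[v], v); ring edges: the rest
  tree <- matrix(c(parent[order_[-1L]], order_[-1L]), ncol = 2L)
  is_tree <- matrix(FALSE, n, n)
  is_tree[tree] <- TRUE; is_tree[tree[, 2:1, drop = FALSE]] <- TRUE
  ring_edges <- which(A == 1 & !is_tree & upper.tri(A), arr.ind = TRUE)
  if (nrow(ring_edges) > 9L)
    stop("too many ring closures for single-digit labels", call. = FALSE)
  ring_lab <- vector("list", n)
  for (r in seq_len(nrow(ring_edges))) {
    u <- ring_edges[r, 1L]; v <- ring_edges[r, 2L]
    ring_lab[[u]] <- c(ring_lab[[u]], r)
    ring_lab[[v]] <- c(ring_lab[[v]], r)
  }
  kids <- lapply(seq_len(n), function(u) order_[
    order_ %in% which(!is.na(parent) & parent == u)])
  emit <- function(u) {
    tok <- paste0(symbols[u], paste(ring_lab[[u]], collapse = ""))
    ch <- kids[[u]]
    if (length(ch) == 0) return(tok)
    parts <- vapply(ch, emit, "")
    last <- length(parts)
    paste0(tok,
           paste0(vapply(parts[-last],
                         function(p) paste0("(", p, ")"), ""),
                  collapse = ""),
           parts[last])
  }
  emit(1L)
}

#' Generate a synthetic protein: sequence, contact map and descriptors
#'
#' The sequence is uniform over the 20 amino acids.  Backbone neighbors
#' (\code{|i-j| = 1}) get contact probability exactly 1; long-range pairs
#' are contacts with a probability that decays exponentially with sequence
#' separation, calibrated so the mean long-range contact rate equals
#' \code{contact_cfg$long_range_rate}.  Contact probabilities are drawn in
#' (0.55, 1) for contacts and (0, 0.45) for non-contacts, keeping a margin
#' around the 0.5 threshold.  Output matrix is symmetric.
#'
#' @param length residue count (>= 2).
#' @param contact_cfg list with \code{long_range_rate} and
#'   \code{contact_decay}.
#' @param seed integer seed.
#' @return list with \code{sequence}, \code{contact_probs} and
#'   \code{features} (the built-in residue descriptors).
#' @export
gen_protein <- function(length, contact_cfg = list(long_range_rate = 0.03,
                                                   contact_decay = 20),
                        seed = 1L) {
  stopifnot(length >= 2)
  n <- as.integer(length)
  withr::with_seed(seed, {
    aa <- paste(sample(rownames(.aa_properties), n, replace = TRUE),
                collapse = "")
    P <- matrix(0, n, n)
    sep <- abs(outer(seq_len(n), seq_len(n), `-`))
    long <- which(sep >= 2 & upper.tri(P), arr.ind = TRUE)
    if (nrow(long) > 0) {
      d <- sep[long]
      w <- exp(-(d - 2) / contact_cfg$contact_decay)
      rate <- pmin(0.9, contact_cfg$long_range_rate * w / mean(w))
      is_contact <- stats::runif(nrow(long)) < rate
      val <- ifelse(is_contact, stats::runif(nrow(long), 0.55, 1),
                    stats::runif(nrow(long), 0, 0.45))
      P[long] <- val
      P[long[, 2:1, drop = FALSE]] <- val
    }
    P[sep == 1] <- 1
  })
  list(sequence = aa, contact_probs = P, features = residue_features(aa))
}

#' Plant a low-rank logistic interaction structure
#'
#' Drug factors \code{u_i} and protein factors \code{v_j} are standard
#' normal in \code{rank} dimensions; each label is Bernoulli with
#' \code{P(y_ij = 1) = sigmoid(scale * u_i . v_j)} and then flipped with
#' probability \code{noise}.  The hidden factors are returned for
#' diagnostics and for injecting the learnable signal into node features.
#'
#' @param M,N entity counts.
#' @param rank latent rank (\code{<= min(M, N)}).
#' @param scale logit scale.
#' @param noise flip probability.
#' @param seed integer seed.
#' @return list with \code{A} (\code{M x N} 0/1 labels), \code{U}
#'   (\code{M x rank}), \code{V} (\code{N x rank}) and \code{prob} (the
#'   pre-flip Bernoulli means).
#' @export
plant_interactions <- function(M, N, rank = 4L, scale = 3, noise = 0.05,
                               seed = 1L) {
  stopifnot(rank <= min(M, N), noise >= 0, noise < 0.5)
  withr::with_seed(seed, {
    U <- matrix(stats::rnorm(M * rank), M, rank)
    V <- matrix(stats::rnorm(N * rank), N, rank)
    prob <- sigmoid(scale * U %*% t(V))
    A <- matrix(stats::rbinom(M * N, 1L, prob), M, N)
    flip <- matrix(stats::runif(M * N) < noise, M, N)
    A <- ifelse(flip, 1 - A, A)
  })
  list(A = A, U = U, V = V, prob = prob)
}

#' Generate a complete synthetic DTI corpus
#'
#' Draws molecules, proteins and planted interaction labels per the
#' configuration, then adds the latent factors as a constant shift on the
#' node feature rows of each entity (through fixed random projections), so
#' the interaction signal is recoverable from the inputs — without this
#' coupling the labels would be unlearnable from structure alone.  The
#' positive pairs form the corpus pair table; negatives are left to the
#' sampler at training time.
#'
#' @param config a \code{\link{synth_config}}.
#' @param featurizer an \code{\link{atom_featurizer}}.
#' @return a \code{dti_corpus} (fields \code{drugs}, \code{proteins},
#'   \code{pairs}) with the generating \code{config} and a \code{latent}
#'   diagnostic list (\code{U}, \code{V}, \code{prob}, \code{A_full})
#'   attached.
#' @export
synth_corpus <- function(config = synth_config(),
                         featurizer = atom_featurizer()) {
  stopifnot(inherits(config, "synth_config"))
  seed <- config$seed
  M <- config$n_drugs; N <- config$n_proteins

  sizes <- withr::with_seed(derive_seed(seed, 20L),
    sample(config$mol_size_range[1]:config$mol_size_range[2], M,
           replace = TRUE))
  lens <- withr::with_seed(derive_seed(seed, 21L),
    sample(config$protein_length_range[1]:config$protein_length_range[2],
           N, replace = TRUE))

  drugs <- lapply(seq_len(M), function(i)
    gen_molecule(sizes[i], seed = derive_seed(seed, 100L + i),
                 featurizer = featurizer,
                 drug_id = sprintf("D%03d", i)))
  prot_raw <- lapply(seq_len(N), function(j)
    gen_protein(lens[j],
                contact_cfg = list(long_range_rate = config$long_range_rate,
                                   contact_decay = config$contact_decay),
                seed = derive_seed(seed, 5000L + j)))
  proteins <- lapply(seq_len(N), function(j)
    build_protein_graph(sprintf("P%03d", j), prot_raw[[j]]$sequence,
                        prot_raw[[j]]$contact_probs,
                        prot_raw[[j]]$features))

  plant <- plant_interactions(M, N, rank = config$rank,
                              scale = config$scale, noise = config$noise,
                              seed = derive_seed(seed, 30L))

  # inject the latent factors into node feature means
  mu1 <- ncol(drugs[[1]]$X); mu2 <- ncol(proteins[[1]]$X)
  proj <- withr::with_seed(derive_seed(seed, 31L), list(
    Pd = matrix(stats::rnorm(config$rank * mu1, sd = 1 / sqrt(config$rank)),
                config$rank, mu1),
    Pp = matrix(stats::rnorm(config$rank * mu2, sd = 1 / sqrt(config$rank)),
                config$rank, mu2)))
  shift_d <- config$feature_shift * plant$U %*% proj$Pd
  shift_p <- config$feature_shift * plant$V %*% proj$Pp
  for (i in seq_len(M))
    drugs[[i]]$X <- sweep(drugs[[i]]$X, 2L, shift_d[i, ], `+`)
  for (j in seq_len(N))
    proteins[[j]]$X <- sweep(proteins[[j]]$X, 2L, shift_p[j, ], `+`)

  pos <- which(plant$A == 1, arr.ind = TRUE)
  pairs <- data.frame(
    drug = vapply(drugs, function(g) g$drug_id, "")[pos[, 1L]],
    protein = vapply(proteins, function(g) g$protein_id, "")[pos[, 2L]],
    label = 1)
  structure(list(drugs = drugs, proteins = proteins, pairs = pairs,
                 config = config,
                 latent = list(U = plant$U, V = plant$V,
                               prob = plant$prob, A_full = plant$A)),
            class = "dti_corpus")
}

#' @export
print.dti_corpus <- function(x, ...) {
  cat("DTI corpus:", length(x$drugs), "drugs,", length(x$proteins),
      "proteins,", nrow(x$pairs), "labeled pairs\n")
  invisible(x)
}
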