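#' Training configuration
#'
#' Collects every hyperparameter of the model and the training loop, with
#' the defaults used throughout: Adam at learning rate \code{1e-4} for 200
#' full-batch epochs; low-level embedding width \code{d1 = 80}; high-level
#' consensus width \code{d2 = 20}; three encoder/decoder layers with hidden
#' widths 64 and 32; fusion coefficient \code{alpha} initialized at 0.5 and
#' learned; skip-connection scale \code{beta = 0.7} fixed; 1:1 negative
#' sampling.
#'
#' @param lr Adam learning rate.
#' @param epochs number of full-batch epochs (>= 1).
#' @param d1 low-level (entity) embedding width.
#' @param d2 high-level consensus embedding width.
#' @param hidden hidden widths of the feature/graph encoder chain
#'   \code{d1 -> hidden... -> d2}; the decoder reverses it.
#' @param lgnn_layers depth of the low-level GCN encoders.
#' @param leaky_slope negative-branch slope of the feature-encoder
#'   LeakyReLU (distinct from the fusion coefficient \code{alpha}).
#' @param alpha_init initial value of the learnable fusion coefficient.
#' @param beta fixed skip-connection scale.
#' @param theta common-neighbor threshold for similarity edges;
#'   \code{NULL} (the default) uses known interactions as the only
#'   high-level edges.
#' @param include_similarity keep SD/SP blocks in the high-level adjacency.
#' @param similarity_from \code{"train"} computes similarity edges from
#'   training interactions only (no label leakage; held-out entities have
#'   no similarity edges under cold-start splits); \code{"all"} computes
#'   them from the full known positive table, so held-out entities keep
#'   their similarity edges.
#' @param negative_ratio negatives sampled per positive.
#' @param test_fraction held-out fraction for entity-level splits (4:1).
#' @param mode cold-start protocol: \code{"S1"} (new drug), \code{"S2"}
#'   (new target) or \code{"S3"} (both).
#' @param seed integer seed driving initialization, splitting and sampling.
#' @param eps clamp width inside the binary cross-entropy.
#' @param threshold classification cut-off for thresholded metrics.
#' @param max_smiles_len,max_seq_len pad/truncate lengths for the
#'   sequence-only ablation variant.
#' @param verbose print the loss every 10 epochs.
#' @return an object of class \code{"hierdti_control"}.
#' @export
hierdti_control <- function(lr = 1e-4, epochs = 200L, d1 = 80L, d2 = 20L,
                            hidden = c(64L, 32L), lgnn_layers = 3L,
                            leaky_slope = 0.01, alpha_init = 0.5,
                            beta = 0.7, theta = NULL,
                            include_similarity = !is.null(theta),
                            similarity_from = c("train", "all"),
                            negative_ratio = 1, test_fraction = 0.2,
                            mode = c("S1", "S2", "S3"), seed = 1L,
                            eps = 1e-7, threshold = 0.5,
                            max_smiles_len = 100L, max_seq_len = 1000L,
                            verbose = FALSE) {
  mode <- match.arg(mode)
  similarity_from <- match.arg(similarity_from)
  stopifnot(lr > 0, epochs >= 1, d1 >= 1, d2 >= 1, lgnn_layers >= 1,
            leaky_slope > 0, leaky_slope < 1, beta >= 0,
            negative_ratio > 0, test_fraction > 0, test_fraction < 1)
  structure(list(lr = lr, epochs = as.integer(epochs), d1 = as.integer(d1),
                 d2 = as.integer(d2), hidden = as.integer(hidden),
                 lgnn_layers = as.integer(lgnn_layers),
                 leaky_slope = leaky_slope, alpha_init = alpha_init,
                 beta = beta, theta = theta,
                 include_similarity = include_similarity,
                 similarity_from = similarity_from,
                 negative_ratio = negative_ratio,
                 test_fraction = test_fraction, mode = mode,
                 seed = as.integer(seed), eps = eps, threshold = threshold,
                 max_smiles_len = as.integer(max_smiles_len),
                 max_seq_len = as.integer(max_seq_len),
                 verbose = isTRUE(verbose)),
            class = "hierdti_control")
}

# Glorot-style uniform initialization scaled by fan-in + fan-out, with an
# activation-dependent gain (sqrt(2) before ReLU layers; 1 elsewhere).  The
# final decoder layer uses a small gain so initial link scores start near
# zero: the Gram reconstruction otherwise opens training by collapsing the
# overall score scale toward the degenerate all-0.5 solution instead of
# learning pair structure.
glorot <- function(fin, fout, gain = 1) {
  lim <- gain * sqrt(6 / (fin + fout))
  matrix(stats::runif(fin * fout, -lim, lim), fin, fout)
}

.gain_relu <- sqrt(2)
.gain_head <- 0.1

# Width chain of the feature/graph encoders: d1 -> hidden ... -> d2.
encoder_widths <- function(control) {
  c(control$d1, control$hidden, control$d2)
}

# All learnable parameters as a flat named list of matrices/scalars.
# Variants: "full", "-L" (sequence label-encoding replaces the low-level
# GCNs), "-F" (no feature encoder, no fusion), "-W" (alpha frozen at 0.5).
init_params <- function(mu1, mu2, control, variant = "full") {
  widths <- encoder_widths(control)
  L <- length(widths) - 1L
  p <- list()
  if (variant == "-L") {
    p[["seq.Wd"]] <- glorot(control$max_smiles_len, control$d1)
    p[["seq.Wp"]] <- glorot(control$max_seq_len, control$d1)
  } else {
    din <- mu1
    for (k in seq_len(control$lgnn_layers)) {
      p[[paste0("ld.W", k)]] <- glorot(din, control$d1, .gain_relu)
      din <- control$d1
    }
    din <- mu2
    for (k in seq_len(control$lgnn_layers)) {
      p[[paste0("lp.W", k)]] <- glorot(din, control$d1, .gain_relu)
      din <- control$d1
    }
  }
  if (variant != "-F") {
    for (l in seq_len(L)) {
      p[[paste0("fe.W", l)]] <- glorot(widths[l], widths[l + 1L])
      p[[paste0("fe.b", l)]] <- numeric(widths[l + 1L])
    }
    p[["alpha"]] <- control$alpha_init
  }
  for (l in seq_len(L)) {
    p[[paste0("ge.W", l)]] <- glorot(widths[l], widths[l + 1L])
  }
  rev_w <- rev(widths)
  for (h in seq_len(L)) {
    p[[paste0("dec.W", h)]] <- glorot(rev_w[h], rev_w[h + 1L],
                                      if (h == L) .gain_head else 1)
  }
  p
}

# Collect a flat parameter list into the nested per-component form used by
# the user-facing layer functions.
params_as_components <- function(params, control) {
  pick <- function(prefix) {
    nm <- grep(paste0("^", prefix, "\\.W"), names(params), value = TRUE)
    nm <- nm[order(as.integer(sub(".*W", "", nm)))]
    lapply(nm, function(n) params[[n]])
  }
  pick_b <- function(prefix) {
    nm <- grep(paste0("^", prefix, "\\.b"), names(params), value = TRUE)
    nm <- nm[order(as.integer(sub(".*b", "", nm)))]
    lapply(nm, function(n) params[[n]])
  }
  list(lgnn_drug = pick("ld"), lgnn_protein = pick("lp"),
       fe = list(W = pick("fe"), b = pick_b("fe"),
                 slope = control$leaky_slope),
       ge = list(W = pick("ge")),
       dec = list(W = pick("dec")),
       alpha = params[["alpha"]], beta = control$beta)
}
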