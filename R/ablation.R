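#' Run an ablation variant end to end
#'
#' Trains and evaluates one variant of the model on the same corpus and
#' split: \code{"full"} (the complete model), \code{"-L"} (the low-level
#' GCNs replaced by integer label-encoding of the SMILES string, padded or
#' truncated to 100 characters, and of the residue sequence, padded or
#' truncated to 1000, each followed by a learned linear projection to
#' \code{d1}), \code{"-F"} (feature encoder and SAIF fusion removed, the
#' graph-encoder output fed straight to the decoder), and \code{"-W"} (the
#' fusion coefficient frozen at 0.5).
#'
#' @param variant one of \code{"full"}, \code{"-L"}, \code{"-F"},
#'   \code{"-W"}.
#' @param corpus a \code{dti_corpus} (see \code{\link{hierdti}}).
#' @param control a \code{\link{hierdti_control}}.
#' @param split optional \code{\link{make_split}}; built from
#'   \code{control} when \code{NULL}.
#' @return the held-out \code{\link[=evaluate_scores]{metric_report}} with
#'   the fitted model attached as attribute \code{"fit"}.
#' @export
run_ablation <- function(variant, corpus, control = hierdti_control(),
                         split = NULL) {
  if (!variant %in% c("full", "-L", "-F", "-W"))
    stop(sprintf("unknown variant '%s'", variant), call. = FALSE)
  fit <- hierdti(corpus, split = split, control = control,
                 variant = variant)
  out <- fit$test_metrics %||% fit$train_metrics
  attr(out, "fit") <- fit
  out
}

#' Sensitivity sweep over the common-neighbor threshold
#'
#' One full train/evaluate cycle per value of the similarity threshold
#' \code{theta}, all with the same seed and split, tabulating the held-out
#' metrics.
#'
#' @param corpus a \code{dti_corpus}.
#' @param control a \code{\link{hierdti_control}}; its \code{theta} is
#'   overridden per run.
#' @param theta_values nonnegative integer thresholds to try.
#' @return data frame with one row per \code{theta} and the six metric
#'   columns.
#' @export
theta_sweep <- function(corpus, control = hierdti_control(),
                        theta_values = 0:5) {
  if (any(theta_values < 0))
    stop("'theta_values' must be nonnegative", call. = FALSE)
  rows <- lapply(theta_values, function(th) {
    ctl <- control
    ctl$theta <- as.integer(th)
    ctl$include_similarity <- TRUE
    fit <- hierdti(corpus, control = ctl)
    m <- fit$test_metrics %||% fit$train_metrics
    data.frame(theta = th, t(unclass(m)))
  })
  do.call(rbind, rows)
}
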