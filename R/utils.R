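# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
check_matrix <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("'%s' must be a numeric matrix", name), call. = FALSE)
  if (!all(is.finite(x)))
    stop(sprintf("'%s' contains non-finite entries", name), call. = FALSE)
  invisible(x)
}

#' @keywords internal
check_binary_matrix <- function(x, name = deparse(substitute(x))) {
  check_matrix(x, name)
  if (!all(x %in% c(0, 1)))
    stop(sprintf("'%s' must contain only 0/1 entries", name), call. = FALSE)
  invisible(x)
}

#' @keywords internal
check_symmetric <- function(x, name = deparse(substitute(x)), tol = 0) {
  if (nrow(x) != ncol(x))
    stop(sprintf("'%s' must be square", name), call. = FALSE)
  if (max(abs(x - t(x))) > tol)
    stop(sprintf("'%s' must be symmetric", name), call. = FALSE)
  invisible(x)
}

# Numerically safe sigmoid.
sigmoid <- function(x) 1 / (1 + exp(-x))

# Row-wise softmax with per-row max subtraction for stability; ties come out
# as equal probabilities by construction.
row_softmax <- function(x) {
  m <- apply(x, 1L, max)
  e <- exp(x - m)
  # floor at the smallest normal double: keeps entries strictly positive
  # even when a logit gap exceeds the exp() underflow threshold (~745)
  e <- pmax(e, .Machine$double.xmin)
  e / rowSums(e)
}

# Deterministic sub-seed derivation: keeps every derived seed a valid 32-bit
# integer whatever the user passes.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1000003 + offset) %% .Machine$integer.max)
}
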