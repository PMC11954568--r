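#' Run the full pipeline from files to artifacts
#'
#' Reads a corpus, builds the hierarchical graph, trains the model under
#' the configured cold-start protocol, evaluates the held-out pairs, and
#' writes four artifacts into the output directory: \code{metrics.json}
#' (the six held-out metrics, 4 decimals), \code{predictions.tsv}
#' (\code{drug_id <TAB> protein_id <TAB> score} at 6 decimals for every
#' held-out pair), \code{checkpoint.rds} (all parameter matrices with their
#' shapes plus the control that produced them) and \code{manifest.json}
#' (configuration, seed and versions — enough to replay the run).
#'
#' @param config a list (or path to a YAML/JSON file) with entries
#'   \code{drugs}, \code{fasta}, \code{interactions}, optional
#'   \code{data_dir} and \code{outdir}, an optional \code{variant}, and any
#'   \code{\link{hierdti_control}} fields under \code{control}.
#' @return invisibly, a list with the fitted model and the artifact paths.
#' @export
run_pipeline <- function(config) {
  config <- load_run_config(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  corpus <- stage("read_corpus",
    read_corpus(config$drugs, config$fasta, config$interactions,
                data_dir = config$data_dir %||% dirname(config$fasta)))
  control <- stage("config",
    do.call(hierdti_control, config$control %||% list()))
  fit <- stage("train",
    hierdti(corpus, control = control,
            variant = config$variant %||% "full"))

  outdir <- config$outdir %||% "hierdti_run"
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(metrics = file.path(outdir, "metrics.json"),
                predictions = file.path(outdir, "predictions.tsv"),
                checkpoint = file.path(outdir, "checkpoint.rds"),
                manifest = file.path(outdir, "manifest.json"))

  stage("write_artifacts", {
    m <- fit$test_metrics %||% fit$train_metrics
    jsonlite::write_json(lapply(as.list(unclass(m)), round, 4L),
                         paths$metrics, auto_unbox = TRUE, digits = NA)

    te <- fit$split$test_pairs
    if (nrow(te) == 0) te <- fit$split$train_pairs
    scores <- fit$ydp[as.matrix(te[, c("drug", "protein")])]
    writeLines(paste0(fit$drug_ids[te$drug], "\t",
                      fit$protein_ids[te$protein], "\t",
                      sprintf("%.6f", scores)),
               paths$predictions)

    saveRDS(list(params = fit$params,
                 shapes = lapply(fit$params, function(x)
                   if (is.matrix(x)) dim(x) else 1L),
                 control = fit$control, variant = fit$variant),
            paths$checkpoint)

    jsonlite::write_json(
      list(config = config[setdiff(names(config), "control")],
           control = unclass(fit$control), variant = fit$variant,
           package_version = as.character(utils::packageVersion("hierdti")),
           r_version = R.version.string),
      paths$manifest, auto_unbox = TRUE, null = "null", digits = NA)
  })
  invisible(list(fit = fit, paths = paths))
}

load_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
      else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  for (f in c("drugs", "fasta", "interactions")) {
    if (is.null(config[[f]]))
      stop(sprintf("run config is missing '%s'", f), call. = FALSE)
    if (!file.exists(config[[f]]))
      stop(sprintf("run config: '%s' does not exist (%s)", f,
                   config[[f]]), call. = FALSE)
  }
  config
}
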