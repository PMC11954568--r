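# Readers and writers for the on-disk corpus dialects:
#   drugs.tsv         drug_id <TAB> SMILES (header optional)
#   proteins.fasta    standard FASTA
#   <id>.cmap         dense whitespace matrix, or triplet lines "i j p"
#                     with 0-based indices
#   <id>.feat         dense whitespace matrix (n x mu2)
#   interactions.tsv  drug_id <TAB> protein_id <TAB> label (label optional)
# All files UTF-8, unix newlines, no quoting.

#' Read a drug table
#'
#' @param path drugs.tsv file: two tab-separated columns, drug id and
#'   SMILES; a \code{drug_id} header line is skipped if present.
#' @param featurizer an \code{\link{atom_featurizer}}.
#' @return list of \code{drug_graph} objects.
#' @export
read_drugs_tsv <- function(path, featurizer = atom_featurizer()) {
  lines <- read_lines_checked(path)
  if (length(lines) && grepl("^drug_id\\b", lines[1L], ignore.case = TRUE))
    lines <- lines[-1L]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 2 || !nzchar(f[1]) || !nzchar(f[2]))
      stop(sprintf("%s:%d: expected 'drug_id<TAB>smiles', got '%s'",
                   path, i + 1L, lines[i]), call. = FALSE)
    g <- build_drug_graph(f[2], featurizer = featurizer, drug_id = f[1])
    g$input_smiles <- f[2]
    out[[i]] <- g
  }
  out
}

#' Read protein records: FASTA plus per-protein contact maps and features
#'
#' For every sequence in the FASTA file, reads \code{<id>.cmap}
#' (contact-probability matrix, dense or 0-based triplets) and, when
#' present, \code{<id>.feat} (per-residue descriptor matrix) from
#' \code{data_dir}; missing feature files fall back to the built-in
#' \code{\link{residue_features}}.
#'
#' @param fasta_path FASTA file of amino-acid sequences.
#' @param data_dir directory holding the \code{.cmap}/\code{.feat} files.
#' @return list of \code{protein_graph} objects.
#' @export
read_proteins <- function(fasta_path, data_dir) {
  seqs <- Biostrings::readAAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  out <- vector("list", length(seqs))
  for (j in seq_along(seqs)) {
    sq <- as.character(seqs[[j]])
    cmap_path <- file.path(data_dir, paste0(ids[j], ".cmap"))
    if (!file.exists(cmap_path))
      stop(sprintf("missing contact map for protein '%s' (%s)", ids[j],
                   cmap_path), call. = FALSE)
    P <- read_contact_map(cmap_path, nchar(sq))
    feat_path <- file.path(data_dir, paste0(ids[j], ".feat"))
    feats <- if (file.exists(feat_path))
      read_dense_matrix(feat_path) else NULL
    out[[j]] <- build_protein_graph(ids[j], sq, P, feats)
  }
  out
}

#' Read a contact-probability map
#'
#' Dense layout (\code{n} lines of \code{n} whitespace-separated values) or
#' sparse triplets (\code{i j p} per line, 0-based indices, symmetrized on
#' read).
#'
#' @param path the \code{.cmap} file.
#' @param n expected dimension (residue count).
#' @return \code{n x n} numeric matrix.
#' @export
read_contact_map <- function(path, n) {
  lines <- read_lines_checked(path)
  fields <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(fields)
  if (length(lines) == n && all(nf == n)) {
    vals <- suppressWarnings(as.numeric(unlist(fields)))
    if (anyNA(vals))
      stop(sprintf("%s: non-numeric entry in dense contact map", path),
           call. = FALSE)
    return(matrix(vals, n, n, byrow = TRUE))
  }
  if (!all(nf == 3))
    stop(sprintf("%s: expected a %dx%d dense matrix or 'i j p' triplets",
                 path, n, n), call. = FALSE)
  P <- matrix(0, n, n)
  for (r in seq_along(fields)) {
    v <- suppressWarnings(as.numeric(fields[[r]]))
    if (anyNA(v) || v[1] != floor(v[1]) || v[2] != floor(v[2]))
      stop(sprintf("%s:%d: malformed triplet '%s'", path, r, lines[r]),
           call. = FALSE)
    i <- v[1] + 1L; j <- v[2] + 1L
    if (i < 1 || i > n || j < 1 || j > n)
      stop(sprintf("%s:%d: index out of range for n = %d", path, r, n),
           call. = FALSE)
    P[i, j] <- v[3]; P[j, i] <- v[3]
  }
  P
}

read_dense_matrix <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(m) <- NULL
  m
}

#' Read a labeled interaction table
#'
#' @param path interactions.tsv: \code{drug_id <TAB> protein_id} with an
#'   optional third 0/1 label column (absent = positive).  Duplicate pairs
#'   are deduplicated with a warning; a header line is skipped if present.
#' @return data frame with columns \code{drug}, \code{protein},
#'   \code{label}.
#' @export
read_interactions_tsv <- function(path) {
  lines <- read_lines_checked(path)
  if (length(lines) && grepl("^drug_id\\b", lines[1L], ignore.case = TRUE))
    lines <- lines[-1L]
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (!length(f) %in% c(2L, 3L))
      stop(sprintf("%s:%d: expected 2 or 3 tab-separated fields, got '%s'",
                   path, i + 1L, lines[i]), call. = FALSE)
    lab <- if (length(f) == 3L) suppressWarnings(as.numeric(f[3])) else 1
    if (is.na(lab) || !lab %in% c(0, 1))
      stop(sprintf("%s:%d: label must be 0 or 1", path, i + 1L),
           call. = FALSE)
    rows[[i]] <- data.frame(drug = f[1], protein = f[2], label = lab)
  }
  out <- do.call(rbind, rows)
  dup <- duplicated(out[, c("drug", "protein")])
  if (any(dup)) {
    warning(sprintf("%d duplicated interaction pair(s) removed", sum(dup)),
            call. = FALSE)
    out <- out[!dup, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Read a complete corpus from disk
#'
#' Loads the drug table, protein records and interaction table, and
#' cross-references the entity identifiers: interaction pairs naming
#' unknown entities are an error.
#'
#' @param drugs_tsv,fasta,interactions_tsv file paths.
#' @param data_dir directory with per-protein \code{.cmap}/\code{.feat}
#'   files (defaults to the FASTA file's directory).
#' @param featurizer an \code{\link{atom_featurizer}}.
#' @return a \code{dti_corpus}.
#' @export
read_corpus <- function(drugs_tsv, fasta, interactions_tsv,
                        data_dir = dirname(fasta),
                        featurizer = atom_featurizer()) {
  drugs <- read_drugs_tsv(drugs_tsv, featurizer)
  proteins <- read_proteins(fasta, data_dir)
  pairs <- read_interactions_tsv(interactions_tsv)
  drug_ids <- vapply(drugs, function(g) g$drug_id, "")
  protein_ids <- vapply(proteins, function(g) g$protein_id, "")
  bad_d <- setdiff(unique(pairs$drug), drug_ids)
  bad_p <- setdiff(unique(pairs$protein), protein_ids)
  if (length(bad_d) || length(bad_p))
    stop("interactions reference unknown ids: ",
         paste(c(bad_d, bad_p), collapse = ", "), call. = FALSE)
  structure(list(drugs = drugs, proteins = proteins, pairs = pairs),
            class = "dti_corpus")
}

read_lines_checked <- function(path) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines[nzchar(trimws(lines))]
}

fmt_num <- function(x) sprintf("%.6f", x)

#' Write a corpus to disk in the standard dialects
#'
#' Emits \code{drugs.tsv}, \code{proteins.fasta}, one \code{.cmap} and one
#' \code{.feat} file per protein, and \code{interactions.tsv} — exactly the
#' formats \code{\link{read_corpus}} reads, so a written fixture reloads
#' and re-writes byte-identically.  Contact probabilities and features are
#' printed at 6 decimals.
#'
#' @param corpus a \code{dti_corpus}.  Drug graphs must carry a SMILES
#'   serialization.
#' @param directory output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_fixture <- function(corpus, directory) {
  corpus <- as_dti_corpus(corpus)
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory))
    stop(sprintf("cannot create directory '%s'", directory), call. = FALSE)
  files <- character(0)

  smiles <- vapply(corpus$drugs,
                   function(g) as.character(g$input_smiles %||% g$smiles),
                   "")
  if (anyNA(smiles) || any(!nzchar(smiles)))
    stop("every drug graph needs a SMILES serialization to be written",
         call. = FALSE)
  p <- file.path(directory, "drugs.tsv")
  writeLines(c("drug_id\tsmiles",
               paste0(vapply(corpus$drugs, function(g) g$drug_id, ""),
                      "\t", smiles)), p)
  files <- c(files, p)

  p <- file.path(directory, "proteins.fasta")
  writeLines(unlist(lapply(corpus$proteins, function(g)
    c(paste0(">", g$protein_id), g$sequence))), p)
  files <- c(files, p)

  for (g in corpus$proteins) {
    cp <- g$contact_probs %||% g$A  # adjacency doubles as 0/1 probability
    pc <- file.path(directory, paste0(g$protein_id, ".cmap"))
    writeLines(apply(cp, 1L, function(r) paste(fmt_num(r), collapse = " ")),
               pc)
    pf <- file.path(directory, paste0(g$protein_id, ".feat"))
    writeLines(apply(g$X, 1L, function(r) paste(fmt_num(r), collapse = " ")),
               pf)
    files <- c(files, pc, pf)
  }

  pairs <- as.data.frame(corpus$pairs)
  p <- file.path(directory, "interactions.tsv")
  writeLines(c("drug_id\tprotein_id\tlabel",
               paste0(pairs$drug, "\t", pairs$protein, "\t",
                      format(pairs$label, trim = TRUE))), p)
  files <- c(files, p)
  invisible(files)
}
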