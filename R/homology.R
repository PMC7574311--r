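# Best-hit homolog annotation of candidate contig proteins against
# reference proteomes, and construction of the confirmation database in
# which candidate contigs are replaced by their reference homologs.

#' Read a reference protein FASTA
#'
#' @param path Protein FASTA path. The accession is the first
#'   whitespace-delimited header token; the remainder of the header is kept
#'   as the description.
#' @return data.frame with columns `accession`, `description`, `seq`.
#' @export
read_reference_proteins <- function(path) {
  if (!file.exists(path)) .stop_input("FASTA file not found: %s", path)
  set <- Biostrings::readBStringSet(path)
  hdr <- names(set)
  acc <- vapply(strsplit(hdr, "[ \t]"), `[[`, character(1), 1L)
  desc <- trimws(sub("^[^ \t]+[ \t]?", "", hdr))
  if (anyDuplicated(acc)) {
    .stop_input("duplicate reference accession(s): %s",
                paste(unique(acc[duplicated(acc)]), collapse = ", "))
  }
  data.frame(accession = acc, description = desc,
             seq = toupper(as.character(set)), stringsAsFactors = FALSE)
}

#' Best-fit reference hit for one query protein
#'
#' Scores the query against every reference with Smith-Waterman local
#' alignment (BLOSUM62 substitution scores, affine gaps: open 11,
#' extend 1 — the standard protein-search defaults) and returns the
#' highest-scoring reference. Ties are broken by higher percent identity,
#' then by lexicographically smaller accession. Percent identity is
#' computed over aligned columns (gap positions included in the
#' denominator).
#'
#' @param query Amino-acid string (non-empty).
#' @param references data.frame with columns `accession`, `seq` and
#'   optionally `description` (see [read_reference_proteins()]).
#' @param matrix Substitution matrix name (default `"BLOSUM62"`).
#' @param gap_open,gap_extend Affine gap penalties (defaults 11 and 1).
#' @param query_id Optional id copied into the result.
#' @return One-row data.frame: `query_id`, `best_accession`,
#'   `alignment_score`, `percent_identity`, `description`.
#' @export
best_fit <- function(query, references, matrix = "BLOSUM62",
                     gap_open = 11, gap_extend = 1, query_id = NA_character_) {
  if (!is.character(query) || length(query) != 1L || !nzchar(query)) {
    .stop_param("query must be a non-empty amino-acid string")
  }
  if (!is.data.frame(references) || !nrow(references)) {
    .stop_param("reference set must be a non-empty data.frame")
  }
  stopifnot(all(c("accession", "seq") %in% names(references)))
  submat <- .get_submatrix(matrix)
  # queries may contain X; restrict to letters the matrix scores
  alpha <- rownames(submat)
  q <- Biostrings::AAString(query)
  scores <- numeric(nrow(references))
  pids <- numeric(nrow(references))
  for (i in seq_len(nrow(references))) {
    aln <- Biostrings::pairwiseAlignment(
      q, Biostrings::AAString(references$seq[i]), type = "local",
      substitutionMatrix = submat,
      gapOpening = gap_open, gapExtension = gap_extend)
    scores[i] <- Biostrings::score(aln)
    pids[i] <- Biostrings::pid(aln, type = "PID1")
  }
  ord <- order(-scores, -pids, references$accession)
  best <- ord[1L]
  data.frame(
    query_id = query_id,
    best_accession = references$accession[best],
    alignment_score = scores[best],
    percent_identity = pids[best],
    description = if ("description" %in% names(references))
      references$description[best] else NA_character_,
    stringsAsFactors = FALSE)
}

.get_submatrix <- function(name) {
  e <- new.env()
  ok <- tryCatch({
    utils::data(list = name, package = "Biostrings", envir = e)
    TRUE
  }, warning = function(w) FALSE, error = function(e) FALSE)
  if (!ok || !exists(name, envir = e)) {
    .stop_param("unknown substitution matrix: %s", name)
  }
  get(name, envir = e)
}

#' Annotate a set of query proteins by best reference hit
#'
#' Runs [best_fit()] for every query. When two reference sets are given
#' (e.g. a close congener proteome and a small same-species set), the best
#' hit in each is reported and the primary annotation is taken from the
#' higher-scoring one.
#'
#' @param queries Named character vector of amino-acid sequences (names
#'   are query ids).
#' @param references Reference data.frame (see [read_reference_proteins()]).
#' @param ... Passed on to [best_fit()].
#' @return data.frame, one row per query, columns as in [best_fit()].
#' @export
annotate_queries <- function(queries, references, ...) {
  stopifnot(is.character(queries))
  if (length(queries) && is.null(names(queries))) {
    .stop_param("queries must be named")
  }
  rows <- lapply(seq_along(queries), function(i) {
    best_fit(queries[[i]], references, query_id = names(queries)[i], ...)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(query_id = character(0), best_accession = character(0),
               alignment_score = numeric(0), percent_identity = numeric(0),
               description = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Replace candidate contigs with their reference homologs
#'
#' Builds the confirmation database: every entry derived from a mapped
#' contig (all its frames and stop-split segments) is removed and replaced
#' by a single entry carrying the homolog's accession and sequence, placed
#' at the position of the contig's first entry. Unmapped entries pass
#' through unchanged. The operation is idempotent for a fixed mapping.
#'
#' @param db A `peptide_db` object.
#' @param mapping data.frame with columns `base_contig`, `accession`,
#'   `seq` (the homolog sequence).
#' @return A new `peptide_db`. Homolog entries keep the original
#'   `base_contig`, with `frame` and `segment` set to `NA`.
#' @export
replace_with_homologs <- function(db, mapping) {
  stopifnot(inherits(db, "peptide_db"), is.data.frame(mapping))
  req <- c("base_contig", "accession", "seq")
  miss <- setdiff(req, names(mapping))
  if (length(miss)) .stop_param("mapping lacks column(s): %s",
                                paste(miss, collapse = ", "))
  entries <- db$entries
  absent <- setdiff(mapping$base_contig, entries$base_contig)
  if (length(absent)) {
    warning(sprintf("mapping references contig(s) absent from the database, skipped: %s",
                    paste(absent, collapse = ", ")), call. = FALSE)
    mapping <- mapping[!mapping$base_contig %in% absent, , drop = FALSE]
  }
  if (!nrow(mapping)) return(db)
  mapped <- entries$base_contig %in% mapping$base_contig
  # anchor each replacement at the first entry of its contig
  first_idx <- tapply(seq_len(nrow(entries)), entries$base_contig, min)
  repl <- data.frame(
    entry_id = mapping$accession,
    base_contig = mapping$base_contig,
    frame = NA_integer_,
    segment = NA_integer_,
    seq = toupper(mapping$seq),
    stringsAsFactors = FALSE)
  repl$.pos <- as.numeric(first_idx[repl$base_contig])
  keep <- entries[!mapped, , drop = FALSE]
  keep$.pos <- as.numeric(which(!mapped))
  out <- rbind(keep, repl)
  out <- out[order(out$.pos), setdiff(names(out), ".pos"), drop = FALSE]
  rownames(out) <- NULL
  res <- db
  res$entries <- out
  res$n_entries <- nrow(out)
  res$n_source_contigs <- length(unique(out$base_contig))
  res
}
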