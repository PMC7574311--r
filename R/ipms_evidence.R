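# Aggregation of peptide-spectrum matches (PSMs) into per-protein evidence
# and the spectral-count acceptance filter used in IP-MS interactor screens.

#' Read a PSM report
#'
#' Reads a tab-separated peptide-spectrum-match report with a header row.
#' Required columns are `spectrum_id`, `peptide`, `proteins`
#' (semicolon-separated accessions) and `sample`; extra columns are
#' tolerated and search-engine exports with different headers can be
#' mapped via `columns`.
#'
#' @param path Path to the TSV report.
#' @param columns Named character vector mapping required names to the
#'   file's column names, e.g.
#'   `c(spectrum_id = "Spectrum Title", peptide = "Sequence",
#'      proteins = "Protein(s)", sample = "Sample")`.
#' @return data.frame with the four canonical columns.
#' @export
read_psm_report <- function(path, columns = NULL) {
  req <- c("spectrum_id", "peptide", "proteins", "sample")
  df <- .read_tsv(path, required = if (is.null(columns)) req else character())
  if (!is.null(columns)) {
    miss <- setdiff(req, names(columns))
    if (length(miss)) .stop_param("columns mapping lacks: %s",
                                  paste(miss, collapse = ", "))
    absent <- setdiff(unname(columns[req]), names(df))
    if (length(absent)) .stop_input("%s: missing mapped column(s): %s",
                                    path, paste(absent, collapse = ", "))
    df <- df[, unname(columns[req])]
    names(df) <- req
  }
  df[, req]
}

.validate_psms <- function(records) {
  req <- c("spectrum_id", "peptide", "proteins", "sample")
  stopifnot(is.data.frame(records))
  miss <- setdiff(req, names(records))
  if (length(miss)) .stop_input("PSM table lacks column(s): %s",
                                paste(miss, collapse = ", "))
  if (!nrow(records)) return(records)
  if (any(!nzchar(records$peptide)) || any(grepl("*", records$peptide, fixed = TRUE))) {
    .stop_input("peptide sequences must be non-empty and stop-free")
  }
  dup <- duplicated(records[, c("sample", "spectrum_id")])
  if (any(dup)) {
    .stop_input("duplicate spectrum_id within a sample: %s",
                paste(utils::head(unique(records$spectrum_id[dup]), 3),
                      collapse = ", "))
  }
  records
}

# Collapse frame/segment extension ids to their base contig. Canonical ids
# drop "_f<k>" plus an optional trailing "_<j>". Frame-blind ids carry the
# bare contig id for the first segment and "_<j>" (j >= 2) for later ones,
# so a trailing "_<j>" is stripped only when the stripped base itself
# occurs in the accession universe — otherwise "contig_7" would wrongly
# collapse to "contig".
.base_accession <- function(acc, universe = acc) {
  strip_f <- function(x) sub("_f[0-9]+(_[0-9]+)?$", "", x)
  bases <- unique(strip_f(universe))
  out <- strip_f(acc)
  cand <- sub("_([2-9]|[1-9][0-9]+)$", "", out)
  is_ext <- cand != out & cand %in% bases
  out[is_ext] <- cand[is_ext]
  out
}

#' Aggregate PSMs into per-protein evidence
#'
#' Collapses a PSM table into one evidence record per protein accession and
#' sample: the number of distinct peptide sequences, the spectral count
#' (number of PSMs) and, when a protein FASTA is supplied, the sequence
#' coverage. Shared peptides are handled by policy: `"all"` credits every
#' matched protein; `"razor"` credits only the protein with the most
#' distinct peptides (ties to the lexicographically smallest accession),
#' so each PSM contributes to exactly one protein.
#'
#' @param records data.frame of PSMs with columns `spectrum_id`, `peptide`,
#'   `proteins` (semicolon-separated string, or a list column of character
#'   vectors) and `sample`.
#' @param group_extensions If `TRUE`, accessions of the form
#'   `<base>_f<k>`, `<base>_f<k>_<j>` or frame-blind `<base>_<j>` (j >= 2)
#'   collapse to `<base>`, so the evidence for a contig's stop-split
#'   segments is pooled.
#' @param shared_peptide_policy `"all"` (default) or `"razor"`.
#' @param protein_seqs Optional named character vector of protein sequences
#'   (names matching post-grouping accessions) used to compute
#'   `coverage_pct`; accessions without a sequence get `NA` coverage.
#' @return data.frame with columns `accession`, `sample`, `n_peptides`,
#'   `n_spectra`, `coverage_pct`, ordered by sample then accession.
#' @export
aggregate_psms <- function(records, group_extensions = FALSE,
                           shared_peptide_policy = c("all", "razor"),
                           protein_seqs = NULL) {
  policy <- match.arg(shared_peptide_policy)
  records <- .validate_psms(records)
  empty <- data.frame(accession = character(0), sample = character(0),
                      n_peptides = integer(0), n_spectra = integer(0),
                      coverage_pct = numeric(0), stringsAsFactors = FALSE)
  if (!nrow(records)) return(empty)

  prot_list <- if (is.list(records$proteins)) records$proteins else
    strsplit(as.character(records$proteins), ";", fixed = TRUE)
  prot_list <- lapply(prot_list, function(p) {
    p <- trimws(p)
    p <- p[nzchar(p)]
    if (!length(p)) .stop_input("PSM with empty protein list")
    unique(p)
  })
  if (group_extensions) {
    universe <- unique(unlist(prot_list, use.names = FALSE))
    prot_list <- lapply(prot_list, function(p)
      unique(.base_accession(p, universe = universe)))
  }

  # long form: one row per (PSM, protein)
  nper <- lengths(prot_list)
  long <- data.frame(
    sample = rep(records$sample, nper),
    spectrum_id = rep(records$spectrum_id, nper),
    peptide = rep(records$peptide, nper),
    accession = unlist(prot_list, use.names = FALSE),
    stringsAsFactors = FALSE)

  if (policy == "razor") {
    # rank proteins by distinct-peptide support within each sample, then
    # keep each PSM only on its top-ranked protein
    support <- unique(long[, c("sample", "accession", "peptide")])
    cnt <- stats::aggregate(peptide ~ sample + accession, data = support,
                            FUN = function(x) length(unique(x)))
    names(cnt)[3] <- "n_distinct"
    long <- merge(long, cnt, by = c("sample", "accession"), sort = FALSE)
    ord <- order(long$sample, long$spectrum_id,
                 -long$n_distinct, long$accession)
    long <- long[ord, , drop = FALSE]
    keep <- !duplicated(long[, c("sample", "spectrum_id")])
    long <- long[keep, , drop = FALSE]
  }

  # "\r" cannot occur in either token, so the paste key is unambiguous
  key <- factor(paste(long$sample, long$accession, sep = "\r"))
  n_spectra <- as.integer(tapply(long$spectrum_id, key, length))
  n_peptides <- as.integer(tapply(long$peptide, key,
                                  function(x) length(unique(x))))
  parts <- strsplit(levels(key), "\r", fixed = TRUE)
  smp <- vapply(parts, `[[`, character(1), 1L)
  acc <- vapply(parts, `[[`, character(1), 2L)
  out <- data.frame(accession = acc, sample = smp,
                    n_peptides = n_peptides, n_spectra = n_spectra,
                    coverage_pct = NA_real_, stringsAsFactors = FALSE)
  if (!is.null(protein_seqs)) {
    for (i in seq_len(nrow(out))) {
      ps <- protein_seqs[out$accession[i]]
      if (!is.na(ps)) {
        peps <- unique(long$peptide[long$sample == out$sample[i] &
                                      long$accession == out$accession[i]])
        out$coverage_pct[i] <- compute_coverage(ps, peps)
      }
    }
  }
  out <- out[order(out$sample, out$accession), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Apply the spectral-count candidate acceptance filter
#'
#' Retains exactly the evidence records with at least `min_peptides`
#' distinct peptides AND at least `min_spectra` spectra (both bounds
#' inclusive: with the defaults, 3 peptides / 6 spectra passes and
#' 3 peptides / 5 spectra does not). Order is preserved.
#'
#' @param evidence data.frame with columns `n_peptides` and `n_spectra`
#'   (e.g. from [aggregate_psms()]).
#' @param min_peptides Minimum distinct peptides (default 3).
#' @param min_spectra Minimum spectral count (default 6).
#' @param return_all If `TRUE`, return every record with logical `pass`
#'   and character `reason` columns instead of dropping failures.
#' @return Filtered data.frame (or annotated full table).
#' @export
filter_candidates <- function(evidence, min_peptides = 3L, min_spectra = 6L,
                              return_all = FALSE) {
  if (!.is_count(min_peptides) || min_peptides < 0 ||
      !.is_count(min_spectra) || min_spectra < 0) {
    .stop_param("thresholds must be non-negative integers")
  }
  stopifnot(is.data.frame(evidence),
            all(c("n_peptides", "n_spectra") %in% names(evidence)))
  pass_pep <- evidence$n_peptides >= min_peptides
  pass_spec <- evidence$n_spectra >= min_spectra
  pass <- pass_pep & pass_spec
  if (return_all) {
    evidence$pass <- pass
    evidence$reason <- ifelse(pass, "pass",
      ifelse(!pass_pep & !pass_spec, "too_few_peptides;too_few_spectra",
        ifelse(!pass_pep, "too_few_peptides", "too_few_spectra")))
    return(evidence)
  }
  out <- evidence[pass, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Subtract control-sample background from bait candidates
#'
#' Optional background removal against a mock/wild-type
#' immunoprecipitation: a bait candidate is dropped when the same
#' accession appears in the control with a spectral count strictly greater
#' than `max_control_fraction` times its bait spectral count.
#'
#' @param candidates Bait-sample evidence data.frame (post-filter).
#' @param control_evidence Control-sample evidence data.frame.
#' @param max_control_fraction Tolerated control/bait spectral-count ratio
#'   in `[0, 1]` (default 0.5). Equality never drops (strict `>`).
#' @param verbose Log each drop decision to stderr.
#' @return `candidates` with a logical `control_flagged` column, drops
#'   removed.
#' @export
subtract_control <- function(candidates, control_evidence,
                             max_control_fraction = 0.5, verbose = FALSE) {
  if (!is.numeric(max_control_fraction) || max_control_fraction < 0 ||
      max_control_fraction > 1) {
    .stop_param("max_control_fraction must be in [0, 1]")
  }
  stopifnot(is.data.frame(candidates))
  ctrl <- stats::setNames(control_evidence$n_spectra,
                          control_evidence$accession)
  ctrl_n <- ctrl[candidates$accession]
  flagged <- !is.na(ctrl_n) &
    ctrl_n > max_control_fraction * candidates$n_spectra
  if (verbose && any(flagged)) {
    for (i in which(flagged)) {
      message(sprintf("dropping %s: control %d spectra > %.2f x bait %d",
                      candidates$accession[i], ctrl_n[i],
                      max_control_fraction, candidates$n_spectra[i]))
    }
  }
  out <- candidates[!flagged, , drop = FALSE]
  out$control_flagged <- FALSE
  rownames(out) <- NULL
  out
}

#' Sequence coverage of a protein by identified peptides
#'
#' Percentage of the protein's residues covered by at least one exact
#' substring occurrence of any peptide. All occurrences of every peptide
#' are counted and overlapping intervals are merged before measuring, so
#' the result is invariant to peptide order and duplication. Peptides with
#' no occurrence contribute nothing.
#'
#' @param protein_seq Protein sequence (non-empty character scalar).
#' @param peptides Character vector of peptide sequences.
#' @param equate_il If `TRUE`, isoleucine and leucine are treated as
#'   interchangeable when matching (some search engines report I/L
#'   ambiguously). Default `FALSE`.
#' @return Coverage percentage in `[0, 100]`.
#' @examples
#' compute_coverage(strrep("A", 20), c("AAAAA"))  # every 5-mer matches
#' @export
compute_coverage <- function(protein_seq, peptides, equate_il = FALSE) {
  if (!is.character(protein_seq) || length(protein_seq) != 1L ||
      !nzchar(protein_seq)) {
    .stop_param("protein_seq must be a non-empty string")
  }
  peptides <- unique(peptides[nzchar(peptides)])
  if (!length(peptides)) return(0)
  subject <- protein_seq
  if (equate_il) {
    subject <- chartr("I", "L", subject)
    peptides <- chartr("I", "L", peptides)
  }
  starts <- integer(0)
  ends <- integer(0)
  for (p in peptides) {
    m <- gregexpr(p, subject, fixed = TRUE)[[1L]]
    if (m[1L] != -1L) {
      starts <- c(starts, as.integer(m))
      ends <- c(ends, as.integer(m) + nchar(p) - 1L)
    }
  }
  if (!length(starts)) return(0)
  covered <- sum(IRanges::width(IRanges::reduce(IRanges::IRanges(starts, ends))))
  100 * covered / nchar(protein_seq)
}
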