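#' @importFrom Biostrings DNAString DNAStringSet AAString AAStringSet
#' @importFrom Biostrings readBStringSet writeXStringSet reverseComplement
NULL

# IUPAC nucleotide alphabet accepted on input (after uppercasing; U is
# normalized to T before validation).
.IUPAC_NT <- "ACGTMRWSYKVHDBN"

#' Read nucleotide contigs from a FASTA file
#'
#' Reads a multi-record nucleotide FASTA (wrapped or single-line) into a
#' named character vector. The contig id is the first whitespace-delimited
#' token of each header. Sequences are uppercased and `U` is normalized to
#' `T`; any residual non-IUPAC character raises an input error naming the
#' offending contig.
#'
#' @param path Path to a nucleotide FASTA file.
#' @return Named character vector of contig sequences (names are ids).
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">c1 some description", "ATGAAA", ">c2", "TTT"), fa)
#' read_contigs(fa)
#' @export
read_contigs <- function(path) {
  if (!file.exists(path)) .stop_input("FASTA file not found: %s", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) .stop_input(
                    "failed to parse FASTA %s: %s", path, conditionMessage(e)))
  seqs <- as.character(set)
  ids <- vapply(strsplit(names(set), "[ \t]"), `[[`, character(1), 1L)
  if (anyNA(ids) || any(!nzchar(ids))) {
    .stop_input("%s: empty FASTA header encountered", path)
  }
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    .stop_input("duplicate contig id(s): %s",
                paste(unique(dup), collapse = ", "))
  }
  names(seqs) <- ids
  normalize_contigs(seqs)
}

# Uppercase, U->T, and validate the IUPAC alphabet for a named vector of
# contig sequences.
normalize_contigs <- function(seqs) {
  out <- chartr("u", "t", toupper(seqs))
  out <- chartr("U", "T", out)
  bad <- grepl(sprintf("[^%s]", .IUPAC_NT), out)
  if (any(bad)) {
    id <- if (is.null(names(out))) which(bad)[1L] else names(out)[bad][1L]
    .stop_input("contig '%s' contains non-IUPAC nucleotide characters", id)
  }
  out
}

#' Translate one reading frame of a nucleotide sequence
#'
#' Codon-by-codon translation under the standard genetic code (table 1),
#' starting at offset `frame - 1` on the forward strand. A trailing partial
#' codon is dropped. Stop codons translate to `*`; any codon containing a
#' character outside `A/C/G/T` (e.g. `N` or another IUPAC ambiguity code)
#' translates to `X` — an ambiguous codon is never treated as evidence of a
#' stop.
#'
#' @param seq A single nucleotide sequence (character scalar; IUPAC
#'   alphabet, case-insensitive, `U` allowed).
#' @param frame Reading frame, an integer in 1..3.
#' @param id Optional contig id used in error messages.
#' @return Amino-acid string (possibly empty), over the 20 standard
#'   residues plus `X` and `*`.
#' @examples
#' translate_frame("ATGCCTGAAGCTAAATAA", 1) # "MPEAK*"
#' translate_frame("ATGCCTGAAGCTAAATAA", 2) # "CLKLN"
#' @export
translate_frame <- function(seq, frame, id = NULL) {
  if (!.is_count(frame) || frame < 1 || frame > 3) {
    .stop_param("frame must be an integer in 1..3 (got %s)",
                paste(frame, collapse = ","))
  }
  if (!is.character(seq) || length(seq) != 1L) {
    .stop_param("seq must be a single character string")
  }
  names(seq) <- if (is.null(id)) "<unnamed>" else id
  .translate_frames(normalize_contigs(seq), frame)[[1L]]
}

# Vectorized frame translation for a named vector of normalized sequences.
# Returns a character vector of amino-acid strings in the same order.
.translate_frames <- function(seqs, frame) {
  n <- nchar(seqs)
  start <- pmin(frame, n + 1L)
  ncodon <- pmax((n - frame + 1L) %/% 3L, 0L)
  sub <- substr(seqs, start, frame - 1L + 3L * ncodon)
  aa <- suppressWarnings(Biostrings::translate(
    Biostrings::DNAStringSet(sub),
    genetic.code = Biostrings::GENETIC_CODE,
    if.fuzzy.codon = "X", no.init.codon = TRUE))
  out <- as.character(aa)
  names(out) <- names(seqs)
  out
}

#' Split a frame translation at stop codons
#'
#' Returns the maximal `*`-free substrings of a translated frame in
#' left-to-right order. Empty segments arising from leading, trailing or
#' consecutive stops are omitted. `X` residues never trigger a split.
#'
#' @param frame_translation Amino-acid string, possibly containing `*`.
#' @return Character vector of stop-free segments (possibly empty).
#' @examples
#' split_at_stops("MPEAK*MVPEA") # c("MPEAK", "MVPEA")
#' split_at_stops("**MA**")      # "MA"
#' @export
split_at_stops <- function(frame_translation) {
  stopifnot(is.character(frame_translation), length(frame_translation) == 1L)
  if (!nzchar(frame_translation)) return(character(0))
  parts <- strsplit(frame_translation, "*", fixed = TRUE)[[1L]]
  parts[nzchar(parts)]
}

#' Name stop-split segments of one contig frame
#'
#' Two naming styles are supported. `canonical` (default elsewhere) yields
#' globally unique, frame-qualified ids: `<base>_f<frame>` for the first
#' segment and `<base>_f<frame>_<j>` for segment `j >= 2`. `frame_blind`
#' replicates the convention seen in proteogenomic contig databases
#' (`contig_1`, `contig_1_2`, ...): `<base>` for the first segment and
#' `<base>_<j>` for later ones — ids are then not guaranteed unique
#' across frames.
#'
#' @param base_contig Contig id (character scalar).
#' @param frame Reading frame of the segments (integer, 1..6).
#' @param segments Character vector of stop-free segments, in order.
#' @param style `"canonical"` or `"frame_blind"`.
#' @return data.frame with columns `entry_id`, `seq`.
#' @export
name_entries <- function(base_contig, frame, segments,
                         style = c("canonical", "frame_blind")) {
  style <- match.arg(style)
  k <- length(segments)
  if (k == 0L) {
    return(data.frame(entry_id = character(0), seq = character(0),
                      stringsAsFactors = FALSE))
  }
  j <- seq_len(k)
  ids <- if (style == "canonical") {
    ifelse(j == 1L,
           sprintf("%s_f%d", base_contig, frame),
           sprintf("%s_f%d_%d", base_contig, frame, j))
  } else {
    ifelse(j == 1L, base_contig, sprintf("%s_%d", base_contig, j))
  }
  data.frame(entry_id = ids, seq = as.character(segments),
             stringsAsFactors = FALSE)
}

#' Filter entries by minimum segment length
#'
#' Retains exactly the entries whose sequence has at least `min_len`
#' residues (boundary inclusive: with the default of 5, a 5-residue
#' segment is kept). `X` residues count toward the length. Order is
#' preserved.
#'
#' @param entries data.frame with columns `entry_id` and `seq` (extra
#'   columns pass through).
#' @param min_len Minimum retained length in amino acids (default 5).
#' @return The filtered data.frame.
#' @export
filter_min_length <- function(entries, min_len = 5L) {
  if (!.is_count(min_len) || min_len < 1) {
    .stop_param("min_len must be an integer >= 1 (got %s)", min_len)
  }
  stopifnot(is.data.frame(entries), all(c("entry_id", "seq") %in% names(entries)))
  out <- entries[nchar(entries$seq) >= min_len, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a peptide search database from nucleotide contigs
#'
#' Translates every contig in every requested reading frame, splits each
#' frame translation at stop codons, names the resulting segments and
#' removes segments shorter than `min_len`. The default frames are the
#' three forward frames (the transcript orientation is taken as given);
#' frames 4..6 translate the reverse complement and can be requested for a
#' six-frame database. Entry order is deterministic: contig input order,
#' then frame, then segment.
#'
#' Duplicate peptide sequences are retained — the database records raw
#' translated segments, not a non-redundant set.
#'
#' @param contigs Named character vector of nucleotide sequences (names are
#'   contig ids), or a path to a nucleotide FASTA file.
#' @param frames Integer vector, subset of 1..6 (default `1:3`).
#' @param min_len Minimum segment length retained (default 5).
#' @param style Entry naming style, `"canonical"` (frame-qualified, unique)
#'   or `"frame_blind"` (frame-blind `contig`, `contig_2`, ... with a warning on
#'   id collisions).
#' @return A `peptide_db` object: list with `entries` (data.frame
#'   `entry_id`, `base_contig`, `frame`, `segment`, `seq`), `n_entries`,
#'   `n_source_contigs`, `n_input_contigs` and `params`.
#' @examples
#' db <- build_database(c(c1 = "ATGCCTGAAGCTAAATAAATGGTTCCTGAAGCT"))
#' db$entries
#' @export
build_database <- function(contigs, frames = 1:3, min_len = 5L,
                           style = c("canonical", "frame_blind")) {
  style <- match.arg(style)
  if (is.character(contigs) && length(contigs) == 1L && is.null(names(contigs)) &&
      file.exists(contigs)) {
    contigs <- read_contigs(contigs)
  }
  if (length(contigs) && (is.null(names(contigs)) || any(!nzchar(names(contigs))))) {
    .stop_input("contigs must be named (names are contig ids)")
  }
  if (anyDuplicated(names(contigs))) {
    .stop_input("duplicate contig id(s): %s",
                paste(unique(names(contigs)[duplicated(names(contigs))]),
                      collapse = ", "))
  }
  if (!length(frames) || !all(frames %in% 1:6)) {
    .stop_param("frames must be a non-empty subset of 1..6")
  }
  frames <- as.integer(frames)
  contigs <- normalize_contigs(contigs)

  # translate all contigs per frame, then split/name/filter per contig
  trans <- list()
  for (f in sort(unique(frames))) {
    s <- contigs
    if (f > 3L) {
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
      names(s) <- names(contigs)
    }
    trans[[as.character(f)]] <- if (length(s)) {
      .translate_frames(s, ifelse(f > 3L, f - 3L, f))
    } else {
      character(0)
    }
  }

  rows <- vector("list", length(contigs) * length(frames))
  k <- 0L
  for (i in seq_along(contigs)) {
    id <- names(contigs)[i]
    for (f in sort(unique(frames))) {
      segs <- split_at_stops(trans[[as.character(f)]][[i]])
      named <- name_entries(id, f, segs, style = style)
      named <- filter_min_length(cbind(named,
                                       base_contig = rep(id, nrow(named)),
                                       frame = rep(f, nrow(named)),
                                       segment = seq_len(nrow(named))),
                                 min_len = min_len)
      if (nrow(named)) {
        k <- k + 1L
        rows[[k]] <- named
      }
    }
  }
  entries <- if (k) do.call(rbind, rows[seq_len(k)]) else
    data.frame(entry_id = character(0), seq = character(0),
               base_contig = character(0), frame = integer(0),
               segment = integer(0), stringsAsFactors = FALSE)
  entries <- entries[, c("entry_id", "base_contig", "frame", "segment", "seq")]
  rownames(entries) <- NULL

  if (style == "frame_blind" && anyDuplicated(entries$entry_id)) {
    warning(sprintf(
      "frame-blind naming produced %d colliding entry id(s) across frames",
      sum(duplicated(entries$entry_id))), call. = FALSE)
  }

  structure(list(
    entries = entries,
    n_entries = nrow(entries),
    n_source_contigs = length(unique(entries$base_contig)),
    n_input_contigs = length(contigs),
    params = list(frames = frames, min_len = as.integer(min_len),
                  genetic_code = 1L, style = style)
  ), class = "peptide_db")
}

#' @export
print.peptide_db <- function(x, ...) {
  cat(sprintf(
    "peptide_db: %d entries from %d/%d contigs (frames %s, min_len %d, %s naming)\n",
    x$n_entries, x$n_source_contigs, x$n_input_contigs,
    paste(x$params$frames, collapse = ","), x$params$min_len,
    x$params$style))
  if (x$n_entries) {
    print(utils::head(x$entries, 5))
    if (x$n_entries > 5) cat(sprintf("... and %d more\n", x$n_entries - 5L))
  }
  invisible(x)
}

#' Write a peptide database to protein FASTA
#'
#' Headers carry the entry id only; sequences are wrapped at 60 columns.
#' Output is byte-deterministic for a given database.
#'
#' @param db A `peptide_db` object.
#' @param path Output FASTA path.
#' @param summary_path Optional path for a JSON summary
#'   (`n_input_contigs`, `n_entries`, `n_source_contigs`, `params`).
#' @return `path`, invisibly.
#' @export
write_peptide_fasta <- function(db, path, summary_path = NULL) {
  stopifnot(inherits(db, "peptide_db"))
  aa <- Biostrings::AAStringSet(db$entries$seq)
  names(aa) <- db$entries$entry_id
  Biostrings::writeXStringSet(aa, path, width = 60L)
  if (!is.null(summary_path)) {
    jsonlite::write_json(db_summary(db), summary_path,
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' Summarize a peptide database
#'
#' @param db A `peptide_db` object.
#' @return Named list with input/entry/source-contig counts and the
#'   construction parameters.
#' @export
db_summary <- function(db) {
  stopifnot(inherits(db, "peptide_db"))
  list(n_input_contigs = db$n_input_contigs,
       n_entries = db$n_entries,
       n_source_contigs = db$n_source_contigs,
       params = db$params)
}

#' Count records in a FASTA file
#'
#' Streams the file in chunks and counts `>` header lines, so arbitrarily
#' large databases are counted in constant memory. The first non-empty
#' line must be a header; a sequence line appearing before any header is
#' reported with its line number.
#'
#' @param path Path to a FASTA file.
#' @param chunk_size Lines per read (default 65536).
#' @return Integer record count.
#' @export
count_entries <- function(path, chunk_size = 65536L) {
  if (!file.exists(path)) .stop_input("FASTA file not found: %s", path)
  con <- file(path, open = "r")
  on.exit(close(con))
  n <- 0L
  line_no <- 0L
  seen_header <- FALSE
  repeat {
    lines <- readLines(con, n = chunk_size)
    if (!length(lines)) break
    is_hdr <- startsWith(lines, ">")
    if (!seen_header) {
      nonempty <- which(nzchar(trimws(lines)))
      if (length(nonempty)) {
        first <- nonempty[1L]
        if (!is_hdr[first]) {
          .stop_input("%s: line %d: sequence data before first '>' header",
                      path, line_no + first)
        }
        seen_header <- TRUE
      }
    }
    n <- n + sum(is_hdr)
    line_no <- line_no + length(lines)
  }
  n
}
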