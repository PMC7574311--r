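# Seeded synthetic-data generators with serialized ground truth, covering
# every pipeline stage: contig FASTA + expected peptide database, PSM
# reports with planted interactors, and per-tissue DE tables with planted
# common/tissue-specific genes. Truth files are plain TSV/JSON so tests
# never depend on generator internals.

# ---- naive translation oracle -------------------------------------------
# A deliberately simple, independent code path (hard-coded codon table,
# character loop) used to compute the expected database for generated
# contigs. It shares no code with build_database().

.CODON_TABLE <- c(
  TTT="F", TTC="F", TTA="L", TTG="L", CTT="L", CTC="L", CTA="L", CTG="L",
  ATT="I", ATC="I", ATA="I", ATG="M", GTT="V", GTC="V", GTA="V", GTG="V",
  TCT="S", TCC="S", TCA="S", TCG="S", CCT="P", CCC="P", CCA="P", CCG="P",
  ACT="T", ACC="T", ACA="T", ACG="T", GCT="A", GCC="A", GCA="A", GCG="A",
  TAT="Y", TAC="Y", TAA="*", TAG="*", CAT="H", CAC="H", CAA="Q", CAG="Q",
  AAT="N", AAC="N", AAA="K", AAG="K", GAT="D", GAC="D", GAA="E", GAG="E",
  TGT="C", TGC="C", TGA="*", TGG="W", CGT="R", CGC="R", CGA="R", CGG="R",
  AGT="S", AGC="S", AGA="R", AGG="R", GGT="G", GGC="G", GGA="G", GGG="G")

#' Naive reference implementation of database construction
#'
#' A brute-force translator/splitter kept intentionally separate from
#' [build_database()]: it walks each contig codon by codon against a
#' hard-coded standard codon table, splits at stops with a character scan,
#' and applies the length filter directly. Used as the ground-truth oracle
#' for generated contigs and in equivalence tests.
#'
#' @param contigs Named character vector of nucleotide sequences.
#' @param frames Integer vector, subset of 1..3.
#' @param min_len Minimum segment length (default 5).
#' @return data.frame `entry_id`, `base_contig`, `frame`, `segment`,
#'   `seq` under canonical naming.
#' @export
naive_build_database <- function(contigs, frames = 1:3, min_len = 5L) {
  rows <- list()
  for (i in seq_along(contigs)) {
    id <- names(contigs)[i]
    s <- toupper(contigs[[i]])
    s <- gsub("U", "T", s)
    for (f in sort(frames)) {
      chars <- strsplit(s, "")[[1L]]
      aa <- character(0)
      pos <- f
      while (pos + 2L <= length(chars)) {
        codon <- paste(chars[pos:(pos + 2L)], collapse = "")
        aa <- c(aa, if (codon %in% names(.CODON_TABLE))
          .CODON_TABLE[[codon]] else "X")
        pos <- pos + 3L
      }
      # split at stops by scanning
      segs <- character(0)
      cur <- ""
      for (a in aa) {
        if (a == "*") {
          if (nzchar(cur)) segs <- c(segs, cur)
          cur <- ""
        } else cur <- paste0(cur, a)
      }
      if (nzchar(cur)) segs <- c(segs, cur)
      seg_no <- 0L
      for (j in seq_along(segs)) {
        seg_no <- seg_no + 1L
        if (nchar(segs[j]) >= min_len) {
          eid <- if (j == 1L) sprintf("%s_f%d", id, f) else
            sprintf("%s_f%d_%d", id, f, j)
          rows[[length(rows) + 1L]] <- data.frame(
            entry_id = eid, base_contig = id, frame = f, segment = j,
            seq = segs[j], stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(entry_id = character(0), base_contig = character(0),
               frame = integer(0), segment = integer(0),
               seq = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# ---- contig generator ----------------------------------------------------

#' Generate random nucleotide contigs with planted stop codons
#'
#' Draws uniform-random A/C/G/T contigs, injects stop codons (frame 1) at
#' a per-codon density, and masks bases to `N` at a given fraction. The
#' expected peptide database is computed with [naive_build_database()] —
#' an independent code path from the main builder — and serialized with
#' the data so downstream tests have ground truth. Regeneration with the
#' same parameters and seed is byte-identical.
#'
#' @param n Number of contigs.
#' @param length_range Integer `c(min, max)` contig length in nt
#'   (default `c(30, 300)`).
#' @param stop_density Per-codon probability of replacing a frame-1 codon
#'   with a random stop codon (default 0.05).
#' @param n_fraction Per-base probability of masking to `N` (default 0).
#' @param seed Integer RNG seed.
#' @param out_dir Optional directory; when given, writes `contigs.fasta`,
#'   `truth_db.tsv` and `params.json`.
#' @return List: `contigs` (named character), `truth` (expected entry
#'   data.frame), `params`, and `paths` when `out_dir` is given.
#' @export
gen_contigs <- function(n, length_range = c(30L, 300L), stop_density = 0.05,
                        n_fraction = 0, seed = 1L, out_dir = NULL) {
  if (!.is_count(n) || n < 0) .stop_param("n must be a non-negative integer")
  if (length(length_range) != 2L || length_range[1L] > length_range[2L] ||
      any(length_range < 0)) {
    .stop_param("length_range must be c(min, max) with 0 <= min <= max")
  }
  if (stop_density < 0 || stop_density >= 1) {
    .stop_param("stop_density must be in [0, 1)")
  }
  if (n_fraction < 0 || n_fraction > 1) {
    .stop_param("n_fraction must be in [0, 1]")
  }
  stops <- c("TAA", "TAG", "TGA")
  contigs <- withr::with_seed(seed, {
    out <- character(n)
    for (i in seq_len(n)) {
      len <- sample(length_range[1L]:length_range[2L], 1L)
      nt <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
      # inject stops on frame-1 codon boundaries
      ncod <- len %/% 3L
      if (ncod > 0 && stop_density > 0) {
        hit <- which(stats::runif(ncod) < stop_density)
        for (k in hit) {
          nt[(3L * (k - 1L) + 1L):(3L * k)] <-
            strsplit(sample(stops, 1L), "")[[1L]]
        }
      }
      if (n_fraction > 0) {
        mask <- stats::runif(len) < n_fraction
        nt[mask] <- "N"
      }
      out[i] <- paste(nt, collapse = "")
    }
    names(out) <- sprintf("contig_%d", seq_len(n))
    out
  })
  truth <- naive_build_database(contigs)
  params <- list(n = n, length_range = as.integer(length_range),
                 stop_density = stop_density, n_fraction = n_fraction,
                 seed = as.integer(seed))
  res <- list(contigs = contigs, truth = truth, params = params)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    fa <- file.path(out_dir, "contigs.fasta")
    writeLines(if (n) paste0(">", names(contigs), "\n", contigs) else character(0), fa)
    tr <- .write_tsv(truth, file.path(out_dir, "truth_db.tsv"))
    pj <- file.path(out_dir, "params.json")
    jsonlite::write_json(params, pj, auto_unbox = TRUE, pretty = TRUE)
    res$paths <- list(fasta = fa, truth = tr, params = pj)
  }
  res
}

# ---- PSM report generator ------------------------------------------------

.random_peptides <- function(n, len_range = c(8L, 15L)) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  out <- character(0)
  while (length(out) < n) {
    need <- n - length(out)
    lens <- sample(len_range[1L]:len_range[2L], need, replace = TRUE)
    cand <- vapply(lens, function(l)
      paste(sample(aa, l, replace = TRUE), collapse = ""), character(1))
    out <- unique(c(out, cand))
  }
  out[seq_len(n)]
}

#' Generate a synthetic PSM report with planted interactors
#'
#' Emulates an IP-MS experiment: `n_true` planted bait interactors receive
#' peptide/spectrum counts above the acceptance filter and `n_background`
#' background proteins receive counts below it. In `"noiseless"` mode the
#' samplers respect their supports exactly (true: >= 3 peptides and >= 6
#' spectra; background: <= 2 peptides or <= 5 spectra), so the filter
#' recovers the planted labels perfectly. In `"negbin"` mode spectral
#' counts are drawn from negative-binomial distributions (means
#' `nb_mu_true` / `nb_mu_background`) and recovery is whatever the drawn
#' counts imply. A `control_overlap` fraction of background proteins also
#' appears in a control sample.
#'
#' @param n_true,n_background Numbers of planted interactors and
#'   background proteins.
#' @param mode `"noiseless"` (default) or `"negbin"`.
#' @param control_overlap Fraction of background proteins also observed in
#'   the control sample (default 0).
#' @param nb_mu_true,nb_mu_background,nb_size Negative-binomial spectral
#'   count parameters for `"negbin"` mode (defaults 10, 2, 5).
#' @param seed Integer RNG seed.
#' @param out_dir Optional directory; writes `psms.tsv`, `labels.tsv`,
#'   `params.json`.
#' @return List: `psms` (data.frame `spectrum_id`, `peptide`, `proteins`,
#'   `sample`), `labels` (data.frame `accession`, `is_true`, `n_peptides`,
#'   `n_spectra`), `params`, and `paths` when `out_dir` is given.
#' @export
gen_psm_report <- function(n_true, n_background, mode = c("noiseless", "negbin"),
                           control_overlap = 0, nb_mu_true = 10,
                           nb_mu_background = 2, nb_size = 5,
                           seed = 1L, out_dir = NULL) {
  mode <- match.arg(mode)
  if (!.is_count(n_true) || n_true < 0 ||
      !.is_count(n_background) || n_background < 0) {
    .stop_param("n_true and n_background must be non-negative integers")
  }
  if (control_overlap < 0 || control_overlap > 1) {
    .stop_param("control_overlap must be in [0, 1]")
  }
  res <- withr::with_seed(seed, {
    n_prot <- n_true + n_background
    acc <- c(if (n_true) sprintf("interactor_%03d", seq_len(n_true)),
             if (n_background) sprintf("background_%03d", seq_len(n_background)))
    is_true <- c(rep(TRUE, n_true), rep(FALSE, n_background))
    n_pep <- integer(n_prot)
    n_spec <- integer(n_prot)
    for (i in seq_len(n_prot)) {
      if (mode == "noiseless") {
        if (is_true[i]) {
          n_pep[i] <- sample(3:6, 1L)
          n_spec[i] <- max(n_pep[i], sample(6:20, 1L))
        } else if (stats::runif(1) < 0.5) {
          n_pep[i] <- sample(1:2, 1L)        # too few peptides
          n_spec[i] <- n_pep[i] + sample(0:8, 1L)
        } else {
          n_spec[i] <- sample(1:5, 1L)       # too few spectra
          n_pep[i] <- sample(seq_len(min(3L, n_spec[i])), 1L)
        }
      } else {
        mu <- if (is_true[i]) nb_mu_true else nb_mu_background
        n_spec[i] <- stats::rnbinom(1L, size = nb_size, mu = mu)
        n_pep[i] <- if (n_spec[i] == 0L) 0L else
          sample(seq_len(min(n_spec[i], 8L)), 1L)
      }
    }
    keep <- n_spec > 0L
    pep_pool <- .random_peptides(sum(n_pep))
    pep_of <- split(pep_pool, rep(seq_len(n_prot), n_pep))
    rows <- list()
    scan <- 0L
    for (i in which(keep)) {
      peps <- pep_of[[as.character(i)]]
      # every distinct peptide gets >= 1 PSM; remaining spectra recycle
      idx <- c(seq_along(peps),
               if (n_spec[i] > n_pep[i])
                 sample(seq_along(peps), n_spec[i] - n_pep[i], replace = TRUE))
      for (p in idx) {
        scan <- scan + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          spectrum_id = sprintf("bait_scan_%06d", scan),
          peptide = peps[p], proteins = acc[i], sample = "bait",
          stringsAsFactors = FALSE)
      }
    }
    # control sample over a fraction of background proteins
    bg_idx <- which(!is_true & keep)
    n_ctrl <- floor(control_overlap * length(bg_idx))
    ctrl_scan <- 0L
    if (n_ctrl > 0) {
      for (i in bg_idx[sample.int(length(bg_idx), n_ctrl)]) {
        peps <- pep_of[[as.character(i)]]
        ns <- sample(seq_len(max(1L, n_spec[i])), 1L)
        for (s in seq_len(ns)) {
          ctrl_scan <- ctrl_scan + 1L
          rows[[length(rows) + 1L]] <- data.frame(
            spectrum_id = sprintf("ctrl_scan_%06d", ctrl_scan),
            peptide = sample(peps, 1L), proteins = acc[i],
            sample = "control", stringsAsFactors = FALSE)
        }
      }
    }
    psms <- if (length(rows)) do.call(rbind, rows) else
      data.frame(spectrum_id = character(0), peptide = character(0),
                 proteins = character(0), sample = character(0),
                 stringsAsFactors = FALSE)
    labels <- data.frame(accession = acc, is_true = is_true,
                         n_peptides = n_pep, n_spectra = n_spec,
                         stringsAsFactors = FALSE)
    list(psms = psms, labels = labels)
  })
  res$params <- list(n_true = n_true, n_background = n_background,
                     mode = mode, control_overlap = control_overlap,
                     nb_mu_true = nb_mu_true,
                     nb_mu_background = nb_mu_background,
                     nb_size = nb_size, seed = as.integer(seed))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    res$paths <- list(
      psms = .write_tsv(res$psms, file.path(out_dir, "psms.tsv")),
      labels = .write_tsv(res$labels, file.path(out_dir, "labels.tsv")),
      params = file.path(out_dir, "params.json"))
    jsonlite::write_json(res$params, res$paths$params,
                         auto_unbox = TRUE, pretty = TRUE)
  }
  res
}

# ---- DE table generator --------------------------------------------------

#' Generate per-tissue DE tables with planted DEG categories
#'
#' Produces one differential-expression table per tissue (leaf, stem,
#' root) over a shared gene universe. Planted genes receive a significant
#' adjusted p (Uniform on `(0, alpha/10)`) and an above-threshold log2
#' fold change (Normal with mean `lfc_effect` and sd 0.1, signed by
#' direction) in exactly their planted tissues; everywhere else genes get
#' null p-values (Uniform on `(0, 1)`) and sub-threshold fold changes
#' (Uniform on `(-0.9, 0.9)`), so with the default thresholds the planted
#' classification is recovered exactly.
#'
#' @param n_genes Size of the gene universe.
#' @param planted Named integer vector of planted counts, names of the
#'   form `<category>_<direction>` with category one of `common`,
#'   `leaf_specific`, `stem_specific`, `root_specific`, `leaf_stem`,
#'   `leaf_root`, `stem_root` and direction `up` or `down`, e.g.
#'   `c(common_up = 74, common_down = 154, leaf_specific_up = 20)`.
#' @param lfc_effect Mean |log2fc| of planted genes (default 2; must
#'   exceed 1 for recovery at the default 2-fold threshold).
#' @param alpha Significance level the planted p-values are scaled to
#'   (default 0.05).
#' @param seed Integer RNG seed.
#' @param out_dir Optional directory; writes `leaf.tsv`, `stem.tsv`,
#'   `root.tsv`, `truth.tsv`, `params.json`.
#' @return List: `tables` (named list of per-tissue data.frames `gene_id`,
#'   `log2fc`, `padj`), `truth` (data.frame `gene_id`, `direction`,
#'   `category`), `params`, `paths` when `out_dir` is given.
#' @export
gen_de_tables <- function(n_genes, planted, lfc_effect = 2, alpha = 0.05,
                          seed = 1L, out_dir = NULL) {
  if (!.is_count(n_genes) || n_genes < 0) {
    .stop_param("n_genes must be a non-negative integer")
  }
  if (length(planted) && is.null(names(planted))) {
    .stop_param("planted must be a named vector")
  }
  ok_names <- as.vector(outer(.DEG_CATEGORIES, c("up", "down"), paste, sep = "_"))
  bad <- setdiff(names(planted), ok_names)
  if (length(bad)) {
    .stop_param("unknown planted category name(s): %s",
                paste(bad, collapse = ", "))
  }
  planted <- planted[planted > 0]
  if (sum(planted) > n_genes) {
    .stop_param("planted counts (%d) exceed n_genes (%d)",
                sum(planted), n_genes)
  }
  cat_tissues <- list(common = .TISSUES,
                      leaf_specific = "leaf", stem_specific = "stem",
                      root_specific = "root",
                      leaf_stem = c("leaf", "stem"),
                      leaf_root = c("leaf", "root"),
                      stem_root = c("stem", "root"))
  res <- withr::with_seed(seed, {
    genes <- sprintf("gene_%05d", seq_len(n_genes))
    # assign planted genes to slots in order, then shuffle identities
    shuffled <- sample(genes)
    truth_rows <- list()
    assign_idx <- 0L
    plan <- list()  # per gene: list(tissues, sign)
    for (nm in names(planted)) {
      parts <- strsplit(nm, "_")[[1L]]
      dir_word <- parts[length(parts)]
      cat <- paste(parts[-length(parts)], collapse = "_")
      for (k in seq_len(planted[[nm]])) {
        assign_idx <- assign_idx + 1L
        g <- shuffled[assign_idx]
        plan[[g]] <- list(tissues = cat_tissues[[cat]],
                          sign = if (dir_word == "up") 1 else -1)
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          gene_id = g,
          direction = if (dir_word == "up") "increased" else "decreased",
          category = cat, stringsAsFactors = FALSE)
      }
    }
    tables <- stats::setNames(vector("list", 3L), .TISSUES)
    for (t in .TISSUES) {
      lfc <- stats::runif(n_genes, -0.9, 0.9)
      padj <- stats::runif(n_genes)
      for (g in names(plan)) {
        if (t %in% plan[[g]]$tissues) {
          i <- match(g, genes)
          lfc[i] <- plan[[g]]$sign * stats::rnorm(1L, lfc_effect, 0.1)
          padj[i] <- stats::runif(1L, 0, alpha / 10)
        }
      }
      tables[[t]] <- data.frame(gene_id = genes,
                                log2fc = round(lfc, 4),
                                padj = signif(padj, 4),
                                stringsAsFactors = FALSE)
    }
    truth <- if (length(truth_rows)) do.call(rbind, truth_rows) else
      data.frame(gene_id = character(0), direction = character(0),
                 category = character(0), stringsAsFactors = FALSE)
    truth <- truth[order(truth$direction, truth$gene_id), , drop = FALSE]
    rownames(truth) <- NULL
    list(tables = tables, truth = truth)
  })
  res$params <- list(n_genes = n_genes, planted = as.list(planted),
                     lfc_effect = lfc_effect, alpha = alpha,
                     seed = as.integer(seed))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list()
    for (t in .TISSUES) {
      paths[[t]] <- .write_tsv(res$tables[[t]],
                               file.path(out_dir, paste0(t, ".tsv")))
    }
    paths$truth <- .write_tsv(res$truth, file.path(out_dir, "truth.tsv"))
    paths$params <- file.path(out_dir, "params.json")
    jsonlite::write_json(res$params, paths$params,
                         auto_unbox = TRUE, pretty = TRUE)
    res$paths <- paths
  }
  res
}
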