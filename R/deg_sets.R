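# Differential-expression calling at fold-change/adjusted-p thresholds,
# direction-aware multi-tissue set classification (common vs
# tissue-specific vs shared-pair), and expression-plasticity summaries.

.TISSUES <- c("leaf", "stem", "root")

.DEG_CATEGORIES <- c("common",
                     "leaf_specific", "stem_specific", "root_specific",
                     "leaf_stem", "leaf_root", "stem_root")

# membership set (sorted tissue subset) -> category label
.category_of <- function(tissues) {
  tissues <- sort(intersect(.TISSUES, tissues))
  key <- paste(tissues, collapse = "+")
  switch(key,
         "leaf+root+stem" = "common",
         "leaf" = "leaf_specific",
         "stem" = "stem_specific",
         "root" = "root_specific",
         "leaf+stem" = "leaf_stem",
         "leaf+root" = "leaf_root",
         "root+stem" = "stem_root",
         NA_character_)
}

#' Read a per-tissue differential-expression table
#'
#' @param path TSV with a header and columns `gene_id`, `log2fc`, `padj`
#'   (extra columns tolerated).
#' @param tissue Optional tissue label attached as a `tissue` column.
#' @return data.frame with the canonical columns.
#' @export
read_de_table <- function(path, tissue = NULL) {
  df <- .read_tsv(path, required = c("gene_id", "log2fc", "padj"))
  df <- df[, c("gene_id", "log2fc", "padj")]
  bad <- which(!is.na(df$padj) & (df$padj < 0 | df$padj > 1))
  if (length(bad)) {
    .stop_input("%s: row %d: padj outside [0, 1]", path, bad[1L])
  }
  bad <- which(is.na(suppressWarnings(as.numeric(df$log2fc))) &
                 !is.na(df$log2fc))
  if (length(bad)) {
    .stop_input("%s: row %d: non-numeric log2fc", path, bad[1L])
  }
  if (!is.null(tissue)) df$tissue <- tissue
  df
}

#' Call differentially expressed genes
#'
#' A gene is a DEG when its adjusted p-value is strictly below `alpha` and
#' its absolute log2 fold change is at least `log2(min_fold)` (inclusive:
#' with the default 2-fold threshold, `log2fc = 1` exactly qualifies).
#' Missing adjusted p-values never qualify. Direction is `increased` for
#' positive log2 fold change and `decreased` otherwise.
#'
#' @param table data.frame with columns `gene_id`, `log2fc`, `padj` and
#'   optionally `tissue`.
#' @param alpha Adjusted-p threshold (default 0.05, strict `<`).
#' @param min_fold Minimum fold change (default 2; tested as
#'   `|log2fc| >= log2(min_fold)`).
#' @return data.frame of DEGs: `gene_id`, `direction`
#'   (`increased`/`decreased`) and `tissue` when present in the input.
#' @export
call_deg <- function(table, alpha = 0.05, min_fold = 2) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    .stop_param("alpha must be in (0, 1)")
  }
  if (!is.numeric(min_fold) || length(min_fold) != 1L || min_fold <= 1) {
    .stop_param("min_fold must be > 1")
  }
  stopifnot(is.data.frame(table),
            all(c("gene_id", "log2fc", "padj") %in% names(table)))
  lfc <- as.numeric(table$log2fc)
  padj <- as.numeric(table$padj)
  is_deg <- !is.na(padj) & padj < alpha & abs(lfc) >= log2(min_fold)
  out <- table[is_deg, , drop = FALSE]
  out$direction <- ifelse(out$log2fc > 0, "increased", "decreased")
  keep <- intersect(c("gene_id", "tissue", "direction", "log2fc", "padj"),
                    names(out))
  out <- out[, keep, drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify direction-aware tissue specificity of DEGs
#'
#' Given the leaf, stem and root DEG sets of one contrast, assigns every
#' (gene, direction) pair to the category determined by its tissue
#' membership set: `common` (all three tissues), a named single-tissue
#' specific category, or a named shared-pair category. Increased and
#' decreased memberships are tallied independently, so a gene increased in
#' leaf and decreased in root contributes to both directions. Genes absent
#' from a tissue's table are treated as not differentially expressed
#' there.
#'
#' @param leaf,stem,root data.frames of DEG calls with columns `gene_id`
#'   and `direction` (see [call_deg()]).
#' @return List with:
#'   * `genes`: data.frame `gene_id`, `direction`, `membership`
#'     (`+`-joined tissues), `category`;
#'   * `counts`: data.frame `direction`, `category`, `n` covering all 7
#'     categories per direction (zeros included);
#'   * `per_tissue_totals`: data.frame `direction`, `tissue`, `n`;
#'   * `percentages`: data.frame `direction`, `category`, `tissue`, `pct` —
#'     the category count as a whole-number percentage of that tissue's
#'     total DEG count in that direction, for each member tissue.
#' @export
classify_tissue_specificity <- function(leaf, stem, root) {
  sets <- list(leaf = leaf, stem = stem, root = root)
  for (t in names(sets)) {
    stopifnot(is.data.frame(sets[[t]]),
              all(c("gene_id", "direction") %in% names(sets[[t]])))
  }
  long <- do.call(rbind, lapply(.TISSUES, function(t) {
    s <- sets[[t]]
    if (!nrow(s)) return(NULL)
    data.frame(gene_id = s$gene_id, direction = s$direction,
               tissue = t, stringsAsFactors = FALSE)
  }))
  dirs <- c("increased", "decreased")
  if (is.null(long)) {
    genes <- data.frame(gene_id = character(0), direction = character(0),
                        membership = character(0), category = character(0),
                        stringsAsFactors = FALSE)
  } else {
    long <- unique(long)
    key <- paste(long$gene_id, long$direction, sep = "\r")
    memb <- tapply(long$tissue, key,
                   function(x) paste(sort(unique(x)), collapse = "+"))
    parts <- strsplit(names(memb), "\r", fixed = TRUE)
    genes <- data.frame(
      gene_id = vapply(parts, `[[`, character(1), 1L),
      direction = vapply(parts, `[[`, character(1), 2L),
      membership = as.character(memb),
      stringsAsFactors = FALSE)
    genes$category <- vapply(strsplit(genes$membership, "+", fixed = TRUE),
                             .category_of, character(1))
    genes <- genes[order(genes$direction, genes$gene_id), , drop = FALSE]
    rownames(genes) <- NULL
  }

  counts <- expand.grid(direction = dirs, category = .DEG_CATEGORIES,
                        stringsAsFactors = FALSE)
  counts$n <- mapply(function(d, cat) {
    sum(genes$direction == d & genes$category == cat)
  }, counts$direction, counts$category)
  counts <- counts[order(match(counts$direction, dirs),
                         match(counts$category, .DEG_CATEGORIES)), ]
  rownames(counts) <- NULL

  totals <- expand.grid(direction = dirs, tissue = .TISSUES,
                        stringsAsFactors = FALSE)
  totals$n <- mapply(function(d, t) {
    if (is.null(long)) 0L else
      sum(long$direction == d & long$tissue == t)
  }, totals$direction, totals$tissue)

  cat_tissues <- list(common = .TISSUES,
                      leaf_specific = "leaf", stem_specific = "stem",
                      root_specific = "root",
                      leaf_stem = c("leaf", "stem"),
                      leaf_root = c("leaf", "root"),
                      stem_root = c("stem", "root"))
  pct_rows <- list()
  for (i in seq_len(nrow(counts))) {
    for (t in cat_tissues[[counts$category[i]]]) {
      tot <- totals$n[totals$direction == counts$direction[i] &
                        totals$tissue == t]
      pct_rows[[length(pct_rows) + 1L]] <- data.frame(
        direction = counts$direction[i], category = counts$category[i],
        tissue = t,
        pct = if (tot > 0) round_half_up(100 * counts$n[i] / tot) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  percentages <- do.call(rbind, pct_rows)
  rownames(percentages) <- NULL

  list(genes = genes, counts = counts,
       per_tissue_totals = totals, percentages = percentages)
}

#' Summarize transcriptome plasticity between two genotypes
#'
#' Compares per-tissue DEG totals of two genotypes (e.g. a silenced line
#' versus the empty-vector control, each against its own unstressed
#' baseline). Two summaries are computed: the ratio of summed totals
#' (`ratio_of_totals`, the default headline) and the mean of the
#' per-tissue ratios (`mean_of_ratios`). The headline value is rounded
#' half-up to one decimal.
#'
#' @param genotype_a Numeric vector of 3 per-tissue DEG totals (the
#'   denominator genotype).
#' @param genotype_b Numeric vector of 3 per-tissue DEG totals (the
#'   numerator genotype).
#' @param method Headline method: `"ratio_of_totals"` (default) or
#'   `"mean_of_ratios"`.
#' @return List: `headline` (1-decimal), `method`, `ratio_of_totals`,
#'   `mean_of_ratios`, `per_tissue_ratios`.
#' @examples
#' summarize_plasticity(c(998, 1195, 587), c(5521, 4426, 2607))$headline
#' @export
summarize_plasticity <- function(genotype_a, genotype_b,
                                 method = c("ratio_of_totals",
                                            "mean_of_ratios")) {
  method <- match.arg(method)
  if (length(genotype_a) != 3L || length(genotype_b) != 3L) {
    .stop_param("expected 3 per-tissue totals per genotype")
  }
  if (any(genotype_a <= 0) || any(genotype_b <= 0)) {
    .stop_param("DEG totals must be positive (zero denominator undefined)")
  }
  per_tissue <- genotype_b / genotype_a
  rot <- sum(genotype_b) / sum(genotype_a)
  mor <- mean(per_tissue)
  headline <- round_half_up(if (method == "ratio_of_totals") rot else mor, 1)
  list(headline = headline, method = method,
       ratio_of_totals = rot, mean_of_ratios = mor,
       per_tissue_ratios = per_tissue)
}

#' Published per-tissue DEG totals for the drought plasticity contrast
#'
#' Per-tissue counts of drought-responsive DEGs (drought vs control within
#' genotype) for an SPL13-silenced alfalfa line and its empty-vector
#' control, as printed in the source study's results. These are inputs for
#' the plasticity summary, not values the package computes.
#'
#' @return data.frame with columns `genotype`, `tissue`, `n_deg`.
#' @export
published_deg_totals <- function() {
  data.frame(
    genotype = rep(c("SPL13RNAi", "EV"), each = 3L),
    tissue = rep(c("leaf", "stem", "root"), 2L),
    n_deg = c(998L, 1195L, 587L, 5521L, 4426L, 2607L),
    stringsAsFactors = FALSE)
}
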