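# Independent brute-force oracles used across tests. These deliberately
# share no code with the implementation paths they check.

# maximal stop-free runs via regex matching
oracle_split <- function(aa) {
  if (!nzchar(aa)) return(character(0))
  unlist(regmatches(aa, gregexpr("[^*]+", aa)))
}

# per-gene membership enumeration for tissue-specificity classification
oracle_classify <- function(leaf, stem, root) {
  sets <- list(leaf = leaf, stem = stem, root = root)
  pairs <- unique(do.call(rbind, lapply(names(sets), function(t)
    sets[[t]][, c("gene_id", "direction")])))
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    g <- pairs$gene_id[i]; d <- pairs$direction[i]
    member <- vapply(sets, function(s)
      any(s$gene_id == g & s$direction == d), logical(1))
    tis <- names(sets)[member]
    cat <- if (length(tis) == 3) "common"
      else if (length(tis) == 1) paste0(tis, "_specific")
      else {
        both <- sort(factor(tis, levels = c("leaf", "stem", "root")))
        paste(as.character(both), collapse = "_")
      }
    data.frame(gene_id = g, direction = d, category = cat,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res[order(res$direction, res$gene_id), , drop = FALSE]
}

# random DEG call tables (gene_id, direction) for property tests
random_deg_sets <- function(n_genes, p_member = 0.3) {
  genes <- sprintf("g%04d", seq_len(n_genes))
  make <- function() {
    pick <- genes[runif(n_genes) < p_member]
    if (!length(pick)) {
      return(data.frame(gene_id = character(0), direction = character(0),
                        stringsAsFactors = FALSE))
    }
    data.frame(gene_id = pick,
               direction = sample(c("increased", "decreased"),
                                  length(pick), replace = TRUE),
               stringsAsFactors = FALSE)
  }
  list(leaf = make(), stem = make(), root = make())
}

# normalize an entry data.frame for set comparison
entry_set <- function(entries) {
  df <- entries[order(entries$entry_id, entries$seq),
                c("entry_id", "base_contig", "frame", "segment", "seq")]
  rownames(df) <- NULL
  df
}
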