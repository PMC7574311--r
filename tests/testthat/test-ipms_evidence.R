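make_psms <- function(peptides, proteins, sample = "bait",
                      ids = sprintf("scan_%03d", seq_along(peptides))) {
  data.frame(spectrum_id = ids, peptide = peptides, proteins = proteins,
             sample = rep_len(sample, length(peptides)),
             stringsAsFactors = FALSE)
}

test_that("PSM aggregation pools contig extensions and counts distinct peptides", {
  psms <- make_psms(c("PEPTIDEA", "PEPTIDEA", "PEPTIDEB", "PEPTIDEC"),
                    c("contig_7", "contig_7", "contig_7_2", "contig_7"))
  ev <- aggregate_psms(psms, group_extensions = TRUE)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$accession, "contig_7")
  expect_identical(ev$n_peptides, 3L)
  expect_identical(ev$n_spectra, 4L)
  # ungrouped, the extension is a separate accession
  ev2 <- aggregate_psms(psms)
  expect_setequal(ev2$accession, c("contig_7", "contig_7_2"))
  # canonical frame-qualified ids group too
  psms3 <- make_psms(c("AAAK", "BBBK"), c("c5_f2", "c5_f2_3"))
  expect_identical(aggregate_psms(psms3, group_extensions = TRUE)$accession, "c5")
  expect_identical(nrow(aggregate_psms(make_psms(character(0), character(0)))), 0L)
})

test_that("shared peptides follow the all vs razor policies", {
  # one peptide shared by A (2 other peptides) and B (0 others)
  psms <- make_psms(c("SHAREDPEP", "AONLYPEP", "AONLYPEPTWO"),
                    c("A;B", "A", "A"))
  all_ev <- aggregate_psms(psms, shared_peptide_policy = "all")
  expect_identical(all_ev$n_spectra[all_ev$accession == "A"], 3L)
  expect_identical(all_ev$n_spectra[all_ev$accession == "B"], 1L)
  razor <- aggregate_psms(psms, shared_peptide_policy = "razor")
  expect_identical(razor$accession, "A")
  expect_identical(razor$n_spectra, 3L)
  # tie on distinct peptides -> lexicographically smallest accession
  tie <- aggregate_psms(make_psms("TIEPEP", "B;A"),
                        shared_peptide_policy = "razor")
  expect_identical(tie$accession, "A")
})

test_that("razor policy conserves spectra: each PSM credited exactly once", {
  withr::with_seed(13, {
    for (rep in 1:5) {
      n <- 60L
      prots <- sprintf("P%02d", 1:8)
      psms <- make_psms(
        peptides = sprintf("PEP%02d", sample(1:25, n, replace = TRUE)),
        proteins = vapply(1:n, function(i)
          paste(sample(prots, sample(1:3, 1)), collapse = ";"), character(1)),
        ids = sprintf("s%03d", 1:n))
      ev <- aggregate_psms(psms, shared_peptide_policy = "razor")
      expect_identical(sum(ev$n_spectra), n)
      expect_true(all(ev$n_spectra >= ev$n_peptides))
    }
  })
})

test_that("aggregation rejects duplicate spectrum ids within a sample", {
  dup <- make_psms(c("AAK", "CCK"), c("A", "B"), ids = c("s1", "s1"))
  expect_error(aggregate_psms(dup), class = "proteodeg_input_error")
  # same id in different samples is fine
  ok <- rbind(make_psms("AAK", "A", sample = "bait", ids = "s1"),
              make_psms("CCK", "B", sample = "control", ids = "s1"))
  expect_identical(nrow(aggregate_psms(ok)), 2L)
})

test_that("candidate filter applies inclusive peptide and spectrum thresholds", {
  ev <- data.frame(
    accession = c("dfr", "chs2", "a", "b", "c"),
    n_peptides = c(6L, 9L, 2L, 3L, 3L),
    n_spectra = c(12L, 38L, 10L, 5L, 6L))
  kept <- filter_candidates(ev)
  expect_setequal(kept$accession, c("dfr", "chs2", "c"))
  annotated <- filter_candidates(ev, return_all = TRUE)
  expect_identical(annotated$reason[annotated$accession == "a"],
                   "too_few_peptides")
  expect_identical(annotated$reason[annotated$accession == "b"],
                   "too_few_spectra")
  expect_error(filter_candidates(ev, min_peptides = -1),
               class = "proteodeg_parameter_error")
})

test_that("published interactor evidence rows all satisfy the acceptance filter", {
  path <- system.file("extdata", "spl13_ipms_candidates.tsv",
                      package = "proteodeg")
  tab <- read.delim(path, stringsAsFactors = FALSE)
  kept <- filter_candidates(tab)
  expect_identical(nrow(kept), nrow(tab))
  dfr <- tab[tab$accession == "Dihydroflavonol_4-reductase", ]
  expect_identical(c(dfr$n_peptides, dfr$n_spectra), c(6L, 12L))
  chs2 <- tab[tab$accession == "Chalcone_synthase_2", ]
  expect_identical(c(chs2$n_peptides, chs2$n_spectra), c(9L, 38L))
})

test_that("raising either filter threshold never gains candidates", {
  withr::with_seed(21, {
    ev <- data.frame(accession = sprintf("p%03d", 1:200),
                     n_peptides = rpois(200, 4),
                     n_spectra = rpois(200, 8))
    ev$n_spectra <- pmax(ev$n_spectra, ev$n_peptides)
    for (mp in 0:6) {
      for (ms in 0:10) {
        n0 <- nrow(filter_candidates(ev, mp, ms))
        expect_lte(nrow(filter_candidates(ev, mp + 1L, ms)), n0)
        expect_lte(nrow(filter_candidates(ev, mp, ms + 1L)), n0)
      }
    }
  })
})

test_that("control subtraction drops on strict excess over the tolerated fraction", {
  bait <- data.frame(accession = c("x", "y", "z"),
                     n_peptides = c(3L, 4L, 5L),
                     n_spectra = c(10L, 10L, 8L))
  ctrl <- data.frame(accession = c("y", "z"),
                     n_peptides = c(2L, 2L),
                     n_spectra = c(8L, 4L))
  # y: 8 > 0.5*10 -> dropped; z: 4 <= 0.5*8 -> kept; x absent -> kept
  out <- subtract_control(bait, ctrl, 0.5)
  expect_setequal(out$accession, c("x", "z"))
  # equality never drops (strict >)
  eq <- subtract_control(data.frame(accession = "x", n_peptides = 3L,
                                    n_spectra = 8L),
                         data.frame(accession = "x", n_peptides = 1L,
                                    n_spectra = 8L),
                         max_control_fraction = 1.0)
  expect_identical(eq$accession, "x")
  expect_error(subtract_control(bait, ctrl, 1.5),
               class = "proteodeg_parameter_error")
})

test_that("coverage merges overlapping occurrences and is order/duplication invariant", {
  prot <- paste0("ABCDEFGH", strrep("Q", 12))  # length 20
  # peptides covering residues 1-5 and 3-8 -> union 1-8 of 20 = 40%
  expect_equal(compute_coverage(prot, c("ABCDE", "CDEFGH")), 40)
  expect_equal(compute_coverage(prot, c("CDEFGH", "ABCDE", "ABCDE")), 40)
  expect_equal(compute_coverage(prot, prot), 100)
  expect_equal(compute_coverage(prot, "WWWW"), 0)
  expect_equal(compute_coverage(prot, character(0)), 0)
  # all occurrences of a repeated peptide count
  expect_equal(compute_coverage("AAQQAAQQAA", "AA"), 60)
  expect_error(compute_coverage("", "AA"), class = "proteodeg_parameter_error")
  # I/L equivalence only when requested
  expect_equal(compute_coverage("MILK", "MLLK"), 0)
  expect_equal(compute_coverage("MILK", "MLLK", equate_il = TRUE), 100)
})

test_that("coverage feeds through aggregation when protein sequences are given", {
  psms <- make_psms(c("ABCDE", "CDEFGH"), c("p1", "p1"))
  seqs <- c(p1 = paste0("ABCDEFGH", strrep("Q", 12)))
  ev <- aggregate_psms(psms, protein_seqs = seqs)
  expect_equal(ev$coverage_pct, 40)
})

test_that("PSM reports read with canonical or mapped column names", {
  tsv <- tempfile(fileext = ".tsv")
  write.table(data.frame("Spectrum Title" = c("s1", "s2"),
                         Sequence = c("AAK", "CCK"),
                         "Protein(s)" = c("A", "A;B"),
                         Sample = "bait", Extra = 1, check.names = FALSE),
              tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  df <- read_psm_report(tsv, columns = c(spectrum_id = "Spectrum Title",
                                         peptide = "Sequence",
                                         proteins = "Protein(s)",
                                         sample = "Sample"))
  expect_identical(names(df), c("spectrum_id", "peptide", "proteins", "sample"))
  ev <- aggregate_psms(df)
  expect_setequal(ev$accession, c("A", "B"))
  expect_error(read_psm_report(tsv), class = "proteodeg_input_error")
})
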