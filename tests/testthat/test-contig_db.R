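test_that("frame translation follows the standard code with partial-codon drop", {
  expect_identical(translate_frame("ATG", 1), "M")
  expect_identical(translate_frame("ATGCCTGAAGCTAAATAA", 1), "MPEAK*")
  # offset by one, trailing 2 nt dropped
  expect_identical(translate_frame("ATGCCTGAAGCTAAATAA", 2), "CLKLN")
  expect_identical(translate_frame("ATGCCTGAAGCTAAATAA", 3), "A*S*I")
  # ambiguous codons become X, never a stop
  expect_identical(translate_frame("ATGNNA", 1), "MX")
  expect_identical(translate_frame("atgrna", 1), "MX")
  # U is normalized to T
  expect_identical(translate_frame("AUGUUU", 1), "MF")
  expect_identical(translate_frame("", 1), "")
  expect_identical(translate_frame("AT", 1), "")
})

test_that("translation rejects bad frames and non-IUPAC input", {
  expect_error(translate_frame("ATG", 0), class = "proteodeg_parameter_error")
  expect_error(translate_frame("ATG", 4), class = "proteodeg_parameter_error")
  expect_error(translate_frame("AT-G", 1, id = "bad1"), "bad1",
               class = "proteodeg_input_error")
})

test_that("stop splitting returns maximal stop-free segments in order", {
  expect_identical(split_at_stops("MPEAK*MVPEA"), c("MPEAK", "MVPEA"))
  expect_identical(split_at_stops("MPEAK"), "MPEAK")
  expect_identical(split_at_stops("**MA**"), "MA")
  expect_identical(split_at_stops("*"), character(0))
  expect_identical(split_at_stops(""), character(0))
  # X never splits
  expect_identical(split_at_stops("MAXXA"), "MAXXA")
})

test_that("stop splitting agrees with a regex oracle on random translations", {
  withr::with_seed(42, {
    for (i in 1:50) {
      aa <- paste(sample(c(LETTERS[1:20], "*", "X"), sample(0:40, 1),
                         replace = TRUE, prob = c(rep(1, 21), 3)),
                  collapse = "")
      expect_identical(split_at_stops(aa), oracle_split(aa), label = aa)
    }
  })
})

test_that("entry naming follows canonical and frame-blind styles", {
  fb <- name_entries("contig_1", 1, c("MPEAK", "MVPEA"), style = "frame_blind")
  expect_identical(fb$entry_id, c("contig_1", "contig_1_2"))
  expect_identical(fb$seq, c("MPEAK", "MVPEA"))
  canon <- name_entries("c9", 2, "AAAAA", style = "canonical")
  expect_identical(canon$entry_id, "c9_f2")
  expect_identical(nrow(name_entries("c9", 3, character(0), "canonical")), 0L)
  canon3 <- name_entries("c9", 3, c("A", "B", "C"), style = "canonical")
  expect_identical(canon3$entry_id, c("c9_f3", "c9_f3_2", "c9_f3_3"))
})

test_that("length filter is boundary-inclusive and order-preserving", {
  entries <- data.frame(entry_id = c("a", "b"), seq = c("MAK", "MPEAK"),
                        stringsAsFactors = FALSE)
  expect_identical(filter_min_length(entries, 5)$entry_id, "b")
  five <- data.frame(entry_id = "b", seq = "MPEAK", stringsAsFactors = FALSE)
  expect_identical(filter_min_length(five, 5), five)
  empty <- five[0, ]
  expect_identical(nrow(filter_min_length(empty, 5)), 0L)
  expect_error(filter_min_length(five, 0), class = "proteodeg_parameter_error")
})

test_that("build_database composes translate/split/name/filter and matches the oracle", {
  expect_identical(build_database(c())$n_entries, 0L)
  toy <- c(c1 = "ATGCCTGAAGCTAAATAAATGGTTCCTGAAGCT", c2 = "TTTTT")
  db <- build_database(toy)
  expect_identical(entry_set(db$entries), entry_set(naive_build_database(toy)))
  expect_identical(db$n_entries, nrow(db$entries))
  expect_identical(db$n_source_contigs, 1L)  # c2 yields no >=5 aa segment
  expect_identical(db$n_input_contigs, 2L)
  # deterministic ordering: contig, then frame, then segment
  expect_false(is.unsorted(match(db$entries$base_contig, names(toy))))
  expect_error(build_database(c(a = "ATG", a = "TTT")),
               class = "proteodeg_input_error")
})

test_that("frame-blind naming warns when ids collide across frames", {
  # both frame 1 and frame 2 yield a surviving first segment -> same id
  contig <- c(cX = "ATGCCTGAAGCTAAAGCTATGCCTGAA")
  expect_warning(db <- build_database(contig, style = "frame_blind"), "collid")
  expect_true(any(duplicated(db$entries$entry_id)))
})

test_that("six-frame mode translates the reverse complement as frames 4-6", {
  contig <- c(r1 = "ATGCCTGAAGCTAAAGGGTTT")
  db6 <- build_database(contig, frames = 1:6, min_len = 5)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(contig[[1]])))
  f4 <- db6$entries[db6$entries$frame == 4, ]
  expect_identical(f4$seq, split_at_stops(translate_frame(rc, 1)))
  expect_identical(f4$entry_id[1], "r1_f4")
})

test_that("FASTA round trip preserves entries and output is byte-deterministic", {
  g <- gen_contigs(30, length_range = c(20, 250), stop_density = 0.08,
                   n_fraction = 0.03, seed = 9)
  db <- build_database(g$contigs)
  f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
  s1 <- tempfile(fileext = ".json")
  write_peptide_fasta(db, f1, summary_path = s1)
  write_peptide_fasta(build_database(g$contigs), f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- Biostrings::readAAStringSet(f1)
  expect_identical(names(back), db$entries$entry_id)
  expect_identical(unname(as.character(back)), db$entries$seq)
  smry <- jsonlite::read_json(s1)
  expect_identical(smry$n_entries, db$n_entries)
  expect_identical(smry$n_source_contigs, db$n_source_contigs)
})

test_that("count_entries streams records and flags malformed files", {
  empty <- tempfile(); file.create(empty)
  expect_identical(count_entries(empty), 0L)
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "MPEAK", ">b", "MMMM", "MMMM", ">c desc", "MA"), fa)
  expect_identical(count_entries(fa), 3L)
  # built database round trip agrees with the oracle's record count
  toy <- c(c1 = "ATGCCTGAAGCTAAATAAATGGTTCCTGAAGCT", c2 = "TTTTT")
  out <- tempfile(fileext = ".fasta")
  write_peptide_fasta(build_database(toy), out)
  expect_identical(count_entries(out), nrow(naive_build_database(toy)))
  bad <- tempfile()
  writeLines(c("", "ACGT", ">a", "ACGT"), bad)
  expect_error(count_entries(bad), "line 2", class = "proteodeg_input_error")
})

test_that("database entries never contain stops or short segments; min_len is monotone", {
  withr::with_seed(7, {
    for (rep in 1:3) {
      seqs <- vapply(sample(0:120, 40, replace = TRUE), function(l)
        paste(sample(c("A", "C", "G", "T", "N"), l, replace = TRUE,
                     prob = c(1, 1, 1, 1, 0.2)), collapse = ""), character(1))
      names(seqs) <- sprintf("s%02d", seq_along(seqs))
      prev <- Inf
      for (ml in c(1, 5, 10, 20)) {
        db <- build_database(seqs, min_len = ml)
        expect_false(any(grepl("*", db$entries$seq, fixed = TRUE)))
        expect_true(all(nchar(db$entries$seq) >= ml))
        expect_lte(db$n_entries, prev)
        prev <- db$n_entries
      }
    }
  })
})
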