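---
title: "Methods: proteogenomic databases, IP-MS evidence and tissue-specific DEG sets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proteogenomic databases, IP-MS evidence and tissue-specific DEG sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteodeg)
```

## The problem

Alfalfa (*Medicago sativa*) has no complete reference proteome, so
peptide-spectrum searches against the congener *M. truncatula* proteome
miss genuinely alfalfa-specific proteins. A practical workaround is
proteogenomic: translate the species' own transcriptome contigs into a
peptide search database and search spectra against that. `proteodeg`
implements this database construction, the downstream spectral-count
filtering used to call candidate bait interactors in
immunoprecipitation–mass-spectrometry (IP-MS) screens, best-hit homolog
annotation of the candidates, and the direction-aware multi-tissue
classification of differential-expression results that the same kind of
drought study produces — plus a seeded synthetic-data generator so that
every stage can be exercised, with known ground truth, without any
external download.

## Database construction from contigs

Each contig is translated codon-by-codon under the standard genetic code
in the three forward reading frames (offsets 0, 1, 2 from the 5′ end). The
choice of forward-only frames is deliberate: assembled transcript contigs
carry their sense-strand orientation, so the reverse strand adds noise
entries without adding real coding sequence.
For assemblies of uncertain orientation, `build_database(frames = 1:6)`
adds the three reverse-complement frames, named `f4`–`f6`.

Numerical/edge rules, all of which the tests pin down:

* A trailing partial codon (fewer than 3 nt) is dropped silently.
* Any codon containing a character outside `A/C/G/T` (an `N` or another
  IUPAC ambiguity code) translates to `X`. An `X` is **not** a stop: only
  `*` splits a translation. An ambiguous codon is not evidence of a stop,
  so this choice is conservative — it can only lengthen segments.
* `U` is normalized to `T` and case is ignored; any character outside the
  IUPAC nucleotide alphabet is an input error naming the contig.
* A frame translation is split at stop codons into its maximal stop-free
  runs; empty runs (leading/trailing/consecutive stops) are dropped.
* Segments shorter than `min_len` (default 5 aa, boundary inclusive —
  a 5-residue segment is kept) are removed after splitting. `X` residues
  count toward the length.
* Duplicate peptide sequences are retained; the database records raw
  translated segments and its entry count is a raw count.

Entry naming was genuinely open. The frame-blind convention
(`contig_1` for a contig's first segment, `contig_1_2` for the second)
cannot distinguish the same segment index in different frames, so the
default here is a frame-qualified canonical form (`contig_1_f2`,
`contig_1_f2_2`, ...) that is globally unique; the frame-blind style
remains available as `style = "frame_blind"` and warns when ids collide.

`count_entries()` streams a FASTA in chunks and counts `>` records in
constant memory, which is how one verifies a multi-gigabyte deposited
database against its published entry count without loading it.

## IP-MS evidence and the candidate filter

`aggregate_psms()` collapses a PSM table into per-protein, per-sample
evidence: distinct peptide sequences (`n_peptides`, modifications
ignored), spectral count (`n_spectra`, the PSM count), and sequence
coverage when protein sequences are supplied. Two shared-peptide policies
are provided because protein inference conventions differ across tools:
`"all"` (default; a shared peptide credits every matched protein — naive
spectral counting) and `"razor"` (credits only the protein with the most
distinct peptides, ties to the lexicographically smallest accession, so
summed spectral counts conserve the PSM total).

When evidence is pooled per contig (`group_extensions = TRUE`), ids are
collapsed to their base contig. Canonical ids strip `_f<k>` and an
optional trailing segment index. For frame-blind ids a trailing `_<j>`
(j ≥ 2) is stripped *only when the stripped base itself occurs among the
accessions*: extensions are numbered from 2, so `contig_7_2` groups with
`contig_7`, while `contig_7` alone is a base id and must not collapse to
`contig`. A base contig genuinely named like an extension (e.g. a contig
literally called `x_2` in a dataset that also contains `x`) would be
mis-grouped; such naming should be avoided upstream.

The candidate filter keeps proteins with at least 3 distinct peptides
**and** at least 6 spectra, both bounds inclusive ("at least" is
literal): 3/6 passes, 3/5 and 2/anything do not. Control subtraction is
off by default — no published rule for using the wild-type control IP is
stated in this class of experiment — but `subtract_control()` documents
one: drop a bait candidate when the control spectral count strictly
exceeds `max_control_fraction` (default 0.5) times the bait count.

Coverage is the percentage of protein residues covered by at least one
exact substring occurrence of any peptide; all occurrences count and
overlaps are merged (interval union via `IRanges::reduce`), making the
result invariant to peptide order and duplication. Isoleucine and leucine
are distinct by default (`equate_il = TRUE` collapses them, for search
engines that report I/L ambiguously).

## Homolog annotation and the confirmation database

"Best fit" annotation is implemented as the highest Smith–Waterman local
alignment score under BLOSUM62 with affine gaps (open 11, extend 1) —
the standard protein-search scoring — with ties broken by higher percent
identity, then lexicographically smaller accession, so results are
independent of reference order. Percent identity is computed over aligned
columns. No E-values are computed: ranking is by raw score, since
database-size calibration is out of scope and the reference sets involved
are small. When two reference sets are available (a large congener
proteome and a small same-species set), annotate against each and take
the primary annotation from the higher-scoring hit.

`replace_with_homologs()` builds the confirmation database: all frame and
segment entries of a mapped candidate contig are removed and replaced by
a single entry carrying the homolog's accession and sequence (replacement
is at contig granularity, not per segment). The operation is idempotent
for a fixed mapping, and mappings to absent contigs warn and are skipped.

## DEG calling and tissue-specificity classification

A gene is differentially expressed when its corrected p-value is strictly
below `alpha` (default 0.05) and its absolute log2 fold change is at
least `log2(min_fold)` (default 2-fold, i.e. `|log2fc| >= 1`, inclusive —
a literal reading of "at least 2-fold"). Missing corrected p-values never
qualify. Multiple-testing correction itself is out of scope: the `padj`
column is taken as produced by the upstream RNA-seq pipeline.

Classification is per direction: a gene's increased and decreased
memberships are tallied independently (a gene up in leaf and down in root
appears once in each direction), and each (gene, direction) pair falls in
exactly one of seven categories — common to all three tissues, one of
three single-tissue-specific categories, or one of three shared-pair
categories — so the counts partition each direction's union. Genes absent
from a tissue's table are treated as not differentially expressed there,
which matters for "common" membership when tables are pre-filtered
upstream. Category percentages are reported per member tissue as
whole-number shares of that tissue's total DEG count in that direction,
rounded half-up, matching how such Venn panels are usually labelled.

`summarize_plasticity()` compares per-tissue DEG totals of two genotypes.
"Average fold" is ambiguous between the ratio of summed totals and the
mean of per-tissue ratios (for the published totals 998/1195/587 vs
5521/4426/2607 these give 4.52 and 4.56); both are returned, and the
headline defaults to the ratio of totals, rounded half-up to one decimal
(4.5 for those inputs). Zero denominators are an error, not an `Inf`.

## The synthetic-data generator

The generators emulate the *structure* of each stage's input, with
minimal, explicit noise models — no distributional information is
available for the real data, so every parameter is surfaced and the
defaults are chosen to be plain:

* **Contigs** (`gen_contigs`): uniform-random A/C/G/T sequences (default
  lengths 30–300 nt, the short-contig regime where early stops and
  sub-5-aa segments are common), stop codons injected on frame-1 codon
  boundaries at a per-codon density (default 0.05), and optional `N`
  masking. The expected database is computed by `naive_build_database()`,
  a deliberately independent brute-force code path (hard-coded codon
  table, character loops), and serialized as truth.
* **PSM reports** (`gen_psm_report`): in noiseless mode, planted
  interactors draw 3–6 distinct peptides and ≥ 6 spectra while background
  proteins draw ≤ 2 peptides or ≤ 5 spectra, so the acceptance filter
  recovers the labels with precision = recall = 1 by construction — this
  validates the filter's logic, not its real-world error rate. A
  negative-binomial mode (default mean spectra 10 for interactors, 2 for
  background, size 5) produces overlapping counts for studying imperfect
  recovery; its oracle is a direct threshold check on the drawn counts.
* **DE tables** (`gen_de_tables`): planted genes receive significant
  corrected p (Uniform on (0, alpha/10)) and |log2fc| ~ Normal(effect,
  0.1), signed by direction, in exactly their planted tissues; everything
  else is null (p ~ Uniform(0,1), log2fc ~ Uniform(−0.9, 0.9), below the
  2-fold threshold by construction). The effect is not clamped, so
  setting it below 1 is a negative control in which planted genes are
  correctly not recovered.

What passing on synthetic data does **not** show: real contigs are not
uniform-random (codon usage, UTRs, assembly artifacts), real spectral
counts are length- and abundance-dependent and contaminated by carryover,
and real DE tables have correlated genes and p-value/effect dependence.
The synthetic results certify the set logic, thresholds and bookkeeping
of each stage, not biological performance.

Identical parameters and seed give byte-identical output files; truth is
written as plain TSV/JSON alongside the data.

## Worked example

```{r pipeline}
# database construction, checked against the independent oracle
g <- gen_contigs(50, seed = 7)
db <- build_database(g$contigs)
db
identical(nrow(db$entries), nrow(g$truth))

# IP-MS: planted interactors recovered by the 3-peptide/6-spectrum filter
p <- gen_psm_report(n_true = 10, n_background = 90, seed = 7)
ev <- aggregate_psms(p$psms)
cand <- filter_candidates(ev[ev$sample == "bait", ])
setequal(cand$accession, p$labels$accession[p$labels$is_true])

# DEG classification with planted common sets
d <- gen_de_tables(2000, c(common_up = 74, common_down = 154), seed = 7)
degs <- lapply(d$tables, call_deg)
cl <- classify_tissue_specificity(degs$leaf, degs$stem, degs$root)
subset(cl$counts, n > 0)

# genotype plasticity from published per-tissue DEG totals
totals <- published_deg_totals()
summarize_plasticity(totals$n_deg[totals$genotype == "SPL13RNAi"],
                     totals$n_deg[totals$genotype == "EV"])$headline
```

## Problem sizes and limitations

The shipped tests run the oracle-equivalence check on 200 random contigs
(lengths 0–300 nt, 5% `N` density), the filter-recovery check on 500
proteins, and the classification oracle on 1000 genes with a 3000-gene
planted-recovery run — sizes at which every suite completes in seconds
while exercising all edge regimes (length-0 contigs, all-stop frames,
boundary counts). Known limitations: frame-blind entry naming cannot be
grouped safely when base ids mimic extension suffixes; `best_fit` is
exact (all-pairs local alignment) and is not meant for large reference
proteomes — use a heuristic search tool there and feed its results in;
and coverage requires exact substring matches, so peptides spanning
sequence variants do not count toward coverage.
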