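spl13_ipms_candidates.tsv

Per-protein IP-MS evidence (sequence coverage %, distinct peptides,
spectral count) for SPL13 bait candidates, transcribed from the published
interactor table of the source drought study. Only rows whose column
boundaries parse unambiguously from the typeset table are included; rows
with ambiguous digit runs (e.g. the eukaryotic translation initiation
factor 5A-1 row) are deliberately excluded. All included rows satisfy the
study's acceptance filter of at least 3 distinct peptides and 6 spectra.
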