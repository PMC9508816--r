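Package: ppredit
Title: PPR-Guided C-to-U RNA Editing: Code Prediction, Off-Target Calling
    and Consensus Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing C-to-U RNA editing installed by PLS-type
    pentatricopeptide repeat (PPR) editing factors expressed against a
    heterologous transcriptome. Implements the PPR-RNA recognition code and
    array-target juxtaposition, replicate-filtered off-target calling from
    per-site base counts against editing-dead controls, per-position
    nucleotide consensus profiles with decile-weighted matching scores, a
    transcriptome-wide candidate-target scanner, editing-site nomenclature
    (eU labels), and a synthetic-data generator that emulates the RNA-seq
    structure of such an experiment (binomial editing, Poisson coverage,
    sequencing-error background) so the whole pipeline can be exercised end
    to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
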