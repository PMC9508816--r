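---
title: "Models and methods behind ppredit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ppredit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppredit)
```

# The biological setting

Plant organelles convert specific cytidines to uridines in their transcripts.
The specificity factors are PLS-type pentatricopeptide repeat (PPR) proteins:
arrays of ~35-amino-acid helical repeats, alternating P ("canonical"), L
("long") and S ("short") variants and ending in a P2-L2-S2 triplet, followed
by E1/E2 extensions and a DYW cytidine deaminase domain. Each repeat binds
one ribonucleotide, and two amino-acid positions per repeat — position 5 and
the terminal position L — largely determine which one. When such a factor is
expressed in a foreign cell, it edits its delivered target and, in
proportion to how permissive its binding preferences are, a spectrum of
*off-targets* in the host transcriptome. Those off-targets are informative:
pooled, their sequence environments expose the factor's per-position
nucleotide preferences far more richly than the handful of native targets
can.

`ppredit` implements the dry-lab layer of such an experiment: the PPR-RNA
code and array juxtaposition (`ppr_code`), replicate-filtered off-target
calling from base counts (`editing_caller`), consensus profiles and
decile-weighted matching scores (`consensus_profile`), a transcriptome
scanner for candidate targets (`target_scanner`), and a synthetic-data
generator (`synthetic_data`) that emulates the statistical structure of the
RNA-seq input so the whole pipeline is testable without any sequencing data.

# The PPR-RNA code and juxtaposition

The core code maps (position 5, position L) to a nucleotide preference:

| 5 | L | preferred |
|---|---|-----------|
| T or S | N | A |
| T or S | D | G |
| N | S | C |
| N | D | U |
| N | N | C or U |

Every other combination yields an explicit empty prediction. Internally the
alphabet is DNA (U is normalised to T on input) because transcriptome FASTA
and pileups are DNA-alphabet; rendering back to RNA is cosmetic.

The array is numbered backwards: the C-terminal repeat is S2-1 and pairs
with target offset −4 relative to the edited cytidine at offset 0, so
repeat *n* pairs with offset −(*n* + 3), one nucleotide per repeat.
`juxtapose()` classifies the observed base at each repeat's offset as a
*match* (in the predicted set), *transition* (purine↔purine or
pyrimidine↔pyrimidine partner of a predicted base), *transversion*
(anything else) or *none* (no prediction). Two tie rules are fixed by
design: a match always wins over a transition, and for the two-element
{C, U} prediction the purines are classified transversions — they are the
transversion partners of both predicted pyrimidines, and a "transition"
reading against only one of them would be arbitrary. L and L2 repeats are
not covered by the core code; where their (5, L) pair happens to occur in
the table we use it, otherwise the row reports "none", and either way the
row is flagged non-canonical rather than dropped, because L-type positions
show real empirical preferences that a tally should expose rather than
hide. We deliberately do not invent a code for L-type combinations such as
MD, LD or VD; they remain empirical.

`mutate_motif()` models single-repeat retargeting: changing an S-type
repeat's L-position from D to N moves its preference from G to A and vice
versa, which is exactly the engineering experiment the juxtaposition tests
encode (S-7 TD→TN redirects offset −10 from G to A; S-4 TN→TD redirects
−7 from A to G).

# Consensus profiles and the matching score

`build_profile()` turns a set of −30..+5 context windows into per-offset
A/C/G/T frequencies. Pads (`-`) and `N` are excluded from numerator and
denominator. With `dedupe = TRUE` (the default), identical window sequences
from transcript variants of the same gene count once, so isoform inflation
does not distort the consensus.

An offset is *thresholded* when a unique nucleotide dominates with
frequency ≥ 40%; its weight is the frequency floored to the nearest 10%
step — the decile, one of 40, 50, …, 90. The matching score of a window is
the sum of decile weights at thresholded offsets where the window carries
the consensus base; `max_score()` is the sum over all thresholded offsets,
and the consensus-matching window attains it exactly. Three numerical
choices are fixed here:

* **Decile cap at 90.** The step ladder never shows a 100 step; a
  frequency of 1.0 floors to 90. This keeps weights bounded and matches
  the cut-off ladder drawn on the published profile figures.
* **Ties at threshold.** Two bases at exactly 40/40 mean no base
  *dominates*; the offset is not thresholded.
* **Integer scores.** Deciles are summed as integers; there is no
  fractional scoring.

Scoring bounds default to −17..+5. The span covers the 13 repeats of a
PPR56-sized array (offsets −16..−4) plus the downstream context through +5
that the E/DYW end of the protein is thought to read, and the flanking
−17 position where weak preferences are still visible. The published
maximum of 990 for the native off-target collection constrains the sum of
deciles but not the span itself, which is why the span is a configuration
parameter rather than a constant; the golden-value test records whatever
span reproduces the published maximum once the off-target list is supplied
(see the README on user-supplied data). The "74 putative binding shift
candidates" excluded from the published profile follow a rule that is
nowhere defined; we implement no guess for it, and the deduplication flag
is the only window-set pruning the profile builder performs.

`profile_shift_report()` compares two profiles offset by offset on their
thresholded (base, decile) pairs — the readout used to show that a
single-repeat mutant redirects the consensus at its juxtaposed position
(and, empirically, often at neighbouring positions too).

# The off-target caller

The caller consumes per-site, per-replicate base counts for
factor-expressing samples and controls (editing-dead DYW mutants, the
other factor, or tag-only transfections), plus a transcriptome annotation
with reference sequences, CDS bounds and an abundance estimate.

The stages, in pipeline order:

1. **Expressed-reference filter.** Transcripts with an abundance estimate
   of ≥ 10 mapped read pairs form the reference set; everything else is
   noise territory for RNA-seq variant detection.
2. **Per-replicate detection.** A replicate supports a site when it holds
   ≥ 2 T reads at ≥ 1% of its coverage. This is a deliberately simple,
   fully documented stand-in for an external statistical variant caller:
   the specificity of the pipeline comes from the consensus and background
   filters, not from this detector, and replacing a tool's opaque internals
   with an auditable rule keeps the artifact self-contained.
3. **Replicate consensus against controls.** A candidate must be supported
   in ≥ 2 factor replicates and in *no* control replicate, and its
   reference base must be C.
4. **Site filters.** (i) control C fraction > 99%; (ii) control T fraction
   < 0.5% (together these exclude genomic SNPs and systematic
   mismapping); (iii) pooled coverage ≥ 20 reads in the factor group and
   in the control group; (iv) pooled editing efficiency ≥ 1.5%. The four
   predicates are independent, so the surviving set is invariant under
   any filter ordering — a property the tests assert directly. Sites with
   no control coverage fail with the coverage reason; their background
   fractions are not evaluable.

Editing rates pool replicates before dividing (ΣT / Σtotal), rather than
averaging per-replicate ratios; replicates with zero coverage therefore
contribute nothing rather than producing undefined terms. Sanger-trace
rates are the T peak over the T+C peak sum at the site.

Coordinates are 0-based half-open internally; labels are 1-based. The
`eU` nomenclature is `gene` + `eU` + CDS position + amino-acid change
(`nad4eU272SL`; a gained stop is written `*`), with signed distances for
UTRs: `eU-55` counts upstream from the start codon (nearest base = 1),
`eU+743` downstream from the stop (first base after the stop = 1).
`parse_site_label()` inverts the format exactly; the tests include the
round trip. Calls are reported per transcript; collapsing identical
windows across isoforms of a gene is deferred to the profile builder's
dedupe flag, so no information is lost before profiling.

Only C→T on the transcript strand is considered: the inputs are
transcript-space alignments, so opposite-strand G→A handling does not
arise.

# The candidate scanner

`scan_transcriptome()` slides the profile over every C in every transcript
and reports matching scores, with windows overhanging transcript ends
scored against pads (contributing 0) and flagged truncated rather than
dropped. Ranking ties break lexicographically by transcript and position
so output is deterministic, and the candidate set is provably identical
whether transcripts are scanned together or in chunks. The scanner accepts
any `consensus_profile` as its weight matrix: the mechanism is the
contribution here, not a particular matrix, and the published matrix
construction (counts versus normalised, pseudo-counts) lives in
supplementary material we do not guess at. `predicted_vs_observed()` joins
candidates with observed calls; its most interesting output is the
high-scoring *non-edited* candidates, the cases pointing to determinants
beyond primary sequence — RNA structure, competing RNA-binding proteins —
which this package deliberately does not model.

# The synthetic-data generator

The generator exists so that every stage above can be exercised against a
known truth. It emulates, with the study's design parameters as defaults:

* a small multi-transcript transcriptome (uniform base composition unless
  configured otherwise), each transcript with a CDS over its central 60%;
* planted C-to-U sites at controlled consensus similarity — either an
  explicit window sequence or the consensus-matching window of a supplied
  profile — with per-site true efficiencies;
* three factor and three control replicates, matching the minimum
  replication of the expression experiment;
* coverage drawn per site and replicate as Poisson(λ), editing as
  Binomial(total, efficiency + ε(1 − efficiency)) at planted sites in
  factor replicates, and a sequencing-error background that places each
  non-reference base at per-base rate ε/3 (an exact three-way multinomial
  split via sequential conditional binomials);
* Sanger-like peak pairs with Normal noise on the peak-ratio readout.

Efficiencies are per-site constants; there is no overdispersion, no
coverage bias, no mapping artefacts, no strand effects. Passing tests on
this generator therefore demonstrate the *logic* of the pipeline —
thresholds, consensus rules, bookkeeping — not robustness to the full
pathology of real RNA-seq, which is exactly the division of labour
intended: the upstream read-level stack (trimming, mapping,
deduplication, statistical variant calling) is out of scope.

Reproducibility is strict: every generator is a pure function of its
arguments and a seed. The pileup simulator fans a single seed into
per-replicate substreams (`seed + 7919·k mod 2³¹ − 1`, factor replicates
counting k = 1, 2, …, controls from k = 101), so adding a replicate never
changes the ones already drawn.

Default problem sizes in the test suite — 10 transcripts of 1 kb, three
plus three replicates, λ = 100 with a λ = 500 arm for rate accuracy, five
seeds — were chosen as the smallest sizes at which the binomial and
Poisson concentration arguments behind the recovery claims hold with
comfortable margin; they are a design choice of the suite, and the same
functions run unchanged at larger sizes.

# Known limitations

* The per-replicate detector is intentionally naive; with very deep
  coverage its fixed 2-read minimum becomes permissive and the 1%-rate arm
  does the work.
* The consensus model is positionally independent (a PFM); it cannot
  represent the bulged-nucleotide alignments occasionally seen at real
  off-targets, nor does it model RNA secondary structure, which is a known
  reason why high-scoring candidates can remain unedited.
* L-type repeats contribute no prediction unless their (5, L) pair happens
  to sit in the core table; their empirical preferences enter only through
  profiles built from observed windows.
* The golden values of the native off-target collection (maximum score
  990, and the worked per-window scores 910 and 780) can only be
  recomputed once the published off-target list is supplied as extdata;
  the packaged tests then verify them, and until then the decile-rule
  worked examples (40 for A at −14, 70 for G at −13) plus the property
  suite carry the validation.
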