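---
title: "mirsight: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mirsight: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirsight)
```

mirsight analyzes what happens downstream of a microRNA locus when both
duplex arms (5p and 3p) are expressed: which sequence variants (isomiRs) of
each mature arm are present, which transcripts carry seed-match sites in
their 3'UTRs, whether those 3'UTRs are shortened by alternative
polyadenylation (APA), and whether predicted targets are actually repressed
in a two-condition count experiment. This vignette documents the models,
the tunable parameters, and the choices made where the design was open.

## IsomiR classification

A small-RNA read is interpreted against the canonical mature of its arm as
a tuple (5' offset, templated 3' offset, substitutions, non-templated 3'
additions). `classify_read()` enumerates every interpretation with the 5'
offset in [-4, +4] and the 3' offset in [-8, +4] (bounds chosen to cover
the deepest end variants seen in practice — a 5 nt 3' trim — with margin),
scores each by `cost = substitutions + tail length`, and keeps the minimum.
Ties break deterministically: fewer invented (tail) bases first, then the
smaller |5' offset|, then the smaller |3' offset|. A best cost above 2 —
the same tolerance the read counter uses — rejects the read as
unclassifiable.

Two consequences of the cost rule are worth spelling out:

* a read one base shorter than canonical whose last base mismatches is
  called a 1 nt truncation with a terminal substitution, not a 2 nt
  truncation plus a 1 nt tail (same cost, fewer invented bases);
* when a precursor is available, a 3' extension base must *match* the
  precursor to count as templated; an extension base that contradicts the
  template is a non-templated addition (NTA), never a "templated extension
  with a substitution". Without a precursor annotation, classification is
  purely mature-relative and every extension base is an addition.

Arm assignment (`assign_arm()`) routes a read to the arm sharing the
longest exact substring with it (computed against a precursor window
around each mature when one is annotated), requiring an anchor of at least
10 nt and no tie. When the anchor fails — typically a substitution
splitting a short, deeply trimmed read's exact match — the classifier
falls back to full enumeration against both arms and accepts a unique
minimum-cost winner; inter-arm ties stay unassigned.

The embedded worked example (`mir200b_fixture()`) is classified without a
precursor, because the precursor annotation used to produce the published
table is unknown; classes are therefore defined purely mature-relative.
One published row mixes DNA and RNA characters; it is stored verbatim,
flagged `alphabet_ambiguous`, and excluded from exact class tallies rather
than silently normalized.

## Seed-site scanning

`seed_patterns()` derives the three canonical target-site match strings
for a mature miRNA from its seed (positions 2–8): the 8mer (perfect match
to positions 2–8 plus an A opposite position 1), the 7mer-m8 (no A), and
the 7mer-A1 (positions 2–7 plus the A). The site A is a literal A in the
mRNA, following the standard convention, not complementarity to miRNA
position 1. `scan_sequence()` tests every position, reports overlapping
sites, and collapses contained classes so an 8mer occurrence is not also
counted as its two embedded 7mers (`collapse = FALSE` restores raw
matches). Scanning is strand-specific — the antisense sequence is never
searched — and is invariant to DNA vs RNA input. `predicted_targets()`
filters genes by site class; the stringent default (`require_8mer = TRUE`)
mirrors the screening convention of keeping only genes with at least one
8mer site before evaluating 3'UTR architecture.

## Read counting

The counting rule is deliberately annotation-driven: a read maps to a gene
when all but at most 2 of its bases align gaplessly to the gene's
*exon-union* sequence (exons pooled across isoforms, so exon boundaries
need not correspond to any single isoform), with mismatches and
end-overhangs both counted as unmatched. Reads are collapsed to unique
sequences before mapping and counts reported on the expanded,
multiplicity-weighted scale. Counting semantics: a unique read increments
its gene; a read hitting several genes at one genomic location increments
each; a read matching several genomic locations is ambiguous and counts
nowhere; repeat-flagged loci (flags come from the annotation, not from
running a repeat masker) receive only uniquely mapped reads. Ties among
equally good locations within one gene keep the leftmost, which cannot
change gene counts. Reads are assumed sense-stranded; `both_strands =
TRUE` enables reverse-complement search for unstranded protocols.

## 3'UTR-loss calling

The published loss calls are binary and their derivation was not stated,
so the package declares its own operationalization: the annotated UTR is
split into proximal and distal segments (at the annotated proximal polyA
site when available, else the midpoint; UTRs under 40 nt are skipped), and
loss is called when `mean(distal) / mean(proximal) < tau` (default `tau =
0.2`) subject to an evidence gate `proximal mean >= 10` reads/base. The
ratio is scale-invariant and reported even when the gate blocks a call. A
two-sample mode (`compare_utr_loss()`, relative threshold 0.5) supports
condition-vs-condition comparisons. Seed sites starting at or beyond the
split (half-open convention) are lost when loss is called;
`site_retention()` conserves `retained + lost = total`. Isoform-ratio
based APA deconvolution is out of scope and listed as future work.

## Differential expression and target response

The exact test is a simplified, fully specified reimplementation of the
NB exact-test idea rather than a clone of any package: counts are rescaled
to the geometric-mean library size with deterministic half-even rounding,
a plug-in dispersion is used (variance = mu + phi * mu^2), and the
two-sided p-value doubles the smaller tail of the exact conditional
distribution of the condition-B group total given the overall total (a
negative hypergeometric, free of the unknown mean; at dispersion 0 it
reduces to the conditional binomial test). Equivalence with the
established implementation is claimed — and tested — only at the property
level (type-I error, power monotonicity, rank agreement), not bit for bit.

Dispersion is estimated by pooled within-group moments with a small-sample
correction on the squared-mean denominator; the tagwise variant shrinks
per-gene moment estimates toward the common value with gene weight `n - 1`
against a prior weight of 10. Log2 fold changes are reported with a 0.5
pseudocount on group means (reporting only — the test never sees it).
Benjamini–Hochberg FDR is reported alongside raw p-values, but
significance calls follow the raw p < 0.05 / fold-change < 0.5 screening
convention the thresholds were taken from. The target-set shift analysis
is a one-sided two-sample Kolmogorov–Smirnov test of the target fold-change
distribution against background. Relative qPCR quantification uses the
2^-ddCt closed form with exactly one calibrator.

## Synthetic data: what it emulates, and what it does not

Every generator is deterministic under an explicit seed and returns its
ground truth. The generators emulate:

* small-RNA read populations around a precursor hairpin (default layout:
  20 nt random flanks, 15 nt loop) with configurable 5'/3' offset
  distributions, per-base substitution rate and mono-nucleotide NTA rate.
  The default `isomir_distribution()` is loosely matched to the embedded
  prevalence table (5' ends mostly canonical, substantial 3' trimming,
  uridylation-biased additions); it is illustrative, not fitted, since no
  generative model was published. Two normalizations keep truth
  recoverable: NTAs are drawn to differ from the next templated base, and
  trim-plus-tail reads are recorded in the minimal-cost form the
  classifier's tie-break prefers;
* two-condition mRNA counts: NB with variance mu + phi * mu^2, gene means
  scaled by library size; genes carrying an implanted seed site are
  repressed in condition B unless flagged UTR-lost, in which case their
  effect is zero (the escape mechanism under study);
* per-base UTR coverage with a proximal/distal step (distal residual 0.05
  when lost) and zero-truncated Gaussian noise. Note the truncation: at
  low residual depth the expected distal mean exceeds the nominal level,
  and the tests' sampling oracle accounts for it;
* implanted seed sites: background UTR sequence is rejection-sampled to
  contain no spurious match for the miRNAs under test, sites are written
  at non-overlapping positions with guard bases (so a 7mer never
  accidentally upgrades to an 8mer), and the construction is re-scanned
  until recovered sites equal the implanted truth exactly — scanner
  acceptance is exact by construction, not statistical.

The generators do *not* model sequencing error profiles, ligation bias,
quality scores, realistic genome structure (each toy gene sits on its own
chromosome), paralogous miRNA families, or isoform-level expression
mixtures. Passing tests therefore demonstrate correctness of the
algorithms under their stated models, not performance on real libraries.

## The end-to-end scenario

The documented recovery experiment (`simulate_study()` +
`analyze_study()`) uses 100 target genes and 400 background genes
(3'UTRs of 400 nt, one implanted 8mer each for the 3p arm's partner
miRNA), repression of intact targets at log2FC = -1, 10% of targets
UTR-lost with zero effect, NB counts at baseline mean 1000, dispersion
0.05, 3 replicates per condition, and coverage at depth 100 with noise sd
5. These sizes keep a full run around a minute on one core while leaving
the statistical margins wide.

One operating point deserves its rationale spelled out: the outcome screen
in this scenario uses `min_fold = 1.5` rather than the default 2. The
simulated repression (fold 0.5) sits exactly on the fold-2 cut, so with
symmetric sampling noise about half of genuinely repressed genes would
land on either side of it and no classifier could reach high recall at
that threshold; a detection threshold strictly inside the simulated effect
(|log2FC| >= 0.585 at fold 1.5) is the standard resolution for a recovery
experiment. `classify_target_outcome()` keeps the fold-2 default for real
analyses.

## Numerical and degenerate-input choices

* All internal coordinates are 0-based half-open; GFF3 (1-based closed)
  and BED12 (0-based half-open) convert at the I/O boundary only.
  Multi-interval 3'UTRs are concatenated in transcript orientation.
* T/U: all miRNA and seed arithmetic happens in the RNA alphabet; genome
  and transcript files may be DNA. Sequences mixing T and U are flagged,
  never guessed.
* The exact test returns p = 1 for all-zero genes; identical groups give
  p = 1 under the doubling rule; conditional weights are computed in log
  space and normalized, so large totals do not underflow.
* Dispersion estimates are clipped at zero; with fewer than two samples in
  every condition the estimator warns and returns a configurable default.
* The loss caller makes no call (NA, flagged) when proximal evidence is
  below the gate, rather than reporting a fragile ratio as a call.
* Pipeline runs derive per-stage seeds from one master seed at fixed
  offsets, so stages are reproducible independently; all tabular output
  is written with fixed numeric formatting and the manifest records md5
  checksums — re-running a config is byte-identical.

## Known limitations

The mapper is gapless by design and does not model splicing gaps inside a
read, indels, or base qualities. The seed scanner implements the three
canonical site classes only (no 6mers, centered, 3'-compensatory or
context scoring). The loss caller assumes a single proximal/distal
dichotomy per UTR. The exact test assumes a common (or supplied)
dispersion and equalized libraries; no GLM, TMM normalization or batch
structure. ADAR-editing inference and cross-mapping correction between
paralogous miRNAs are out of scope.
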