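---
title: "Methods: quantifying a cohort's circRNA landscape with circscape"
author: "circscape authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying a cohort's circRNA landscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circscape)
```

# Overview

Circular RNAs (circRNAs) arise when a downstream splice donor joins an
upstream splice acceptor, producing a covalently closed transcript whose
diagnostic feature is the back-splice junction (BSJ). `circscape`
implements a cohort-scale pipeline around that junction: building a
confident circRNA catalog from BSJ predictions, quantifying circular
against linear splicing at the junction level, comparing
circular-to-linear output between sample groups, testing circRNAs for
cohort specificity, characterizing the flanking introns that drive
back-splicing, scanning for RNA-binding-protein (RBP) motifs, and a set
of cohort statistics built so that a *global* shift in circRNA output —
the situation in MYCN-amplified tumors, where circRNAs are broadly
suppressed — is not silently normalized away.

Because the patient data this kind of analysis is designed for are
access-restricted, the package ships a synthetic cohort generator that
plants all the effects the pipeline is meant to detect. Every stage is
therefore testable end-to-end offline, and the test suite exercises the
pipeline against known truth.

# The synthetic cohort

`sim_spec()` fixes the study conditions; `generate_annotation()` and
`simulate_cohort_counts()` realize them. Defaults:

* **Cohort**: two groups of 20 samples (`MNA`, `HR_nMNA`), echoing a
  tumor cohort split into a *MYCN*-amplified subgroup and high-risk
  non-amplified controls. Library-size factors are drawn log-normal
  (sigma = 0.3) around 1, a realistic depth spread that gives the
  size-factor machinery real work.
* **Genes**: 200 genes (one chromosome per 50), 4–9 exons of
  100–300 nt, introns of 400–3000 nt, random strand. Counts are
  negative binomial with dispersion 0.2 (variance = mu + 0.2 mu²), a
  mid-range value for bulk RNA-seq; dispersion 0 gives Poisson counts,
  used by the Fano calibration tests.
* **circRNAs**: 30% of genes carry one truth circRNA over an internal
  exon block, with baseline circular output 5–30% of the host gene's.
  The suppressed group's circRNA count means are multiplied by 0.5
  before sampling — the planted global-suppression effect, chosen as a
  clear two-fold shift detectable at desk scale.
* **Specific circRNAs**: 10 circRNAs are elevated 8-fold in the focal
  cohort only, so control cohorts simulated with `focal = FALSE` share
  the gene universe but lack the elevation.
* **Repeats**: a fixed 300-nt Alu-like sequence (one synthetic
  subfamily — only interval overlap matters downstream) is inserted
  into introns at rate `alu_seed_fraction` (default 0.3), and into
  introns flanking circRNA exons at `min(1, 3 x alu_seed_fraction)`.
  Flanking introns are also drawn two-fold longer
  (`flank_len_factor = 2`), emulating the long, repeat-rich introns of
  circRNA-producing genes.

Two structural guarantees are built into circRNA-producing genes: they
carry at least seven exons with the acceptor placed at exon ≥ 4 and the
donor at most at exon k−3, so flanking introns and junction exons
external to the circle always exist; and on each side of the circle the
adjacent intron is made strictly the longest (it is the flank the
selector will pick) while the side's remaining introns are raised — each
staying below the flank — until they cumulate past it. The second
guarantee makes length-matched control-intron selection feasible for
*every* synthetic circRNA, which the invariant tests assert without
exception.

What the generator does **not** emulate: sequencing errors and quality
variation, real Alu subfamily structure or inverted-repeat pairing,
alternative transcripts (one transcript per gene), batch effects between
cohorts, and intergenic or intron-derived circRNAs. Tests passing on
this cohort therefore demonstrate the correctness of the computations
and the recoverability of planted effects, not robustness to the full
messiness of patient RNA-seq.

Reads are emitted directly as SAM records
(`simulate_junction_reads()`), so no aligner is needed: each counted
fragment becomes a proper pair spanning the junction breakpoint (first
mate reverse, second forward, MAPQ 60), and labeled decoy records
(MAPQ 5, secondary flag, inverted orientation, non-spanning placement)
let tests assert that the counting rules reject exactly what they
should. FASTQ export is available for users who want to run a real
aligner.

# Catalog construction

`read_ciri2()` consumes the CIRI2 header dialect (columns `circRNA_ID`,
`chr`, `circRNA_start`, `circRNA_end`, `junction_reads`, `strand`,
`circRNA_type`). Filters:

* **Blacklist** — predictions on chrM, chrY, or any contig outside the
  declared primary-chromosome set are removed.
* **Expression** — a candidate is kept iff it is expressed in at least
  25% of samples *or* carries ≥ 20 BSJ reads in ≥ 3 samples.
  "Expressed" means ≥ 1 BSJ read in that sample: the rule needs a
  per-sample notion of expression and the read-support branch already
  carries the stringency, so the laxest sensible definition is used.
  The 25% is realized as `ceiling(0.25 * n)` so the criterion is
  attainable for non-divisible cohort sizes.
* **Annotation** — both candidate boundaries must match exon
  boundaries of one and the same gene within 1 bp; per-end
  discrepancies are recorded and preserved downstream. Unstranded
  candidates are matched on both strands, ties broken by smaller total
  discrepancy and then lexicographic gene id, so results are
  deterministic. Rejections are classified (`no-gene`, `cross-gene`,
  `boundary`) for audit.

Filters commute and are idempotent, which the suite asserts —
order-dependence here would be a latent bug class.

# Junction quantification

The pseudo-reference makes junctions contiguous so spliced alignment is
unnecessary. Each confident circRNA contributes a 160-nt BSJ contig:
the last 80 nt of the donor exon spliced to the first 80 nt of the
acceptor exon. The target length is fixed at 160 nt; the 80/80 split is
symmetric because that maximizes the smaller of the two overhangs.
CircRNAs whose donor or acceptor exon is shorter than 80 nt cannot be
trimmed to spec and are dropped (logged as `untrimmable`). Every unique
annotated exon–exon junction of the host gene becomes a linear contig
at full exon lengths, so reads without a back-splice prefer the linear
contigs; genes with no linear junction drop their circRNAs.

Counting (`count_junction_reads()`): a fragment counts once per contig
when at least one mate's primary alignment covers the breakpoint window
`[offset − 4, offset + 5]` (that is, a minimum overhang of 5 nt on each
side, a configurable and explicitly testable stand-in for what an
aligner's seeding would enforce), with MAPQ ≥ 13 and first-mate-reverse
/ second-mate-forward orientation read from the SAM flags of primary
records. Secondary and supplementary records are ignored. No
insert-size window is imposed: the orientation requirement fixes the
mate-strand roles and the pseudo-reference contigs are short enough
that a size constraint would add nothing testable.

Per circRNA and sample, `summarize_bsj_linear()` reports the BSJ count,
the mean over all of the gene's linear junctions, and the mean over
linear junctions *external* to the back-splice span (neither junction
exon inside the span). A missing external junction yields an absent
value, never a silent zero.

# Ratios, productive genes, dispersion

The circ:linear ratio is formed per gene and sample *after* averaging
across isoforms on both sides, avoiding isoform-specific biases.
Records with zero linear expression have no ratio (absent, counted
separately). Group comparison pools all gene × sample ratios per group
— matching an ECDF drawn over all genes and tumors — and applies a
two-sided Mann–Whitney U test: exact by complete enumeration when both
pooled sizes are ≤ 8 (enumeration handles ties without approximation),
and a tie-corrected, continuity-corrected normal approximation
otherwise. The exact path is verified against an independent
enumeration oracle for all group sizes with n₁ + n₂ ≤ 10.

A gene is circRNA-productive when its ratio of expressed circRNA
isoforms to expressed mRNA isoforms strictly exceeds 1.2. The ratio is
a ratio of isoform *counts*, not abundances — the natural reading of an
isoform ratio — with "expressed" meaning ≥ 1 BSJ read in ≥ 1 sample
(circ) and ≥ 1 TPM in ≥ 1 sample (mRNA). These definitions are
documented defaults rather than derived facts; the abundance-based
alternative would require only a different input table to
`call_productive_genes()`.

The Fano factor (variance over mean; 1 under Poisson dynamics) is
computed per isoform across samples with the unbiased n−1 variance,
averaged per feature, and compared circ vs linear by rank test. Two
properties pin the implementation: Poisson-simulated counts give mean
Fano in [0.9, 1.1], and scaling a feature's counts by c scales its Fano
by exactly c.

# Cohort specificity

CPM normalization divides by the sample's total BSJ counts (× 10⁶);
isoform CPMs can be summed to gene level. The top-expressed ranking
orders by mean CPM across samples with a lexicographic tie-break so the
top-500 list is stable across runs.

The tandem test compares each circRNA (prevalence-filtered: CPM ≥ 1 in
≥ 30% of focal samples — the filter concerns the focal cohort, whose
prevalence defines candidacy) against two control cohorts with
*one-sided* (focal greater) Mann–Whitney tests. One-sided is the
deliberate choice: the procedure looks for circRNAs elevated in the
focal cohort, and a two-sided reading would also flag depleted ones.
Benjamini–Hochberg correction is applied separately within each test
across features, and a circRNA passes when **both** adjusted values
fall below 0.001 — applying the threshold after adjustment is the
stricter of the two possible readings, and the unadjusted p-values are
also reported so the other reading can be audited. The combined
p-value is the plain sum of the two test p-values; it can exceed 1, is
reported as-is, and is never used as a threshold (its role is ranking
and reporting).

# Flanking introns, controls, Alu enrichment

The putative circRNA sequence splices all annotated exons of the host
gene inside the back-splice span (candidate coordinates, so ±1-bp
boundary discrepancies are preserved); overlapping exon variants are
resolved by keeping the longest, ties to the leftmost. The control
sequence is the longer of the fully-spliced upstream or downstream
exon sets, symmetrically trimmed to the circRNA's length —
`floor(excess/2)` from the start and `ceiling(excess/2)` from the end,
the odd nucleotide going to the end trim. Controls shorter than the
circRNA are kept but flagged and excluded from length-matched analyses.

Flanking introns are the longest intron upstream of the acceptor and
downstream of the donor (transcript orientation, ≥ 15 nt). Control
introns are chosen greedily by decreasing length among the gene's
introns, skipping any that overlap the circRNA span, the flanks, or
previously chosen controls, until their cumulative length reaches the
flanks'. No intron splicing is performed — spliced controls would
create non-physiological intron–intron junctions that distort motif
counts — so each control stays an independent interval. The intron
universe is the union of per-transcript exon gaps deduplicated by exact
coordinates. Alu enrichment counts introns intersecting ≥ 1 repeat
interval (≥ 1 bp) and applies a two-sided Fisher exact test per stratum
(upstream, downstream, combined); Fisher p-values are validated against
direct hypergeometric enumeration for tables with totals up to 40.

Exons of overlapping *other* genes are excluded from the circRNA
sequence: the construction is restricted to the matched gene, the
interpretation that keeps sequence content attributable to the host
locus.

# Motif scanning

ATtRACT-style collections are cleaned before use: entries whose PWM
length disagrees with their consensus length are spurious and dropped;
motifs shorter than 6 nt are dropped; entries with identical matrices
are merged into one (RBP names pooled) to avoid overcounting; rows not
summing to 1 are renormalized with a warning.

Scoring uses per-position log₂ odds against a zero-order background
fitted on the circRNA sequences (+1 pseudocount per nucleotide so all
frequencies are positive). PWM probabilities are floored at 1e−3 before
the log — ATtRACT matrices contain zeros, which would otherwise give
−∞ scores; the floor is configurable. Scores are discretized at 1e−3
granularity and the exact null score distribution is computed by
dynamic programming over positions; the match cutoff is the smallest
attainable score whose tail probability under the background is below
1e−4. The DP is verified against brute-force enumeration of all 4^L
words for L ≤ 8 (tolerance 1e−9 after matching discretization). A
consequence worth stating plainly: under a uniform background the best
attainable p for a 6-mer is 4⁻⁶ ≈ 2.44e−4 ≥ 1e−4, so exact 6-mer
motifs can never match at the strict cutoff. That is the mathematics of
the threshold, not a bug; the cutoff is configurable and the behavior
is asserted in the tests rather than patched away.

Scanning slides both the given and reverse-complement orientation over
each sequence; every window at or above the cutoff counts one hit
(overlaps count individually), and windows containing non-ACGT symbols
are skipped and tallied. Sequence-set enrichment is a per-motif
one-sided Fisher test on sequences-with-hits (target vs control) with
BH correction — the simplest documented mode of sequence-set
enrichment tools, fully specified and fully testable, used here instead
of rank-based alternatives whose internal statistic is not pinned down.

Dinucleotide-preserving shuffles use the Altschul–Erikson construction:
last-exit edges are drawn by rejection sampling until they form an
arborescence into the final vertex, the remaining edges are permuted,
and the Eulerian walk is read off — uniform over arrangements, with the
dinucleotide multiset preserved exactly on every draw (asserted over
10,000 draws in the test suite).

# Cohort statistics

* **Proliferative index**: median over signature genes of
  log₂(TPM + 1) per sample — the +1 pseudocount is needed because zero
  TPMs are common, and it is stated rather than implied. Samples are
  clustered on the 1-D index (Euclidean, complete linkage, cut at two)
  and labeled high/low by mean. The shipped signature file is a
  synthetic stand-in named accordingly; a real proliferation signature
  is a drop-in replacement (one gene id per line).
* **Clustering conventions**: per-sample proportion normalization, then
  per-feature z-scores; Manhattan distance for samples, Canberra for
  features, complete linkage throughout (one stated convention, the
  default of the heatmap tooling this mirrors, configurable at the
  `hclust` level). Zero-variance features are excluded with a log.
* **RBP–circRNA correlation**: Spearman (average-rank ties) between
  every RBP and circRNA expression vector, clustered by Euclidean
  distance of the coefficient rows/columns; block summaries count
  strong correlations (|rho| ≥ 0.3 by default) normalized by the
  product of the two cluster sizes.
* **Size factors**: median-of-ratios computed on *gene* counts and
  applied to circRNA counts. This is the pipeline's defining
  normalization rule: circ-derived factors would absorb a global
  circRNA shift into the normalization, while gene-derived factors
  preserve it. The contrast — the planted suppression survives
  gene-based normalization and vanishes under circ-based normalization
  — is asserted on the synthetic cohort, and the estimator is checked
  to 1e−12 against an independent implementation.
* **Percentile-group comparison**: high/low groups are samples strictly
  above the 80th / strictly below the 20th percentile of a driver's
  expression (linear-interpolation percentiles, type 7; strict
  inequalities per the words "above" and "below"). Features with fewer
  than 5 summed reads are prefiltered. Each feature is compared by
  two-sided rank test on size-factor-normalized counts with BH at 5%,
  and the up/down split is tested against 50:50 by chi-squared. A
  negative-binomial GLM would be the heavyweight alternative for the
  per-feature test; the rank-test surrogate is used deliberately —
  the bespoke content here is the normalization rule, not the GLM — and
  this substitution is the package's most visible deviation from
  GLM-based differential pipelines.

# Problem sizes and numerical choices

The test suite runs the full pipeline at desk scale: the shared unit
cohort uses 30 genes and 4 + 4 samples; the suppression-recovery check
runs 20 seeds of a 60-gene, 20 + 20 cohort (each seed significant at
p < 1e−4, with a Kolmogorov–Smirnov uniformity check of the null
p-values at suppression 1.0); specificity recovery uses ~310 circRNAs
with 40/30/30 samples; the Fano calibration uses 200 features × 100
samples. These sizes are the package's chosen simulation scale — large
enough that the planted effects are unambiguous, small enough to keep
the suite fast.

Numerical conventions collected in one place: sample variance uses
n−1; percentiles interpolate linearly; exact rank tests switch to the
normal approximation above group size 8; PWM scores are floored at
1e−3 and discretized at 1e−3; Fisher tests are two-sided for Alu
enrichment and one-sided for motif and specificity enrichment (each
direction is part of the respective scientific question); all
tie-breaks (gene matching, top-expressed ranking, exon overlap
resolution) are deterministic and documented at the function level.

# Known limitations

Intron-derived and intergenic circRNAs are cataloged but excluded from
exon-based stages. The generator's single-transcript genes understate
isoform complexity, so isoform-averaging code paths see less variety
than real annotation provides (they are exercised by hand-built
fixtures instead). The motif-enrichment Fisher mode ignores hit counts
beyond presence/absence. The specificity test assumes comparable CPM
scales across cohorts; batch correction is out of scope and must happen
upstream.
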