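# circscape

Cohort-scale analysis of the circular RNA (circRNA) landscape from
back-splice junction predictions.

Circular RNAs are covalently closed transcripts produced when a
downstream splice donor joins an upstream acceptor (a *back-splice
junction*, BSJ). In tumors driven by oncogenic MYC-family factors,
circRNA output can be *globally* suppressed — a signal that standard
count normalization silently removes, because size factors estimated on
the circRNA counts themselves absorb the shift. `circscape` implements
a junction-level pipeline built around that problem:

* **Catalog** — parse CIRI2-style BSJ predictions, drop blacklist
  contigs (chrM/chrY/unplaced), keep candidates expressed in ≥ 25% of
  samples *or* supported by ≥ 20 reads in ≥ 3 samples, and match both
  boundaries to exons of a single gene within 1 bp.
* **Quantification** — a pseudo-reference of 160-nt BSJ contigs
  (80 nt donor + 80 nt acceptor) and full-length linear junction
  contigs; fragments count when a primary alignment spans the
  breakpoint with MAPQ ≥ 13 and first-mate-reverse /
  second-mate-forward orientation.
* **Ratio statistics** — per-gene circ:linear expression ratios
  (isoform-averaged), pooled per group and compared by Mann–Whitney U
  (exact by enumeration for small groups); circRNA-productive genes
  (isoform ratio > 1.2); Fano-factor dispersion (variance/mean; 1 under
  Poisson dynamics).
* **Specificity** — tandem one-sided Mann–Whitney tests of the focal
  cohort against two control cohorts on CPMs, both FDR-adjusted
  p < 0.001 required; the combined p is the sum of the two.
* **Introns & repeats** — putative circRNA sequences with
  length-matched spliced controls, longest-flanking-intron selection
  with greedy length-matched control introns, Alu-overlap Fisher
  enrichment.
* **Motifs** — ATtRACT-style PWM cleaning, exact p-value score
  thresholds by dynamic programming (cutoff p < 1e−4),
  both-orientation scanning, Altschul–Erikson dinucleotide-preserving
  shuffles, sequence-set Fisher enrichment.
* **Cohort statistics** — proliferative index (median log₂ TPM of a
  signature), Manhattan/Canberra clustering conventions, Spearman
  RBP–circRNA correlation clustering, **gene-based median-of-ratios
  size factors applied to circRNA counts** (the rule that keeps a
  global circRNA shift visible), and 80th/20th-percentile group
  comparisons with a chi-squared direction test.

A synthetic cohort generator (`sim_spec()`, `generate_annotation()`,
`simulate_cohort_counts()`, `simulate_junction_reads()`) plants the
effects the pipeline is meant to detect — global circRNA suppression in
one group, cohort-specific circRNAs, Alu-seeded extra-long flanking
introns — so everything is testable offline against known truth.

## Worked example

The numbered scripts under `analysis/` run the whole workflow on the
synthetic cohort (two groups of 20 samples; circRNA means halved in the
`MNA` group):

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_build_catalog.R
Rscript analysis/03_quantify_junctions.R
Rscript analysis/04_ratio_dispersion.R
# ... through 08; outputs land in results/
```

What they print (seed 1):

```
circ_sim: 4 chromosomes, 200 genes, 60 truth circRNAs ( 10 cohort-specific ), 431 Alu-like repeats
candidates across the cohort: 260
after blacklist + expression filters: 60
confident circRNAs: 60 | rejected: 0
junction_reference: 60 bsj + 387 linear contigs over 60 genes
counting round-trip accuracy on 1788 cells: 1.0000
pooled ratio contrast: p = 4.38e-60, lower group = MNA
median ratio  MNA: 0.080   HR_nMNA: 0.157
specific circRNAs called: 10 | planted recovered: 10/10 | false positives: 0
flank intron mean 3592 nt vs control 2243 nt (p = 3.76e-22)
suppressed/control circ mean after gene-based factors: 0.500
                            after circ-based factors: 0.980
high-driver vs low-driver circRNAs: 25 down, 0 up (chi^2 p = 5.73e-07)
```

Reading: the 260 raw candidates (60 truth + noise on blacklist contigs
and unannotated positions) collapse to exactly the 60 truth circRNAs;
counting the simulated alignments reproduces the count matrix
cell-for-cell; the pooled circ:linear ratio distribution of the
suppressed group sits at roughly half the control's median; all ten
planted cohort-specific circRNAs pass the tandem test with no false
positives; flanking introns are longer and Alu-enriched relative to
matched controls; and the planted two-fold suppression is fully visible
under gene-based size factors (ratio 0.50) but erased when factors are
estimated from the circRNA counts themselves (0.98) — the package's
central normalization point.

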