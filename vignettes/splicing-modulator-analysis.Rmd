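---
title: "Downstream analysis of splicing-modulator RNA-seq studies with spliceRescue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Downstream analysis of splicing-modulator RNA-seq studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceRescue)
```

## The scientific setting

Small-molecule splicing modulators such as Branaplam stabilise the
interaction between U1 snRNP and selected 5' splice sites and thereby promote
the inclusion of exons — including exons absent from the reference annotation
("novelSS" exons). In disease contexts such as Huntington's disease (HD),
where patient cells show a broad fingerprint of aberrant alternative
splicing (AS), two questions arise downstream of any junction-count based
differential-splicing caller (rMATS and its relatives):

1. *What does the drug do?* Which events respond coherently to treatment
   across cell types and genotypes, do the responsive exons share splice-site
   sequence features, and what happens to the expression of the host genes
   when a frameshift-inducing exon is spliced in?
2. *What does the drug undo?* How much of the disease-associated splicing
   deviation is pulled back toward the control state ("rescue"), and is
   residual RNA-binding-protein (RBP) occupancy different between rescued and
   non-rescued events?

`spliceRescue` implements this downstream layer as a reusable, tested
pipeline. It consumes rMATS-dialect junction-count tables — it never re-runs
alignment or the caller's likelihood model — together with a genome FASTA,
an annotation exon-boundary set, eCLIP peak files and gene-count tables.
Because the patient datasets such analyses are built on are typically
access-restricted, the package ships a first-class synthetic-data generator
that emulates the full study structure with recorded ground truth, so every
stage is verifiable end to end without any download.

## Event model and filters

Each AS event (cassette exon SE, alternative 3'/5' splice sites, mutually
exclusive exons, retained intron) is identified by a canonical key built from
its type, chromosome, strand and full coordinate tuple
(`event_key()`), so the identical junction found in independent caller runs
joins exactly. All coordinates are 0-based half-open, matching the caller's
`*_0base` start columns and BED.

The inclusion level (PSI, \(\psi\)) of an event with inclusion and skipping
junction counts \(I\) and \(S\) and effective form lengths \(l_I\), \(l_S\) is

\[ \psi = \frac{I/l_I}{I/l_I + S/l_S}. \]

`compute_psi()` recomputes this only to validate the consumed tables'
`IncLevel` columns; the pipeline otherwise trusts the caller's estimates.

Two filters define the analysis universe and the hit list:

* **Coverage** (`coverage_filter()`): an event is analysable when its total
  junction support \(I+S\) is at least 10 in *every* sample of both groups
  (inclusive at 10). Total junction support is used because a PSI needs both
  isoforms' denominators.
* **Significance** (`significant_events()`): FDR strictly below 0.05 and
  absolute inclusion-level difference (ΔPSI) strictly above 0.1. The sign
  convention is that a *negative* difference means the exon is *included* in
  the target (second) condition.

The rescue stage additionally applies a strict "more than 10 reads in every
single sample" detection rule. The two coverage notions (≥ 10 vs > 10) are
deliberately kept distinct because they serve different definitions; both are
exposed as parameters.

## ΔPSI matrix and response clustering

Events significant in any of the four drug-vs-vehicle comparisons (two cell
types × two genotypes) form the rows of an events × comparisons ΔPSI matrix
(`build_delta_psi_matrix()`). A cell is *masked* when the event did not pass
the coverage filter in that comparison; masking is recorded explicitly, and
every row retains at least one observed cell.

Clustering (`cluster_events()`) uses k-means with k = 10, 10 random restarts,
300 maximum iterations and a fixed seed of 42 by default, on the raw ΔPSI
scale (no column scaling — all columns already share the [-1, 1] range).
K-means accepts no missing values, so masked cells are imputed with 0, the
neutral "no change" value; the imputation value is configurable and recorded
in the result, and imputation never touches observed cells. Cluster ids are
arbitrary labels: any comparison with a reference partition goes through the
adjusted Rand index, never raw ids.

A cluster is flagged *coherent* when every unmasked cell shares one sign
(`cluster_summary()`; a fractional alternative is available). Coherent
all-negative clusters — exon inclusion in every treated condition — are the
drug-responsive signature, and their novelSS fraction is reported alongside.
Events with imputed cells sit between a coherent profile and a
single-comparison response, so their assignment is genuinely ambiguous; any
quantitative recovery statement in the package's tests is therefore made on
fully observed rows.

## Splice-site k-mer enrichment

For the drug-responsive (cassette-like) events, 10-nt windows centred on the
target exon's 3' and 5' splice sites are extracted — 5 bases on each side of
the boundary, which just fits an 8-mer — and compared against background
windows at the *upstream exon's own 3' splice site* and the *downstream
exon's own 5' splice site* (`extract_windows()`). Minus-strand windows are
reverse-complemented so the splice-site grammar always reads in the sense
direction. Overlapping k-mers (k = 4, 6, 8 by default) are pooled across
events and tested per k-mer with a two-sided Fisher exact test on
foreground-vs-background occurrence counts (`kmer_enrichment()`). The window
half-width is configurable because window phrasing conventions differ between
tools; pooled occurrence counting is the default, with per-event
presence/absence available, since either reading is defensible. No
multiple-testing correction is applied by default — ranked P values with
relative frequencies mirror the usual scatter-plot presentation — and BH
adjustment is one call away (`recompute_bh_fdr()`).

## RBP binding enrichment

Each event is widened to the region from its upstream exon start to its
downstream exon end, and intersected with eCLIP peaks that pass
−log10(P) ≥ 3 *and* log2(fold change) ≥ 3 (both inclusive,
`filter_peaks()`). An event is *bound* by an RBP on ≥ 1 bp overlap with any
of its peaks, counted once regardless of peak multiplicity
(`events_bound()`). Enrichment of binding among significant events uses the
upper-tail hypergeometric test with the coverage-passing universe as
background: with \(N\) background events, \(K\) bound, a foreground of
\(n\) with \(k\) bound,

\[ P = \Pr(X \ge k), \qquad X \sim \mathrm{Hypergeom}(N, K, n), \qquad
   \text{fold} = \frac{k/n}{K/N}. \]

The fold-enrichment definition is the package's own (the ratio of bound
fractions); it is the natural x-axis for an enrichment scatter and is
recorded here as an assumption. Peaks are pooled across cell lines per RBP by
default, with the manifest making per-cell-line analysis the caller's choice
(eCLIP releases differ in whether replicate or IDR-merged files are used).
Strand-aware intersection is off by default and available as a flag.
Binding differences between rescued and non-rescued events use the two-sided
Fisher exact test on the 2×2 bound × rescued table
(`rescued_vs_unrescued_binding()`).

## Rescue quantification

For disease events (significant in control-vehicle vs disease-vehicle) that
satisfy the strict detection rule, the deviation from control is measured as
the absolute difference of group-mean PSI under vehicle and under drug:

\[ d_{\mathrm{veh}} = |\bar\psi_{\mathrm{ctrl}} - \bar\psi_{\mathrm{dis,veh}}|,
   \qquad
   d_{\mathrm{drug}} = |\bar\psi_{\mathrm{ctrl}} - \bar\psi_{\mathrm{dis,drug}}|. \]

An event is *rescued* when \(d_{\mathrm{drug}}\) drops strictly below 0.1
(`rescue_records()`; comparisons are rounded to 9 decimals so that an exact
tie at the corridor edge is treated as the boundary value, not as a
floating-point accident). Group PSI is the arithmetic mean of per-sample
inclusion levels; a paired per-sample mode is available but off by default.
The cohort summary (`rescue_summary()`) reports the mean deviations, the
percent reduction \(100\,(1 - \bar d_{\mathrm{drug}}/\bar d_{\mathrm{veh}})\),
the rescued fraction, a two-sided Wilcoxon rank-sum test between the two
deviation samples (normal approximation without continuity correction at
n ≥ 20, exact enumeration below), and the rescued / still-included /
still-excluded partition used for pie-chart style reporting.

`drug_targets_disease_events()` reports the raw intersection and Jaccard
index between the drug-responsive and disease-associated hit lists — a small
overlap indicates the drug acts on the disease fingerprint indirectly rather
than by targeting the same junctions.

## Expression consequences

RPKM is computed as \(10^9 c / (L\, D)\) for count \(c\), transcript length
\(L\) and per-sample depth \(D\) (`rpkm()`); the depth denominator defaults
to the sum of assigned gene counts, the closest observable to "million mapped
reads", and can be overridden. Drug responses are summarised per comparison
as log2 ratios of group-mean RPKM, defined only when both means are positive,
and genes are called consistently up/down when the strict sign agrees across
all comparisons (`consistent_direction_genes()`). Formal differential
expression testing is deliberately out of scope; the log2-ratio machinery is
what the consistency analysis needs.

`novel_exon_consequence()` holds the transcript arithmetic for an induced
novel exon: the included-isoform amplicon equals the excluded amplicon plus
the exon length; a frameshift occurs iff the length is not a multiple of 3;
and, given the exon sequence and the reading-frame offset at entry, in-frame
stop codons are counted. The frame offset is a parameter because it is not
derivable without the real transcript sequence.

## The synthetic-data generator

`generate_dataset()` emulates the study structure the pipeline assumes — it
is the package's test bed, not a read simulator. Defaults are fixed once to
the study conditions:

* two cell types, fibroblast-like (4 replicates per condition) and
  neuron-like (3), each with four conditions (control/disease × vehicle/drug)
  and six emitted comparisons;
* disease-associated cassette events with |ΔPSI| drawn from 0.15–0.6 in both
  cell types;
* 55 drug-induced novelSS exons in two coherent inclusion clusters (ΔPSI
  +0.65 and +0.35 under drug), with PSI below 0.1 under vehicle, their
  115-nt exons carrying AGAGTAAG at the 5' splice site and TTCAGTTT at the
  3' splice site with probability 0.9, and their boundaries excluded from
  the annotation set;
* a planted rescue fraction of 0.5, with rescued events returning to within
  ±0.02 of the control PSI (well inside the 0.1 corridor, as a rescue
  should be);
* mean junction depth 100 (Poisson), per-sample PSI noise via a
  clamped normal with sd 0.05, counts split binomially between the isoforms
  using the effective form lengths so that `compute_psi()` inverts the
  simulation exactly in expectation — emitted inclusion levels then agree
  with recomputed PSI to the printed precision (0.001);
* table P values from a Welch t-test on per-sample PSIs with BH FDR per
  table (the caller's likelihood model is out of scope and irrelevant to
  downstream correctness);
* RBP models with background binding rates, a disease-enriched binder and a
  rescue-preferential binder (QKI-like), peaks written inside bound events'
  regions with passing significance values plus sub-threshold decoys;
* planted consistently up- and down-regulated genes (log2 effect ±1) among
  the drug-induced events' host genes. All other genes receive deliberately
  sign-mixed per-comparison effects (magnitude 0.3–0.6) so that the
  consistency ground truth remains well defined under counting noise —
  with near-zero effects the strict-sign call would be decided by noise and
  no truth assertion would be possible.

The generator is seed-deterministic down to file bytes (paths inside
`truth.json` are stored relative to the bundle directory for this reason).
`small_fixture()` adds adversarial boundary rows — an event with exactly 10
reads in every sample, FDR exactly 0.05, |ΔPSI| exactly 0.1, and peaks at
exactly (3.0, 3.0) and (·, 2.99) — to pin the strict/inclusive threshold
semantics in tests. For those forced rows the statistic columns are pinned
while inclusion levels stay count-derived, so PSI validation is unaffected.

What the generator does *not* emulate: realistic gene structures and intron
lengths, correlated biological replicates, overdispersed counts,
isoform-level read assignment ambiguity, annotation errors, or peak-calling
artefacts. Passing tests therefore demonstrate the correctness and
calibration of the downstream arithmetic and statistics under the stated
model, not robustness to every failure mode of real libraries.

Problem sizes in the shipped tests and acceptance script were chosen to make
sampling noise small relative to the tested margins: 1000 disease events for
rescue-fraction recovery (binomial noise ±0.016), the default 55-event
drug set for cluster and motif recovery across 20 seeds, and 1000 null
replicates (universe 4000, foreground 800, binding prevalence drawn per
replicate so the discrete P-value support mixes to a near-continuous null)
for the uniformity check of the hypergeometric test.

## Numerical and design choices, in one place

* Strict inequalities for FDR/ΔPSI significance and the rescue corridor;
  inclusive thresholds for coverage (≥ 10) and peak filtering (≥ 3), each
  matching its definition verbatim.
* The junction-count ("JC") table flavour is assumed throughout.
* MXE ΔPSI refers to the first exon's inclusion, per the caller's
  convention.
* Odds ratios are cross-products with a +0.5 continuity fallback when any
  cell is zero (reported alongside the exact P, which never uses the
  correction).
* Fisher tests are two-sided; enrichment direction is read from the odds
  ratio.
* Shared-event reporting between two comparisons is per direction; callers
  aggregate as needed.
* Chromosome naming is normalised ("chr1" ≡ "1") for interval work; an
  unknown contig in overlap queries counts as non-overlapping with a
  warning, while a contig missing from the genome FASTA is an error (window
  extraction cannot proceed).
* k-means determinism comes from a fixed RNG seed around the restarts; the
  global RNG state is saved and restored, so pipeline results do not depend
  on call order.

## Limitations

The package analyses caller output; biases introduced upstream (alignment,
junction filtering, the caller's PSI estimator) pass through untouched.
Hypergeometric enrichment assumes exchangeable events, ignoring region
length: longer events intersect more peaks by chance, so fold enrichments
should be compared between RBPs, not read as absolute effect sizes. The
coherence flag is strict by default and will reject clusters with a single
discordant observed cell; use the fractional variant for noisy designs.
Rescue is defined on group means; designs with strong per-sample pairing
information may prefer the paired mode.
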