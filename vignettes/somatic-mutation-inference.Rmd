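---
title: "Inferring somatic mutations from bulk RNA-seq and modeling mutation-rate covariates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring somatic mutations from bulk RNA-seq and modeling mutation-rate covariates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somarna)
```

## The problem

Bulk RNA-seq of many individuals ("accessions") contains, besides the
germline genotype, traces of somatic mutations: rare alternate alleles
supported by a minority of reads at expressed positions. Distinguishing
them from sequencing errors, alignment artifacts around splice junctions,
RNA editing, allele-specific expression and unannotated germline variation
requires an aggressive cascade of filters. Once a credible set of somatic
calls exists, the genewise mutation count becomes a response variable:
how do transcriptional strand, replication timing, GC content, DNA
methylation, chromatin accessibility and histone marks relate to where
mutations accumulate?

`somarna` implements both halves — the calling cascade and the genewise
modeling — together with a synthetic-data generator that emits every input
the pipeline consumes (reference FASTA, GFF3 annotation, germline VCF, mask
BEDs, signal bedGraphs, a per-accession pileup TSV) with planted true
mutations and planted artifact classes, so the entire pipeline is testable
without any external download.

## The calling cascade

Candidate sites are accession × position records with exactly two observed
base calls, coverage ≥ 40 reads, and a minor-allele count ≥ 6 counted over
bases with Phred quality ≥ 30. We read the coverage cutoff as applying to
raw coverage and the quality threshold as applying to allele counting; the
published description is compatible with either reading at the boundary.

Each subsequent filter records a named flag; a candidate *passes* when no
flag is set. In order:

* **germline** — position matches an annotated germline variant (any
  alternate allele; positions are compared exactly).
* **blacklist**, **rna_edit** — position falls inside a mask interval
  (BED input, 0-based half-open on disk).
* **splice_junction** — distance to the nearest annotated interval
  boundary base is < 7 bp (distance 0 at the terminal exonic base).
* **seq_error** — upper-tail binomial probability
  P(X ≥ alt | n = coverage, p = 0.001) ≥ 1e-4; p = 0.001 matches the
  Phred-30 counting threshold.
* **vaf** — lower-tail binomial probability
  P(K ≤ alt | n = ref + alt, 0.5) > 0.05, i.e. the counts are consistent
  with a true variant allele fraction of 0.5 or more (a missed germline
  heterozygote).
* **read_pos_bias**, **map_qual_bias**, **base_qual_bias**,
  **strand_bias**, **var_dist_bias** — two-sided Mann–Whitney comparisons
  of alternate- versus reference-supporting read attributes at α = 0.05.
* **polynucleotide** — a maximal run of ≥ 7 identical reference bases lies
  within 20 bp (boundary cases: distance ≤ 20 flags; the candidate inside
  the run has distance 0).
* **recurrence_fraction**, **recurrent** — applied to candidates passing
  everything above: loci mutated in ≥ max(2, ⌈0.04 · n⌉) accessions, then
  loci mutated in ≥ 2 accessions among the remaining survivors. The floor
  of two exists because a locus observed in a single accession is not
  repeated; without it the 4% rule degenerates for cohorts under 25
  accessions.
* **outlier_accession** — accessions are split into four equal-width bins
  of total depth; within each bin, accessions whose surviving mutation
  count lies outside [Q25 − 1.5·IQR, Q75 + 1.5·IQR] (type-7 quantiles) are
  excluded, as is any accession alone in its bin.
* **ambiguous_region** — position is not inside a UTR/exonic interval that
  overlaps no other gene's UTR/exonic intervals. Intervals are split at
  cross-gene overlap boundaries so the label is exact per base.

Only the last three filters are order-dependent (they consume prior
survivors); all others are independently callable and idempotent.

### The Mann–Whitney implementation

The test uses exact enumeration of the null U distribution when both
groups have ≤ 8 observations and no ties, otherwise the normal
approximation with tie correction and continuity correction; a fully tied
comparison (e.g. constant mapping quality on both sides) returns p = 1 and
never flags. The variant-distance statistic assigns each read the mean
absolute distance between its position-in-read and the positions of the
reference-supporting reads (self excluded for reference reads). Comparing
within-group mean pairwise distances directly would make the test strongly
anticonservative, because within-group means share the group's realized
dispersion; the cross-group form applies the same transform to every
read's position, so under the null both groups' values are exchangeable
and the test stays near its nominal level.

A consequence worth stating plainly: with four effectively active tests at
α = 0.05 (mapping quality is constant for uniquely mapped reads), a
candidate with perfectly null attributes passes all bias tests with
probability ≈ 0.95⁴ ≈ 0.81. Joint attrition of true mutations at this
level is intrinsic to the published thresholds, not an implementation
artifact, and it is visible in the end-to-end recovery numbers the test
suite computes.

## Genewise features and offsets

For each gene, mutation type and strand class the modeling table carries:

* **b** — base-aware effective gene length: the number of unambiguous
  UTR/exonic positions passing the site-level coverage filter in at least
  one accession whose reference base, read on the strand implied by the
  gene strand and strand class, is the type's pyrimidine. The union over
  accessions is used, not the average.
* **d\*** — normalized depth: total depth over those accession × position
  pairs divided by b (reads per site, summed across accessions). The exact
  identity d\*·b = summed depth holds by construction.
* **strand class** — a mutation is collapsed to its pyrimidine
  representation (C>A, C>G, C>T, T>A, T>C, T>G, complementing
  purine-reference records); it is *template*-strand when the pyrimidine
  lies opposite the annotated gene strand. The assignment is invariant to
  complementing the whole locus.
* **covariates** — GC content over the gene's unambiguous UTR/exonic
  bases; replication timing as log2 of the overlap-weighted mean of
  late/early signal ratios; and per-mark chromatin signal as the sum over
  replicate files and regions of signal × overlap, divided by the summed
  UTR/exonic length. We use the summed UTR/exonic length (not the
  annotated gene span) as the normalizing length in both aggregations so
  numerator and denominator share the same support; both aggregations are
  invariant to splitting a track region into adjacent pieces of equal
  value. Genes with no overlapping track region are excluded from that
  model rather than zero-filled, because zero is a meaningful signal
  value.

Covariates are standardized to zero mean and unit variance within each
mutation-type table after row exclusions (b = 0 or missing covariates).
log d\* and the template-strand indicator are deliberately left
unstandardized so their coefficients keep interpretable units.

## The penalized Poisson model

Genewise counts are modeled independently per mutation type as

E[m] = b · exp{ α + κ·log d\* + γ·1[template] + X·β }

with offset log b, maximized under an L1 penalty on κ, γ and β (α
unpenalized). The penalty grid is 100 log-spaced values from the smallest
penalty zeroing all coefficients down to 1e-4 of it; the chosen penalty
minimizes mean held-out Poisson deviance over 10 folds whose assignment is
derived from a stated seed. We chose the deviance-minimizing penalty
rather than the one-standard-error rule; the former recovers small
coefficients (a strand effect of ±0.1 survives shrinkage) at the cost of
retaining some null covariates with small nonzero estimates — in the
package's own recovery simulations roughly half the null-covariate
estimates are exactly zero at the chosen penalty. The fit is delegated to
coordinate descent (glmnet) with standardization disabled; the
unpenalized limit is cross-checked against an IRLS fit in the test suite.

Supporting analyses: partial correlation t-values of each covariate with
m/b conditioned on log d\* (with a guarded zero for covariates collinear
with the conditioning variable); a locus-level Poisson recurrence model
E[m_l]/c_l = exp(α + β log(d_l/c_l)) with offset log c_l; alternate-allele
entropy −Σ p(b) log p(b) over the three non-reference bases in natural
log, whose uniform limit is ln 3 ≈ 1.10; 96-channel trinucleotide
catalogs with reverse-complemented purine contexts; and a deterministic
KL-divergence nonnegative matrix factorization (multiplicative updates
from a seeded initialization) as the signature-extraction stand-in, with
greedy cosine matching against planted or user-supplied reference
signatures.

## What the generator emulates — and what it does not

`simulate_genome()` packs strand-annotated genes (UTR/exon/intron
structure) onto random chromosomes at a target GC fraction of 0.42, always
including one overlapping gene pair so ambiguity handling is exercised,
and plants homopolymer runs of ≥ 7 bases at a configurable rate per kb.
`simulate_tracks()` draws per-gene latent multivariate-normal covariate
values with a user correlation matrix and realizes them as
piecewise-constant bedGraph regions (gene spans split into 2–3 regions of
equal value); chromatin marginals are mean 0.4, sd 0.12 on [0, 1], and
replication timing is an early/late pair with early ≡ 1.
`simulate_pileup()` emits one site observation per accession × covered
position: coverage is Poisson around accession × gene expression factors
(mean 100 reads, accession factors uniform on 0.6–1.5, gene factors
log-normal with σ = 0.3), a per-read miscall rate of 3e-4 produces
background third alleles, and per-read attributes follow stated choices —
position uniform on [0, 94), mapping quality constant 60 (shifted down 20
for biased reads, which also concentrate in the first 10 positions), base
quality integer-rounded Normal(36, 2) truncated to [2, 41], strand
Bernoulli(0.5).

Planted classes: 100 private true somatic mutations at allele fraction
0.25; 30 unannotated germline-leak loci carried by ~30% of accessions at
fraction 0.5; 20 each of polynucleotide-adjacent, splice-edge, high-VAF
(0.9) and biased-read records; records at annotated germline positions;
and one outlier accession with a 10× private mutation load. Records are
planted only where they are detectable (coverage ≥ 60 in the carrier;
≥ 40 for germline-class records), away from other artifact contexts, so
each class isolates one filter. The per-accession true-mutation density
(two per accession) mirrors a desk-scale cohort; at this density the
groupwise IQR outlier rule operates near its discrete degeneracy (IQR
often 0), which the recovery tests make visible.

Not emulated: read-level data (the generator emits pileup-level
observations, since every filter consumes pileup-level quantities),
FASTQ/BAM, bigWig (bedGraph only), realistic sequence-context mutation
spectra, allele-specific expression, and correlated attribute structure
between reads. Passing tests therefore demonstrate the pipeline's
*semantics* — each filter removes what it claims to remove, each feature
aggregates what its formula states — not calibration against real
A. thaliana data.

## Numerical and design choices

* Internal coordinates are 1-based closed (the IRanges convention);
  conversions to 0-based half-open BED/bedGraph and 1-based VCF/GFF3
  happen only in the readers and writers.
* Quantiles use the type-7 (linear interpolation) rule.
* Binomial tails are computed with `pbinom`; tests verify agreement with
  direct pmf summation to 1e-12 relative error.
* Distance conventions: "within 20 bp" flags at distance ≤ 20; "less than
  7 bp" flags at distance < 7, measured to the terminal exonic base.
* "Evenly spaced" accession groups are equal-width depth bins (not
  equal-count quartiles).
* Degenerate inputs: zero-coverage sites are errors for the binomial
  error test; an all-zero count vector yields a degenerate model fit with
  a warning; empty Mann–Whitney groups skip the test without flagging;
  zero vectors are rejected by cosine similarity; entropy is undefined at
  loci with no mutations.
* One master seed drives every simulation; each sub-generator derives a
  labeled sub-stream, so identical configuration reproduces byte-identical
  outputs (the pipeline manifest records md5 checksums).
* Test problem sizes: end-to-end recovery uses 20 genes × 50 accessions ×
  10 seeds; model recovery uses 2,000 rows × 6 types × 20 replicates;
  the recurrence model 10,000 loci. These sizes give Monte-Carlo
  tolerances of a few percent while keeping the default suite fast.

## Known limitations

* The five bias tests jointly remove ≈ 19% of perfectly clean candidates
  at α = 0.05; any application valuing sensitivity should consider a
  multiplicity correction, which the published procedure does not apply.
* The IQR outlier rule is unstable when per-accession mutation counts are
  small integers; with large cohorts and realistic counts this matters
  less.
* The signature stand-in is a point-estimate factorization; it reports no
  uncertainty and its solutions are unique only up to the usual NMF
  indeterminacies.
* Germline removal is position-exact; nearby but unannotated germline
  variation is handled only by the VAF and recurrence filters.
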