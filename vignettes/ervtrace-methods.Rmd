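---
title: "Methods: pedigree-aware analysis of retroviral germline colonization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pedigree-aware analysis of retroviral germline colonization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ervtrace)
```

## The problem

Koalas are in the middle of retroviral germline colonization: the koala
retrovirus (KoRV) and the older phaCin-beta lineage still segregate as
polymorphic insertions, while phaCin-beta-like is largely fixed. In a
pedigreed captive population every integration is an inherited biallelic
variant — the pre-integration site is the reference allele, the provirus
the alternative allele — so standard population and quantitative genetics
apply: allele frequencies, Mendelian transmission, de novo events,
selection against deleterious insertions, and marker–trait association.
`ervtrace` implements that full analysis chain and ships a synthetic
cohort generator with exact truth tables so that each stage can be
validated without access to restricted sequencing data.

## Integration-site discovery

Two read classes witness an integration in short-read data: *anchored
mates* (a host-aligned read whose mate aligns to a viral reference) and
*soft-clipped junction reads* (clips must exceed 20 bp; host alignments
need mapping quality >= 30). Evidence is pooled and clustered per family
and contig by single-linkage chaining on sorted positions: consecutive
positions at most one gap apart join a cluster. The gap is 500 bp for KoRV
(absent from the reference assembly, so clusters are tight around a point
breakpoint) and 9 kbp for the older lineages whose ~8 kbp proviruses are
present in the assembly and spread the evidence. Clusters need at least 20
pooled reads. Only soft-clip termini vote for the exact breakpoint (modal
terminus; ties break toward the smaller coordinate, a deterministic choice
the source method leaves open); a cluster overlapping an annotated ERV
interval is reported as a *known* site with the annotated start/end
instead of a point breakpoint.

Sites are shared between individuals when their cluster extents overlap,
and the shared registry is the transitive closure of pairwise overlap.
Using cluster extents rather than resolved breakpoints matters: the two
junction termini of one physical insertion differ by the target-site
duplication (TSD) length, and point-breakpoint merging would split one
site into two registry entries.

## Zygosity from read ratios

At each site, reads are tallied as *soft-clipped* (clip terminus within
+/-10 bp of the site, the TSD tolerance) or *crossing* (spanning the site
with both ends strictly beyond the margin window; coordinates are 0-based
half-open throughout, converted to 1-based only at the VCF/SAM boundary).
With f the soft-clipped fraction, novel sites call: f > 0.7 homozygous
alternative, 0.3 <= f <= 0.7 heterozygous, f < 0.3 undetermined (-1).
The inclusive het window is what reproduces the printed operating
characteristics of the method: a true heterozygote at coverage c is missed
with probability P[X < ceil(0.3c) or X > floor(0.7c)], X ~ Binomial(c,
1/2) — 0.643% at 40x, 10.94% at 10x (`miss_probability()`). For known
sites the reference carries the provirus, so the crossing fraction (mean
over the two annotated breakpoints) supports the integration allele; the
het window is mirrored symmetrically, and the allele orientation is
isolated behind `call_genotype_known()` because the source method states
only the >70% homozygosity rule.

Population matrices assume hom-ref for individuals with no evidence at a
registry site, code replicate disagreements as -1, and are filtered on
AAF > 0, undetermined fraction <= 0.1 and per-site Mendelian error <= 0.05
(all boundary-inclusive as worded).

## Pedigree dynamics

De novo germline integrations are heterozygous sites unique to a joey
(coverage >= 40 reads) with both parents confidently 0 — a parent called
-1 blocks the candidate, since it cannot exclude inheritance.
A subtlety worth knowing: the per-site Mendelian-error filter (<= 0.05)
interacts with cohort size. A genuine de novo event *is* a Mendelian
violation at one triad, so its per-site error rate is 1/n over n
assessable offspring — with fewer than 20 assessable offspring every
singleton de novo site is filtered out before the joey-specific screen
ever sees it. The published cohort had 63 offspring with a genotyped
parent (1/63 = 0.016 passes); simulated cohorts need comparable triad
counts for the de novo analysis to be non-trivial.

Transmission to the next generation validates a candidate when any
genotyped offspring is heterozygous at >= 10 reads; the expected number of
transmitted integrations composes Mendelian segregation with the miss
model, 0.5 x (1 - miss(10)) = 44.5%. Per-generation integration rates are
new events over triads; elimination is a positive deceased-only allele
frequency with no living carrier. The denominator behind the published
per-bp elimination rates is not stated in the source; `elimination_rate()`
exposes it (`diploid_factor`), and a factor of 4 x haploid length is the
reconstruction consistent with the printed values.

## Mutation rate and molecular dating

Trio SNV candidates pass when the joey is heterozygous for an allele
absent in both parents with depth >= 20, genotype quality >= 20 and allele
balance >= 0.4 (inclusive). Rates divide total de novo counts by trios x
diploid genome length (haploid length is the parameter; the x2 lives
inside the formula to avoid double multiplication); the per-year variant
divides each trio's count by the mean parental age first. LTR divergence
is a global-alignment p-distance in which a contiguous indel counts as a
single event — that convention is what makes one 1-bp indel in 1000 bases
equal 0.001. Colonization time = divergence / (2 x per-year rate), because
both LTRs accumulate substitutions independently after integration.

## Long-read inverse-PCR calling

Viral segments are excised from each read by iterative local alignment
against the supplied viral references (>= 90% identity, the same criterion
the flank filter uses; the source names no viral-match thresholds). Host
flanks survive if matches exceed 50 bp at identity >= 0.90 and mapq >= 30.
Junction-side flank termini are binned; peaks need support strictly above
10 reads; a left and right peak pair within 10 bp (TSD) or across at most
1,411 bp of annotation-masked sequence (the longest masked recKoRV).
Support of a pair is the sum of both peaks (configurable: sum/max/min; the
source says only "coverage"); >= 500 reads classifies endogenous, less is
somatic, with per-sample overrides mirroring the manually curated
1000-read exception. Automatic threshold selection is not attempted.

## Association and risk scores

Markers with MAF >= 0.01 are tested additively (genotype 0/1/2; -1 is
missing per marker) with logistic or linear regression — IRLS with
tolerance 1e-8 and at most 50 iterations; perfect separation is flagged,
not fatal. P-values are two-sided Wald tests without multiple-testing
correction; Bonferroni uses 953,591 independent tests as a *parameter*
(the LD pruning that produced it is out of scope), with suggestive
-log10 p cutoffs of 1.3 (ERVs) and 6 (SNPs). Covariates enter when they
improve AIC by more than 5 points against the base model.

The genetic risk score sums raw odds ratios times effect-allele counts —
raw ORs, not log-ORs, exactly as published, with a `weight_kind`-style
switch available by passing log-OR weights. Reference-allele effects count
2 - genotype; missing genotypes contribute 0 (mean imputation behind a
flag). Accuracy is estimated by 100 random 75/25 train/test splits with a
single-predictor logistic model, and the classification cutoff is the
accuracy-maximizing midpoint of the sorted unique scores (smallest on
ties; the searched grid is not stated in the source).

**Stratified splits.** The splits are stratified by class by default, a
choice the source leaves open. With ~200 individuals in balanced classes,
an unstratified 75/25 split makes the test-set majority class
systematically the *opposite* of the training majority, so the
intercept-driven classifier under the null scores ~0.44 rather than 0.5.
Stratification removes that artifact (null accuracy ~0.46–0.48; the
residual dip below 0.5 is the usual finite-sample anti-learning of
split-based evaluation and shrinks with n).

## What the synthetic cohort generator emulates

`generate_cohort()` states a world: 150 bp reads at 30x mean junction
coverage (per-site coverage is Poisson — shotgun depth variation without
GC bias), a 5 bp TSD (gammaretroviral TSDs run 4–6 bp; the source states
only the +/-10 bp calling margin), founder allele frequencies drawn per
family (Beta(0.4, 4) for the young segregating lineages, Beta(8, 0.4) for
the near-fixed phaCin-beta-like), Hardy–Weinberg founders, Mendelian
transmission, and Poisson de novo integrations per joey at the published
rates (0.33 KoRV, 0.02 phaCin-beta per generation), always heterozygous
in the joey because a new insertion arises on one gamete. Founders are
unrelated and sites unlinked — the analysis never uses LD. The trio SNV
simulator plants true de novo mutations at 1.03e-8 per bp per generation
over a *realistic* haploid length (3,234,982,288 bp, decoupled from the
scaled-down contigs, since SNV records never touch the simulated
sequence) plus decoys that each fail one quality filter.

Three deliberate departures from raw realism, and what they imply for a
green test:

* contigs are ~150–500 kb, not 3.2 Gb, and same-family sites are placed at
  least one chaining gap plus 2.5 kb apart, reproducing the separation
  regime of real densities (~1 site / 1.5 Mb). Tests therefore do not
  probe cluster collision behaviour at unrealistic densities.
* no base-level sequencing error, indels, recombination or mappability
  bias; soft-clip noise at non-carrier sites defaults to 0 because the
  source asserts no noise model (the rate is an exposed knob). Recall and
  false-positive results are for the clean-read regime.
* junction coverage for genotyping and de novo screening is
  Poisson(2 x mean coverage): informative reads accrue over both junction
  ends, which is how a 30x genome supports the 40-read joey floor.

## Numerical choices

Thresholds follow the source's wording exactly: "exceeding 20 bp" is
strict, "at least 20 reads" inclusive, the het window inclusive at both
edges, ">10 reads" strict, ">= 500 reads" inclusive. Breakpoint and
cutoff ties break toward the smallest value. `expected_transmissions()`
rounds to the nearest integer (16 x 0.445 = 7.1 prints as seven). A
single pipeline seed fans out to per-stage child seeds; every simulation
function restores the caller's RNG state. Degenerate inputs: zero
coverage yields an undetermined call and miss probability 1; a cluster
with no soft-clip votes resolves to its midpoint with a low-confidence
flag; empty founder sets are rejected as an empty pedigree.

## Known limitations

Sub-strain assignment per locus is reported only as aggregate fractions
(short reads cannot separate KoRV strains reliably). Genotypes have no
base-quality-aware likelihoods and -1 calls are not imputed. The
elimination-rate denominator and the unrounded per-year rate behind the
published 312,191-year date are not recoverable from the source; the
package reports both its exact arithmetic (312,500 years from the rounded
rate) and the configurable denominator. Kinship/mixed-model correction of
the association tests is out of scope, as are the external aligner and
variant-caller internals the real pipeline depends on.
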