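# ervtrace

Pedigree-aware analysis of ongoing retroviral germline colonization, built
around the koala system: the koala retrovirus (KoRV) and the older
phaCin-beta lineages still segregate as polymorphic endogenous retrovirus
(ERV) insertions, so in a pedigreed population each integration behaves as
an inherited biallelic variant — the pre-integration site is the reference
allele, the provirus the alternative. `ervtrace` is for population and
conservation geneticists who want to track those variants across
generations: where they integrate, who carries them, how often new ones
arise, which are purged, and what they do to health traits.

## What it computes

* **Integration-site discovery** from short-read evidence: anchored-mate
  pairs and soft-clipped junction reads (> 20 bp clips, mapq ≥ 30) are
  chained per family by single-linkage with family-specific gaps (500 bp
  KoRV, 9 kbp otherwise); clusters need ≥ 20 reads; modal soft-clip
  termini give exact breakpoints for novel sites.
* **Read-ratio zygosity**: with soft-clip fraction *f* at a site,
  *f* > 0.7 → hom-alt, 0.3 ≤ *f* ≤ 0.7 → het, else undetermined. A true
  het at coverage *c* is missed with probability
  P[X < ⌈0.3c⌉ or X > ⌊0.7c⌋], X ~ Bin(c, ½): 0.643% at 40×, 10.94% at
  10×. Site QC: AAF > 0, undetermined ≤ 0.1, Mendelian error ≤ 0.05.
* **Pedigree dynamics**: de novo integrations (het joey at ≥ 40 reads,
  both parents 0), F2 validation at ≥ 10 reads, per-generation rates,
  eliminated integrations (deceased-only carriers).
* **Mutation rate & dating**: trio de novo SNVs (DP ≥ 20, GQ ≥ 20,
  AB ≥ 0.4); rate = Σ de novo / (n_trios × haploid length × 2); LTR
  p-distance (contiguous indel = one event) dates colonization as
  divergence / (2 × per-year rate).
* **Long-read inverse-PCR calling**: viral-segment excision, flank filters
  (> 50 bp, ≥ 90% identity, mapq ≥ 30), breakpoint peaks (> 10 reads),
  TSD pairing (≤ 10 bp, or ≤ 1,411 bp masked recKoRV), endogenous vs
  somatic at ≥ 500 reads with per-sample overrides.
* **Association & risk scores**: additive logistic/linear tests
  (MAF ≥ 0.01, two-sided Wald, ΔAIC < −5 covariate selection), odds-ratio
  weighted genetic risk scores with 100-rep 75/25 bootstrap accuracy and
  accuracy-maximizing cutoff selection.
* **Synthetic cohorts**: `generate_cohort()` builds references, provirus
  models, multi-generation pedigrees with Mendelian transmission, Poisson
  de novo integrations, trio SNV calls and phenotypes — with exact truth
  tables, so every stage above is testable offline.

See `vignettes/ervtrace-methods.Rmd` for the model details and design
choices.

## Worked example

```r
library(ervtrace)

miss_probability(40)                      # 0.00643  -> the "0.6%" at 40x
miss_probability(10)                      # 0.109375 -> ~10% at 10x
expected_transmissions(16, 10)            # inheritance 0.445, expected 7
integration_rate(15, 46)                  # 0.33 new KoRV per generation
colonization_time(0.001, 1.6e-9)          # 312500 years

cfg <- sim_config(seed = 11, n_contigs = 2, contig_length = 150000,
                  families = list(korv_family(8), phacinb_family(5),
                                  phacinb_like_family(4)))
res <- run_pipeline(cfg, n_founders = 12, n_generations = 2)
res$manifest[c("n_registry_sites", "n_sites_after_qc", "n_triads",
               "n_denovo_candidates")]
res$denovo[, c("site_id", "joey_id", "joey_coverage", "f2")]
```

Output of the pipeline block (exactly as printed):

```
registry 16, after QC 16, triads 24, de novo 8, eliminated 1
KoRV rate 0.29 | mu_gen 1.07e-08 mu_year 1.57e-09 | LTR div 0.00198 | colonization 631560 y
                   site_id joey_id joey_coverage            f2
        KoRV:contig2:51148   SB112            59     validated
        KoRV:contig1:36773   SB116            52     validated
        KoRV:contig1:26373   SB120            68 not_validated
        KoRV:contig2:82073   SB126            50  not_assessed
       KoRV:contig1:101149   SB128            48  not_assessed
       KoRV:contig2:148369   SB130            73  not_assessed
 phaCin-beta:contig1:34264   SB133            55  not_assessed
        KoRV:contig2:78896   SB135            79  not_assessed
```

All 8 candidates are the 8 events the generator actually planted (the
truth table confirms recall 8/8 with zero false positives); the KoRV
integration rate 0.29 ≈ 7/24 triads against a configured 0.33 per joey;
the estimated mutation rate 1.07 × 10⁻⁸ recovers the planted
1.03 × 10⁻⁸ per bp per generation; "validated" means a genotyped F2
offspring carries one copy at ≥ 10 reads.

## Command line

```sh
inst/cli/ervtrace miss-prob --coverage 40
inst/cli/ervtrace simulate --seed 1 --founders 12 --generations 3 --out out/
inst/cli/ervtrace run-all  --seed 1 --out out/
```
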