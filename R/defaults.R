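#' Default thresholds used across the pipeline
#'
#' All numeric defaults of the analysis stages in one place, so they can be
#' audited and overridden consistently. Each value is the operational
#' threshold of the published koala ERV pedigree analysis workflow:
#' evidence clustering (>= 20 reads, 500 bp chaining gap for KoRV vs
#' 9 kbp for the older ERV lineages), soft-clip extraction (> 20 bp clips,
#' mapping quality >= 30), the +/-10 bp target-site-duplication margin,
#' the 30--70\% heterozygous read-ratio window, site QC cutoffs
#' (undetermined <= 0.1, Mendelian error <= 0.05), de novo integration
#' coverage floors (40 reads in the joey, 10 in the F2), trio SNV filters
#' (DP >= 20, GQ >= 20, allele balance >= 0.4), long-read calling (peaks
#' > 10 reads, 1,411 bp masked recKoRV gap, 500-read endogenous cutoff),
#' and association/risk-score settings (MAF >= 0.01, Delta-AIC < -5,
#' suggestive -log10 p of 1.3 for ERVs and 6 for SNPs, 100 bootstrap
#' repeats with a 75\% training split).
#'
#' @return Named list of defaults.
#' @export
ervtrace_defaults <- function() {
  list(
    min_cluster_reads   = 20L,
    gap_korv            = 500L,
    gap_other           = 9000L,
    min_clip            = 20L,
    min_mapq            = 30L,
    tsd_margin          = 10L,
    het_window          = c(0.3, 0.7),
    undet_max           = 0.1,
    mendel_max          = 0.05,
    min_joey_coverage   = 40L,
    f2_coverage         = 10L,
    snv_min_dp          = 20L,
    snv_min_gq          = 20L,
    snv_min_ab          = 0.4,
    peak_min_reads      = 10L,   # strict: peaks need support > 10
    tsd_window          = 10L,
    max_masked_gap      = 1411L,
    endogenous_min_reads = 500L,
    flank_min_len       = 50L,   # strict: matches must exceed 50 bp
    flank_min_identity  = 0.90,
    maf_min             = 0.01,
    delta_aic           = -5,
    suggestive_erv_log10 = 1.3,
    suggestive_snp_log10 = 6,
    n_independent_tests = 953591L,
    bootstrap_reps      = 100L,
    train_fraction      = 0.75
  )
}
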