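#' Filter candidate de novo SNVs in trios
#'
#' Keeps records where the joey is heterozygous for an allele absent in
#' both parents (the dominant, conservatively defined de novo class) and
#' the quality thresholds pass inclusively: depth >= `min_dp`, genotype
#' quality >= `min_gq`, allele balance >= `min_ab` at joey-het sites.
#' Records missing any of the three fields are excluded and counted in the
#' `n_excluded_missing` attribute.
#'
#' @param trio_records data.frame(contig, pos1, gt_sire, gt_dam, gt_joey,
#'   dp, gq, ab) with genotype codes in \{0, 1, 2\}.
#' @param min_dp,min_gq,min_ab Inclusive thresholds.
#' @return The passing subset, same columns.
#' @export
filter_de_novo_snvs <- function(trio_records, min_dp = 20L, min_gq = 20L,
                                min_ab = 0.4) {
  r <- trio_records
  missing_fields <- is.na(r$dp) | is.na(r$gq) | is.na(r$ab)
  r2 <- r[!missing_fields, , drop = FALSE]
  keep <- r2$gt_joey == 1L & r2$gt_sire == 0L & r2$gt_dam == 0L &
    r2$dp >= min_dp & r2$gq >= min_gq & r2$ab >= min_ab
  out <- r2[keep, , drop = FALSE]
  attr(out, "n_excluded_missing") <- sum(missing_fields)
  out
}

#' Germline mutation rate per base pair per generation
#'
#' Total de novo SNVs over all trios divided by the number of trios times
#' the diploid genome length (haploid length x 2).
#'
#' @param n_denovo_by_trio Numeric vector, one de novo count per trio.
#' @param haploid_length Haploid assembly length in bp.
#' @return Mutations per bp per generation.
#' @export
rate_per_generation <- function(n_denovo_by_trio, haploid_length) {
  if (length(n_denovo_by_trio) < 1L) stop("need at least one trio", call. = FALSE)
  stopifnot(haploid_length > 0)
  sum(n_denovo_by_trio) / (length(n_denovo_by_trio) * haploid_length * 2)
}

#' Germline mutation rate per base pair per year
#'
#' Each trio's de novo count is first converted to a per-year count by
#' dividing by the arithmetic mean age of its parents, then averaged over
#' trios against the diploid genome length.
#'
#' @param n_denovo_by_trio De novo counts per trio.
#' @param parental_ages data.frame(sire_age, dam_age) in years, one row per
#'   trio; all ages must be positive.
#' @param haploid_length Haploid assembly length in bp.
#' @return Mutations per bp per year.
#' @export
rate_per_year <- function(n_denovo_by_trio, parental_ages, haploid_length) {
  if (length(n_denovo_by_trio) < 1L) stop("need at least one trio", call. = FALSE)
  stopifnot(haploid_length > 0,
            length(n_denovo_by_trio) == nrow(parental_ages))
  if (any(!is.finite(parental_ages$sire_age) | parental_ages$sire_age <= 0 |
            !is.finite(parental_ages$dam_age) | parental_ages$dam_age <= 0))
    stop("parental ages must be positive", call. = FALSE)
  mean_age <- (parental_ages$sire_age + parental_ages$dam_age) / 2
  sum(n_denovo_by_trio / mean_age) /
    (length(n_denovo_by_trio) * haploid_length * 2)
}

#' LTR divergence (p-distance) between the two LTRs of a provirus
#'
#' The 5' and 3' LTRs are identical at integration, so their divergence
#' acts as a molecular clock. Sequences are globally aligned and the
#' p-distance is the number of differing alignment columns over the aligned
#' length, with a contiguous insertion/deletion counted as a single
#' difference event (one 1-bp indel in 1000 bases gives 0.001).
#'
#' @param ltr5_seq,ltr3_seq Character strings or `DNAString`s.
#' @return p-distance in substitutions (plus indel events) per site.
#' @export
ltr_divergence <- function(ltr5_seq, ltr3_seq) {
  s5 <- as.character(ltr5_seq); s3 <- as.character(ltr3_seq)
  if (!nzchar(s5) || !nzchar(s3)) stop("empty sequence", call. = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(s5), Biostrings::DNAString(s3), type = "global",
    gapOpening = 10, gapExtension = 0.5)
  a <- strsplit(as.character(Biostrings::pattern(aln)), "")[[1]]
  b <- strsplit(as.character(Biostrings::subject(aln)), "")[[1]]
  gap <- a == "-" | b == "-"
  mism <- !gap & a != b
  gap_events <- sum(diff(c(FALSE, gap)) == 1L)
  (sum(mism) + gap_events) / length(a)
}

#' Date the start of germline colonization from LTR divergence
#'
#' Colonization time = divergence / (2 x per-year rate): both LTRs
#' accumulate substitutions independently after integration.
#'
#' @param divergence LTR p-distance (substitutions per site).
#' @param per_year_rate Mutations per bp per year (> 0).
#' @return Time in years.
#' @export
colonization_time <- function(divergence, per_year_rate) {
  if (per_year_rate <= 0) stop("per_year_rate must be > 0", call. = FALSE)
  divergence / (2 * per_year_rate)
}
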