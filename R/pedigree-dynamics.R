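#' List complete triads in a pedigree
#'
#' @param pedigree An `erv_pedigree` data.frame.
#' @return data.frame(sire_id, dam_id, joey_id) for every individual with
#'   both parents present in the pedigree.
#' @export
find_triads <- function(pedigree) {
  ok <- !is.na(pedigree$sire) & !is.na(pedigree$dam) &
    pedigree$sire %in% pedigree$id & pedigree$dam %in% pedigree$id
  data.frame(sire_id = pedigree$sire[ok], dam_id = pedigree$dam[ok],
             joey_id = pedigree$id[ok], stringsAsFactors = FALSE)
}

#' Detect de novo germline integrations in triads
#'
#' A candidate is a site where the joey is a well-covered heterozygote
#' (coverage >= `min_joey_coverage` reads, which leaves only a 0.6\% chance
#' of misclassifying a true het at 40x) and both parents are confidently
#' homozygous reference. Parents called undetermined (-1) cannot exclude
#' inheritance and therefore block the candidate.
#'
#' @param matrix Genotype matrix (individuals x sites).
#' @param coverage Matching junction-coverage matrix.
#' @param triads data.frame(sire_id, dam_id, joey_id).
#' @param min_joey_coverage Coverage floor for the joey call (inclusive).
#' @return data.frame of candidates (site_id, sire_id, dam_id, joey_id,
#'   joey_coverage).
#' @export
find_de_novo <- function(matrix, coverage, triads, min_joey_coverage = 40L) {
  out <- list()
  for (i in seq_len(nrow(triads))) {
    tri <- triads[i, ]
    if (!all(c(tri$sire_id, tri$dam_id, tri$joey_id) %in% rownames(matrix))) {
      warning("triad with joey ", tri$joey_id,
              " has members missing from the matrix; skipped")
      next
    }
    hit <- which(matrix[tri$joey_id, ] == 1L &
                   coverage[tri$joey_id, ] >= min_joey_coverage &
                   matrix[tri$sire_id, ] == 0L &
                   matrix[tri$dam_id, ] == 0L)
    if (length(hit))
      out[[length(out) + 1L]] <- data.frame(
        site_id = colnames(matrix)[hit], sire_id = tri$sire_id,
        dam_id = tri$dam_id, joey_id = tri$joey_id,
        joey_coverage = unname(coverage[tri$joey_id, hit]),
        stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(site_id = character(0), sire_id = character(0),
                      dam_id = character(0), joey_id = character(0),
                      joey_coverage = numeric(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Validate a de novo integration in the next generation
#'
#' Validated when any genotyped offspring of the candidate joey carries one
#' copy of the integration at coverage >= `min_offspring_coverage` reads.
#'
#' @param candidate One row of [find_de_novo()] output.
#' @param matrix,coverage Genotype and coverage matrices.
#' @param pedigree The pedigree linking joeys to offspring.
#' @param min_offspring_coverage Coverage floor for the F2 call.
#' @return "validated", "not_validated", or "not_assessed" (no genotyped
#'   offspring).
#' @export
validate_f2 <- function(candidate, matrix, coverage, pedigree,
                        min_offspring_coverage = 10L) {
  kids <- pedigree$id[!is.na(pedigree$sire) & pedigree$sire == candidate$joey_id |
                        !is.na(pedigree$dam) & pedigree$dam == candidate$joey_id]
  kids <- intersect(kids, rownames(matrix))
  if (!length(kids)) return("not_assessed")
  g <- matrix[kids, candidate$site_id]
  cv <- coverage[kids, candidate$site_id]
  if (any(g == 1L & cv >= min_offspring_coverage)) "validated" else
    "not_validated"
}

#' Germline integration rate per generation
#'
#' @param n_new_by_family Named (or plain) numeric counts of new germline
#'   integrations per family.
#' @param n_triads Number of triads assessed (>= 1).
#' @return Rates per generation, rounded to two decimals as reported.
#' @export
integration_rate <- function(n_new_by_family, n_triads) {
  if (n_triads < 1) stop("n_triads must be >= 1", call. = FALSE)
  round(n_new_by_family / n_triads, 2)
}

#' Expected number of transmitted new integrations
#'
#' A new heterozygous integration is transmitted to a given offspring with
#' probability 0.5; detection in the offspring additionally requires the
#' coverage-dependent het call to succeed, so the observable inheritance
#' rate is 0.5 (1 - miss(threshold)): 44.5\% at the 10-read validation
#' floor. The expected count is rounded to the nearest integer.
#'
#' @param n_new Number of new integrations assessed.
#' @param offspring_coverage_threshold Coverage at which offspring are
#'   validated.
#' @return list(inheritance_rate, expected).
#' @export
expected_transmissions <- function(n_new, offspring_coverage_threshold = 10L) {
  inh <- 0.5 * (1 - miss_probability(offspring_coverage_threshold))
  list(inheritance_rate = inh, expected = round(n_new * inh))
}

#' Find integrations eliminated from the living population
#'
#' A site is eliminated when its allele frequency among deceased
#' individuals is positive but no living individual carries it. Sites with
#' AAF_deceased above `high_freq_aaf` are flagged as high-frequency losses.
#'
#' @param matrix Genotype matrix.
#' @param vital_status Named character vector ("living"/"deceased") over
#'   the matrix rows.
#' @param high_freq_aaf Flag threshold on the deceased-only AAF (strict >).
#' @return data.frame(site_id, aaf_deceased, aaf_living, eliminated,
#'   high_frequency, carriers).
#' @export
find_eliminated <- function(matrix, vital_status, high_freq_aaf = 0.05) {
  vs <- vital_status[rownames(matrix)]
  if (!any(vs == "living")) stop("cannot assess elimination", call. = FALSE)
  aaf_of <- function(m) {
    n0 <- colSums(m == 0L); n1 <- colSums(m == 1L); n2 <- colSums(m == 2L)
    called <- n0 + n1 + n2
    ifelse(called > 0, (2 * n2 + n1) / (2 * called), 0)
  }
  aaf_d <- aaf_of(matrix[vs == "deceased", , drop = FALSE])
  aaf_l <- aaf_of(matrix[vs == "living", , drop = FALSE])
  eliminated <- aaf_d > 0 & aaf_l == 0
  carriers <- lapply(seq_len(ncol(matrix)), function(j)
    rownames(matrix)[matrix[, j] > 0L])
  # eliminated sites cannot have living carriers, by construction
  stopifnot(!any(vapply(which(eliminated), function(j)
    any(vs[carriers[[j]]] == "living"), TRUE)))
  out <- data.frame(site_id = colnames(matrix), aaf_deceased = unname(aaf_d),
                    aaf_living = unname(aaf_l),
                    eliminated = unname(eliminated),
                    high_frequency = unname(eliminated & aaf_d > high_freq_aaf),
                    stringsAsFactors = FALSE)
  out$carriers <- carriers
  out
}

#' Elimination rate per base pair per generation
#'
#' Mirrors the shape of the per-generation mutation-rate denominator:
#' eliminated count over triads times the diploid genome length. The exact
#' denominator behind the published elimination rates is not stated, so it
#' is configurable via `diploid_factor`.
#'
#' @param n_eliminated Count of eliminated integrations (per family).
#' @param n_triads Number of triads.
#' @param haploid_length Haploid assembly length in bp.
#' @param diploid_factor Multiplier turning haploid into the denominator
#'   genome length (default 2).
#' @return Rate per bp per generation.
#' @export
elimination_rate <- function(n_eliminated, n_triads, haploid_length,
                             diploid_factor = 2) {
  stopifnot(n_triads > 0, haploid_length > 0)
  n_eliminated / (n_triads * haploid_length * diploid_factor)
}
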