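#' Excise viral segments from a long read, keeping host flanks
#'
#' Iteratively local-aligns each viral reference against the read, masks
#' every acceptable match (identity >= `min_identity` over >=
#' `min_viral_match` bp), and returns the remaining host flank segments
#' with their original read offsets. Reads without any viral match yield
#' zero flanks (such reads carry no junction information).
#'
#' @param read Character string or `DNAString`.
#' @param viral_references Named character vector or `DNAStringSet` of
#'   viral sequences (strains and/or LTRs).
#' @param min_identity Minimum fraction of matching bases in a viral hit.
#' @param min_viral_match Minimum viral match length in bp.
#' @param max_hits Maximum viral segments excised per read.
#' @return data.frame(flank_seq, read_start0, read_end0) of host flanks
#'   (0-based half-open read offsets), ordered along the read.
#' @export
excise_viral_segments <- function(read, viral_references,
                                  min_identity = 0.90,
                                  min_viral_match = 50L, max_hits = 5L) {
  seq <- as.character(read)
  n <- nchar(seq)
  masked <- rep(FALSE, n)
  refs <- as.character(viral_references)
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2)
  found_any <- FALSE
  for (it in seq_len(max_hits)) {
    cur <- strsplit(seq, "")[[1]]
    cur[masked] <- "N"
    cur <- paste(cur, collapse = "")
    best <- NULL
    for (ref in refs) {
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(cur), Biostrings::DNAString(ref),
        type = "local", substitutionMatrix = submat,
        gapOpening = 5, gapExtension = 2)
      st <- IRanges::start(Biostrings::pattern(aln))
      en <- IRanges::end(Biostrings::pattern(aln))
      len <- en - st + 1L
      if (length(st) == 0L || len < min_viral_match) next
      ident <- Biostrings::pid(aln) / 100
      if (ident < min_identity) next
      if (is.null(best) || len > best$len)
        best <- list(st = st, en = en, len = len)
    }
    if (is.null(best)) break
    masked[best$st:best$en] <- TRUE
    found_any <- TRUE
  }
  if (!found_any || all(masked) )
    return(data.frame(flank_seq = character(0), read_start0 = integer(0),
                      read_end0 = integer(0), stringsAsFactors = FALSE))
  r <- rle(masked)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- !r$values
  data.frame(flank_seq = substring(seq, starts[keep], ends[keep]),
             read_start0 = starts[keep] - 1L, read_end0 = ends[keep],
             stringsAsFactors = FALSE)
}

#' Filter flank alignments on length, identity and mapping quality
#'
#' Matches must be strictly longer than `min_len` bp, with identity >=
#' `min_identity` and mapping quality >= `min_mapq` (both inclusive).
#'
#' @param alignments data.frame with columns match_length, identity, mapq.
#' @param min_len,min_identity,min_mapq Thresholds.
#' @return Filtered data.frame.
#' @export
filter_flanks <- function(alignments, min_len = 50L, min_identity = 0.90,
                          min_mapq = 30L) {
  alignments[alignments$match_length > min_len &
               alignments$identity >= min_identity &
               alignments$mapq >= min_mapq, , drop = FALSE]
}

#' Align host flanks exactly against a reference (synthetic-data oracle)
#'
#' Error-free synthetic flanks are exact substrings of the reference, so an
#' exact-match search stands in for a long-read aligner in tests and in the
#' simulated pipeline. One best (first) hit per flank is reported.
#'
#' @param flanks data.frame from [excise_viral_segments()], plus a
#'   `read_id` column; the flank adjacent to the viral segment on its right
#'   is a "left" flank and vice versa (derived from read offsets by the
#'   caller or annotated here via `side`).
#' @param reference Named character vector of contig sequences.
#' @param side Optional character vector of junction sides per flank.
#' @return data.frame in the flank-alignment schema used by
#'   [call_breakpoint_peaks()].
#' @export
align_flanks_exact <- function(flanks, reference, side = NULL) {
  out <- list()
  for (i in seq_len(nrow(flanks))) {
    for (ct in names(reference)) {
      hit <- regexpr(flanks$flank_seq[i], reference[[ct]], fixed = TRUE)
      if (hit > 0) {
        out[[length(out) + 1L]] <- data.frame(
          read_id = flanks$read_id[i] %||% NA_character_,
          host_contig = ct, host_start0 = as.integer(hit) - 1L,
          host_end0 = as.integer(hit) - 1L + nchar(flanks$flank_seq[i]),
          match_length = nchar(flanks$flank_seq[i]), identity = 1,
          mapq = 60L,
          side = if (is.null(side)) NA_character_ else side[i],
          stringsAsFactors = FALSE)
        break
      }
    }
  }
  if (!length(out))
    return(data.frame(read_id = character(0), host_contig = character(0),
                      host_start0 = integer(0), host_end0 = integer(0),
                      match_length = integer(0), identity = numeric(0),
                      mapq = integer(0), side = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Call breakpoint peaks from flank alignments
#'
#' Flank termini (the junction-side end of each aligned flank) are binned
#' per position; positions supported by more than `min_reads` flanks are
#' emitted as peaks. A "left" flank abuts the virus on its right, so its
#' junction terminus is `host_end0`; a "right" flank's terminus is
#' `host_start0`.
#'
#' @param flanks Flank-alignment data.frame with `side` annotations.
#' @param min_reads Peaks require support strictly greater than this.
#' @return data.frame(contig, pos0, side, support).
#' @export
call_breakpoint_peaks <- function(flanks, min_reads = 10L) {
  if (nrow(flanks) == 0L)
    return(data.frame(contig = character(0), pos0 = integer(0),
                      side = character(0), support = integer(0),
                      stringsAsFactors = FALSE))
  terminus <- ifelse(flanks$side == "left", flanks$host_end0,
                     flanks$host_start0)
  key <- paste(flanks$host_contig, terminus, flanks$side, sep = "\r")
  tab <- table(key)
  tab <- tab[tab > min_reads]
  if (!length(tab))
    return(data.frame(contig = character(0), pos0 = integer(0),
                      side = character(0), support = integer(0),
                      stringsAsFactors = FALSE))
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  out <- data.frame(contig = vapply(parts, `[[`, "", 1L),
                    pos0 = as.integer(vapply(parts, `[[`, "", 2L)),
                    side = vapply(parts, `[[`, "", 3L),
                    support = as.integer(tab), stringsAsFactors = FALSE)
  out[order(out$contig, out$pos0), , drop = FALSE]
}

#' Pair left and right breakpoint peaks into integrations
#'
#' A left and a right peak on the same contig are paired when their
#' positions agree within the target-site-duplication window (10 bp), or
#' when they are separated by annotation-masked sequence of at most
#' `max_masked_gap` bp (the longest masked recKoRV is 1,411 bp). Greedy
#' nearest-neighbour pairing; unpaired peaks are returned separately.
#'
#' @param peaks Output of [call_breakpoint_peaks()], optionally with a
#'   `sample_id` column.
#' @param tsd_window TSD tolerance in bp (inclusive).
#' @param masked_intervals Optional data.frame(contig, start0, end0) of
#'   masked sequence.
#' @param max_masked_gap Maximum masked separation in bp (inclusive).
#' @return list(pairs, unpaired).
#' @export
pair_breakpoints <- function(peaks, tsd_window = 10L, masked_intervals = NULL,
                             max_masked_gap = 1411L) {
  pairs <- list(); used <- rep(FALSE, nrow(peaks))
  lefts <- which(peaks$side == "left")
  rights <- which(peaks$side == "right")
  masked_ok <- function(ct, lo, hi) {
    if (is.null(masked_intervals) || hi - lo > max_masked_gap) return(FALSE)
    mi <- masked_intervals[masked_intervals$contig == ct, , drop = FALSE]
    any(mi$start0 <= lo + tsd_window & mi$end0 >= hi - tsd_window)
  }
  for (li in lefts) {
    cand <- rights[!used[rights] & peaks$contig[rights] == peaks$contig[li]]
    if (!length(cand)) next
    d <- abs(peaks$pos0[cand] - peaks$pos0[li])
    ok <- d <= tsd_window
    if (!any(ok)) {
      ok <- vapply(cand, function(ri) masked_ok(
        peaks$contig[li], min(peaks$pos0[li], peaks$pos0[ri]),
        max(peaks$pos0[li], peaks$pos0[ri])), TRUE)
    }
    if (!any(ok)) next
    ri <- cand[ok][which.min(d[ok])]
    used[c(li, ri)] <- TRUE
    pairs[[length(pairs) + 1L]] <- data.frame(
      contig = peaks$contig[li],
      pos_left0 = peaks$pos0[li], pos_right0 = peaks$pos0[ri],
      support_left = peaks$support[li], support_right = peaks$support[ri],
      sample_id = if ("sample_id" %in% names(peaks)) peaks$sample_id[li]
      else NA_character_,
      stringsAsFactors = FALSE)
  }
  list(pairs = if (length(pairs)) do.call(rbind, pairs) else
    data.frame(contig = character(0), pos_left0 = integer(0),
               pos_right0 = integer(0), support_left = integer(0),
               support_right = integer(0), sample_id = character(0),
               stringsAsFactors = FALSE),
    unpaired = peaks[!used, , drop = FALSE])
}

#' Classify paired integrations as endogenous or somatic by read support
#'
#' Support at or above the sample's threshold (default 500 reads; per-
#' sample overrides allowed, mirroring the manually curated 1000-read
#' exception) marks an endogenous germline integration; lower support marks
#' a somatic integration enriched by the inverse PCR.
#'
#' @param pairs `pairs` element of [pair_breakpoints()].
#' @param endogenous_min_reads Default threshold (inclusive).
#' @param per_sample_overrides Named numeric of per-sample thresholds.
#' @param aggregate How the two peaks' support combines: "sum" (default),
#'   "max" or "min".
#' @return `pairs` with added `support` and `class` columns.
#' @export
classify_endogenous <- function(pairs, endogenous_min_reads = 500L,
                                per_sample_overrides = NULL,
                                aggregate = c("sum", "max", "min")) {
  aggregate <- match.arg(aggregate)
  if (nrow(pairs) == 0L) {
    pairs$support <- numeric(0); pairs$class <- character(0)
    return(pairs)
  }
  support <- switch(aggregate,
                    sum = pairs$support_left + pairs$support_right,
                    max = pmax(pairs$support_left, pairs$support_right),
                    min = pmin(pairs$support_left, pairs$support_right))
  thr <- rep(endogenous_min_reads, nrow(pairs))
  if (!is.null(per_sample_overrides)) {
    idx <- match(pairs$sample_id, names(per_sample_overrides))
    thr[!is.na(idx)] <- per_sample_overrides[idx[!is.na(idx)]]
  }
  if (is.null(endogenous_min_reads) || any(is.na(thr)))
    stop("no threshold for sample(s): ",
         paste(unique(pairs$sample_id[is.na(thr)]), collapse = ", "),
         call. = FALSE)
  pairs$support <- support
  pairs$class <- ifelse(support >= thr, "endogenous", "somatic")
  pairs
}
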