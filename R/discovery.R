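#' Map viral reference names to ERV families
#'
#' @param families List of [family_model()] objects.
#' @return Named character vector: reference name -> family label.
#' @export
viral_reference_names <- function(families) {
  out <- character(0)
  for (fam in families) {
    nm <- names(fam$substrains)
    out[nm] <- fam$name
  }
  out
}

#' Collapse viral reference hits to family labels
#'
#' Short reads cannot reliably distinguish sub-strains of the same
#' retrovirus, so all hits to any KoRV strain are treated as "KoRV";
#' sub-strain identities are retained for reporting (e.g. the KoRV-A vs
#' KoRV-B read fractions).
#'
#' @param ref_names Character vector of viral reference names hit.
#' @param families List of [family_model()] objects defining the
#'   configured references.
#' @return data.frame with columns `family`, `substrain`.
#' @export
collapse_family <- function(ref_names, families) {
  map <- viral_reference_names(families)
  unknown <- setdiff(unique(ref_names), names(map))
  if (length(unknown))
    stop("unknown viral reference(s): ", paste(unknown, collapse = ", "),
         "; configured: ", paste(names(map), collapse = ", "), call. = FALSE)
  data.frame(family = unname(map[ref_names]), substrain = ref_names,
             stringsAsFactors = FALSE)
}

#' Extract viral integration evidence from paired alignment sets
#'
#' Combines the two evidence classes: host-aligned reads whose mate aligned
#' to a viral sequence (anchored mates), and reads partially aligned to a
#' viral sequence whose soft-clipped host segment exceeds `min_clip` bp.
#' Host alignments below `min_mapq` are dropped; host records with no
#' corresponding viral alignment are skipped and counted in the
#' `n_skipped` attribute.
#'
#' @param virus_alignments data.frame(qname, rname, is_mate, ...) of viral
#'   alignments; `is_mate` is TRUE when the viral alignment belongs to the
#'   mate of the host-aligned read.
#' @param host_alignments data.frame with SAM-like columns (qname, rname,
#'   pos, mapq, cigar) of the same reads aligned to the retrovirus-masked
#'   host assembly.
#' @param families Configured [family_model()] list.
#' @param min_clip Soft-clips must exceed this many bases (strict >).
#' @param min_mapq Minimum host mapping quality (inclusive).
#' @return data.frame of evidence records (read_id, evidence_class, family,
#'   substrain, host_contig, host_pos0, terminus0, clip_length, mapq).
#' @export
extract_evidence <- function(virus_alignments, host_alignments, families,
                             min_clip = 20L, min_mapq = 30L) {
  empty <- data.frame(read_id = character(0), evidence_class = character(0),
                      family = character(0), substrain = character(0),
                      host_contig = character(0), host_pos0 = integer(0),
                      terminus0 = integer(0), clip_length = integer(0),
                      mapq = integer(0), stringsAsFactors = FALSE)
  if (nrow(host_alignments) == 0L) return(empty)
  cig <- parse_cigar(host_alignments$cigar)
  clip <- pmax(cig$lead_clip, cig$trail_clip)
  pos0 <- host_alignments$pos - 1L
  terminus0 <- ifelse(cig$lead_clip >= cig$trail_clip, pos0,
                      pos0 + cig$ref_width)
  partial <- virus_alignments[!virus_alignments$is_mate, , drop = FALSE]
  mates <- virus_alignments[virus_alignments$is_mate, , drop = FALSE]
  vfam <- function(qnames, set) {
    i <- match(qnames, set$qname)
    collapse_family(set$rname[i], families)
  }
  keep_q <- host_alignments$mapq >= min_mapq
  is_sc <- keep_q & clip > min_clip & host_alignments$qname %in% partial$qname
  is_am <- keep_q & !is_sc & host_alignments$qname %in% mates$qname
  n_skipped <- sum(keep_q & !is_sc & !is_am &
                     !host_alignments$qname %in% virus_alignments$qname)
  if (n_skipped > 0)
    warning(n_skipped, " host record(s) without viral alignment skipped")
  sc <- host_alignments[is_sc, , drop = FALSE]
  am <- host_alignments[is_am, , drop = FALSE]
  out <- rbind(
    if (nrow(sc)) {
      f <- vfam(sc$qname, partial)
      data.frame(read_id = sc$qname, evidence_class = "softclip",
                 family = f$family, substrain = f$substrain,
                 host_contig = sc$rname, host_pos0 = pos0[is_sc],
                 terminus0 = terminus0[is_sc], clip_length = clip[is_sc],
                 mapq = sc$mapq, stringsAsFactors = FALSE)
    } else NULL,
    if (nrow(am)) {
      f <- vfam(am$qname, mates)
      data.frame(read_id = am$qname, evidence_class = "anchored_mate",
                 family = f$family, substrain = f$substrain,
                 host_contig = am$rname, host_pos0 = pos0[is_am],
                 terminus0 = NA_integer_, clip_length = NA_integer_,
                 mapq = am$mapq, stringsAsFactors = FALSE)
    } else NULL)
  if (is.null(out)) empty else out
}

#' Cluster integration evidence by single-linkage position chaining
#'
#' Within each (family, contig), evidence positions are sorted and chained:
#' consecutive positions at most `gap` apart join the same cluster, where
#' the gap is family specific (500 bp for KoRV, 9 kbp for older lineages).
#' Clusters supported by fewer than `min_reads` pooled evidence reads
#' (anchored mates and soft-clips both count) are discarded.
#'
#' @param evidence Output of [extract_evidence()].
#' @param min_reads Minimum pooled reads per cluster (inclusive >=).
#' @param gap_by_family Named numeric of chaining gaps; a "default" entry
#'   covers unlisted families.
#' @return data.frame of clusters with a `member_idx` list column holding
#'   row indices into `evidence`.
#' @export
cluster_evidence <- function(evidence, min_reads = 20L,
                             gap_by_family = c(KoRV = 500, default = 9000)) {
  empty <- data.frame(cluster_id = character(0), family = character(0),
                      contig = character(0), min_pos0 = integer(0),
                      max_pos0 = integer(0), n_reads = integer(0),
                      stringsAsFactors = FALSE)
  empty$member_idx <- list()
  if (is.null(evidence) || nrow(evidence) == 0L) return(empty)
  out <- list()
  for (key in unique(paste(evidence$family, evidence$host_contig, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    fam <- parts[1]; ct <- parts[2]
    idx <- which(evidence$family == fam & evidence$host_contig == ct)
    idx <- idx[order(evidence$host_pos0[idx])]
    pos <- evidence$host_pos0[idx]
    gap <- if (fam %in% names(gap_by_family)) gap_by_family[[fam]] else
      gap_by_family[["default"]] %||% 9000
    brk <- c(0L, which(diff(pos) > gap), length(pos))
    for (k in seq_len(length(brk) - 1L)) {
      mem <- idx[(brk[k] + 1L):brk[k + 1L]]
      if (length(mem) < min_reads) next
      out[[length(out) + 1L]] <- data.frame(
        cluster_id = sprintf("%s:%s:%d", fam, ct, min(evidence$host_pos0[mem])),
        family = fam, contig = ct,
        min_pos0 = min(evidence$host_pos0[mem]),
        max_pos0 = max(evidence$host_pos0[mem]),
        n_reads = length(mem), stringsAsFactors = FALSE)
      out[[length(out)]]$member_idx <- list(mem)
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res[order(res$family, res$contig, res$min_pos0), , drop = FALSE]
}

#' Resolve a cluster to an integration site
#'
#' If the cluster overlaps a known-ERV interval of the reference annotation
#' the site is reported as known with the annotated start/end. Otherwise
#' the site is novel with a single exact breakpoint: the modal soft-clip
#' terminus among cluster members (ties broken toward the smaller
#' coordinate). A cluster with no soft-clip evidence gets the cluster
#' midpoint and a low-confidence flag.
#'
#' @param cluster One row of [cluster_evidence()] output.
#' @param evidence The evidence table the cluster indexes into.
#' @param known_intervals Optional data.frame(contig, start0, end0, ...) of
#'   annotated ERV intervals (0-based half-open).
#' @return One-row data.frame: site_id, family, contig, novel_flag,
#'   breakpoint0, start0, end0, support, low_confidence.
#' @export
resolve_breakpoint <- function(cluster, evidence, known_intervals = NULL) {
  stopifnot(nrow(cluster) == 1L)
  mem <- evidence[cluster$member_idx[[1L]], , drop = FALSE]
  if (nrow(mem) == 0L) stop("cluster has no members", call. = FALSE)
  if (!is.null(known_intervals) && nrow(known_intervals)) {
    ki <- known_intervals[known_intervals$contig == cluster$contig, ,
                          drop = FALSE]
    if ("family" %in% names(ki))
      ki <- ki[ki$family == cluster$family, , drop = FALSE]
    hit <- which(ki$start0 <= cluster$max_pos0 & ki$end0 > cluster$min_pos0)
    if (length(hit)) {
      hit <- hit[1L]
      return(data.frame(
        site_id = sprintf("%s:%s:%d", cluster$family, cluster$contig,
                          ki$start0[hit]),
        family = cluster$family, contig = cluster$contig, novel_flag = FALSE,
        breakpoint0 = NA_integer_, start0 = ki$start0[hit],
        end0 = ki$end0[hit], support = cluster$n_reads,
        cluster_min0 = cluster$min_pos0, cluster_max0 = cluster$max_pos0,
        low_confidence = FALSE, stringsAsFactors = FALSE))
    }
  }
  term <- mem$terminus0[mem$evidence_class == "softclip"]
  term <- term[!is.na(term)]
  if (length(term)) {
    tab <- table(term)
    bp <- min(as.integer(names(tab)[tab == max(tab)]))
    low <- FALSE
  } else {
    bp <- as.integer(floor((cluster$min_pos0 + cluster$max_pos0) / 2))
    low <- TRUE
  }
  data.frame(site_id = sprintf("%s:%s:%d", cluster$family, cluster$contig, bp),
             family = cluster$family, contig = cluster$contig,
             novel_flag = TRUE, breakpoint0 = bp, start0 = bp,
             end0 = bp + 1L, support = cluster$n_reads,
             cluster_min0 = cluster$min_pos0, cluster_max0 = cluster$max_pos0,
             low_confidence = low, stringsAsFactors = FALSE)
}

#' Discover integration sites for one individual
#'
#' Convenience wrapper: evidence extraction, family-aware clustering and
#' breakpoint resolution.
#'
#' @inheritParams extract_evidence
#' @inheritParams cluster_evidence
#' @param known_intervals See [resolve_breakpoint()].
#' @return data.frame of integration sites.
#' @export
discover_sites <- function(virus_alignments, host_alignments, families,
                           known_intervals = NULL, min_clip = 20L,
                           min_mapq = 30L, min_reads = 20L,
                           gap_by_family = NULL) {
  if (is.null(gap_by_family)) {
    gap_by_family <- vapply(families, `[[`, 1L, "cluster_gap")
    names(gap_by_family) <- vapply(families, `[[`, "", "name")
  }
  ev <- extract_evidence(virus_alignments, host_alignments, families,
                         min_clip = min_clip, min_mapq = min_mapq)
  cl <- cluster_evidence(ev, min_reads = min_reads,
                         gap_by_family = gap_by_family)
  if (nrow(cl) == 0L)
    return(data.frame(site_id = character(0), family = character(0),
                      contig = character(0), novel_flag = logical(0),
                      breakpoint0 = integer(0), start0 = integer(0),
                      end0 = integer(0), support = integer(0),
                      low_confidence = logical(0), stringsAsFactors = FALSE))
  do.call(rbind, lapply(seq_len(nrow(cl)), function(i)
    resolve_breakpoint(cl[i, , drop = FALSE], ev, known_intervals)))
}

#' Merge per-individual site lists into a shared registry
#'
#' Sites of the same family whose intervals overlap are collapsed into one
#' registry entry carrying all contributing individuals; entries are
#' maximal under transitive closure of pairwise overlap. Intervals are
#' 0-based half-open, so abutting intervals do not merge.
#'
#' @param site_tables data.frame of per-individual sites (as returned by
#'   [discover_sites()]) with an `individual` column.
#' @return list(registry, carriers): the shared site registry and the
#'   site-to-carrier mapping.
#' @export
merge_sites_across_individuals <- function(site_tables) {
  stopifnot("individual" %in% names(site_tables))
  if (nrow(site_tables) == 0L)
    return(list(registry = data.frame(), carriers = data.frame()))
  st <- site_tables
  # Sites are shared when their cluster locations overlap; novel sites fall
  # back to their point breakpoint when no cluster extent is available.
  if (all(c("cluster_min0", "cluster_max0") %in% names(st))) {
    st$.start0 <- ifelse(st$novel_flag, st$cluster_min0, st$start0)
    st$.end0 <- ifelse(st$novel_flag, st$cluster_max0 + 1L, st$end0)
  } else {
    st$.start0 <- ifelse(st$novel_flag, st$breakpoint0, st$start0)
    st$.end0 <- ifelse(st$novel_flag, st$breakpoint0 + 1L, st$end0)
  }
  reg <- list(); car <- list()
  for (key in unique(paste(st$family, st$contig, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    sub <- st[st$family == parts[1] & st$contig == parts[2], , drop = FALSE]
    ir <- IRanges::IRanges(start = sub$.start0 + 1L, end = sub$.end0)
    red <- IRanges::reduce(ir, min.gapwidth = 0L)
    hits <- IRanges::findOverlaps(ir, red)
    grp <- S4Vectors::subjectHits(hits)[order(S4Vectors::queryHits(hits))]
    for (k in seq_along(red)) {
      members <- sub[grp == k, , drop = FALSE]
      s0 <- IRanges::start(red)[k] - 1L
      e0 <- IRanges::end(red)[k]
      bp_vals <- members$breakpoint0[!is.na(members$breakpoint0)]
      bp <- if (length(bp_vals)) {
        tb <- table(bp_vals)
        min(as.integer(names(tb)[tb == max(tb)]))
      } else NA_integer_
      reg[[length(reg) + 1L]] <- data.frame(
        site_id = sprintf("%s:%s:%d", parts[1], parts[2], s0),
        family = parts[1], contig = parts[2], start0 = s0, end0 = e0,
        breakpoint0 = bp, novel_flag = all(members$novel_flag),
        support = sum(members$support),
        n_carriers = length(unique(members$individual)),
        stringsAsFactors = FALSE)
      car[[length(car) + 1L]] <- data.frame(
        site_id = reg[[length(reg)]]$site_id,
        individual = unique(members$individual), stringsAsFactors = FALSE)
    }
  }
  registry <- do.call(rbind, reg)
  registry <- registry[order(registry$family, registry$contig,
                             registry$start0), , drop = FALSE]
  rownames(registry) <- NULL
  list(registry = registry, carriers = do.call(rbind, car))
}
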