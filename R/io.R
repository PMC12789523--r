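#' Read and validate a pedigree table
#'
#' Expects a TSV with header columns id, sire, dam, sex, birth_year,
#' vital_status, cause_of_death (empty sire/dam marks a founder). Validates
#' id uniqueness and acyclicity of the sire/dam graph.
#'
#' @param path TSV path.
#' @return An `erv_pedigree` data.frame.
#' @export
read_pedigree <- function(path) {
  ped <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character", na.strings = c("", "NA"))
  need <- c("id", "sire", "dam")
  if (!all(need %in% names(ped)))
    stop("pedigree must have columns id, sire, dam", call. = FALSE)
  if ("birth_year" %in% names(ped))
    ped$birth_year <- as.integer(ped$birth_year)
  validate_pedigree(ped)
  structure(ped, class = c("erv_pedigree", "data.frame"))
}

validate_pedigree <- function(ped) {
  dup <- ped$id[duplicated(ped$id)]
  if (length(dup))
    stop("duplicate id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  # Kahn-style peeling: anything left over sits on a parentage cycle
  depth <- pedigree_depths(ped)
  cyc <- ped$id[is.na(depth)]
  if (length(cyc))
    stop("cyclic parentage involving: ", paste(cyc, collapse = ", "),
         call. = FALSE)
  invisible(ped)
}

pedigree_depths <- function(ped) {
  depth <- stats::setNames(rep(NA_integer_, nrow(ped)), ped$id)
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(ped))) {
      if (!is.na(depth[i])) next
      pd <- c(if (!is.na(ped$sire[i]) && ped$sire[i] %in% ped$id)
        depth[ped$sire[i]] else 0L,
        if (!is.na(ped$dam[i]) && ped$dam[i] %in% ped$id)
          depth[ped$dam[i]] else 0L)
      if (anyNA(pd)) next
      depth[i] <- max(pd) + 1L
      changed <- TRUE
    }
    if (!changed) break
  }
  depth
}

#' Generation depth of a pedigree
#'
#' Founders have depth 1; each offspring is one deeper than its deepest
#' parent. A four-generation pedigree has depth 4.
#'
#' @param pedigree An `erv_pedigree`.
#' @return Integer depth.
#' @export
pedigree_depth <- function(pedigree) {
  max(pedigree_depths(pedigree), na.rm = TRUE)
}

#' @rdname read_pedigree
#' @param pedigree Pedigree to write.
#' @param path Output TSV path.
#' @export
write_pedigree <- function(pedigree, path) {
  cols <- intersect(c("id", "sire", "dam", "sex", "birth_year",
                      "vital_status", "cause_of_death"), names(pedigree))
  utils::write.table(as.data.frame(pedigree)[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

family_alt_id <- function(family) {
  toupper(gsub("[^A-Za-z0-9]", "", family))
}

#' Write the site registry and genotype matrix as VCF 4.2
#'
#' Sites become symbolic mobile-element insertion records
#' (`<INS:ME:KORV>` etc.) with INFO keys FAM, SUPPORT, NOVEL and END for
#' known reference-carried integrations; genotypes are encoded 0/0, 0/1,
#' 1/1 with undetermined calls as `./.`. Internal 0-based breakpoints are
#' converted to 1-based POS at this boundary.
#'
#' @param registry Site registry (see [merge_sites_across_individuals()]).
#' @param matrix Genotype matrix whose columns match `registry$site_id`.
#' @param path Output path.
#' @param contig_lengths Named contig lengths for the header.
#' @return The path, invisibly.
#' @export
write_sites_vcf <- function(registry, matrix, path, contig_lengths = NULL) {
  stopifnot(identical(colnames(matrix), registry$site_id))
  if (!is.null(contig_lengths)) {
    bad <- registry$end0 > contig_lengths[registry$contig]
    if (any(bad))
      stop("site coordinates outside reference: ",
           paste(registry$site_id[bad], collapse = ", "), call. = FALSE)
  }
  hdr <- c("##fileformat=VCFv4.2",
           if (!is.null(contig_lengths))
             sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
                     as.integer(contig_lengths)),
           sprintf("##ALT=<ID=INS:ME:%s,Description=\"%s integration\">",
                   unique(family_alt_id(registry$family)),
                   unique(registry$family)),
           "##INFO=<ID=FAM,Number=1,Type=String,Description=\"ERV family\">",
           "##INFO=<ID=SUPPORT,Number=1,Type=Integer,Description=\"Supporting reads\">",
           "##INFO=<ID=NOVEL,Number=1,Type=Integer,Description=\"1 if absent from the reference assembly\">",
           "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End of known integration (1-based inclusive)\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", rownames(matrix)), collapse = "\t"))
  gt_map <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1", `-1` = "./.")
  pos1 <- ifelse(registry$novel_flag, registry$breakpoint0 + 1L,
                 registry$start0 + 1L)
  info <- sprintf("FAM=%s;SUPPORT=%d;NOVEL=%d", registry$family,
                  as.integer(registry$support),
                  as.integer(registry$novel_flag))
  info <- ifelse(registry$novel_flag, info,
                 paste0(info, sprintf(";END=%d", registry$end0)))
  body <- vapply(seq_len(nrow(registry)), function(i) {
    paste(c(registry$contig[i], pos1[i], registry$site_id[i], "N",
            sprintf("<INS:ME:%s>", family_alt_id(registry$family[i])),
            ".", "PASS", info[i], "GT",
            unname(gt_map[as.character(matrix[, i])])), collapse = "\t")
  }, "")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_sites_vcf
#' @export
read_sites_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "##")]
  header <- strsplit(body[1L], "\t", fixed = TRUE)[[1]]
  inds <- header[-(1:9)]
  rows <- strsplit(body[-1L], "\t", fixed = TRUE)
  get_info <- function(info, key) {
    m <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]*"), info))
    if (!length(m)) NA_character_ else sub(paste0(".*", key, "="), "", m)
  }
  gt_map <- c("0/0" = 0L, "0/1" = 1L, "1/1" = 2L, "./." = -1L)
  registry <- do.call(rbind, lapply(rows, function(r) {
    info <- r[8L]
    novel <- get_info(info, "NOVEL") == "1"
    pos0 <- as.integer(r[2L]) - 1L
    end0 <- if (novel) pos0 + 1L else as.integer(get_info(info, "END"))
    data.frame(site_id = r[3L], family = get_info(info, "FAM"),
               contig = r[1L], start0 = pos0, end0 = end0,
               breakpoint0 = if (novel) pos0 else NA_integer_,
               novel_flag = novel,
               support = as.integer(get_info(info, "SUPPORT")),
               stringsAsFactors = FALSE)
  }))
  gm <- vapply(rows, function(r) unname(gt_map[r[-(1:9)]]),
               integer(length(inds)))
  m <- matrix(as.integer(gm), nrow = length(inds),
              dimnames = list(inds, registry$site_id))
  list(registry = registry, matrix = m)
}

#' Write SAM-like alignment records
#'
#' @param records data.frame(qname, flag, rname, pos, mapq, cigar, rnext,
#'   pnext, tlen, seq).
#' @param path Output SAM path.
#' @param contig_lengths Named lengths for the `@SQ` header lines.
#' @return The path, invisibly.
#' @export
write_sam <- function(records, path, contig_lengths) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contig_lengths),
                   as.integer(contig_lengths)))
  qual <- "*"
  body <- if (nrow(records)) {
    seqs <- if ("seq" %in% names(records)) records$seq else "*"
    paste(records$qname, records$flag, records$rname, records$pos,
          records$mapq, records$cigar, records$rnext, records$pnext,
          records$tlen, seqs, qual, sep = "\t")
  } else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_sam
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines))
    return(data.frame(qname = character(0), flag = integer(0),
                      rname = character(0), pos = integer(0),
                      mapq = integer(0), cigar = character(0),
                      rnext = character(0), pnext = integer(0),
                      tlen = integer(0), seq = character(0),
                      stringsAsFactors = FALSE))
  f <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(qname = vapply(f, `[[`, "", 1L),
             flag = as.integer(vapply(f, `[[`, "", 2L)),
             rname = vapply(f, `[[`, "", 3L),
             pos = as.integer(vapply(f, `[[`, "", 4L)),
             mapq = as.integer(vapply(f, `[[`, "", 5L)),
             cigar = vapply(f, `[[`, "", 6L),
             rnext = vapply(f, `[[`, "", 7L),
             pnext = as.integer(vapply(f, `[[`, "", 8L)),
             tlen = as.integer(vapply(f, `[[`, "", 9L)),
             seq = vapply(f, `[[`, "", 10L), stringsAsFactors = FALSE)
}

#' Known-ERV interval BED I/O (0-based half-open)
#'
#' @param intervals data.frame(contig, start0, end0, site_id, family).
#' @param path BED path.
#' @return The path / the interval data.frame.
#' @export
write_known_erv_bed <- function(intervals, path) {
  gr <- GenomicRanges::GRanges(
    intervals$contig,
    IRanges::IRanges(start = intervals$start0 + 1L, end = intervals$end0),
    name = if ("site_id" %in% names(intervals)) intervals$site_id else ".")
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname write_known_erv_bed
#' @export
read_known_erv_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
             start0 = IRanges::start(gr) - 1L, end0 = IRanges::end(gr),
             site_id = if (!is.null(gr$name)) gr$name else NA_character_,
             stringsAsFactors = FALSE)
}

#' Write reference or viral sequences as FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_reference_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
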