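fams <- list(korv_family(), phacinb_family(), phacinb_like_family())

test_that("viral hits collapse to family labels with sub-strain tallies", {
  hit <- collapse_family("KoRV-B", fams)
  expect_equal(hit$family, "KoRV")
  expect_equal(hit$substrain, "KoRV-B")
  expect_equal(collapse_family("phaCin-beta", fams)$family, "phaCin-beta")
  expect_error(collapse_family("HERV-K", fams), "KoRV-A")

  tab <- collapse_family(rep(c("KoRV-A", "KoRV-B"), c(982, 18)), fams)
  expect_true(all(tab$family == "KoRV"))
  expect_equal(mean(tab$substrain == "KoRV-A") * 100, 98.2)
})

test_that("evidence extraction enforces clip and mapq thresholds", {
  host <- data.frame(
    qname = c("lowq", "clip20", "clip21", "mate1", "orphan"),
    rname = "c1", pos = c(100L, 200L, 300L, 400L, 500L),
    mapq = c(29L, 60L, 60L, 60L, 60L),
    cigar = c("100M50S", "130M20S", "129M21S", "150M", "150M"),
    stringsAsFactors = FALSE)
  virus <- data.frame(
    qname = c("lowq", "clip20", "clip21", "mate1"),
    rname = "KoRV-A", mapq = 60L, cigar = "50M",
    is_mate = c(FALSE, FALSE, FALSE, TRUE), stringsAsFactors = FALSE)
  expect_warning(ev <- extract_evidence(virus, host, fams), "skipped")
  expect_false("lowq" %in% ev$read_id)          # mapq 29 excluded
  expect_false("clip20" %in% ev$read_id)        # exactly 20 bp is excluded
  expect_equal(ev$evidence_class[ev$read_id == "clip21"], "softclip")
  expect_equal(ev$clip_length[ev$read_id == "clip21"], 21L)
  expect_equal(ev$terminus0[ev$read_id == "clip21"], 299L + 129L)
  expect_equal(ev$evidence_class[ev$read_id == "mate1"], "anchored_mate")
})

test_that("every carried truth site leaves evidence at 30x", {
  cfg <- fixed_aaf_config(seed = 13, aaf = 0.5, n_sites = 8L)
  co <- generate_cohort(cfg, 16, 1)
  n_checked <- 0L
  for (id in co$pedigree$id) {
    rec <- emit_alignment_records(co, id, "short_read")
    ev <- extract_evidence(rec$virus, rec$host, cfg$families)
    carried <- co$sites[co$genotypes[id, co$sites$site_id] > 0, ]
    for (i in seq_len(nrow(carried))) {
      near <- ev$host_contig == carried$contig[i] &
        abs(ev$host_pos0 - carried$position0[i]) <= 600
      expect_gte(sum(near), 1L)
      n_checked <- n_checked + 1L
    }
  }
  expect_gte(n_checked, 50L)   # recall checked over at least 50 site calls
})

test_that("clustering honours the 20-read floor and family gaps", {
  expect_equal(nrow(cluster_evidence(evidence_df(rep(1000, 19)))), 0L)
  expect_equal(nrow(cluster_evidence(evidence_df(rep(1000, 20)))), 1L)
  expect_equal(nrow(cluster_evidence(evidence_df(numeric(0)))), 0L)

  # hand-traced chaining oracle: nearest inter-read gap 681
  pos <- c(1000:1019, 1700:1719)
  korv <- cluster_evidence(evidence_df(pos, family = "KoRV"))
  expect_equal(nrow(korv), 2L)
  phac <- cluster_evidence(evidence_df(pos, family = "phaCin-beta"))
  expect_equal(nrow(phac), 1L)
  expect_equal(phac$n_reads, 40L)
})

test_that("chaining equals the brute-force union-find oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    pos <- sort(sample.int(20000L, 150L))
    gap <- sample(c(120L, 500L, 2000L), 1L)
    got <- cluster_evidence(evidence_df(pos), min_reads = 1L,
                            gap_by_family = c(KoRV = gap))
    oracle <- brute_force_clusters(pos, gap)
    got_sets <- lapply(got$member_idx, function(ix) sort(pos[ix]))
    oracle_sets <- lapply(oracle, sort)
    expect_equal(length(got_sets), length(oracle_sets))
    key <- function(s) paste(s, collapse = ",")
    expect_setequal(vapply(got_sets, key, ""), vapply(oracle_sets, key, ""))
  }
})

test_that("raising min_reads or widening the gap never adds clusters", {
  for (seed in 6:9) {
    set.seed(seed)
    pos <- sample.int(30000L, 400L, replace = TRUE)
    base <- nrow(cluster_evidence(evidence_df(pos), min_reads = 5L,
                                  gap_by_family = c(KoRV = 300)))
    stricter <- nrow(cluster_evidence(evidence_df(pos), min_reads = 10L,
                                      gap_by_family = c(KoRV = 300)))
    wider <- nrow(cluster_evidence(evidence_df(pos), min_reads = 5L,
                                   gap_by_family = c(KoRV = 900)))
    expect_lte(stricter, base)
    expect_lte(wider, base)
  }
})

test_that("breakpoints resolve by modal terminus with deterministic ties", {
  mk_cluster <- function(term) {
    ev <- evidence_df(term)
    cl <- cluster_evidence(ev, min_reads = 1L)
    list(ev = ev, cl = cl)
  }
  x <- mk_cluster(rep(c(5000L, 5001L), c(12L, 3L)))
  expect_equal(resolve_breakpoint(x$cl, x$ev)$breakpoint0, 5000L)

  y <- mk_cluster(rep(c(5000L, 5010L), c(7L, 7L)))
  expect_equal(resolve_breakpoint(y$cl, y$ev)$breakpoint0, 5000L)

  known <- data.frame(contig = "c1", start0 = 8000L, end0 = 16000L,
                      family = "KoRV", stringsAsFactors = FALSE)
  z <- mk_cluster(rep(8500L, 25L))
  site <- resolve_breakpoint(z$cl, z$ev, known)
  expect_false(site$novel_flag)
  expect_equal(c(site$start0, site$end0), c(8000L, 16000L))

  # no soft-clip votes: midpoint with a low-confidence flag
  ev <- evidence_df(c(1000L, 1100L), class = "anchored_mate")
  ev$terminus0 <- NA_integer_
  cl <- cluster_evidence(ev, min_reads = 1L)
  site <- resolve_breakpoint(cl, ev)
  expect_true(site$low_confidence)
  expect_equal(site$breakpoint0, 1050L)
})

test_that("site merging is overlap-based, half-open, and transitive", {
  mk <- function(ind, s, e) data.frame(
    individual = ind, family = "KoRV", contig = "c1", novel_flag = FALSE,
    breakpoint0 = NA_integer_, start0 = s, end0 = e, support = 25L,
    stringsAsFactors = FALSE)
  two <- merge_sites_across_individuals(rbind(mk("A", 100L, 200L),
                                              mk("B", 150L, 250L)))
  expect_equal(nrow(two$registry), 1L)
  expect_setequal(two$carriers$individual, c("A", "B"))

  adj <- merge_sites_across_individuals(rbind(mk("A", 100L, 200L),
                                              mk("B", 200L, 300L)))
  expect_equal(nrow(adj$registry), 2L)

  chain <- merge_sites_across_individuals(rbind(mk("A", 100L, 200L),
                                                mk("B", 150L, 250L),
                                                mk("C", 240L, 400L)))
  expect_equal(nrow(chain$registry), 1L)
  expect_setequal(chain$carriers$individual, c("A", "B", "C"))
})
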