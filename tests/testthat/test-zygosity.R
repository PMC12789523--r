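test_that("read tallies respect the TSD margin arithmetic", {
  p <- 5000L
  site <- list(contig = "c1", position0 = p)
  aln <- function(pos, cigar) data.frame(rname = "c1", pos = pos,
                                         cigar = cigar,
                                         stringsAsFactors = FALSE)
  # unclipped read spanning [p-50, p+50]
  t1 <- tally_site_reads(aln(p - 50L + 1L, "101M"), site)
  expect_equal(t1, list(n_softclip = 0L, n_crossing = 1L))
  # clip terminus at p+10: inside the inclusive margin
  t2 <- tally_site_reads(aln(p - 40L + 1L, "50M30S"), site)
  expect_equal(t2$n_softclip, 1L)
  # unclipped read whose alignment ends at p+11 (half-open): neither class
  t3 <- tally_site_reads(aln(p - 90L + 1L, "101M"), site)
  expect_equal(t3, list(n_softclip = 0L, n_crossing = 0L))
  expect_error(
    tally_site_reads(aln(1L, "101M"), list(contig = "c1", position0 = 999999L),
                     contig_lengths = c(c1 = 10000L)),
    "outside")
})

test_that("novel-site genotype calls follow the 30-70% read-ratio rule", {
  expect_equal(call_genotype_novel(make_tally(20L, 20L)), 1L)
  expect_equal(call_genotype_novel(make_tally(29L, 11L)), 2L)   # f = 0.725
  expect_equal(call_genotype_novel(make_tally(28L, 12L)), 1L)   # f = 0.70
  expect_equal(call_genotype_novel(make_tally(11L, 29L)), -1L)  # f = 0.275
  expect_equal(call_genotype_novel(make_tally(12L, 28L)), 1L)   # f = 0.30
  expect_equal(call_genotype_novel(make_tally(0L, 0L)), -1L)
})

test_that("known-site calls use the mean crossing fraction over breakpoints", {
  expect_equal(call_genotype_known(make_tally(0L, 30L), make_tally(0L, 25L)),
               2L)
  expect_equal(call_genotype_known(make_tally(15L, 15L), make_tally(20L, 20L)),
               1L)
  expect_equal(call_genotype_known(make_tally(30L, 70L), make_tally(30L, 70L)),
               1L)                                   # g = 0.70 inclusive edge
  expect_equal(call_genotype_known(make_tally(0L, 0L), make_tally(15L, 25L)),
               1L)                                   # one empty: use other
  expect_equal(call_genotype_known(make_tally(0L, 0L), make_tally(0L, 0L)),
               -1L)
})

test_that("population matrix applies the absence and consensus rules", {
  reg <- data.frame(site_id = c("s1", "s2"), stringsAsFactors = FALSE)
  calls <- data.frame(
    individual = c("A", "A", "B", "B", "B"),
    site_id = c("s1", "s2", "s1", "s1", "s1"),
    call = c(1L, 2L, 1L, 2L, 1L), stringsAsFactors = FALSE)
  m <- build_population_matrix(calls, reg, c("A", "B", "C"))
  expect_equal(m["A", "s1"], 1L)
  expect_equal(m["B", "s1"], -1L)      # replicates disagree -> undetermined
  expect_equal(m["C", "s1"], 0L)       # never detected -> hom ref
  agree <- data.frame(individual = "A", site_id = "s1",
                      call = c(1L, 1L, 1L), stringsAsFactors = FALSE)
  expect_equal(build_population_matrix(agree, reg, "A")["A", "s1"], 1L)
  expect_error(build_population_matrix(calls, reg, c("A", "A")), "duplicate")
})

test_that("site QC computes AAF, undetermined fraction and Mendelian errors", {
  m <- matrix(c(rep(0L, 8), 1L, 1L), ncol = 1,
              dimnames = list(paste0("i", 1:10), "s1"))
  qc <- site_qc(m, ped_df(paste0("i", 1:10)))
  expect_equal(qc$site$aaf, 0.1)
  expect_equal(qc$site$undetermined_fraction, 0)

  ped <- ped_df(c("p1", "p2", "kid"), sire = c(NA, NA, "p1"),
                dam = c(NA, NA, "p2"))
  m2 <- matrix(c(0L, 0L, 2L), ncol = 1,
               dimnames = list(c("p1", "p2", "kid"), "s1"))
  qc2 <- site_qc(m2, ped)
  expect_equal(qc2$site$mendel_error_rate, 1)
  expect_equal(qc2$animal$mendel_error_rate[qc2$animal$id == "kid"], 1)

  # noise-free simulated cohort (no de novo events): zero Mendelian error
  co <- generate_cohort(small_config(
    seed = 8, denovo_integration_rate = c(KoRV = 0)), 8, 2)
  qc3 <- site_qc(co$genotypes, co$pedigree)
  expect_true(all(qc3$animal$mendel_error_rate == 0, na.rm = TRUE))
  expect_true(all(qc3$site$aaf >= 0 & qc3$site$aaf <= 1, na.rm = TRUE))
})

test_that("site filters are boundary-inclusive and idempotent", {
  m <- matrix(c(0L, 0L, 0L, 0L, 0L,      # AAF 0 -> dropped
                1L, 0L, 0L, 0L, 0L,      # kept
                1L, -1L, 0L, 0L, 0L,     # undet 0.2 > 0.1 -> dropped
                1L, 1L, 1L, 1L, 1L), ncol = 4,
              dimnames = list(paste0("i", 1:5), paste0("s", 1:4)))
  qc <- site_qc(m, ped_df(paste0("i", 1:5)))
  f <- apply_site_filters(m, qc)
  expect_setequal(colnames(f), c("s2", "s4"))
  expect_identical(apply_site_filters(f, site_qc(f, ped_df(paste0("i", 1:5)))),
                   f)

  # undetermined fraction exactly 0.1 is retained (<=)
  m10 <- matrix(c(-1L, rep(1L, 9)), ncol = 1,
                dimnames = list(paste0("i", 1:10), "s1"))
  qc10 <- site_qc(m10, ped_df(paste0("i", 1:10)))
  expect_equal(ncol(apply_site_filters(m10, qc10)), 1L)
})

test_that("miss_probability matches exhaustive enumeration for c <= 20", {
  for (cv in 1:20)
    expect_equal(miss_probability(cv), enumerate_miss(cv), tolerance = 1e-12)
  expect_equal(miss_probability(1), 1)
  expect_equal(miss_probability(0), 1)
  expect_equal(round(miss_probability(40), 5), 0.00643)
  expect_equal(miss_probability(10), 0.109375)
})

test_that("genotype-call confusion matches the binomial model at 40x", {
  tal <- simulate_site_evidence(rep(1L, 1e5), 40L, seed = 23)
  calls <- ifelse(tal$n_softclip / 40 > 0.7, 2L,
                  ifelse(tal$n_softclip / 40 >= 0.3, 1L, -1L))
  miss_freq <- mean(calls != 1L)
  p <- miss_probability(40)
  se <- sqrt(p * (1 - p) / 1e5)
  expect_lt(abs(miss_freq - p), 3 * se)
})

test_that("VCF round-trip reproduces the genotype matrix exactly", {
  set.seed(4)
  n_ind <- 20L; n_site <- 50L
  reg <- data.frame(
    site_id = sprintf("KoRV:c1:%d", seq_len(n_site) * 100L),
    family = "KoRV", contig = "c1", start0 = seq_len(n_site) * 100L,
    end0 = seq_len(n_site) * 100L + 1L,
    breakpoint0 = seq_len(n_site) * 100L,
    novel_flag = rep(c(TRUE, FALSE), length.out = n_site),
    support = 30L, stringsAsFactors = FALSE)
  reg$end0[!reg$novel_flag] <- reg$start0[!reg$novel_flag] + 50L
  m <- matrix(sample(c(-1L, 0L, 1L, 2L), n_ind * n_site, replace = TRUE),
              n_ind, n_site, dimnames = list(sprintf("SB%03d", seq_len(n_ind)),
                                             reg$site_id))
  path <- tempfile(fileext = ".vcf")
  write_sites_vcf(reg, m, path, contig_lengths = c(c1 = 100000L))
  back <- read_sites_vcf(path)
  expect_identical(back$matrix, m)
  expect_equal(back$registry$site_id, reg$site_id)
  expect_equal(back$registry$novel_flag, reg$novel_flag)
  expect_equal(back$registry$end0, reg$end0)
})
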