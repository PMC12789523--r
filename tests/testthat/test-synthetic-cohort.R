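test_that("config validation rejects impossible worlds", {
  expect_error(sim_config(denovo_integration_rate = c(KoRV = -1)), "rates")
  expect_error(sim_config(contig_length = 1000L, read_length = 150L),
               "contig_length")
  expect_error(family_model("x", ltr_length = 10L), "ltr_length")
  expect_error(generate_cohort(small_config(), 0, 1), "empty pedigree")
})

test_that("degenerate founder frequencies give the expected fixed cohorts", {
  co0 <- generate_cohort(fixed_aaf_config(aaf = 0), 6, 2)
  expect_true(all(co0$genotypes == 0L))
  expect_equal(nrow(co0$denovo), 0L)

  co1 <- generate_cohort(fixed_aaf_config(aaf = 1), 6, 2)
  expect_true(all(co1$genotypes == 2L))
  qc <- site_qc(co1$genotypes, co1$pedigree)
  expect_true(all(qc$site$aaf == 1))
})

test_that("transmission from het x hom-ref parents is Binomial(1, 0.5)", {
  set.seed(11)
  off <- ervtrace:::mendelian_transmit(rep(1L, 10000), rep(0L, 10000))
  frac <- mean(off)            # transmitted-allele fraction
  se <- sqrt(0.25 / 10000)
  expect_lt(abs(frac - 0.5), 3 * se)
  expect_true(all(off %in% 0:1))
})

test_that("identical config yields identical truth tables and records", {
  a <- generate_cohort(small_config(seed = 5), 6, 2)
  b <- generate_cohort(small_config(seed = 5), 6, 2)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$sites, b$sites)
  expect_identical(a$pedigree, b$pedigree)
  expect_identical(a$denovo, b$denovo)
  ra <- emit_alignment_records(a, a$pedigree$id[1], "short_read")
  rb <- emit_alignment_records(b, b$pedigree$id[1], "short_read")
  expect_identical(ra, rb)
})

test_that("truth genotypes are Mendelian-consistent when de novo rate is 0", {
  cfg <- small_config(seed = 3,
                      denovo_integration_rate = c(KoRV = 0))
  co <- generate_cohort(cfg, 8, 3)
  G <- co$genotypes
  ped <- co$pedigree
  kids <- ped[!is.na(ped$sire), ]
  for (i in seq_len(nrow(kids))) {
    gs <- G[kids$sire[i], ]; gd <- G[kids$dam[i], ]; gc <- G[kids$id[i], ]
    mn <- (gs == 2L) + (gd == 2L)
    mx <- (gs >= 1L) + (gd >= 1L)
    expect_true(all(gc >= mn & gc <= mx),
                info = paste("offspring", kids$id[i]))
  }
})

test_that("site evidence tallies follow the binomial read model", {
  expect_equal(simulate_site_evidence(0L, 40L, noise = 0, seed = 1),
               data.frame(n_softclip = 0L, n_crossing = 40L))
  expect_equal(simulate_site_evidence(2L, 40L, noise = 0, seed = 1),
               data.frame(n_softclip = 40L, n_crossing = 0L))
  tal <- simulate_site_evidence(rep(1L, 1e5), 40L, seed = 7)
  expect_lt(abs(mean(tal$n_softclip / 40) - 0.5), 0.005)
})

test_that("het soft-clip counts pass a chi-square GOF vs Binomial(c, 0.5)", {
  cv <- 20L
  draws <- simulate_site_evidence(rep(1L, 2e4), cv, seed = 19)$n_softclip
  obs <- tabulate(draws + 1L, nbins = cv + 1L)
  p <- dbinom(0:cv, cv, 0.5)
  # pool sparse tails for a valid chi-square approximation
  pool <- p * 2e4 >= 5
  o <- c(sum(obs[!pool]), obs[pool])
  e <- c(sum(p[!pool]), p[pool])
  gof <- suppressWarnings(chisq.test(o, p = e / sum(e)))
  expect_gt(gof$p.value, 0.01)
})

test_that("short-read emission produces the two evidence classes", {
  co <- generate_cohort(fixed_aaf_config(aaf = 0), 4, 1)
  rec <- emit_alignment_records(co, co$pedigree$id[1], "short_read")
  expect_equal(nrow(rec$host), 0L)           # no carried integrations

  # over many het sites the mean junction support matches coverage/2
  cfg <- fixed_aaf_config(seed = 21, aaf = 0.5, n_sites = 8L)
  co <- generate_cohort(cfg, 30, 1)
  truth <- do.call(rbind, lapply(co$pedigree$id, function(id)
    emit_alignment_records(co, id, "short_read")$truth))
  het <- truth[truth$genotype == 1L, ]
  expect_gt(nrow(het), 200L)
  expect_lt(abs(mean(het$n_softclip) - cfg$mean_coverage / 2),
            0.1 * cfg$mean_coverage / 2)
  # soft-clips in emitted SAM records always exceed the 20 bp floor
  rec <- emit_alignment_records(co, co$pedigree$id[1], "short_read")
  cig <- ervtrace:::parse_cigar(rec$host$cigar)
  clips <- pmax(cig$lead_clip, cig$trail_clip)
  expect_true(all(clips[clips > 0] > 20L))
})

test_that("long-read emission labels endogenous vs somatic truth", {
  cfg <- small_config(seed = 9, endogenous_support = 600,
                      somatic_support = 40, n_somatic = 2L)
  co <- generate_cohort(cfg, 6, 1)
  carrier <- rownames(co$genotypes)[
    rowSums(co$genotypes[, co$sites$family == "KoRV", drop = FALSE]) > 0][1]
  rec <- emit_alignment_records(co, carrier, "long_read",
                                emit_sequences = FALSE)
  expect_true(all(c("endogenous", "somatic") %in% rec$truth$type))
  expect_true(all(rec$truth$type[grepl("^somatic", rec$truth$site_id)] ==
                    "somatic"))
  # flank table carries both junction sides per read
  expect_setequal(unique(rec$flanks$side), c("left", "right"))
})

test_that("trio SNV simulation plants truth and decoys as configured", {
  cfg <- small_config()
  expect_error(simulate_trio_snv_calls(list(sire = NA, dam = "a", joey = "b"),
                                       cfg), "not a triad")

  quiet <- sim_config(snv_mutation_rate = 0, snv_haploid_length = 1e6)
  sim <- simulate_trio_snv_calls(list(sire = "s", dam = "d", joey = "j"),
                                 quiet, n_false_positives = 0, seed = 2)
  expect_equal(nrow(sim$records), 0L)

  # Poisson(2) oracle: rate 1e-6 on 1e6 bp haploid over 100 trios
  cfg2 <- sim_config(snv_mutation_rate = 1e-6, snv_haploid_length = 1e6)
  counts <- vapply(1:100, function(i)
    nrow(simulate_trio_snv_calls(list(sire = "s", dam = "d", joey = "j"),
                                 cfg2, n_false_positives = 0,
                                 seed = 100 + i)$truth), 1L)
  se <- sqrt(2 / 100)
  expect_lt(abs(mean(counts) - 2), 3 * se)

  # planted artifacts appear in the records but never in the truth list
  sim3 <- simulate_trio_snv_calls(list(sire = "s", dam = "d", joey = "j"),
                                  cfg2, n_false_positives = 30, seed = 5)
  key <- function(d) paste(d$contig, d$pos1)
  fp <- sim3$records[!key(sim3$records) %in% key(sim3$truth), ]
  expect_gt(nrow(fp), 0L)
  passes <- fp$gt_sire == 0L & fp$gt_dam == 0L & fp$gt_joey == 1L &
    fp$dp >= 20L & fp$gq >= 20L & fp$ab >= 0.4
  expect_false(any(passes))
})
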