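trio1 <- data.frame(sire_id = "s", dam_id = "d", joey_id = "j",
                    stringsAsFactors = FALSE)

mk_mats <- function(g, cov) {
  ids <- c("s", "d", "j")
  list(m = matrix(g, 3, 1, dimnames = list(ids, "site1")),
       cv = matrix(cov, 3, 1, dimnames = list(ids, "site1")))
}

test_that("de novo candidates need a 40x het joey and 0/0 parents", {
  x <- mk_mats(c(0L, 0L, 1L), c(60, 60, 39))
  expect_equal(nrow(find_de_novo(x$m, x$cv, trio1)), 0L)
  x <- mk_mats(c(0L, 0L, 1L), c(60, 60, 45))
  cand <- find_de_novo(x$m, x$cv, trio1)
  expect_equal(cand$site_id, "site1")
  expect_equal(cand$joey_coverage, 45)
  # a -1 parent cannot exclude inheritance
  x <- mk_mats(c(-1L, 0L, 1L), c(60, 60, 45))
  expect_equal(nrow(find_de_novo(x$m, x$cv, trio1)), 0L)
  # triad member missing from the matrix is skipped with a warning
  expect_warning(
    out <- find_de_novo(x$m, x$cv,
                        data.frame(sire_id = "ghost", dam_id = "d",
                                   joey_id = "j", stringsAsFactors = FALSE)),
    "skipped")
  expect_equal(nrow(out), 0L)
})

test_that("planted de novo events are recovered exactly on truth matrices", {
  cfg <- small_config(seed = 17, denovo_integration_rate = c(KoRV = 1.2))
  co <- generate_cohort(cfg, 8, 2)
  G <- co$genotypes
  cov <- matrix(60, nrow(G), ncol(G), dimnames = dimnames(G))
  triads <- find_triads(co$pedigree)
  cand <- find_de_novo(G, cov, triads)
  expect_gte(nrow(co$denovo), 5L)
  expect_setequal(paste(cand$site_id, cand$joey_id),
                  paste(co$denovo$site_id, co$denovo$joey_id))

  # de-novo-rate-0 cohorts yield no candidates in any triad
  co0 <- generate_cohort(small_config(
    seed = 18, denovo_integration_rate = c(KoRV = 0)), 8, 2)
  cov0 <- matrix(60, nrow(co0$genotypes), ncol(co0$genotypes),
                 dimnames = dimnames(co0$genotypes))
  expect_equal(nrow(find_de_novo(co0$genotypes, cov0,
                                 find_triads(co0$pedigree))), 0L)
})

test_that("F2 validation uses the 10-read floor", {
  ped <- ped_df(c("s", "d", "j", "mate", "f2"),
                sire = c(NA, NA, "s", NA, "j"),
                dam = c(NA, NA, "d", NA, "mate"),
                sex = c("M", "F", "M", "F", "F"))
  ids <- ped$id
  cand <- data.frame(site_id = "site1", joey_id = "j",
                     stringsAsFactors = FALSE)
  mk <- function(gf2, cf2) {
    list(m = matrix(c(0L, 0L, 1L, 0L, gf2), 5, 1,
                    dimnames = list(ids, "site1")),
         cv = matrix(c(60, 60, 60, 60, cf2), 5, 1,
                     dimnames = list(ids, "site1")))
  }
  x <- mk(1L, 12)
  expect_equal(validate_f2(cand, x$m, x$cv, ped), "validated")
  x <- mk(1L, 9)
  expect_equal(validate_f2(cand, x$m, x$cv, ped), "not_validated")
  ped2 <- ped[ped$id != "f2", ]
  x <- mk(1L, 12)
  expect_equal(validate_f2(cand, x$m[1:4, , drop = FALSE],
                           x$cv[1:4, , drop = FALSE], ped2), "not_assessed")
})

test_that("integration rates reproduce the published worked examples", {
  expect_equal(unname(integration_rate(c(KoRV = 15, phaCinB = 1), 46)),
               c(0.33, 0.02))
  expect_equal(integration_rate(5, 9), 0.56)
  expect_error(integration_rate(5, 0), "n_triads")
})

test_that("expected transmissions compose the binomial miss model", {
  et <- expected_transmissions(16, 10)
  expect_equal(round(et$inheritance_rate * 100), 45)
  expect_equal(et$expected, 7)
  expect_equal(expected_transmissions(0)$expected, 0)
  et40 <- expected_transmissions(16, 40)
  expect_equal(et40$inheritance_rate, 0.5 * (1 - miss_probability(40)))
  expect_equal(round(et40$inheritance_rate, 4), 0.4968)
})

test_that("F1->F2 transmission frequency matches 0.5(1 - miss(c))", {
  # >= 500 simulated transmissions of a het site at coverage 30
  set.seed(31)
  n <- 600L; cv <- 30L
  inherited <- ervtrace:::mendelian_transmit(rep(1L, n), rep(0L, n))
  tal <- simulate_site_evidence(inherited, cv)
  f <- tal$n_softclip / cv
  detected <- inherited == 1L & f >= 0.3 & f <= 0.7
  expected <- 0.5 * (1 - miss_probability(cv))
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(mean(detected) - expected), 3 * se)
})

test_that("eliminated sites have deceased-only carriers", {
  ids <- paste0("i", 1:10)
  vs <- setNames(rep(c("deceased", "living"), each = 5), ids)
  m <- cbind(site_a = c(rep(1L, 4), 0L, rep(0L, 5)),     # 4 deceased hets
             site_b = c(rep(1L, 4), 0L, 1L, rep(0L, 4)), # one living carrier
             site_c = rep(0L, 10))
  rownames(m) <- ids
  rep_ <- find_eliminated(m, vs)
  expect_true(rep_$eliminated[rep_$site_id == "site_a"])
  expect_gt(rep_$aaf_deceased[rep_$site_id == "site_a"], 0.05)
  expect_true(rep_$high_frequency[rep_$site_id == "site_a"])
  expect_false(rep_$eliminated[rep_$site_id == "site_b"])
  expect_false(rep_$eliminated[rep_$site_id == "site_c"])
  expect_error(find_eliminated(m, setNames(rep("deceased", 10), ids)),
               "cannot assess")

  # truth-kill oracle: flag exactly the sites whose carriers all died
  set.seed(41)
  G <- matrix(rbinom(30 * 20, 2, 0.2), 30, 20,
              dimnames = list(paste0("k", 1:30), paste0("s", 1:20)))
  vs2 <- setNames(rep("living", 30), rownames(G))
  kill_sites <- paste0("s", 1:5)
  vs2[rowSums(G[, kill_sites, drop = FALSE]) > 0] <- "deceased"
  if (!any(vs2 == "living")) vs2[1] <- "living"
  rep2 <- find_eliminated(G, vs2)
  truth_elim <- vapply(colnames(G), function(s) {
    carr <- rownames(G)[G[, s] > 0]
    length(carr) > 0 && all(vs2[carr] == "deceased")
  }, TRUE)
  expect_equal(setNames(rep2$eliminated, rep2$site_id), truth_elim)
})

test_that("elimination-rate arithmetic and reconstruction behave", {
  expect_equal(elimination_rate(4, 2, 1e6), 1e-6)
  expect_equal(elimination_rate(0, 46, 3234982288), 0)
  # one denominator choice consistent with the published 9.58e-10
  expect_equal(round(elimination_rate(570, 46, 3234982288,
                                      diploid_factor = 4), 12) * 1e10,
               9.58, tolerance = 0.01)
})
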