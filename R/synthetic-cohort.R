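#' ERV family model for the synthetic cohort generator
#'
#' Describes one retroviral lineage segregating in the simulated host
#' population: the provirus geometry (LTR and internal lengths), the
#' chaining gap used when clustering read evidence for this family, the
#' distribution founder allele frequencies are drawn from, and whether the
#' family's integrations are present in the reference assembly ("known"
#' sites called by start/end rather than a single breakpoint).
#'
#' @param name Family label, e.g. "KoRV".
#' @param ltr_length LTR length in bp (>= 50).
#' @param internal_length Internal proviral sequence length in bp.
#' @param cluster_gap Maximum read-position difference chained into one
#'   evidence cluster: 500 bp for KoRV, 9000 bp for the older lineages
#'   whose proviruses (~8 kbp) are present in the assembly.
#' @param founder_aaf Distribution of founder integration allele
#'   frequencies: `list(dist = "beta", shape1 =, shape2 =)` or
#'   `list(dist = "fixed", value =)`.
#' @param known_in_reference Logical; TRUE when the reference assembly
#'   carries this family's integrations.
#' @param n_sites Number of polymorphic sites simulated for the family.
#' @param substrains Optional named numeric vector of sub-strain reference
#'   names and their read fractions (e.g. KoRV-A vs KoRV-B).
#' @return An object of class `erv_family`.
#' @export
family_model <- function(name, ltr_length = 500L, internal_length = 7400L,
                         cluster_gap = 9000L,
                         founder_aaf = list(dist = "beta", shape1 = 0.4, shape2 = 4),
                         known_in_reference = FALSE, n_sites = 15L,
                         substrains = NULL) {
  if (ltr_length < 50) stop("ltr_length must be >= 50", call. = FALSE)
  if (cluster_gap <= 0) stop("cluster_gap must be > 0", call. = FALSE)
  if (is.null(substrains)) substrains <- stats::setNames(1, name)
  structure(list(name = name, ltr_length = as.integer(ltr_length),
                 internal_length = as.integer(internal_length),
                 cluster_gap = as.integer(cluster_gap),
                 founder_aaf = founder_aaf,
                 known_in_reference = isTRUE(known_in_reference),
                 n_sites = as.integer(n_sites),
                 substrains = substrains),
            class = "erv_family")
}

#' @rdname family_model
#' @export
korv_family <- function(n_sites = 20L) {
  family_model("KoRV", ltr_length = 505L, internal_length = 7440L,
               cluster_gap = 500L,
               founder_aaf = list(dist = "beta", shape1 = 0.4, shape2 = 4),
               known_in_reference = FALSE, n_sites = n_sites,
               substrains = c("KoRV-A" = 0.982, "KoRV-B" = 0.018))
}

#' @rdname family_model
#' @export
phacinb_family <- function(n_sites = 15L) {
  family_model("phaCin-beta", ltr_length = 550L, internal_length = 7000L,
               cluster_gap = 9000L,
               founder_aaf = list(dist = "beta", shape1 = 0.4, shape2 = 4),
               known_in_reference = FALSE, n_sites = n_sites)
}

#' @rdname family_model
#' @export
phacinb_like_family <- function(n_sites = 10L) {
  family_model("phaCin-beta-like", ltr_length = 550L, internal_length = 7000L,
               cluster_gap = 9000L,
               founder_aaf = list(dist = "beta", shape1 = 8, shape2 = 0.4),
               known_in_reference = TRUE, n_sites = n_sites)
}

#' Simulation configuration
#'
#' Houses the knobs of the synthetic cohort generator. Defaults emulate the
#' sequencing design of the motivating study: 150 bp paired-end reads at a
#' mean genome coverage of 30x, a 5 bp target-site duplication
#' (gammaretroviral TSDs run 4-6 bp), and per-family de novo germline
#' integration rates of 0.33 (KoRV) and 0.02 (phaCin-beta) per joey per
#' generation.
#'
#' @param seed Integer; a fixed seed yields byte-identical outputs.
#' @param n_contigs,contig_length Host reference geometry.
#' @param read_length Read length in bp.
#' @param mean_coverage Mean junction coverage (fold); per-site coverage is
#'   Poisson with this mean.
#' @param tsd_length Target-site duplication length in bp.
#' @param families List of [family_model()] objects.
#' @param denovo_integration_rate Named numeric: expected new germline
#'   integrations per joey per family.
#' @param snv_mutation_rate De novo SNVs per bp per generation.
#' @param snv_haploid_length Haploid genome length used by the trio SNV
#'   simulator and the mutation-rate denominator. The SNV records never
#'   touch the simulated contig sequences, so this defaults to the real
#'   haploid assembly length (3,234,982,288 bp) rather than the scaled-down
#'   `contig_length`, giving realistic per-trio mutation counts.
#' @param softclip_noise_rate Fraction of spurious junction reads emitted at
#'   non-carrier sites (default 0; no noise model is asserted by the study).
#' @param leukemia_log_or Log-odds effect of the designated risk site on the
#'   simulated leukemia trait among deceased animals.
#' @param endogenous_support,somatic_support Mean long-read support for
#'   endogenous germline vs somatic integrations in iPCR mode.
#' @param n_somatic Somatic integrations per individual in iPCR mode.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_contigs = 2L, contig_length = 200000L,
                       read_length = 150L, mean_coverage = 30,
                       tsd_length = 5L,
                       families = list(korv_family(), phacinb_family(),
                                       phacinb_like_family()),
                       denovo_integration_rate = c("KoRV" = 0.33,
                                                   "phaCin-beta" = 0.02,
                                                   "phaCin-beta-like" = 0),
                       snv_mutation_rate = 1.03e-8,
                       snv_haploid_length = 3234982288,
                       softclip_noise_rate = 0,
                       leukemia_log_or = 1.5,
                       endogenous_support = 600, somatic_support = 40,
                       n_somatic = 2L) {
  if (any(denovo_integration_rate < 0)) stop("rates must be >= 0", call. = FALSE)
  if (snv_mutation_rate < 0 || softclip_noise_rate < 0)
    stop("rates must be >= 0", call. = FALSE)
  if (contig_length <= 10 * read_length)
    stop("contig_length must exceed 10 * read_length", call. = FALSE)
  fam_names <- vapply(families, `[[`, "", "name")
  rate <- stats::setNames(rep(0, length(fam_names)), fam_names)
  hit <- intersect(names(denovo_integration_rate), fam_names)
  rate[hit] <- denovo_integration_rate[hit]
  structure(list(seed = as.integer(seed), n_contigs = as.integer(n_contigs),
                 contig_length = as.integer(contig_length),
                 read_length = as.integer(read_length),
                 mean_coverage = mean_coverage,
                 tsd_length = as.integer(tsd_length),
                 families = stats::setNames(families, fam_names),
                 denovo_integration_rate = rate,
                 snv_mutation_rate = snv_mutation_rate,
                 snv_haploid_length = snv_haploid_length,
                 softclip_noise_rate = softclip_noise_rate,
                 leukemia_log_or = leukemia_log_or,
                 endogenous_support = endogenous_support,
                 somatic_support = somatic_support,
                 n_somatic = as.integer(n_somatic)),
            class = "sim_config")
}

draw_founder_aaf <- function(fam, n) {
  d <- fam$founder_aaf
  switch(d$dist,
         beta = stats::rbeta(n, d$shape1, d$shape2),
         fixed = rep(d$value, n),
         stop("unknown founder_aaf dist: ", d$dist, call. = FALSE))
}

# Mendelian transmission: one allele per parent, Binomial(1, g/2) each.
mendelian_transmit <- function(g_sire, g_dam) {
  stats::rbinom(length(g_sire), 1L, g_sire / 2) +
    stats::rbinom(length(g_dam), 1L, g_dam / 2)
}

#' Generate a pedigreed synthetic cohort with full truth tables
#'
#' Builds a host reference, viral reference sequences, a set of segregating
#' integration sites per ERV family, and a multi-generation pedigree in
#' which founder genotypes are drawn under Hardy-Weinberg from the family's
#' founder allele-frequency distribution, each offspring receives one
#' allele per parent per site, and new germline integrations arise per joey
#' as Poisson draws per family at uniformly placed positions (always
#' heterozygous in the joey: a new insertion arises on a single gamete).
#' Every genotype and de novo event is recorded in the returned truth
#' tables, so downstream detection stages can be scored exactly.
#'
#' @param config A [sim_config()].
#' @param n_founders Number of founders (>= 2).
#' @param n_generations Number of offspring generations (>= 1).
#' @return An object of class `erv_cohort`: reference and viral sequences,
#'   site table, known-ERV intervals, pedigree, truth genotype matrix,
#'   de novo event table and phenotype table.
#' @export
generate_cohort <- function(config, n_founders, n_generations) {
  stopifnot(inherits(config, "sim_config"))
  if (n_founders == 0) stop("empty pedigree", call. = FALSE)
  if (n_founders < 2) stop("n_founders must be >= 2", call. = FALSE)
  if (n_generations < 1) stop("n_generations must be >= 1", call. = FALSE)
  with_seed(child_seed(config$seed, 1), {
    contigs <- paste0("contig", seq_len(config$n_contigs))
    reference <- stats::setNames(
      vapply(contigs, function(x) random_dna(config$contig_length), ""), contigs)

    viral_refs <- character(0)
    ltr_seqs <- character(0)
    for (fam in config$families) {
      ltr <- random_dna(fam$ltr_length)
      internal <- random_dna(fam$internal_length)
      provirus <- paste0(ltr, internal, ltr)
      ltr_seqs[fam$name] <- ltr
      for (s in names(fam$substrains)) {
        sq <- provirus
        if (s != names(fam$substrains)[1]) {
          # sub-strains differ by ~2% substitutions
          n <- nchar(sq)
          k <- max(1L, round(0.02 * n))
          idx <- sample.int(n, k)
          sub <- sample(c("A", "C", "G", "T"), k, replace = TRUE)
          sq_split <- strsplit(sq, "")[[1]]
          sq_split[idx] <- sub
          sq <- paste(sq_split, collapse = "")
        }
        viral_refs[s] <- sq
      }
    }

    # Real ERV densities (~1 site per 1.5 Mb) make same-family sites within
    # one chaining gap rare; enforce that separation on the small simulated
    # contigs so truth sites map 1:1 to evidence clusters.
    margin <- 1000L
    draw_spaced <- function(fam, n, existing) {
      minsep <- fam$cluster_gap + 2500L
      out <- existing
      added <- 0L
      while (added < n) {
        placed <- FALSE
        for (try in 1:200) {
          ct <- sample(contigs, 1L)
          p0 <- sample.int(config$contig_length - 2L * margin, 1L) + margin
          if (!any(out$contig == ct & abs(out$position0 - p0) < minsep)) {
            out <- rbind(out, data.frame(contig = ct, position0 = p0,
                                         stringsAsFactors = FALSE))
            placed <- TRUE
            break
          }
        }
        if (!placed) break  # contigs saturated; fewer sites than requested
        added <- added + 1L
      }
      utils::tail(out, added)
    }
    sites <- do.call(rbind, lapply(config$families, function(fam) {
      pos <- draw_spaced(fam, fam$n_sites,
                         data.frame(contig = character(0),
                                    position0 = integer(0),
                                    stringsAsFactors = FALSE))
      n <- nrow(pos)
      data.frame(site_id = sprintf("%s:%s:%d", fam$name, pos$contig,
                                   pos$position0),
                 family = fam$name, contig = pos$contig,
                 position0 = pos$position0,
                 known_flag = fam$known_in_reference,
                 founder_aaf = draw_founder_aaf(fam, n),
                 stringsAsFactors = FALSE)
    }))
    rownames(sites) <- NULL
    sites <- sites[!duplicated(sites$site_id), , drop = FALSE]

    prov_len <- vapply(config$families, function(f)
      2L * f$ltr_length + f$internal_length, 1L)
    known <- sites[sites$known_flag, , drop = FALSE]
    known_erv <- data.frame(contig = known$contig, start0 = known$position0,
                            end0 = known$position0 + prov_len[known$family],
                            site_id = known$site_id, family = known$family,
                            stringsAsFactors = FALSE)

    # pedigree -------------------------------------------------------------
    ids <- sprintf("SB%d", 100L + seq_len(n_founders) - 1L)
    ped <- data.frame(id = ids, sire = NA_character_, dam = NA_character_,
                      sex = rep(c("M", "F"), length.out = n_founders),
                      birth_year = sample(1978:1984, n_founders, replace = TRUE),
                      generation = 0L, stringsAsFactors = FALSE)
    ns <- nrow(sites)
    G <- matrix(stats::rbinom(n_founders * ns, 2L,
                              rep(sites$founder_aaf, each = n_founders)),
                nrow = n_founders,
                dimnames = list(ids, sites$site_id))
    denovo <- data.frame(site_id = character(0), joey_id = character(0),
                         family = character(0), contig = character(0),
                         position0 = integer(0), generation = integer(0),
                         stringsAsFactors = FALSE)
    next_id <- 100L + n_founders
    for (g in seq_len(n_generations)) {
      prev <- ped[ped$generation == g - 1L, , drop = FALSE]
      males <- prev$id[prev$sex == "M"]
      females <- prev$id[prev$sex == "F"]
      if (length(males) == 0 || length(females) == 0)
        stop("generation ", g - 1L, " lacks one sex; increase n_founders",
             call. = FALSE)
      n_off <- n_founders
      off_ids <- sprintf("SB%d", next_id + seq_len(n_off) - 1L)
      next_id <- next_id + n_off
      sire <- sample(males, n_off, replace = TRUE)
      dam <- sample(females, n_off, replace = TRUE)
      ped <- rbind(ped, data.frame(
        id = off_ids, sire = sire, dam = dam,
        sex = rep(c("F", "M"), length.out = n_off),
        birth_year = 1978L + 8L * g + sample(0:3, n_off, replace = TRUE),
        generation = g, stringsAsFactors = FALSE))
      Gs <- G[sire, , drop = FALSE]
      Gd <- G[dam, , drop = FALSE]
      Goff <- matrix(stats::rbinom(length(Gs), 1L, Gs / 2) +
                       stats::rbinom(length(Gd), 1L, Gd / 2),
                     nrow = n_off, dimnames = list(off_ids, colnames(G)))
      G <- rbind(G, Goff)
      # de novo germline integrations, heterozygous in the joey
      for (fam in config$families) {
        rate <- config$denovo_integration_rate[fam$name]
        if (rate <= 0) next
        k_per <- stats::rpois(n_off, rate)
        for (j in which(k_per > 0)) {
          for (e in seq_len(k_per[j])) {
            fam_sites <- sites[sites$family == fam$name, , drop = FALSE]
            pos <- draw_spaced(fam, 1L,
                               fam_sites[, c("contig", "position0")])
            if (nrow(pos) == 0L) next
            ct <- pos$contig; p0 <- pos$position0
            sid <- sprintf("%s:%s:%d", fam$name, ct, p0)
            if (sid %in% colnames(G)) next
            newcol <- matrix(0L, nrow(G), 1L,
                             dimnames = list(rownames(G), sid))
            newcol[off_ids[j], 1L] <- 1L
            G <- cbind(G, newcol)
            sites <- rbind(sites, data.frame(
              site_id = sid, family = fam$name, contig = ct, position0 = p0,
              known_flag = FALSE, founder_aaf = 0,
              stringsAsFactors = FALSE))
            denovo <- rbind(denovo, data.frame(
              site_id = sid, joey_id = off_ids[j], family = fam$name,
              contig = ct, position0 = p0, generation = g,
              stringsAsFactors = FALSE))
          }
        }
      }
    }

    # vital status and phenotypes -----------------------------------------
    n_ind <- nrow(ped)
    p_dead <- ifelse(ped$generation < n_generations, 0.6, 0.1)
    deceased <- stats::rbinom(n_ind, 1L, p_dead) == 1L
    if (all(deceased)) deceased[n_ind] <- FALSE
    if (!any(deceased)) deceased[1L] <- TRUE
    ped$vital_status <- ifelse(deceased, "deceased", "living")

    korv_sites <- sites$site_id[sites$family == "KoRV" & sites$founder_aaf > 0]
    risk_site <- if (length(korv_sites)) korv_sites[1L] else NA_character_
    base_logit <- stats::qlogis(0.25)
    risk_g <- if (!is.na(risk_site)) G[ped$id, risk_site] else rep(0L, n_ind)
    p_leuk <- stats::plogis(base_logit + config$leukemia_log_or * risk_g)
    leuk <- deceased & stats::rbinom(n_ind, 1L, p_leuk) == 1L
    ped$cause_of_death <- NA_character_
    ped$cause_of_death[deceased] <- ifelse(
      leuk[deceased], "leukemia",
      sample(c("lymphoma", "sarcoma", "infection", "age"),
             sum(deceased), replace = TRUE,
             prob = c(0.15, 0.05, 0.3, 0.5)))
    has_offspring <- ped$id %in% c(ped$sire, ped$dam)
    age_at_death <- ifelse(deceased,
                           pmax(0.5, stats::rnorm(n_ind, 12, 4)), NA_real_)
    phenotypes <- data.frame(
      individual_id = ped$id,
      leukemia_case = deceased & leuk,
      neoplasia_case = deceased &
        ped$cause_of_death %in% c("leukemia", "lymphoma", "sarcoma"),
      reproduction_success = has_offspring,
      age_at_death = age_at_death,
      stringsAsFactors = FALSE)

    structure(list(config = config, reference = reference,
                   viral_refs = viral_refs, ltr_seqs = ltr_seqs,
                   sites = sites, known_erv = known_erv,
                   pedigree = structure(ped, class = c("erv_pedigree",
                                                       "data.frame")),
                   genotypes = G, denovo = denovo,
                   phenotypes = phenotypes,
                   trait_model = list(leukemia_site = risk_site,
                                      log_or = config$leukemia_log_or)),
              class = "erv_cohort")
  })
}

#' Simulate junction read tallies at one integration site
#'
#' Inverts the zygosity model: a heterozygote yields soft-clipped junction
#' reads as Binomial(coverage, 0.5) against crossing reads; a homozygous
#' carrier yields (almost) all junction reads soft-clipped; a non-carrier
#' yields soft-clips only at the spurious-read noise rate.
#'
#' @param genotype Integer vector of genotype codes in \{0, 1, 2\}.
#' @param coverage Integer vector of junction coverages (recycled).
#' @param noise Spurious soft-clip rate for non-carrier alleles.
#' @param seed Optional seed (RNG state restored afterwards).
#' @return data.frame with columns `n_softclip`, `n_crossing`.
#' @export
simulate_site_evidence <- function(genotype, coverage, noise = 0, seed = NULL) {
  stopifnot(all(genotype %in% 0:2), all(coverage >= 0), noise >= 0)
  n <- max(length(genotype), length(coverage))
  genotype <- rep_len(genotype, n)
  coverage <- rep_len(as.integer(coverage), n)
  with_seed(seed, {
    sc <- integer(n)
    sc[genotype == 1L] <- stats::rbinom(sum(genotype == 1L),
                                        coverage[genotype == 1L], 0.5)
    sc[genotype == 0L] <- stats::rbinom(sum(genotype == 0L),
                                        coverage[genotype == 0L], noise)
    g2 <- genotype == 2L
    sc[g2] <- coverage[g2] - stats::rbinom(sum(g2), coverage[g2], noise)
    data.frame(n_softclip = sc, n_crossing = coverage - sc)
  })
}

#' Emit alignment or long-read records for one individual
#'
#' Short-read mode emits, for every carried integration, the two evidence
#' classes used in discovery: anchored-mate pairs (host-aligned read whose
#' mate aligns to a viral reference) and junction reads soft-clipped at the
#' breakpoint (clips always exceed 20 bp). Long-read mode emits inverse-PCR
#' style reads containing a viral LTR segment flanked by >= 50 bp of host
#' sequence, with endogenous-level support at germline sites and low
#' support at extra somatic sites, plus the idealized flank-alignment table
#' a lossless excision + alignment of those reads would produce.
#'
#' @param cohort An `erv_cohort`.
#' @param individual_id Studbook id present in the cohort.
#' @param mode "short_read" or "long_read".
#' @param seed Optional seed; default derives from the cohort seed and id.
#' @param emit_sequences Long-read mode: build actual read sequences
#'   (set FALSE to keep only the flank-alignment truth, much faster).
#' @return Short-read mode: list(host, virus, truth). Long-read mode:
#'   list(reads, flanks, truth).
#' @export
emit_alignment_records <- function(cohort, individual_id,
                                   mode = c("short_read", "long_read"),
                                   seed = NULL, emit_sequences = TRUE) {
  stopifnot(inherits(cohort, "erv_cohort"))
  mode <- match.arg(mode)
  if (!individual_id %in% rownames(cohort$genotypes))
    stop("unknown individual: ", individual_id, call. = FALSE)
  cfg <- cohort$config
  if (is.null(seed))
    seed <- child_seed(cfg$seed, 1000L + match(individual_id,
                                               rownames(cohort$genotypes)))
  g <- cohort$genotypes[individual_id, ]
  sites <- cohort$sites
  with_seed(seed, {
    if (mode == "short_read") {
      emit_short_read(cohort, individual_id, g, sites, cfg)
    } else {
      emit_long_read(cohort, individual_id, g, sites, cfg, emit_sequences)
    }
  })
}

emit_short_read <- function(cohort, individual_id, g, sites, cfg) {
  rl <- cfg$read_length
  tsd <- cfg$tsd_length
  carried <- which(g[sites$site_id] > 0)
  rows <- list(); vrows <- list(); truth <- list()
  emit_site <- function(si, n_sc, n_am, label) {
    fam <- cfg$families[[sites$family[si]]]
    p <- sites$position0[si]
    ct <- sites$contig[si]
    strains <- names(fam$substrains)
    refseq <- cohort$reference[[ct]]
    host <- NULL; virus <- NULL
    if (n_sc > 0) {
      side <- stats::rbinom(n_sc, 1L, 0.5) == 1L  # TRUE = left junction
      alen <- sample(40:(rl - 21L), n_sc, replace = TRUE)
      clip <- rl - alen
      pos1 <- ifelse(side, p - alen + 1L, p + tsd + 1L)
      cigar <- ifelse(side, sprintf("%dM%dS", alen, clip),
                      sprintf("%dS%dM", clip, alen))
      qn <- sprintf("%s_%s_sc%03d", individual_id, sites$site_id[si],
                    seq_len(n_sc))
      hseq <- substring(refseq, pos1, pos1 + alen - 1L)
      vpart <- substring(cohort$ltr_seqs[[fam$name]], 1L, clip)
      seq <- ifelse(side, paste0(hseq, vpart), paste0(vpart, hseq))
      host <- data.frame(qname = qn, flag = 0L, rname = ct, pos = pos1,
                         mapq = 60L, cigar = cigar, rnext = "*", pnext = 0L,
                         tlen = 0L, seq = seq, stringsAsFactors = FALSE)
      virus <- data.frame(
        qname = qn,
        rname = sample(strains, n_sc, replace = TRUE, prob = fam$substrains),
        mapq = 60L, cigar = sprintf("%dM%dS", clip, alen),
        is_mate = FALSE, stringsAsFactors = FALSE)
    }
    if (n_am > 0) {
      side <- stats::rbinom(n_am, 1L, 0.5) == 1L
      d <- sample(5:250, n_am, replace = TRUE)
      pos1 <- ifelse(side, p - d - rl + 1L, p + tsd + d + 1L)
      qn <- sprintf("%s_%s_am%03d", individual_id, sites$site_id[si],
                    seq_len(n_am))
      seq <- substring(refseq, pos1, pos1 + rl - 1L)
      host2 <- data.frame(qname = qn, flag = 0L, rname = ct, pos = pos1,
                          mapq = 60L, cigar = sprintf("%dM", rl),
                          rnext = "*", pnext = 0L, tlen = 0L, seq = seq,
                          stringsAsFactors = FALSE)
      virus2 <- data.frame(
        qname = qn,
        rname = sample(strains, n_am, replace = TRUE, prob = fam$substrains),
        mapq = 60L, cigar = sprintf("%dM", rl),
        is_mate = TRUE, stringsAsFactors = FALSE)
      host <- rbind(host, host2)
      virus <- rbind(virus, virus2)
    }
    rows[[length(rows) + 1L]] <<- host
    vrows[[length(vrows) + 1L]] <<- virus
    truth[[length(truth) + 1L]] <<- data.frame(
      site_id = sites$site_id[si], genotype = unname(g[sites$site_id[si]]),
      n_softclip = n_sc, n_anchored = n_am, n_evidence = n_sc + n_am,
      stringsAsFactors = FALSE)
  }
  for (si in carried) {
    cov_allele <- cfg$mean_coverage * g[sites$site_id[si]] / 2
    n_sc <- stats::rpois(1L, cov_allele)
    n_am <- stats::rpois(1L, cov_allele)
    emit_site(si, n_sc, n_am, "carried")
  }
  if (cfg$softclip_noise_rate > 0) {
    for (si in which(g[sites$site_id] == 0)) {
      n_noise <- stats::rpois(1L, cfg$softclip_noise_rate * cfg$mean_coverage)
      if (n_noise > 0) emit_site(si, n_noise, 0L, "noise")
    }
  }
  empty_host <- data.frame(qname = character(0), flag = integer(0),
                           rname = character(0), pos = integer(0),
                           mapq = integer(0), cigar = character(0),
                           rnext = character(0), pnext = integer(0),
                           tlen = integer(0), seq = character(0),
                           stringsAsFactors = FALSE)
  empty_virus <- data.frame(qname = character(0), rname = character(0),
                            mapq = integer(0), cigar = character(0),
                            is_mate = logical(0), stringsAsFactors = FALSE)
  list(host = if (length(rows)) do.call(rbind, rows) else empty_host,
       virus = if (length(vrows)) do.call(rbind, vrows) else empty_virus,
       truth = if (length(truth)) do.call(rbind, truth) else
         data.frame(site_id = character(0), genotype = integer(0),
                    n_softclip = integer(0), n_anchored = integer(0),
                    n_evidence = integer(0), stringsAsFactors = FALSE))
}

emit_long_read <- function(cohort, individual_id, g, sites, cfg,
                           emit_sequences) {
  tsd <- cfg$tsd_length
  korv <- sites[sites$family == "KoRV" & g[sites$site_id] > 0, , drop = FALSE]
  # extra somatic integrations unique to this individual
  margin <- 1000L
  n_som <- cfg$n_somatic
  som <- if (n_som > 0) {
    ct <- sample(names(cohort$reference), n_som, replace = TRUE)
    p0 <- vapply(ct, function(x)
      sample.int(cfg$contig_length - 2L * margin, 1L) + margin, 1L)
    data.frame(site_id = sprintf("somatic:%s:%s:%d", individual_id, ct, p0),
               contig = ct, position0 = p0, type = "somatic",
               stringsAsFactors = FALSE)
  } else NULL
  tab <- rbind(
    if (nrow(korv)) data.frame(site_id = korv$site_id, contig = korv$contig,
                               position0 = korv$position0,
                               type = "endogenous", stringsAsFactors = FALSE),
    som)
  if (is.null(tab) || nrow(tab) == 0L) {
    return(list(reads = data.frame(read_id = character(0), site_id = character(0),
                                   sequence = character(0), stringsAsFactors = FALSE),
                flanks = empty_flank_df(),
                truth = data.frame(site_id = character(0), contig = character(0),
                                   position0 = integer(0), type = character(0),
                                   n_reads = integer(0), stringsAsFactors = FALSE)))
  }
  mean_sup <- ifelse(tab$type == "endogenous",
                     cfg$endogenous_support, cfg$somatic_support)
  tab$n_reads <- stats::rpois(nrow(tab), mean_sup)
  ltr <- cohort$ltr_seqs[["KoRV"]]
  reads <- list(); flanks <- list()
  for (i in seq_len(nrow(tab))) {
    n <- tab$n_reads[i]
    if (n == 0L) next
    p <- tab$position0[i]; ct <- tab$contig[i]
    fl <- sample(60:300, n, replace = TRUE)
    fr <- sample(60:300, n, replace = TRUE)
    rid <- sprintf("%s_%s_lr%04d", individual_id, tab$site_id[i], seq_len(n))
    if (emit_sequences) {
      refseq <- cohort$reference[[ct]]
      seq <- paste0(substring(refseq, p - fl + 1L, p),
                    ltr,
                    substring(refseq, p + tsd + 1L, p + tsd + fr))
      reads[[length(reads) + 1L]] <- data.frame(
        read_id = rid, site_id = tab$site_id[i], sequence = seq,
        stringsAsFactors = FALSE)
    }
    flanks[[length(flanks) + 1L]] <- data.frame(
      read_id = rep(rid, 2L)[order(rep(seq_len(n), 2L))],
      sample_id = individual_id,
      host_contig = ct,
      host_start0 = as.vector(rbind(p - fl, rep(p + tsd, n))),
      host_end0 = as.vector(rbind(rep(p, n), p + tsd + fr)),
      match_length = as.vector(rbind(fl, fr)),
      identity = stats::runif(2L * n, 0.95, 1),
      mapq = 60L,
      side = rep(c("left", "right"), n),
      stringsAsFactors = FALSE)
  }
  list(reads = if (length(reads)) do.call(rbind, reads) else
         data.frame(read_id = character(0), site_id = character(0),
                    sequence = character(0), stringsAsFactors = FALSE),
       flanks = if (length(flanks)) do.call(rbind, flanks) else empty_flank_df(),
       truth = tab)
}

empty_flank_df <- function() {
  data.frame(read_id = character(0), sample_id = character(0),
             host_contig = character(0), host_start0 = integer(0),
             host_end0 = integer(0), match_length = integer(0),
             identity = numeric(0), mapq = integer(0), side = character(0),
             stringsAsFactors = FALSE)
}

#' Simulate trio SNV calls with a de novo truth list
#'
#' Plants true de novo SNVs at `snv_mutation_rate` per bp per generation
#' over the diploid genome (2 x haploid length) with quality fields that
#' pass the downstream filters, and adds planted artifacts that each fail
#' at least one filter (low depth, low genotype quality, low allele
#' balance, or inherited from a heterozygous parent), so the de novo
#' filtering stage has real work to do. The truth list is exact.
#'
#' @param trio list(sire =, dam =, joey =) of ids; both parents required.
#' @param config A [sim_config()].
#' @param n_false_positives Expected count of planted artifacts (Poisson).
#' @param seed Optional seed.
#' @return list(records, truth): `records` is a trio SNV table (contig,
#'   pos1, gt_sire, gt_dam, gt_joey, dp, gq, ab); `truth` the subset of
#'   positions that are genuine de novo mutations.
#' @export
simulate_trio_snv_calls <- function(trio, config, n_false_positives = 30,
                                    seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(trio$sire) || is.null(trio$dam) || is.na(trio$sire) ||
      is.na(trio$dam))
    stop("not a triad", call. = FALSE)
  hap <- as.numeric(config$snv_haploid_length)
  contigs <- paste0("contig", seq_len(config$n_contigs))
  contig_len <- floor(hap / config$n_contigs)
  with_seed(seed, {
    n_true <- stats::rpois(1L, 2 * config$snv_mutation_rate * hap)
    mk <- function(n, gt_sire, gt_dam, gt_joey, dp, gq, ab) {
      if (n == 0L) return(NULL)
      data.frame(contig = sample(contigs, n, replace = TRUE),
                 pos1 = sample.int(contig_len, n),
                 gt_sire = gt_sire, gt_dam = gt_dam, gt_joey = gt_joey,
                 dp = dp, gq = gq, ab = ab, stringsAsFactors = FALSE)
    }
    true_rec <- mk(n_true, 0L, 0L, 1L,
                   dp = 20L + stats::rpois(n_true, 20),
                   gq = pmin(99L, 20L + stats::rpois(n_true, 40)),
                   ab = stats::runif(n_true, 0.4, 0.6))
    n_fp <- stats::rpois(1L, n_false_positives)
    fp_rec <- NULL
    if (n_fp > 0) {
      mode <- sample(c("low_dp", "low_gq", "low_ab", "inherited"), n_fp,
                     replace = TRUE)
      dp <- ifelse(mode == "low_dp", sample(5:19, n_fp, replace = TRUE),
                   20L + stats::rpois(n_fp, 20))
      gq <- ifelse(mode == "low_gq", sample(5:19, n_fp, replace = TRUE),
                   pmin(99L, 20L + stats::rpois(n_fp, 40)))
      ab <- ifelse(mode == "low_ab", stats::runif(n_fp, 0.05, 0.39),
                   stats::runif(n_fp, 0.4, 0.6))
      gt_sire <- ifelse(mode == "inherited", 1L, 0L)
      fp_rec <- mk(n_fp, gt_sire, 0L, 1L, dp, gq, ab)
    }
    records <- rbind(true_rec, fp_rec)
    if (is.null(records))
      records <- mk(0L, integer(0), integer(0), integer(0), integer(0),
                    integer(0), numeric(0))
    if (is.null(records))
      records <- data.frame(contig = character(0), pos1 = integer(0),
                            gt_sire = integer(0), gt_dam = integer(0),
                            gt_joey = integer(0), dp = integer(0),
                            gq = integer(0), ab = numeric(0),
                            stringsAsFactors = FALSE)
    truth <- if (!is.null(true_rec)) true_rec[, c("contig", "pos1")] else
      data.frame(contig = character(0), pos1 = integer(0),
                 stringsAsFactors = FALSE)
    ord <- order(records$contig, records$pos1)
    list(records = records[ord, , drop = FALSE], truth = truth)
  })
}
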