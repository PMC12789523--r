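#' Run the full simulated analysis pipeline
#'
#' Executes simulate -> discover -> genotype -> pedigree dynamics ->
#' mutation rate & dating -> association -> risk score on a synthetic
#' cohort, returning a run manifest of per-stage record counts. With a
#' fixed seed the manifest (and any written outputs) are identical across
#' runs.
#'
#' Junction coverage for genotyping and de novo screening is drawn
#' Poisson(2 x mean_coverage): reads informative at an integration are
#' tallied over both junction ends, so nominal 30x genome coverage
#' supports the 40-read joey floor.
#'
#' @param config A [sim_config()].
#' @param n_founders,n_generations Cohort shape.
#' @param out_dir Optional directory for file outputs (FASTA, BED, SAM,
#'   VCF, TSV, JSON manifest).
#' @return list with the cohort, intermediate results and `manifest`.
#' @export
run_pipeline <- function(config, n_founders = 12L, n_generations = 3L,
                         out_dir = NULL) {
  cohort <- generate_cohort(config, n_founders, n_generations)
  ped <- cohort$pedigree
  ids <- ped$id
  fams <- cohort$config$families
  contig_lengths <- stats::setNames(
    rep(config$contig_length, config$n_contigs), names(cohort$reference))

  # --- discovery --------------------------------------------------------
  per_ind <- lapply(ids, function(id) {
    rec <- emit_alignment_records(cohort, id, "short_read")
    s <- discover_sites(rec$virus, rec$host, fams,
                        known_intervals = cohort$known_erv)
    if (nrow(s)) s$individual <- id
    s
  })
  per_ind <- per_ind[vapply(per_ind, nrow, 1L) > 0]
  merged <- merge_sites_across_individuals(do.call(rbind, per_ind))
  registry <- merged$registry

  # --- genotyping (read tallies simulated from truth) -------------------
  truth_pos <- cohort$sites
  match_truth <- function(i) {
    cand <- which(truth_pos$family == registry$family[i] &
                    truth_pos$contig == registry$contig[i] &
                    truth_pos$position0 >= registry$start0[i] - config$tsd_length - 10L &
                    truth_pos$position0 <= registry$end0[i] + 10L)
    if (length(cand)) cand[1L] else NA_integer_
  }
  truth_idx <- vapply(seq_len(nrow(registry)), match_truth, 1L)
  keep <- !is.na(truth_idx)
  registry <- registry[keep, , drop = FALSE]
  truth_idx <- truth_idx[keep]
  with_seed(child_seed(config$seed, 2), {
    nI <- length(ids); nS <- nrow(registry)
    coverage <- matrix(stats::rpois(nI * nS, 2 * config$mean_coverage),
                       nI, nS, dimnames = list(ids, registry$site_id))
    gtruth <- cohort$genotypes[ids, truth_pos$site_id[truth_idx],
                               drop = FALSE]
    calls <- matrix(-1L, nI, nS, dimnames = list(ids, registry$site_id))
    no_evidence <- matrix(FALSE, nI, nS)
    for (j in seq_len(nS)) {
      tal <- simulate_site_evidence(gtruth[, j], coverage[, j],
                                    noise = config$softclip_noise_rate)
      no_evidence[, j] <- tal$n_softclip == 0L
      calls[, j] <- vapply(seq_len(nI), function(i) {
        t1 <- list(n_softclip = tal$n_softclip[i],
                   n_crossing = tal$n_crossing[i])
        if (registry$novel_flag[j]) call_genotype_novel(t1) else {
          # known sites: crossing reads carry the integration allele
          t_inv <- list(n_softclip = t1$n_crossing, n_crossing = t1$n_softclip)
          call_genotype_known(t_inv, t_inv)
        }
      }, 1L)
    }
    # integrations never detected in an individual are assumed hom-ref
    calls[no_evidence & calls == -1L] <- 0L
    matrix_calls <- calls
    qc <- site_qc(matrix_calls, ped)
    filtered <- apply_site_filters(matrix_calls, qc)
    coverage <- coverage[, colnames(filtered), drop = FALSE]

    # --- pedigree dynamics ----------------------------------------------
    triads <- find_triads(ped)
    denovo <- find_de_novo(filtered, coverage, triads)
    denovo$f2 <- if (nrow(denovo)) vapply(seq_len(nrow(denovo)), function(i)
      validate_f2(denovo[i, ], filtered, coverage, ped), "") else character(0)
    fam_of_site <- registry$family[match(colnames(filtered), registry$site_id)]
    n_new <- table(factor(fam_of_site[match(denovo$site_id,
                                            colnames(filtered))],
                          levels = names(fams)))
    rates <- integration_rate(as.numeric(n_new), nrow(triads))
    names(rates) <- names(n_new)
    vital <- stats::setNames(ped$vital_status, ped$id)
    elim <- find_eliminated(filtered, vital)

    # --- mutation rate and dating ---------------------------------------
    hap <- as.numeric(config$snv_haploid_length)
    trio_counts <- integer(nrow(triads)); ages <- list()
    for (i in seq_len(nrow(triads))) {
      tri <- triads[i, ]
      sim <- simulate_trio_snv_calls(
        list(sire = tri$sire_id, dam = tri$dam_id, joey = tri$joey_id),
        config, seed = child_seed(config$seed, 3000L + i))
      passed <- filter_de_novo_snvs(sim$records)
      trio_counts[i] <- nrow(passed)
      by <- stats::setNames(ped$birth_year, ped$id)
      ages[[i]] <- data.frame(
        sire_age = max(1, by[tri$joey_id] - by[tri$sire_id]),
        dam_age = max(1, by[tri$joey_id] - by[tri$dam_id]))
    }
    mu_gen <- rate_per_generation(trio_counts, hap)
    mu_year <- rate_per_year(trio_counts, do.call(rbind, ages), hap)
    ltr5 <- cohort$ltr_seqs[["KoRV"]]
    ltr3 <- local({
      x <- strsplit(ltr5, "")[[1]]
      k <- max(1L, round(0.001 * length(x)))
      idx <- sample.int(length(x), k)
      x[idx] <- vapply(x[idx], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
      paste(x, collapse = "")
    })
    div <- ltr_divergence(ltr5, ltr3)
    colon <- if (mu_year > 0) colonization_time(div, mu_year) else NA_real_

    # --- association and risk score -------------------------------------
    phen <- cohort$phenotypes
    dead <- ped$id[ped$vital_status == "deceased"]
    assoc <- grs <- boot <- cut <- NULL
    y <- phen$leukemia_case[match(dead, phen$individual_id)]
    if (length(dead) >= 10L && length(unique(y)) == 2L) {
      assoc <- additive_association(filtered[dead, , drop = FALSE], y,
                                    model = "logistic")
      sug <- assoc[assoc$p_value <= 0.05 & !assoc$separation_flag, ,
                   drop = FALSE]
      if (nrow(sug)) {
        model <- data.frame(marker_id = sug$marker_id,
                            weight = sug$odds_ratio,
                            effect_allele = "alt", stringsAsFactors = FALSE)
        grs <- genetic_risk_score(filtered[dead, , drop = FALSE], model)
        boot <- tryCatch(
          bootstrap_accuracy(grs, y, seed = child_seed(config$seed, 4)),
          error = function(e) NULL)
        cut <- choose_cutoff(grs, y)
      }
    }

    manifest <- list(
      seed = config$seed,
      n_individuals = length(ids),
      n_truth_sites = nrow(cohort$sites),
      n_registry_sites = nrow(merged$registry),
      n_sites_after_qc = ncol(filtered),
      n_triads = nrow(triads),
      n_denovo_candidates = nrow(denovo),
      integration_rate = as.list(rates),
      n_eliminated = sum(elim$eliminated),
      mutation_rate_per_generation = mu_gen,
      mutation_rate_per_year = mu_year,
      ltr_divergence = div,
      colonization_time_years = colon,
      n_suggestive_markers = if (is.null(assoc)) 0L else
        sum(assoc$p_value <= 0.05 & !assoc$separation_flag),
      grs_mean_accuracy = if (is.null(boot)) NA_real_ else
        boot$mean_accuracy,
      grs_cutoff = if (is.null(cut)) NA_real_ else cut$cutoff)

    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_reference_fasta(cohort$reference,
                            file.path(out_dir, "reference.fa"))
      write_reference_fasta(cohort$viral_refs, file.path(out_dir, "virus.fa"))
      if (nrow(cohort$known_erv))
        write_known_erv_bed(cohort$known_erv,
                            file.path(out_dir, "known_erv.bed"))
      write_pedigree(ped, file.path(out_dir, "pedigree.tsv"))
      write_sites_vcf(registry[match(colnames(filtered), registry$site_id), ],
                      filtered, file.path(out_dir, "sites.vcf"),
                      contig_lengths)
      utils::write.table(denovo[, setdiff(names(denovo), "carriers")],
                         file.path(out_dir, "denovo.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      utils::write.table(elim[elim$eliminated,
                              setdiff(names(elim), "carriers")],
                         file.path(out_dir, "eliminated.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }

    list(cohort = cohort, registry = registry, matrix = matrix_calls,
         filtered = filtered, coverage = coverage, qc = qc, triads = triads,
         denovo = denovo, eliminated = elim, association = assoc, grs = grs,
         bootstrap = boot, cutoff = cut, manifest = manifest)
  })
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic cohort), `run-all` (full
#' pipeline with manifest), `miss-prob` (binomial het miss probability).
#' Common flags: `--seed`, `--out`, `--founders`, `--generations`,
#' `--coverage`.
#'
#' @param args Character vector, e.g. `commandArgs(trailingOnly = TRUE)`.
#' @return Exit status, invisibly.
#' @export
ervtrace_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    message("usage: ervtrace <simulate|run-all|miss-prob> [--seed N] ",
            "[--out DIR] [--founders N] [--generations N] [--coverage N]")
    return(invisible(1L))
  }
  cmd <- args[1L]
  opt <- function(name, default) {
    i <- which(args == paste0("--", name))
    if (length(i) && i < length(args)) args[i + 1L] else default
  }
  seed <- as.integer(opt("seed", "1"))
  out <- opt("out", NULL)
  switch(cmd,
         "miss-prob" = {
           cv <- as.integer(opt("coverage", "40"))
           cat(sprintf("coverage %d: miss probability %.5f\n", cv,
                       miss_probability(cv)))
         },
         "simulate" = {
           cohort <- generate_cohort(sim_config(seed = seed),
                                     as.integer(opt("founders", "12")),
                                     as.integer(opt("generations", "3")))
           if (!is.null(out)) {
             dir.create(out, showWarnings = FALSE, recursive = TRUE)
             write_reference_fasta(cohort$reference,
                                   file.path(out, "reference.fa"))
             write_pedigree(cohort$pedigree, file.path(out, "pedigree.tsv"))
             utils::write.table(cohort$sites, file.path(out, "sites.tsv"),
                                sep = "\t", quote = FALSE, row.names = FALSE)
           }
           cat(sprintf("cohort: %d individuals, %d sites, %d de novo events\n",
                       nrow(cohort$pedigree), nrow(cohort$sites),
                       nrow(cohort$denovo)))
         },
         "run-all" = {
           res <- run_pipeline(sim_config(seed = seed),
                               as.integer(opt("founders", "12")),
                               as.integer(opt("generations", "3")),
                               out_dir = out)
           cat(jsonlite::toJSON(res$manifest, auto_unbox = TRUE,
                                pretty = TRUE, digits = NA), "\n")
         },
         stop("unknown subcommand: ", cmd, call. = FALSE))
  invisible(0L)
}
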