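# Shared fixtures and independent oracles, built in code at test time.

small_config <- function(seed = 1L, ...) {
  sim_config(seed = seed, n_contigs = 2L, contig_length = 150000L,
             families = list(korv_family(8L), phacinb_family(5L),
                             phacinb_like_family(4L)), ...)
}

# Degenerate-founder config: every site fixed at the given AAF.
fixed_aaf_config <- function(seed = 1L, aaf = 0, denovo = 0, n_sites = 6L) {
  fam <- family_model("KoRV", ltr_length = 505L, cluster_gap = 500L,
                      founder_aaf = list(dist = "fixed", value = aaf),
                      n_sites = n_sites,
                      substrains = c("KoRV-A" = 0.982, "KoRV-B" = 0.018))
  sim_config(seed = seed, n_contigs = 1L, contig_length = 120000L,
             families = list(fam),
             denovo_integration_rate = c(KoRV = denovo))
}

# Brute-force union-find over the pairwise <= gap relation: the stated
# independent oracle for single-linkage chaining.
brute_force_clusters <- function(pos, gap) {
  n <- length(pos)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (abs(pos[i] - pos[j]) <= gap) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  unname(split(pos, roots))
}

# Exhaustive enumeration of the het-window miss probability for c <= 20:
# walk every outcome count k with its binomial weight.
enumerate_miss <- function(cv, window = c(0.3, 0.7), p = 0.5) {
  ks <- 0:cv
  inside <- ks >= ceiling(window[1] * cv) & ks <= floor(window[2] * cv)
  sum(choose(cv, ks[!inside]) * p^ks[!inside] * (1 - p)^(cv - ks[!inside]))
}

make_tally <- function(sc, cr) list(n_softclip = sc, n_crossing = cr)

# Evidence data.frame builder for clustering tests.
evidence_df <- function(pos, family = "KoRV", contig = "c1",
                        class = "softclip") {
  if (length(pos) == 0L)
    return(data.frame(read_id = character(0), evidence_class = character(0),
                      family = character(0), substrain = character(0),
                      host_contig = character(0), host_pos0 = integer(0),
                      terminus0 = integer(0), clip_length = integer(0),
                      mapq = integer(0), stringsAsFactors = FALSE))
  data.frame(read_id = sprintf("r%04d", seq_along(pos)),
             evidence_class = class, family = family, substrain = family,
             host_contig = contig, host_pos0 = as.integer(pos),
             terminus0 = as.integer(pos), clip_length = 30L, mapq = 60L,
             stringsAsFactors = FALSE)
}

# Minimal pedigree table builder.
ped_df <- function(id, sire = NA, dam = NA, sex = "F", birth_year = 2000L,
                   vital_status = "living", cause_of_death = NA) {
  structure(data.frame(id = id, sire = sire, dam = dam, sex = sex,
                       birth_year = birth_year, vital_status = vital_status,
                       cause_of_death = cause_of_death,
                       stringsAsFactors = FALSE),
            class = c("erv_pedigree", "data.frame"))
}
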