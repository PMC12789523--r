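#' Additive marker-trait association by logistic or linear regression
#'
#' Fits, per marker, trait ~ genotype (+ covariates) with the genotype
#' coded additively (0/1/2 copies of the integration allele; undetermined
#' calls are treated as missing for that marker). Markers with minor allele
#' frequency below `maf_min` are skipped. For binary traits the model is
#' logistic (IRLS, convergence 1e-8, max 50 iterations) and the odds ratio
#' is exp(estimate); p-values are two-sided Wald tests without
#' multiple-testing correction. Perfect separation is flagged, not fatal.
#'
#' @param genotypes Matrix individuals x markers with codes \{0,1,2,-1\}.
#' @param phenotype Numeric/logical vector over the matrix rows.
#' @param covariates Optional data.frame of covariates over the same rows.
#' @param maf_min Minimum minor allele frequency (inclusive >=).
#' @param model "logistic" or "linear".
#' @return data.frame(marker_id, n, maf, estimate, odds_ratio, se, p_value,
#'   direction, separation_flag).
#' @export
additive_association <- function(genotypes, phenotype, covariates = NULL,
                                 maf_min = 0.01,
                                 model = c("logistic", "linear")) {
  model <- match.arg(model)
  phenotype <- as.numeric(phenotype)
  stopifnot(length(phenotype) == nrow(genotypes))
  fam <- if (model == "logistic") stats::binomial() else stats::gaussian()
  out <- lapply(colnames(genotypes), function(m) {
    g <- genotypes[, m]
    g[g < 0L] <- NA_integer_
    keep <- !is.na(g) & !is.na(phenotype)
    df <- data.frame(y = phenotype[keep], g = g[keep])
    if (!is.null(covariates)) {
      df <- cbind(df, covariates[keep, , drop = FALSE])
      keep2 <- stats::complete.cases(df)
      df <- df[keep2, , drop = FALSE]
    }
    aaf <- mean(df$g) / 2
    maf <- min(aaf, 1 - aaf)
    if (is.nan(maf) || maf < maf_min) return(NULL)
    fit <- suppressWarnings(stats::glm(
      y ~ ., data = df, family = fam,
      control = stats::glm.control(epsilon = 1e-8, maxit = 50L)))
    co <- summary(fit)$coefficients
    if (!"g" %in% rownames(co)) return(NULL)  # collinear / degenerate
    est <- co["g", 1L]; se <- co["g", 2L]
    sep <- model == "logistic" && (!fit$converged || abs(est) > 15 || se > 100)
    p <- 2 * stats::pnorm(-abs(est / se))
    data.frame(marker_id = m, n = nrow(df), maf = maf, estimate = est,
               odds_ratio = if (model == "logistic") exp(est) else NA_real_,
               se = se, p_value = p,
               direction = ifelse(est >= 0, "up", "down"),
               separation_flag = sep, stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out))
    return(data.frame(marker_id = character(0), n = integer(0),
                      maf = numeric(0), estimate = numeric(0),
                      odds_ratio = numeric(0), se = numeric(0),
                      p_value = numeric(0), direction = character(0),
                      separation_flag = logical(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Select covariates by the Delta-AIC criterion
#'
#' Each candidate is evaluated against the base (intercept-only) model; a
#' covariate is retained when adding it lowers the AIC by more than 5
#' points (Delta-AIC < -5). Collinear or unusable candidates are skipped
#' with a warning.
#'
#' @param trait Response vector.
#' @param candidates data.frame of candidate covariates.
#' @param model "logistic" or "linear".
#' @param threshold Delta-AIC cutoff (default -5).
#' @return Character vector of retained covariate names.
#' @export
select_covariates <- function(trait, candidates, model = c("logistic", "linear"),
                              threshold = -5) {
  model <- match.arg(model)
  if (is.null(candidates) || ncol(candidates) == 0L) return(character(0))
  fam <- if (model == "logistic") stats::binomial() else stats::gaussian()
  keep <- character(0)
  for (nm in colnames(candidates)) {
    df <- data.frame(y = as.numeric(trait), x = candidates[[nm]])
    df <- df[stats::complete.cases(df), , drop = FALSE]
    base <- stats::glm(y ~ 1, data = df, family = fam)
    fit <- tryCatch(suppressWarnings(stats::glm(y ~ x, data = df, family = fam)),
                    error = function(e) NULL)
    if (is.null(fit) || anyNA(stats::coef(fit))) {
      warning("covariate '", nm, "' skipped (collinear or unusable)")
      next
    }
    if (stats::AIC(fit) - stats::AIC(base) < threshold) keep <- c(keep, nm)
  }
  keep
}

#' Significance thresholds for genome-wide marker testing
#'
#' @param n_independent Number of independent tests behind the Bonferroni
#'   correction (the published analysis used 953,591 LD-pruned SNPs; the
#'   pruning itself is taken as a parameter, not recomputed).
#' @param suggestive_erv_log10,suggestive_snp_log10 Suggestive -log10 p
#'   cutoffs for ERVs and SNPs.
#' @return list(bonferroni_alpha, suggestive_erv_p, suggestive_snp_p, ...).
#' @export
significance_thresholds <- function(n_independent = 953591L,
                                    suggestive_erv_log10 = 1.3,
                                    suggestive_snp_log10 = 6) {
  list(bonferroni_alpha = 0.05 / n_independent,
       suggestive_erv_log10 = suggestive_erv_log10,
       suggestive_snp_log10 = suggestive_snp_log10,
       suggestive_erv_p = 10^(-suggestive_erv_log10),
       suggestive_snp_p = 10^(-suggestive_snp_log10))
}

#' Odds-ratio-weighted genetic risk score
#'
#' Each individual's score sums weight x effect-allele count over the model
#' markers. Weights are the raw odds ratios (or betas for continuous
#' traits), as in the published score. Markers whose effect allele is the
#' reference allele count reference copies (2 - genotype). Missing or
#' undetermined genotypes contribute 0 by default.
#'
#' @param genotypes Matrix individuals x markers (codes \{0,1,2,-1\}) or a
#'   single named genotype vector.
#' @param model data.frame(marker_id, weight, effect_allele) with
#'   effect_allele in \{"ref", "alt"\}.
#' @param missing_action "zero" (default) or "mean" imputation of the
#'   effect-allele count.
#' @return Named numeric vector of scores.
#' @export
genetic_risk_score <- function(genotypes, model,
                               missing_action = c("zero", "mean")) {
  missing_action <- match.arg(missing_action)
  if (is.null(dim(genotypes)))
    genotypes <- matrix(genotypes, nrow = 1L,
                        dimnames = list("ind", names(genotypes)))
  scores <- stats::setNames(numeric(nrow(genotypes)), rownames(genotypes))
  n_absent <- 0L
  for (i in seq_len(nrow(model))) {
    m <- model$marker_id[i]
    if (!m %in% colnames(genotypes)) { n_absent <- n_absent + 1L; next }
    g <- genotypes[, m]
    g[g < 0L] <- NA_integer_
    cnt <- if (model$effect_allele[i] == "ref") 2 - g else g
    if (missing_action == "mean") {
      cnt[is.na(cnt)] <- mean(cnt, na.rm = TRUE)
    }
    cnt[is.na(cnt)] <- 0
    scores <- scores + model$weight[i] * cnt
  }
  attr(scores, "n_absent_markers") <- n_absent
  scores
}

#' Bootstrap prediction accuracy of a risk score
#'
#' Repeatedly splits the data into training (75\%) and testing (25\%) sets,
#' fits a single-predictor logistic regression of the outcome on the score
#' in the training set, and records the fraction of correctly classified
#' test individuals (probability 0.5 decision rule). Splits whose training
#' set contains one class are redrawn (bounded retries).
#'
#' @param scores Numeric risk scores.
#' @param labels Binary outcomes (0/1 or logical).
#' @param reps Number of bootstrap iterations.
#' @param train_fraction Training-set fraction.
#' @param seed Optional seed (RNG state restored).
#' @param stratified Stratify the split by class (default TRUE: in a small
#'   balanced cohort an unstratified split makes the test-set majority the
#'   opposite of the training majority, biasing null accuracy below 0.5).
#' @return list(mean_accuracy, accuracies).
#' @export
bootstrap_accuracy <- function(scores, labels, reps = 100L,
                               train_fraction = 0.75, seed = NULL,
                               stratified = TRUE) {
  labels <- as.integer(as.logical(labels))
  n <- length(scores)
  stopifnot(length(labels) == n, length(unique(labels)) == 2L)
  with_seed(seed, {
    acc <- vapply(seq_len(reps), function(r) {
      for (try in 1:25) {
        tr <- if (stratified) {
          unlist(lapply(split(seq_len(n), labels), function(ix)
            sample(ix, max(1L, round(train_fraction * length(ix))))))
        } else sample.int(n, round(train_fraction * n))
        if (length(unique(labels[tr])) == 2L && length(tr) < n) break
        if (try == 25L) stop("could not draw a two-class training split",
                             call. = FALSE)
      }
      te <- setdiff(seq_len(n), tr)
      fit <- suppressWarnings(stats::glm(
        y ~ s, data = data.frame(y = labels[tr], s = scores[tr]),
        family = stats::binomial()))
      p <- stats::predict(fit, newdata = data.frame(s = scores[te]),
                          type = "response")
      mean((p > 0.5) == (labels[te] == 1L))
    }, 1)
    list(mean_accuracy = mean(acc), accuracies = acc)
  })
}

#' Select the score cutoff maximizing classification accuracy
#'
#' Scores above the cutoff classify as cases. Candidates default to the
#' midpoints between sorted unique scores; ties in accuracy break toward
#' the smallest cutoff.
#'
#' @param scores Numeric scores.
#' @param labels Binary outcomes.
#' @param candidates Optional cutoff grid.
#' @return list(cutoff, accuracy).
#' @export
choose_cutoff <- function(scores, labels, candidates = NULL) {
  labels <- as.integer(as.logical(labels))
  u <- sort(unique(scores))
  if (is.null(candidates)) {
    candidates <- if (length(u) >= 2L) (utils::head(u, -1) + u[-1]) / 2 else u
  }
  stopifnot(length(candidates) >= 1L)
  acc <- vapply(candidates, function(cut)
    mean((scores > cut) == (labels == 1L)), 1)
  best <- min(candidates[acc == max(acc)])
  list(cutoff = best, accuracy = max(acc))
}
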