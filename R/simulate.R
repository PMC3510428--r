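#' Specification of a synthetic case-control cohort
#'
#' Defines the cohort the simulator draws: population controls under
#' Hardy-Weinberg equilibrium with block LD, and case classes of
#' increasing phenotypic extremity whose planted genetic load grows with
#' the class. Null SNPs are identically distributed in all classes; causal
#' SNPs shift their alternate-allele frequency in cases through a logistic
#' selection model whose per-allele log-odds in extremity class of rank r
#' (1 = least extreme case class) is
#' `effect_per_allele * class_load_multiplier^(r - 1)`.
#'
#' @param n_controls number of population controls
#' @param n_cases_per_class named integer vector of case counts, one per
#'   extremity class in increasing order of extremity
#' @param n_snps total SNPs simulated
#' @param n_causal number of causal SNPs (must be <= `n_snps`)
#' @param maf_range minor-allele-frequency interval in (0, 0.5] from which
#'   per-SNP MAFs are drawn uniformly
#' @param effect_per_allele log-odds increment per alternate allele at a
#'   causal SNP in the least extreme case class
#' @param class_load_multiplier factor scaling the causal log-odds per
#'   extremity class step (> 1 plants a class-graded genetic load)
#' @param baseline_prob baseline probability of case ascertainment for a
#'   subject carrying the population-average causal load (default 0.01).
#'   The extreme phenotype is rare, so the logistic intercept
#'   `qlogis(baseline_prob)` sits far below zero; in that regime logistic
#'   selection acts like exponential tilting and the per-allele log-odds
#'   translate into real allele-frequency shifts instead of saturating.
#' @param ld_block_size number of consecutive SNPs per LD block
#' @param ld_rho latent Gaussian within-block correlation in [0, 1)
#' @param missing_rate fraction of dosages set missing completely at random
#' @param seed integer seed fixing every output bit
#' @return an object of class `sim_spec`
#' @export
sim_spec <- function(n_controls = 1000,
                     n_cases_per_class = c("100-104" = 300,
                                           "105-109" = 150,
                                           "110+" = 50),
                     n_snps = 2000, n_causal = 40,
                     maf_range = c(0.05, 0.5),
                     effect_per_allele = 0.3,
                     class_load_multiplier = 1.5,
                     baseline_prob = 0.01,
                     ld_block_size = 10, ld_rho = 0.3,
                     missing_rate = 0, seed = 1) {
  spec <- list(n_controls = as.integer(n_controls),
               n_cases_per_class = n_cases_per_class,
               n_snps = as.integer(n_snps), n_causal = as.integer(n_causal),
               maf_range = maf_range,
               effect_per_allele = effect_per_allele,
               class_load_multiplier = class_load_multiplier,
               baseline_prob = baseline_prob,
               ld_block_size = as.integer(ld_block_size),
               ld_rho = ld_rho, missing_rate = missing_rate,
               seed = as.integer(seed))
  class(spec) <- "sim_spec"
  validate_sim_spec(spec)
}

validate_sim_spec <- function(spec) {
  with(spec, {
    if (n_controls < 1 || any(n_cases_per_class < 1))
      stop("all cohort class sizes must be >= 1")
    if (is.null(names(n_cases_per_class)) || anyDuplicated(names(n_cases_per_class)))
      stop("n_cases_per_class must have unique class names")
    if (n_causal > n_snps) stop("n_causal must be <= n_snps")
    if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
        maf_range[1] > maf_range[2])
      stop("maf_range must be an interval within (0, 0.5]")
    if (ld_rho < 0 || ld_rho >= 1) stop("ld_rho must be in [0, 1)")
    if (ld_block_size < 1) stop("ld_block_size must be >= 1")
    if (missing_rate < 0 || missing_rate >= 1)
      stop("missing_rate must be in [0, 1)")
    if (effect_per_allele < 0 || class_load_multiplier <= 0)
      stop("effect_per_allele must be >= 0 and class_load_multiplier > 0")
    if (baseline_prob <= 0 || baseline_prob >= 1)
      stop("baseline_prob must be in (0, 1)")
  })
  spec
}

# Draw n subjects' genotypes: latent exchangeable-Gaussian blocks
# thresholded at the HWE genotype quantiles, so marginal MAF is exact.
draw_genotypes <- function(n, maf, block, rho) {
  p <- length(maf)
  z <- matrix(stats::rnorm(n * p), n, p)
  if (rho > 0) {
    for (b in unique(block)) {
      idx <- which(block == b)
      shared <- stats::rnorm(n)
      z[, idx] <- sqrt(rho) * shared + sqrt(1 - rho) * z[, idx]
    }
  }
  q0 <- stats::qnorm((1 - maf)^2)                    # below: genotype 0
  q1 <- stats::qnorm((1 - maf)^2 + 2 * maf * (1 - maf))
  g <- matrix(0L, n, p)
  g <- g + (z > rep(q0, each = n)) + (z > rep(q1, each = n))
  storage.mode(g) <- "integer"
  g
}

#' Simulate a case-control cohort with planted effects
#'
#' Controls are a population sample: every SNP drawn under Hardy-Weinberg
#' at its MAF, with block LD induced by a latent Gaussian copula
#' (within-block correlation `ld_rho`) thresholded at the HWE genotype
#' quantiles. Cases of each extremity class are obtained by rejection
#' sampling from the same population: a drawn subject with causal dosages
#' `g` is accepted with probability
#' `plogis(qlogis(baseline_prob) + sum(beta_class * (g - 2 * maf)))`, a
#' logistic selection model centred at the population-average causal load.
#' Null SNPs therefore keep identical distributions in all classes while
#' causal alternate-allele frequencies rise with the class rank.
#'
#' @param spec a [sim_spec()]
#' @return a list with elements `genotypes` ([genotype_matrix()]),
#'   `phenotypes` (`phenotype_table`) and `truth` (list: `causal_snp_ids`,
#'   `maf`, per-class causal effects `beta`, and `expected_causal_freq`, a
#'   classes x causal-SNPs matrix of single-SNP approximate expected
#'   alternate-allele frequencies)
#' @export
simulate_cohort <- function(spec) {
  spec <- validate_sim_spec(spec)
  set.seed(spec$seed)
  p <- spec$n_snps
  maf <- stats::runif(p, spec$maf_range[1], spec$maf_range[2])
  block <- rep(seq_len(ceiling(p / spec$ld_block_size)),
               each = spec$ld_block_size)[seq_len(p)]
  causal <- sort(sample.int(p, spec$n_causal))
  classes <- names(spec$n_cases_per_class)
  n_class <- length(classes)
  beta <- spec$effect_per_allele *
    spec$class_load_multiplier^(seq_len(n_class) - 1)
  names(beta) <- classes

  controls <- draw_genotypes(spec$n_controls, maf, block, spec$ld_rho)

  alpha0 <- stats::qlogis(spec$baseline_prob)
  sample_cases <- function(n_needed, b) {
    # no planted load: selection is flat, cases are population draws
    if (length(causal) == 0 || b == 0)
      return(draw_genotypes(n_needed, maf, block, spec$ld_rho))
    out <- matrix(0L, 0, p)
    tries <- 0L
    batch <- max(ceiling(2 * n_needed / spec$baseline_prob / 100), 500L)
    while (nrow(out) < n_needed) {
      tries <- tries + 1L
      if (tries > 500L)
        stop("case rejection sampling failed to accept enough subjects; ",
             "baseline_prob or effect sizes may be infeasible")
      cand <- draw_genotypes(batch, maf, block, spec$ld_rho)
      eta <- as.vector(cand[, causal, drop = FALSE] %*% rep(b, length(causal))) -
        sum(b * 2 * maf[causal])
      keep <- stats::runif(nrow(cand)) < stats::plogis(alpha0 + eta)
      out <- rbind(out, cand[keep, , drop = FALSE])
    }
    out[seq_len(n_needed), , drop = FALSE]
  }
  cases <- lapply(seq_len(n_class), function(r)
    sample_cases(spec$n_cases_per_class[r], beta[r]))

  dosage <- do.call(rbind, c(list(controls), cases))
  n_total <- nrow(dosage)
  if (spec$missing_rate > 0)
    dosage[stats::runif(length(dosage)) < spec$missing_rate] <- NA
  subj <- sprintf("S%05d", seq_len(n_total))
  rownames(dosage) <- subj
  snp_ids <- sprintf("snp%05d", seq_len(p))
  snps <- data.frame(snp_id = snp_ids, chromosome = as.character(block),
                     position = seq_len(p), allele_ref = "A",
                     allele_alt = "G", stringsAsFactors = FALSE)
  colnames(dosage) <- snp_ids
  geno <- genotype_matrix(dosage, snps)

  cls <- c(rep("control", spec$n_controls),
           rep(classes, times = spec$n_cases_per_class))
  pheno <- phenotype_table(
    data.frame(subject_id = subj,
               label = ifelse(cls == "control", "control", "case"),
               sex = sample(c("F", "M"), n_total, replace = TRUE),
               extremity_class = cls, stringsAsFactors = FALSE),
    class_levels = c("control", classes))

  # single-SNP approximation: genotype-weighted logistic acceptance,
  # ignoring the load contributed by the other causal SNPs
  exp_freq <- t(vapply(seq_len(n_class), function(r) {
    vapply(causal, function(j) {
      pj <- maf[j]
      w <- c((1 - pj)^2, 2 * pj * (1 - pj), pj^2)
      acc <- stats::plogis(alpha0 + beta[r] * (0:2 - 2 * pj))
      sum((0:2) * w * acc) / (2 * sum(w * acc))
    }, numeric(1))
  }, numeric(length(causal))))
  dimnames(exp_freq) <- list(classes, snp_ids[causal])

  truth <- list(causal_snp_ids = snp_ids[causal], maf = stats::setNames(maf, snp_ids),
                beta = beta, expected_causal_freq = exp_freq,
                ld_block = stats::setNames(block, snp_ids))
  list(genotypes = geno, phenotypes = pheno, truth = truth)
}

#' Simulate genetic risk profiles with planted cluster structure
#'
#' Generates monotone nondecreasing mean profile curves in [0, 1], one per
#' cluster, separated by at least `separation` in sup-norm, and draws
#' observations by adding Gaussian noise clipped back to [0, 1]. Used as a
#' fixture with known labels for the profile clustering stage.
#'
#' @param n_clusters number of planted clusters
#' @param n_per_cluster observations per cluster
#' @param profile_length number of profile coordinates (nested-model index)
#' @param separation minimum sup-norm gap between cluster mean curves
#' @param noise_sd standard deviation of the additive noise
#' @param seed integer seed
#' @return list with `profiles` (matrix, rows = subjects) and `labels`
#'   (integer vector of true cluster indices)
#' @export
simulate_profiles <- function(n_clusters, n_per_cluster, profile_length,
                              separation, noise_sd, seed = 1) {
  stopifnot(n_clusters >= 1, n_per_cluster >= 1, profile_length >= 1,
            separation >= 0, noise_sd >= 0)
  top <- 0.95
  levels_ <- top - (n_clusters - seq_len(n_clusters)) * separation
  if (levels_[1] < 0)
    stop("infeasible: ", n_clusters, " cluster means separated by ",
         separation, " do not fit in [0, 1]")
  set.seed(seed)
  t_ <- seq_len(profile_length) / profile_length
  ramp <- 1 - (1 - t_)^2                      # monotone, ramp(1) = 1
  means <- outer(levels_, ramp)               # clusters x length
  labels <- rep(seq_len(n_clusters), each = n_per_cluster)
  profiles <- means[labels, , drop = FALSE] +
    matrix(stats::rnorm(length(labels) * profile_length, sd = noise_sd),
           length(labels), profile_length)
  profiles <- pmin(pmax(profiles, 0), 1)
  rownames(profiles) <- sprintf("P%04d", seq_along(labels))
  list(profiles = profiles, labels = labels)
}
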