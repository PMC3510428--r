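#' Dirichlet-multinomial Bayes factor for one SNP
#'
#' Evidence that the 3-level genotype distribution differs between cases
#' and controls. With Dirichlet(`alpha`) pseudocounts the marginal
#' likelihood of a count vector n is
#' `m(n; alpha) = Gamma(sum a)/Gamma(sum a + N) * prod Gamma(a_i + n_i)/Gamma(a_i)`
#' and the Bayes factor compares independent group distributions to a
#' shared one: `BF = m(case) * m(control) / m(pooled)`. The posterior
#' probability of association is `BF * pi / (BF * pi + 1 - pi)` for prior
#' probability `pi`. All computation is in log space.
#'
#' @param counts_case,counts_control integer vectors of genotype counts
#'   `(n0, n1, n2)`; missing genotypes are excluded before counting
#' @param alpha strictly positive Dirichlet pseudocounts, default uniform
#'   `c(1, 1, 1)`
#' @param prior prior probability of association `pi` in (0, 1); any fixed
#'   value yields the same SNP ranking
#' @return list with `bayes_factor`, `log_bf` and `posterior_prob_assoc`
#' @export
#' @examples
#' snp_bayes_factor(c(2, 0, 0), c(0, 0, 2))$bayes_factor  # 2.5
snp_bayes_factor <- function(counts_case, counts_control,
                             alpha = c(1, 1, 1), prior = 0.5) {
  stopifnot(length(counts_case) == length(alpha),
            length(counts_control) == length(alpha))
  if (any(counts_case < 0) || any(counts_control < 0))
    stop("genotype counts must be nonnegative")
  if (any(alpha <= 0)) stop("Dirichlet pseudocounts must be > 0")
  if (prior <= 0 || prior >= 1) stop("prior must be in (0, 1)")
  log_marg <- function(n) {
    lgamma(sum(alpha)) - lgamma(sum(alpha) + sum(n)) +
      sum(lgamma(alpha + n) - lgamma(alpha))
  }
  log_bf <- log_marg(counts_case) + log_marg(counts_control) -
    log_marg(counts_case + counts_control)
  post <- stats::plogis(log_bf + stats::qlogis(prior))
  list(bayes_factor = exp(log_bf), log_bf = log_bf,
       posterior_prob_assoc = post)
}

# genotype count table (n0, n1, n2) per column of a dosage matrix,
# missing excluded; returns 3 x p
genotype_counts <- function(dosage) {
  m <- vapply(0:2, function(g) colSums(dosage == g, na.rm = TRUE),
              numeric(ncol(dosage)))
  if (is.null(dim(m))) m <- matrix(m, nrow = 1)  # single-SNP panel
  t(m)
}

#' Per-SNP association scan
#'
#' Computes genotype count tables, Bayes factors and posterior
#' probabilities of association for every SNP in a cohort.
#'
#' @param genotypes a [genotype_matrix()]
#' @param phenotypes a `phenotype_table` covering the genotyped subjects
#' @inheritParams snp_bayes_factor
#' @return data frame of class `snp_association` with one row per SNP:
#'   counts, `log_bf`, `bayes_factor`, `posterior_prob_assoc`, ordered as
#'   the input genotypes
#' @export
snp_associations <- function(genotypes, phenotypes, alpha = c(1, 1, 1),
                             prior = 0.5) {
  phenotypes <- align_phenotypes(genotypes, phenotypes)
  is_case <- phenotypes$label == "case"
  if (!any(is_case) || !any(!is_case))
    stop("both cases and controls are required")
  cc <- genotype_counts(genotypes$dosage[is_case, , drop = FALSE])
  ct <- genotype_counts(genotypes$dosage[!is_case, , drop = FALSE])
  log_marg_mat <- function(n3p) {
    # n3p: 3 x p count matrix
    lgamma(sum(alpha)) - lgamma(sum(alpha) + colSums(n3p)) +
      colSums(lgamma(alpha + n3p)) - sum(lgamma(alpha))
  }
  log_bf <- log_marg_mat(cc) + log_marg_mat(ct) - log_marg_mat(cc + ct)
  out <- data.frame(
    snp_id = genotypes$snps$snp_id,
    chromosome = genotypes$snps$chromosome,
    position = genotypes$snps$position,
    case_n0 = cc[1, ], case_n1 = cc[2, ], case_n2 = cc[3, ],
    control_n0 = ct[1, ], control_n1 = ct[2, ], control_n2 = ct[3, ],
    log_bf = log_bf, bayes_factor = exp(log_bf),
    posterior_prob_assoc = stats::plogis(log_bf + stats::qlogis(prior)),
    stringsAsFactors = FALSE)
  class(out) <- c("snp_association", "data.frame")
  out
}

#' Squared Pearson correlation between two dosage vectors
#'
#' The LD measure used for pruning: r-squared of pairwise-complete
#' dosages. Defined as 0 when either vector is constant on the complete
#' pairs.
#'
#' @param g1,g2 dosage vectors of equal length (0/1/2/NA)
#' @return r-squared in [0, 1]
#' @export
genotype_r2 <- function(g1, g2) {
  if (length(g1) != length(g2))
    stop("dosage vectors differ in length (", length(g1), " vs ",
         length(g2), ")")
  ok <- !is.na(g1) & !is.na(g2)
  if (sum(ok) < 2) stop("fewer than 2 complete pairs")
  if (stats::sd(g1[ok]) == 0 || stats::sd(g2[ok]) == 0) return(0)
  stats::cor(g1[ok], g2[ok])^2
}

#' Rank SNPs by posterior probability of association and prune LD
#'
#' SNPs are sorted by descending posterior probability of association
#' (ties broken by chromosome, position, then snp_id, ascending) and a
#' single greedy pass walks down the list: a SNP is dropped iff its
#' genotype r-squared with any already-retained higher-ranked SNP exceeds
#' `r2_threshold`.
#'
#' @param associations a `snp_association` frame from [snp_associations()]
#'   (or any frame with `snp_id`, `posterior_prob_assoc`, `chromosome`,
#'   `position`)
#' @param genotypes the [genotype_matrix()] the associations were computed
#'   from (dosages are needed for r-squared)
#' @param r2_threshold LD threshold in (0, 1]; retained pairs never exceed
#'   it (default 0.7)
#' @return object of class `ranked_panel`: list with `snp_ids` (retained,
#'   in rank order), `pruned_out`, `r2_threshold` and the rank-ordered
#'   association frame
#' @export
rank_and_prune <- function(associations, genotypes, r2_threshold = 0.7) {
  if (r2_threshold <= 0 || r2_threshold > 1)
    stop("r2_threshold must be in (0, 1]")
  missing_snp <- setdiff(associations$snp_id, genotypes$snps$snp_id)
  if (length(missing_snp))
    stop("association snp_id(s) absent from genotypes: ",
         paste(utils::head(missing_snp, 5), collapse = ", "))
  ord <- order(-associations$posterior_prob_assoc, associations$chromosome,
               associations$position, associations$snp_id)
  ranked <- associations[ord, , drop = FALSE]
  dos <- genotypes$dosage[, ranked$snp_id, drop = FALSE]
  any_missing <- anyNA(dos)
  use <- if (any_missing) "pairwise.complete.obs" else "everything"
  r2 <- suppressWarnings(stats::cor(dos, use = use))^2
  r2[is.na(r2)] <- 0  # constant columns: r2 defined as 0
  keep <- logical(nrow(ranked))
  for (i in seq_len(nrow(ranked))) {
    keep[i] <- !any(r2[i, keep] > r2_threshold)
  }
  structure(list(snp_ids = ranked$snp_id[keep],
                 pruned_out = ranked$snp_id[!keep],
                 r2_threshold = r2_threshold,
                 ranking = ranked),
            class = "ranked_panel")
}

#' @export
print.ranked_panel <- function(x, ...) {
  cat("ranked_panel:", length(x$snp_ids), "SNPs retained,",
      length(x$pruned_out), "pruned at r2 >", x$r2_threshold, "\n")
  cat("  top of panel:",
      paste(utils::head(x$snp_ids, 5), collapse = ", "), "\n")
  invisible(x)
}
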