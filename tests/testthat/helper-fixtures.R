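# Small deterministic fixtures shared across test files.

# genotype matrix from a plain dosage matrix (subjects x SNPs)
make_geno <- function(dosage, subject_ids = NULL, snp_ids = NULL) {
  dosage <- as.matrix(dosage)
  if (is.null(subject_ids)) subject_ids <- sprintf("S%03d", seq_len(nrow(dosage)))
  if (is.null(snp_ids)) snp_ids <- sprintf("s%02d", seq_len(ncol(dosage)))
  rownames(dosage) <- subject_ids
  colnames(dosage) <- snp_ids
  genotype_matrix(dosage,
                  snps = data.frame(snp_id = snp_ids, chromosome = "1",
                                    position = seq_along(snp_ids),
                                    allele_ref = "A", allele_alt = "G",
                                    stringsAsFactors = FALSE))
}

# phenotype table with n_case cases ('100-104') then n_control controls,
# ids matching make_geno order (cases first)
make_pheno <- function(n_case, n_control,
                       subject_ids = sprintf("S%03d", seq_len(n_case + n_control))) {
  phenotype_table(data.frame(
    subject_id = subject_ids,
    label = rep(c("case", "control"), c(n_case, n_control)),
    sex = "unknown",
    extremity_class = rep(c("100-104", "control"), c(n_case, n_control)),
    stringsAsFactors = FALSE))
}

# exact rational Dirichlet-multinomial marginal for alpha = (1,1,1):
# m(n) = 2 * n0! n1! n2! / (N + 2)!   (independent oracle, factorial form)
exact_log_marg_unif <- function(n) {
  log(2) + sum(lfactorial(n)) - lfactorial(sum(n) + 2)
}
exact_log_bf_unif <- function(n_case, n_control) {
  exact_log_marg_unif(n_case) + exact_log_marg_unif(n_control) -
    exact_log_marg_unif(n_case + n_control)
}

# all genotype count tables (n0, n1, n2) with total <= n_max
enumerate_tables <- function(n_max) {
  g <- expand.grid(n0 = 0:n_max, n1 = 0:n_max, n2 = 0:n_max)
  as.matrix(g[rowSums(g) <= n_max, , drop = FALSE])
}

# strongly separating single-SNP probability tables (the 9/13 vs 2/13
# worked fixture), replicated over k panel SNPs
make_separating_tables <- function(k = 1) {
  case <- matrix(rep(c(9, 3, 1) / 13, k), nrow = 3,
                 dimnames = list(genotype = 0:2,
                                 snp_id = sprintf("s%02d", seq_len(k))))
  control <- matrix(rep(c(2, 4, 7) / 13, k), nrow = 3,
                    dimnames = dimnames(case))
  list(case = case, control = control)
}

# adjusted Rand index between two partitions (independent of the package's
# clustering code); falls back to a direct computation if mclust is absent
ari <- function(a, b) {
  if (requireNamespace("mclust", quietly = TRUE))
    return(mclust::adjustedRandIndex(a, b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab)); si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab))); n <- comb2(sum(tab))
  exp_ <- si * sj / n
  (sij - exp_) / ((si + sj) / 2 - exp_)
}
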