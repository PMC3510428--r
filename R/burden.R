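#' Read a risk-allele catalog
#'
#' A CSV/TSV table of disease-associated SNP alleles with columns
#' `snp_id`, `risk_allele` (the allele base, e.g. `"A"`), and
#' `disease_group`.
#'
#' @param path file path (comma-separated for `.csv`, otherwise tab)
#' @return data frame of class `risk_catalog`
#' @export
read_risk_catalog <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  risk_catalog(tab)
}

#' Validate / construct a risk-allele catalog
#' @param tab data frame with columns `snp_id`, `risk_allele`,
#'   `disease_group`
#' @return validated `risk_catalog` data frame
#' @export
risk_catalog <- function(tab) {
  req <- c("snp_id", "risk_allele", "disease_group")
  missing_cols <- setdiff(req, names(tab))
  if (length(missing_cols))
    stop("risk catalog lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  key <- paste(tab$snp_id, tab$disease_group, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (snp_id, disease_group) in catalog")
  class(tab) <- c("risk_catalog", "data.frame")
  tab
}

#' Intersect a risk-allele catalog with a genotype panel
#'
#' Restricts the catalog to SNPs present in the genotype matrix and
#' resolves each risk allele to the reference or alternate side of the
#' panel SNP. Entries whose risk allele matches neither panel allele
#' (e.g. a strand flip) are flagged and excluded by default.
#'
#' @param catalog a `risk_catalog`
#' @param genotypes a [genotype_matrix()]
#' @param drop_mismatched exclude allele-mismatched entries (default
#'   `TRUE`); `FALSE` keeps them with `side = NA`
#' @return list with `catalog` (matched subset with an added `side`
#'   column, `"ref"`/`"alt"`), `n_matched` (count of catalog SNPs found
#'   in the panel), and `mismatched` (flagged entries)
#' @export
intersect_catalog <- function(catalog, genotypes, drop_mismatched = TRUE) {
  idx <- match(catalog$snp_id, genotypes$snps$snp_id)
  present <- !is.na(idx)
  sub <- catalog[present, , drop = FALSE]
  meta <- genotypes$snps[idx[present], , drop = FALSE]
  side <- ifelse(sub$risk_allele == meta$allele_alt, "alt",
                 ifelse(sub$risk_allele == meta$allele_ref, "ref",
                        NA_character_))
  sub$side <- side
  mismatched <- sub[is.na(side), , drop = FALSE]
  if (nrow(mismatched) && drop_mismatched) {
    warning(nrow(mismatched),
            " catalog entr(y/ies) with risk allele matching neither ",
            "ref nor alt; excluded")
    sub <- sub[!is.na(side), , drop = FALSE]
  }
  rownames(sub) <- NULL
  list(catalog = sub, n_matched = sum(present), mismatched = mismatched)
}

#' Disease-allele burden rates by disease group
#'
#' For each disease group, each subject's burden is the dosage of risk
#' alleles summed over the group's SNPs (alternate dosage, or `2 -
#' dosage` when the risk allele is the reference), divided by the number
#' of the group's SNPs with a non-missing genotype in that subject — a
#' per-SNP rate in [0, 2] robust to missingness. Case and control mean
#' rates are compared by a seeded two-sided permutation test on the mean
#' difference. Groups with no matched SNPs are omitted with a warning. A
#' Bonferroni-adjusted p-value column is included for reference; the
#' primary presentation is unadjusted per-group, matching the stratified
#' analysis this reproduces.
#'
#' @param matched output of [intersect_catalog()] (or a `risk_catalog`
#'   data frame that already has a `side` column)
#' @param genotypes a [genotype_matrix()]
#' @param phenotypes a `phenotype_table`
#' @param n_perm permutations (default 999)
#' @param seed integer seed
#' @return data frame of class `burden_table`, one row per disease group:
#'   `n_snps`, `mean_case`, `mean_control`, `difference`, `p_value`,
#'   `p_bonferroni`
#' @export
burden_rates <- function(matched, genotypes, phenotypes, n_perm = 999,
                         seed = 1) {
  cat_ <- if (is.list(matched) && !is.data.frame(matched)) matched$catalog
          else matched
  if (!"side" %in% names(cat_))
    stop("catalog must carry a 'side' column; run intersect_catalog() first")
  phenotypes <- align_phenotypes(genotypes, phenotypes)
  is_case <- phenotypes$label == "case"
  if (!any(is_case) || !any(!is_case))
    stop("both classes must be non-empty")
  groups <- unique(cat_$disease_group)
  set.seed(seed)
  rows <- list()
  for (g in groups) {
    entries <- cat_[cat_$disease_group == g, , drop = FALSE]
    if (nrow(entries) == 0) {
      warning("disease group '", g, "' has no matched SNPs; omitted")
      next
    }
    dos <- genotypes$dosage[, entries$snp_id, drop = FALSE]
    risk <- dos
    flip <- entries$side == "ref"
    risk[, flip] <- 2L - dos[, flip, drop = FALSE]
    n_obs <- rowSums(!is.na(risk))
    rate <- rowSums(risk, na.rm = TRUE) / n_obs      # NaN if all missing
    ok <- n_obs > 0
    r <- rate[ok]; ic <- is_case[ok]
    diff_obs <- mean(r[ic]) - mean(r[!ic])
    perm <- replicate(n_perm, {
      s <- sample(ic)
      mean(r[s]) - mean(r[!s])
    })
    p <- (1 + sum(abs(perm) >= abs(diff_obs))) / (n_perm + 1)
    rows[[g]] <- data.frame(disease_group = g, n_snps = nrow(entries),
                            mean_case = mean(r[ic]),
                            mean_control = mean(r[!ic]),
                            difference = diff_obs, p_value = p,
                            stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no disease group with matched SNPs")
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(out$p_value * nrow(out), 1)
  rownames(out) <- NULL
  class(out) <- c("burden_table", "data.frame")
  out
}
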