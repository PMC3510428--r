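#' Laplace-smoothed genotype probability tables
#'
#' For each panel SNP and each class, estimates
#' `P(g | class) = (count_g + smoothing) / (class total + 3 * smoothing)`
#' over the non-missing genotypes of that SNP. These per-group
#' multinomials are the naive-Bayes building blocks of the nested models.
#'
#' @param panel character vector of SNP ids, in panel (rank) order
#' @param genotypes a [genotype_matrix()]
#' @param phenotypes a `phenotype_table`
#' @param smoothing positive Laplace pseudocount (default 1)
#' @return list with matrices `case` and `control`, each 3 x k with rows
#'   genotypes 0..2 and columns the panel SNPs; every column sums to 1
#' @export
fit_tables <- function(panel, genotypes, phenotypes, smoothing = 1) {
  if (smoothing <= 0) stop("smoothing must be > 0")
  missing_snp <- setdiff(panel, genotypes$snps$snp_id)
  if (length(missing_snp))
    stop("panel SNP(s) absent from genotypes: ",
         paste(utils::head(missing_snp, 5), collapse = ", "))
  phenotypes <- align_phenotypes(genotypes, phenotypes)
  is_case <- phenotypes$label == "case"
  if (!any(is_case) || !any(!is_case))
    stop("both classes must be non-empty")
  dos <- genotypes$dosage[, panel, drop = FALSE]
  smooth <- function(counts) {
    pr <- sweep(counts + smoothing, 2, colSums(counts) + 3 * smoothing, "/")
    dimnames(pr) <- list(genotype = 0:2, snp_id = panel)
    pr
  }
  list(case = smooth(genotype_counts(dos[is_case, , drop = FALSE])),
       control = smooth(genotype_counts(dos[!is_case, , drop = FALSE])))
}

# subjects x k matrix of per-SNP log likelihood ratios
# log P(g | case) - log P(g | control); 0 where the dosage is missing
llr_matrix <- function(tables, dosage) {
  k <- ncol(tables$case)
  llr_lookup <- log(tables$case) - log(tables$control)  # 3 x k
  out <- matrix(0, nrow(dosage), k,
                dimnames = list(rownames(dosage), colnames(tables$case)))
  for (g in 0:2) {
    hit <- !is.na(dosage) & dosage == g
    out[hit] <- rep(llr_lookup[g + 1, ], each = nrow(dosage))[hit]
  }
  out
}

#' Posterior probability of case status under a nested model
#'
#' Naive-Bayes posterior for model j (the first j panel SNPs):
#' `P(case | g) = prior * prod_j P(g_j | case) / normalising sum`,
#' evaluated in log space. SNPs with missing dosage for the subject are
#' skipped, so a subject with every panel SNP missing gets the class
#' prior back.
#'
#' @param tables probability tables from [fit_tables()]
#' @param dosages dosage vector for one subject over the panel (panel
#'   order), or a subjects x panel matrix
#' @param j model size: use the first `j` panel SNPs (default: all)
#' @param class_prior prior probability of case status (default 0.5,
#'   matched design)
#' @return posterior probability (vector if `dosages` is a matrix)
#' @export
posterior_case <- function(tables, dosages, j = ncol(tables$case),
                           class_prior = 0.5) {
  if (j < 1 || j > ncol(tables$case)) stop("model size j out of range")
  if (is.null(dim(dosages))) dosages <- matrix(dosages, 1)
  llr <- llr_matrix(lapply(tables, function(m) m[, seq_len(j), drop = FALSE]),
                    dosages[, seq_len(j), drop = FALSE])
  stats::plogis(rowSums(llr) + stats::qlogis(class_prior))
}

#' Sensitivity and specificity at a classification threshold
#'
#' Sensitivity is the fraction of cases with posterior >= `threshold`
#' (predicted case); specificity the fraction of controls with posterior
#' below it.
#'
#' @param posteriors per-subject posterior case probabilities
#' @param labels character vector `case`/`control`, aligned to `posteriors`
#' @param threshold classification threshold (default 0.5; posterior equal
#'   to the threshold is called "case")
#' @return named numeric vector `c(sensitivity, specificity)`
#' @export
sensitivity_specificity <- function(posteriors, labels, threshold = 0.5) {
  is_case <- labels == "case"
  if (!any(is_case) || !any(!is_case))
    stop("need at least one case and one control")
  pred_case <- posteriors >= threshold
  c(sensitivity = mean(pred_case[is_case]),
    specificity = mean(!pred_case[!is_case]))
}

# stratified fold assignment, deterministic given seed
make_folds <- function(is_case, folds, seed) {
  f <- integer(length(is_case))
  rs <- local({ set.seed(seed); list(case = sample(which(is_case)),
                                     control = sample(which(!is_case))) })
  f[rs$case] <- rep_len(seq_len(folds), length(rs$case))
  f[rs$control] <- rep_len(seq_len(folds), length(rs$control))
  f
}

# posterior matrix (subjects x model sizes 1..k) from cumulative LLR sums
posterior_curve <- function(tables, dosage, class_prior) {
  llr <- llr_matrix(tables, dosage)
  cum <- t(apply(llr, 1, cumsum))
  if (ncol(llr) == 1) cum <- matrix(cum, ncol = 1)
  stats::plogis(cum + stats::qlogis(class_prior))
}

#' Forward construction of nested models with a stopping rule
#'
#' Walks down the ranked panel adding one SNP at a time; model j uses
#' exactly the first j SNPs. At each size the balanced performance
#' `(sensitivity + specificity) / 2` is measured — by stratified k-fold
#' cross-validation (default) or resubstitution — and SNPs stop being
#' added once no improvement greater than `epsilon` over the best value
#' seen has occurred for `patience` consecutive additions. The selected
#' size `k_max` is the argmax of balanced performance over the explored
#' prefix. Final probability tables are refit on the full data for the
#' first `k_max` SNPs.
#'
#' @param panel ranked SNP ids (a `ranked_panel` or character vector)
#' @param genotypes a [genotype_matrix()]
#' @param phenotypes a `phenotype_table`
#' @param epsilon minimum improvement in balanced performance that resets
#'   the patience counter (default 0.001)
#' @param patience consecutive non-improving additions tolerated before
#'   stopping (default 10)
#' @param folds cross-validation folds (default 5); ignored under
#'   resubstitution
#' @param threshold classification threshold (default 0.5)
#' @param class_prior prior probability of case status (default 0.5)
#' @param smoothing Laplace pseudocount (default 1)
#' @param scheme `"cv"` (stratified k-fold, default) or `"resubstitution"`
#' @param seed integer seed for the fold assignment
#' @return object of class `nested_model_set`: list with `panel` (the
#'   first `k_max` SNP ids), `tables` (full-data tables over the panel),
#'   `k_max`, `class_prior`, `smoothing`, `threshold`, and `performance`
#'   (data frame over the explored prefix: `j`, `sensitivity`,
#'   `specificity`, `balanced`, `scheme`)
#' @export
forward_build <- function(panel, genotypes, phenotypes,
                          epsilon = 0.001, patience = 10, folds = 5,
                          threshold = 0.5, class_prior = 0.5,
                          smoothing = 1, scheme = c("cv", "resubstitution"),
                          seed = 1) {
  scheme <- match.arg(scheme)
  if (inherits(panel, "ranked_panel")) panel <- panel$snp_ids
  if (!length(panel)) stop("panel is empty")
  phenotypes <- align_phenotypes(genotypes, phenotypes)
  is_case <- phenotypes$label == "case"
  dos <- genotypes$dosage[, panel, drop = FALSE]
  n <- nrow(dos)

  if (scheme == "cv") {
    if (folds < 2) stop("folds must be >= 2 for cross-validation")
    if (folds > min(sum(is_case), sum(!is_case)))
      stop("folds exceeds the size of a class")
    fold <- make_folds(is_case, folds, seed)
    post <- matrix(NA_real_, n, length(panel))
    for (f in seq_len(folds)) {
      test <- fold == f
      tab <- fit_tables(panel, genotype_matrix(dos[!test, , drop = FALSE],
                                               genotypes$snps[match(panel, genotypes$snps$snp_id), ]),
                        phenotypes[!test, , drop = FALSE], smoothing)
      post[test, ] <- posterior_curve(tab, dos[test, , drop = FALSE],
                                      class_prior)
    }
  } else {
    tab <- fit_tables(panel, genotypes, phenotypes, smoothing)
    post <- posterior_curve(tab, dos, class_prior)
  }

  pred_case <- post >= threshold
  sens <- colMeans(pred_case[is_case, , drop = FALSE])
  spec <- colMeans(!pred_case[!is_case, , drop = FALSE])
  balanced <- (sens + spec) / 2

  # sequential stopping on the performance sequence
  best <- -Inf
  since_improve <- 0L
  explored <- length(panel)
  for (j in seq_along(panel)) {
    if (balanced[j] > best + epsilon) {
      best <- balanced[j]
      since_improve <- 0L
    } else {
      since_improve <- since_improve + 1L
      if (since_improve >= patience) { explored <- j; break }
    }
  }
  k_max <- which.max(balanced[seq_len(explored)])

  final_panel <- panel[seq_len(k_max)]
  final_tables <- fit_tables(final_panel, genotypes, phenotypes, smoothing)
  structure(list(panel = final_panel, tables = final_tables,
                 k_max = k_max, class_prior = class_prior,
                 smoothing = smoothing, threshold = threshold,
                 performance = data.frame(
                   j = seq_len(explored),
                   sensitivity = sens[seq_len(explored)],
                   specificity = spec[seq_len(explored)],
                   balanced = balanced[seq_len(explored)],
                   scheme = scheme, stringsAsFactors = FALSE),
                 explored = explored),
            class = "nested_model_set")
}

#' @export
print.nested_model_set <- function(x, ...) {
  perf <- x$performance[x$k_max, ]
  cat("nested_model_set: k_max =", x$k_max, "SNPs (explored",
      x$explored, ")\n")
  cat(sprintf("  %s sensitivity %.3f, specificity %.3f at threshold %.2f\n",
              perf$scheme, perf$sensitivity, perf$specificity, x$threshold))
  invisible(x)
}

#' Ensemble prediction over the nested models
#'
#' The unweighted mean over j = 1..k_max of the posterior case probability
#' under model j — more robust to false-positive SNPs in the panel than
#' the single largest model.
#'
#' @param model_set a `nested_model_set` from [forward_build()]
#' @param genotypes a [genotype_matrix()] of subjects to predict (must
#'   contain the panel SNPs), or a dosage matrix/vector in panel order
#' @return named vector of ensemble posterior probabilities in [0, 1]
#' @export
ensemble_predict <- function(model_set, genotypes) {
  dos <- panel_dosages(model_set, genotypes)
  post <- posterior_curve(model_set$tables, dos, model_set$class_prior)
  rowMeans(post)
}

# extract a subjects x panel dosage matrix from whatever the user passed
panel_dosages <- function(model_set, genotypes) {
  if (inherits(genotypes, "genotype_matrix")) {
    missing_snp <- setdiff(model_set$panel, genotypes$snps$snp_id)
    if (length(missing_snp))
      stop("panel SNP(s) absent from genotypes: ",
           paste(utils::head(missing_snp, 5), collapse = ", "))
    genotypes$dosage[, model_set$panel, drop = FALSE]
  } else if (is.null(dim(genotypes))) {
    matrix(genotypes, 1, dimnames = list("subject", NULL))
  } else {
    as.matrix(genotypes)
  }
}
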