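#' Fit the exceptional-longevity classifier family
#'
#' The top-level fitter tying the pipeline together: (1) every SNP is
#' scored with a Dirichlet-multinomial Bayes factor and ranked by its
#' posterior probability of association; (2) SNPs in strong LD with a
#' higher-ranked SNP are pruned; (3) nested naive-Bayes models are built
#' forward over the pruned panel, one SNP at a time, until sensitivity
#' and specificity stop improving; prediction averages the posterior case
#' probabilities of all nested models (the ensemble).
#'
#' @param genotypes a [genotype_matrix()]
#' @param phenotypes a `phenotype_table` covering the genotyped subjects
#' @param alpha Dirichlet pseudocounts for the per-SNP Bayes factor
#' @param prior prior probability of association used for ranking
#' @param r2_threshold LD pruning threshold (default 0.7)
#' @param class_prior prior probability of case status in the classifiers
#' @param smoothing Laplace pseudocount for the genotype tables
#' @param epsilon,patience,folds,scheme stopping-rule controls, see
#'   [forward_build()]
#' @param threshold classification threshold
#' @param seed integer seed (cross-validation folds)
#' @return object of class `longevity_model` wrapping the association
#'   scan (`associations`), the pruned `ranked_panel` (`panel`), and the
#'   selected `nested_model_set` (`model_set`)
#' @seealso [predict.longevity_model()], [compute_profiles()],
#'   [cluster_profiles()]
#' @export
longevity_model <- function(genotypes, phenotypes,
                            alpha = c(1, 1, 1), prior = 0.5,
                            r2_threshold = 0.7, class_prior = 0.5,
                            smoothing = 1, epsilon = 0.001, patience = 10,
                            folds = 5, threshold = 0.5,
                            scheme = c("cv", "resubstitution"), seed = 1) {
  scheme <- match.arg(scheme)
  cl <- match.call()
  phenotypes <- align_phenotypes(genotypes, phenotypes)
  assoc <- snp_associations(genotypes, phenotypes, alpha = alpha,
                            prior = prior)
  panel <- rank_and_prune(assoc, genotypes, r2_threshold = r2_threshold)
  model_set <- forward_build(panel, genotypes, phenotypes,
                             epsilon = epsilon, patience = patience,
                             folds = folds, threshold = threshold,
                             class_prior = class_prior,
                             smoothing = smoothing, scheme = scheme,
                             seed = seed)
  structure(list(associations = assoc, panel = panel,
                 model_set = model_set, call = cl),
            class = "longevity_model")
}

#' @export
print.longevity_model <- function(x, ...) {
  cat("Exceptional-longevity classifier family\n")
  cat("Call: ", deparse(x$call), "\n", sep = "")
  cat("  SNPs scanned:", nrow(x$associations),
      "| panel after LD pruning:", length(x$panel$snp_ids), "\n")
  print(x$model_set)
  invisible(x)
}

#' @export
summary.longevity_model <- function(object, top = 10, ...) {
  ms <- object$model_set
  perf <- ms$performance[ms$k_max, ]
  top_snps <- object$panel$ranking[
    match(ms$panel, object$panel$ranking$snp_id),
    c("snp_id", "chromosome", "position", "log_bf", "posterior_prob_assoc")]
  out <- list(n_snps = nrow(object$associations),
              n_panel = length(object$panel$snp_ids),
              n_pruned = length(object$panel$pruned_out),
              k_max = ms$k_max,
              sensitivity = perf$sensitivity,
              specificity = perf$specificity,
              scheme = perf$scheme,
              top_snps = utils::head(top_snps, top))
  class(out) <- "summary.longevity_model"
  out
}

#' @export
print.summary.longevity_model <- function(x, ...) {
  cat("Exceptional-longevity classifier family\n")
  cat(sprintf("  %d SNPs scanned; %d retained after LD pruning (%d pruned)\n",
              x$n_snps, x$n_panel, x$n_pruned))
  cat(sprintf("  selected model size k_max = %d (%s)\n", x$k_max, x$scheme))
  cat(sprintf("  sensitivity %.3f, specificity %.3f\n",
              x$sensitivity, x$specificity))
  cat("  model SNPs (rank order):\n")
  print(x$top_snps, row.names = FALSE)
  invisible(x)
}

#' Predict from a fitted longevity model
#'
#' @param object a `longevity_model`
#' @param genotypes a [genotype_matrix()] of subjects to predict; defaults
#'   would require the training data, so it must be supplied
#' @param type `"ensemble"` (mean posterior over the nested models,
#'   default), `"profile"` (the subjects x k_max matrix of per-model
#'   posteriors, i.e. the genetic risk profiles) or `"class"`
#'   (`case`/`control` call at the model threshold)
#' @param threshold classification threshold for `type = "class"`
#'   (defaults to the fitted threshold)
#' @param ... unused
#' @return numeric vector, matrix, or character vector according to `type`
#' @export
predict.longevity_model <- function(object, genotypes,
                                    type = c("ensemble", "profile", "class"),
                                    threshold = object$model_set$threshold,
                                    ...) {
  type <- match.arg(type)
  ms <- object$model_set
  if (type == "profile") return(compute_profiles(ms, genotypes))
  ens <- ensemble_predict(ms, genotypes)
  if (type == "ensemble") return(ens)
  ifelse(ens >= threshold, "case", "control")
}

#' Plot the performance curve of the forward search
#'
#' Sensitivity, specificity and balanced performance against nested model
#' size, with the selected `k_max` marked.
#'
#' @param x a `longevity_model` or `nested_model_set`
#' @param ... passed to [graphics::matplot()]
#' @return invisibly, the performance data frame
#' @export
plot.longevity_model <- function(x, ...) plot(x$model_set, ...)

#' @export
plot.nested_model_set <- function(x, ...) {
  p <- x$performance
  graphics::matplot(p$j, cbind(p$sensitivity, p$specificity, p$balanced),
                    type = "l", lty = c(2, 3, 1), col = c(4, 2, 1),
                    xlab = "nested model size j",
                    ylab = "performance", ylim = c(0, 1), ...)
  graphics::abline(v = x$k_max, col = "grey60", lty = 4)
  graphics::legend("bottomright",
                   c("sensitivity", "specificity", "balanced", "k_max"),
                   lty = c(2, 3, 1, 4), col = c(4, 2, 1, "grey60"),
                   bty = "n")
  invisible(p)
}
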