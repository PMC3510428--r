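#' Genetic risk profiles
#'
#' The per-subject curve of posterior case probability as SNPs are added
#' along the panel: row s, column j is the posterior under nested model j
#' for subject s. Subjects with every panel SNP missing sit at the class
#' prior across the whole profile.
#'
#' @param model_set a `nested_model_set` from [forward_build()]
#' @param genotypes a [genotype_matrix()] containing the panel SNPs, or a
#'   dosage matrix in panel order
#' @param subjects optional character vector restricting (and ordering)
#'   the subjects profiled; unknown ids are an error
#' @return numeric matrix subjects x k_max with values in [0, 1], class
#'   `risk_profiles`
#' @export
compute_profiles <- function(model_set, genotypes, subjects = NULL) {
  dos <- panel_dosages(model_set, genotypes)
  if (!is.null(subjects)) {
    idx <- match(subjects, rownames(dos))
    if (anyNA(idx))
      stop("unknown subject id(s): ",
           paste(utils::head(subjects[is.na(idx)], 5), collapse = ", "))
    dos <- dos[idx, , drop = FALSE]
  }
  out <- posterior_curve(model_set$tables, dos, model_set$class_prior)
  colnames(out) <- model_set$panel
  class(out) <- c("risk_profiles", class(out))
  out
}

# --- Bayesian model-based clustering of profiles -------------------------

# log marginal likelihood of one cluster under an independent
# normal-inverse-gamma model per profile coordinate:
#   x_i ~ N(mu, s2), mu | s2 ~ N(mu0, s2/kappa0), s2 ~ InvGamma(a0, b0)
# suff: list(n, sum, sumsq) with sum/sumsq vectors over coordinates
log_marginal_cluster <- function(suff, prior) {
  n <- suff$n
  xbar <- suff$sum / n
  ss <- pmax(suff$sumsq - n * xbar^2, 0)
  kn <- prior$strength + n
  an <- prior$var_shape + n / 2
  bn <- prior$var_scale + ss / 2 +
    prior$strength * n * (xbar - prior$mean)^2 / (2 * kn)
  sum(-n / 2 * log(2 * pi) + 0.5 * log(prior$strength / kn) +
        lgamma(an) - lgamma(prior$var_shape) +
        prior$var_shape * log(prior$var_scale) - an * log(bn))
}

#' Cluster genetic risk profiles into signatures
#'
#' Bayesian model-based agglomerative clustering. Each cluster is modelled
#' as an independent Gaussian per profile coordinate with a conjugate
#' normal-inverse-gamma prior; the marginal likelihood of a cluster is
#' available in closed form. Starting from singletons, the pair of
#' clusters whose merge has the largest Bayes factor (marginal likelihood
#' of the merged cluster over the product of the two separate ones) is
#' merged, as long as that Bayes factor is at least `min_bf`; ties break
#' on the lowest pair of current cluster indices. The mean profile of each
#' final cluster is its genetic signature.
#'
#' @param profiles numeric matrix, subjects x profile length, as produced
#'   by [compute_profiles()]
#' @param prior_mean prior mean of each coordinate (default 0.5, the
#'   uninformative midpoint of a probability profile)
#' @param prior_strength pseudo-observations behind the prior mean
#'   (default 1)
#' @param var_shape,var_scale inverse-gamma shape and scale of the
#'   coordinate variance prior (defaults 1 and 0.01)
#' @param min_bf minimum Bayes factor required to apply a merge (default
#'   1; `Inf` leaves every profile a singleton)
#' @return object of class `signature_clustering`: list with `partition`
#'   (named integer vector subject -> cluster), `cluster_means`,
#'   `log_marginal` (sum of per-cluster log marginal likelihoods),
#'   `merge_trace` (data frame of applied merges with log Bayes factors),
#'   `min_bf` and the prior
#' @export
cluster_profiles <- function(profiles, prior_mean = 0.5,
                             prior_strength = 1, var_shape = 1,
                             var_scale = 0.01, min_bf = 1) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 2) stop("need at least 2 profiles")
  if (anyNA(profiles)) stop("profiles must not contain missing values")
  prior <- list(mean = prior_mean, strength = prior_strength,
                var_shape = var_shape, var_scale = var_scale)
  n <- nrow(profiles)
  ids <- rownames(profiles)
  if (is.null(ids)) ids <- as.character(seq_len(n))

  # live clusters: sufficient statistics and member lists
  suff <- lapply(seq_len(n), function(i)
    list(n = 1, sum = profiles[i, ], sumsq = profiles[i, ]^2))
  members <- as.list(seq_len(n))
  logm <- vapply(suff, log_marginal_cluster, numeric(1), prior = prior)
  alive <- rep(TRUE, n)

  merge_suff <- function(a, b)
    list(n = a$n + b$n, sum = a$sum + b$sum, sumsq = a$sumsq + b$sumsq)

  # pairwise merge scores (log BF); NA for dead pairs
  score <- matrix(NA_real_, n, n)
  pair_score <- function(i, j)
    log_marginal_cluster(merge_suff(suff[[i]], suff[[j]]), prior) -
      logm[i] - logm[j]
  log_min_bf <- log(min_bf)
  if (log_min_bf < Inf) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      score[i, j] <- pair_score(i, j)
  }

  trace <- list()
  repeat {
    if (all(is.na(score))) break
    best <- max(score, na.rm = TRUE)
    if (best < log_min_bf) break
    hit <- which(score == best, arr.ind = TRUE)
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE][1, ]  # tie-break
    i <- hit[1]; j <- hit[2]
    trace[[length(trace) + 1L]] <-
      data.frame(cluster_a = i, cluster_b = j, log_bf = best)
    suff[[i]] <- merge_suff(suff[[i]], suff[[j]])
    members[[i]] <- c(members[[i]], members[[j]])
    logm[i] <- log_marginal_cluster(suff[[i]], prior)
    alive[j] <- FALSE
    score[j, ] <- NA; score[, j] <- NA
    for (k in which(alive)) {
      if (k == i) next
      s <- pair_score(min(i, k), max(i, k))
      score[min(i, k), max(i, k)] <- s
    }
  }

  live <- which(alive)
  partition <- integer(n)
  for (ci in seq_along(live)) partition[members[[live[ci]]]] <- ci
  names(partition) <- ids
  means <- t(vapply(live, function(i) suff[[i]]$sum / suff[[i]]$n,
                    numeric(ncol(profiles))))
  rownames(means) <- paste0("signature_", seq_along(live))
  structure(list(partition = partition, cluster_means = means,
                 log_marginal = sum(logm[live]),
                 merge_trace = if (length(trace)) do.call(rbind, trace)
                               else data.frame(cluster_a = integer(),
                                               cluster_b = integer(),
                                               log_bf = numeric()),
                 min_bf = min_bf, prior = prior),
            class = "signature_clustering")
}

#' @export
print.signature_clustering <- function(x, ...) {
  sizes <- table(x$partition)
  cat("signature_clustering:", length(sizes), "genetic signature(s) from",
      length(x$partition), "profiles\n")
  cat("  cluster sizes:", paste(as.integer(sizes), collapse = ", "), "\n")
  cat(sprintf("  total log marginal likelihood: %.2f (min BF %.3g)\n",
              x$log_marginal, x$min_bf))
  invisible(x)
}

#' @export
plot.signature_clustering <- function(x, ...) {
  graphics::matplot(t(x$cluster_means), type = "l", lty = 1,
                    xlab = "nested model size j",
                    ylab = "posterior probability of case status",
                    ylim = c(0, 1), ...)
  graphics::legend("bottomright", rownames(x$cluster_means),
                   lty = 1, col = seq_len(nrow(x$cluster_means)), bty = "n")
  invisible(x)
}

#' Association between genetic signatures and a phenotype
#'
#' Tests whether the clusters (signatures) differ in a phenotype — the
#' extremity class treated as an ordinal rank, or the age of onset of a
#' named disease — by a permutation test on the between-cluster variance
#' of mean ranks (the Kruskal-Wallis numerator).
#'
#' @param clustering a `signature_clustering`
#' @param phenotypes a `phenotype_table` with subject ids matching the
#'   clustered profiles
#' @param variable `"extremity_class"` or the name of an onset column
#'   (e.g. `"onset_dementia"`)
#' @param n_perm number of label permutations (default 1000)
#' @param seed integer seed for the permutations
#' @return object of class `signature_association`: per-cluster summary
#'   table (`n`, `median`), observed `statistic`, permutation `p.value`
#'   and `n_perm`
#' @export
signature_phenotype_association <- function(clustering, phenotypes,
                                            variable = "extremity_class",
                                            n_perm = 1000, seed = 1) {
  if (!variable %in% names(phenotypes))
    stop("variable '", variable, "' absent from phenotype table")
  idx <- match(names(clustering$partition), phenotypes$subject_id)
  if (anyNA(idx))
    stop("clustered subject(s) missing from phenotype table")
  vals <- phenotypes[[variable]][idx]
  if (is.factor(vals)) vals <- as.integer(vals)
  cl <- clustering$partition
  keep <- !is.na(vals)
  vals <- vals[keep]; cl <- cl[keep]
  sizes <- table(cl)
  if (sum(sizes >= 2) < 2)
    stop("need at least 2 clusters with at least 2 members each")

  between_rank_var <- function(v, g) {
    r <- rank(v)
    m <- tapply(r, g, mean)
    nn <- tapply(r, g, length)
    sum(nn * (m - mean(r))^2)
  }
  obs <- between_rank_var(vals, cl)
  set.seed(seed)
  perm <- replicate(n_perm, between_rank_var(vals, sample(cl)))
  p <- (1 + sum(perm >= obs)) / (n_perm + 1)
  summary_tab <- data.frame(cluster = as.integer(names(sizes)),
                            n = as.integer(sizes),
                            median = as.numeric(tapply(vals, cl, stats::median)))
  structure(list(summary = summary_tab, statistic = obs, p.value = p,
                 n_perm = n_perm, variable = variable),
            class = "signature_association")
}

#' @export
print.signature_association <- function(x, ...) {
  cat("signature-phenotype association (", x$variable, ")\n", sep = "")
  print(x$summary, row.names = FALSE)
  cat(sprintf("  between-cluster rank variance %.2f, permutation p = %.4g (N = %d)\n",
              x$statistic, x$p.value, x$n_perm))
  invisible(x)
}
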