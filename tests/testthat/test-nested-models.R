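test_that("Laplace-smoothed tables follow the closed form and normalize", {
  # 8 cases with genotype 0, 1 with 1, 1 with 2; 2/4/4 controls
  dos <- matrix(c(rep(0, 8), 1, 2, rep(0, 2), rep(1, 4), rep(2, 4)), ncol = 1)
  g <- make_geno(dos, snp_ids = "s01")
  p <- make_pheno(10, 10)
  tab <- fit_tables("s01", g, p, smoothing = 1)
  expect_equal(unname(tab$case[, "s01"]), c(9, 2, 2) / 13, tolerance = 1e-12)
  expect_equal(colSums(tab$case), c(s01 = 1), tolerance = 1e-12)
  expect_equal(colSums(tab$control), c(s01 = 1), tolerance = 1e-12)
  # a class with no observed genotypes falls back to the uniform prior
  dos2 <- matrix(c(rep(NA, 10), rep(0:1, 5)), ncol = 1)
  tab2 <- fit_tables("s01", make_geno(dos2, snp_ids = "s01"), p)
  expect_equal(unname(tab2$case[, 1]), rep(1 / 3, 3), tolerance = 1e-12)
})

test_that("posterior_case applies the two-class Bayes rule in log space", {
  tab <- make_separating_tables(1)
  # P(0|case) = 9/13, P(0|control) = 2/13, prior 1/2 -> 9/11
  expect_equal(unname(posterior_case(tab, 0)), 9 / 11, tolerance = 1e-12)
  # identical tables: likelihood cancels, posterior = class prior
  same <- list(case = tab$case, control = tab$case)
  expect_equal(unname(posterior_case(same, 2, class_prior = 0.3)), 0.3)
  # all panel SNPs missing: skip rule returns the class prior
  tab3 <- make_separating_tables(3)
  expect_equal(unname(posterior_case(tab3, c(NA, NA, NA),
                                     class_prior = 0.4)), 0.4)
  expect_error(posterior_case(tab, 0, j = 2), "out of range")
})

test_that("sensitivity and specificity count threshold calls correctly", {
  post <- c(0.9, 0.4, 0.2, 0.6)
  labels <- c("case", "case", "control", "control")
  ss <- sensitivity_specificity(post, labels, 0.5)
  expect_equal(unname(ss), c(0.5, 0.5))
  expect_equal(unname(sensitivity_specificity(c(1, 1, 0, 0), labels)),
               c(1, 1))
  # boundary convention: posterior equal to threshold is called "case"
  expect_equal(unname(sensitivity_specificity(rep(0.5, 4), labels, 0.5)),
               c(1, 0))
  expect_error(sensitivity_specificity(0.5, "case"), "at least one")
})

test_that("forward search stops after a perfectly separating first SNP", {
  set.seed(2)
  n <- 40
  sep <- c(rep(2, n / 2), rep(0, n / 2))            # perfect separator
  noise <- matrix(sample(0:2, n * 15, replace = TRUE), n, 15)
  g <- make_geno(cbind(sep, noise))
  p <- make_pheno(n / 2, n / 2)
  fit <- forward_build(colnames(g$dosage), g, p, patience = 5, folds = 4,
                       seed = 1)
  expect_equal(fit$k_max, 1L)
  expect_lte(fit$explored, 1 + 5)                   # patience-limited
  expect_equal(fit$performance$balanced[1], 1)
  # epsilon = 0 with patience = panel length explores the whole panel
  fit2 <- forward_build(colnames(g$dosage), g, p, epsilon = 0,
                        patience = 16, folds = 4, seed = 1)
  expect_equal(fit2$explored, 16L)
  expect_error(forward_build(colnames(g$dosage), g, p, folds = 30),
               "folds")
})

test_that("model j uses exactly the first j SNPs (nesting)", {
  tab <- list(
    case = matrix(c(0.7, 0.2, 0.1, 0.1, 0.2, 0.7), 3,
                  dimnames = list(genotype = 0:2, snp_id = c("a", "b"))),
    control = matrix(c(0.1, 0.2, 0.7, 0.7, 0.2, 0.1), 3,
                     dimnames = list(genotype = 0:2, snp_id = c("a", "b"))))
  p1 <- posterior_case(tab, c(0, 2), j = 1)
  p2 <- posterior_case(tab, c(0, 2), j = 2)
  # j = 1 ignores the second SNP entirely
  expect_equal(unname(p1), 0.7 / (0.7 + 0.1), tolerance = 1e-12)
  expect_equal(unname(p2), 0.7 * 0.7 / (0.7 * 0.7 + 0.1 * 0.1),
               tolerance = 1e-12)
})

test_that("ensemble prediction is the mean of the nested posteriors", {
  tab <- make_separating_tables(4)
  ms <- structure(list(panel = colnames(tab$case), tables = tab,
                       k_max = 4L, class_prior = 0.5, smoothing = 1,
                       threshold = 0.5),
                  class = "nested_model_set")
  dos <- c(0, 2, NA, 1)
  posts <- sapply(1:4, function(j) posterior_case(tab, dos, j = j))
  ens <- ensemble_predict(ms, dos)
  expect_equal(unname(ens), mean(posts), tolerance = 1e-12)
  expect_gte(ens, min(posts)); expect_lte(ens, max(posts))
  # identical tables give a flat ensemble at the class prior
  same <- structure(list(panel = "s01",
                         tables = list(case = tab$case[, 1, drop = FALSE],
                                       control = tab$case[, 1, drop = FALSE]),
                         k_max = 1L, class_prior = 0.5, smoothing = 1,
                         threshold = 0.5),
                    class = "nested_model_set")
  expect_equal(unname(ensemble_predict(same, 2)), 0.5)
})

test_that("predictions are invariant to consistent genotype relabeling", {
  sim <- simulate_cohort(sim_spec(
    n_controls = 120, n_cases_per_class = c("100-104" = 120),
    n_snps = 60, n_causal = 10, effect_per_allele = 0.8, seed = 4))
  panel <- colnames(sim$genotypes$dosage)[1:20]
  fit <- forward_build(panel, sim$genotypes, sim$phenotypes, folds = 4,
                       seed = 2)
  flipped <- sim$genotypes
  flipped$dosage <- 2L - flipped$dosage
  fit_f <- forward_build(panel, flipped, sim$phenotypes, folds = 4, seed = 2)
  expect_equal(fit_f$k_max, fit$k_max)
  expect_equal(ensemble_predict(fit_f, flipped),
               ensemble_predict(fit, sim$genotypes), tolerance = 1e-10)
})

test_that("fitted models serialize to JSON and back", {
  sim <- simulate_cohort(sim_spec(
    n_controls = 60, n_cases_per_class = c("100-104" = 60),
    n_snps = 30, n_causal = 5, effect_per_allele = 1, seed = 6))
  fit <- forward_build(colnames(sim$genotypes$dosage)[1:10],
                       sim$genotypes, sim$phenotypes, folds = 3, seed = 1)
  path <- file.path(tempdir(), "model.json")
  save_model(fit, path)
  fit2 <- load_model(path)
  expect_equal(fit2$panel, fit$panel)
  expect_equal(fit2$tables$case, fit$tables$case, tolerance = 1e-12)
  expect_equal(ensemble_predict(fit2, sim$genotypes),
               ensemble_predict(fit, sim$genotypes), tolerance = 1e-12)
})
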