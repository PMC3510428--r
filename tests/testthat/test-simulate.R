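test_that("simulation specs are validated", {
  expect_error(sim_spec(n_causal = 50, n_snps = 40), "n_causal")
  expect_error(sim_spec(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_spec(maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(sim_spec(ld_rho = 1), "ld_rho")
  expect_error(sim_spec(effect_per_allele = -1), "effect_per_allele")
})

test_that("fixing the seed fixes every output bit", {
  spec <- sim_spec(n_controls = 50, n_cases_per_class = c("100-104" = 30),
                   n_snps = 100, n_causal = 5, missing_rate = 0.02,
                   seed = 11)
  a <- simulate_cohort(spec)
  b <- simulate_cohort(spec)
  expect_identical(a$genotypes$dosage, b$genotypes$dosage)
  expect_identical(as.data.frame(a$phenotypes), as.data.frame(b$phenotypes))
  expect_identical(a$truth, b$truth)
})

test_that("with no causal SNPs, case-control differences behave as the null", {
  spec <- sim_spec(n_controls = 800,
                   n_cases_per_class = c("100-104" = 800),
                   n_snps = 400, n_causal = 0, ld_rho = 0, seed = 5)
  sim <- simulate_cohort(spec)
  is_case <- sim$phenotypes$label == "case"
  f_case <- colMeans(sim$genotypes$dosage[is_case, ]) / 2
  f_ctrl <- colMeans(sim$genotypes$dosage[!is_case, ]) / 2
  pbar <- (f_case + f_ctrl) / 2
  z <- (f_case - f_ctrl) /
    sqrt(pbar * (1 - pbar) * (1 / (2 * 800) + 1 / (2 * 800)))
  # two-proportion z statistics approximately standard normal across SNPs
  expect_lt(abs(mean(z)), 0.15)
  expect_gt(stats::sd(z), 0.85)
  expect_lt(stats::sd(z), 1.15)
})

test_that("LD blocks show high within-block and low between-block r2", {
  spec <- sim_spec(n_controls = 2000, n_cases_per_class = c("100-104" = 1),
                   n_snps = 100, n_causal = 0, ld_block_size = 10,
                   ld_rho = 0.9, seed = 3)
  sim <- simulate_cohort(spec)
  ctrl <- sim$genotypes$dosage[sim$phenotypes$label == "control", ]
  r2 <- stats::cor(ctrl)^2
  block <- sim$truth$ld_block
  same <- outer(block, block, "==")
  diag(same) <- NA
  within <- mean(r2[same & upper.tri(r2)], na.rm = TRUE)
  between <- mean(r2[!same & upper.tri(r2)], na.rm = TRUE)
  expect_gt(within, 0.3)
  expect_lt(between, 0.05)
})

test_that("planted causal allele frequencies increase with extremity class", {
  spec <- sim_spec(n_controls = 500,
                   n_cases_per_class = c("100-104" = 500, "105-109" = 500,
                                         "110+" = 500),
                   n_snps = 200, n_causal = 3, effect_per_allele = 1.0,
                   class_load_multiplier = 1.5, ld_rho = 0, seed = 9)
  sim <- simulate_cohort(spec)
  causal <- sim$truth$causal_snp_ids
  mean_freq <- sapply(levels(sim$phenotypes$extremity_class), function(cl) {
    idx <- sim$phenotypes$extremity_class == cl
    mean(colMeans(sim$genotypes$dosage[idx, causal, drop = FALSE]) / 2)
  })
  expect_true(all(diff(mean_freq) > 0))
  # the planted truth orders its expected frequencies the same way
  exp_by_class <- rowMeans(sim$truth$expected_causal_freq)
  expect_true(all(diff(exp_by_class) > 0))
})

test_that("null genotype frequencies agree across classes (chi-square calibration)", {
  spec <- sim_spec(n_controls = 600,
                   n_cases_per_class = c("100-104" = 600),
                   n_snps = 300, n_causal = 10, effect_per_allele = 0.8,
                   ld_block_size = 10, ld_rho = 0.3, seed = 13)
  sim <- simulate_cohort(spec)
  # restrict to blocks carrying no causal SNP: those SNPs are exactly null
  block <- sim$truth$ld_block
  causal_blocks <- unique(block[sim$truth$causal_snp_ids])
  null_ids <- names(block)[!block %in% causal_blocks]
  is_case <- sim$phenotypes$label == "case"
  pvals <- vapply(null_ids, function(s) {
    tab <- table(factor(sim$genotypes$dosage[, s], levels = 0:2), is_case)
    suppressWarnings(stats::chisq.test(tab)$p.value)
  }, numeric(1))
  expect_lt(abs(mean(pvals) - 0.5), 0.08)
  expect_lt(mean(pvals < 0.05), 0.10)
})

test_that("simulated profiles respect their planted structure", {
  # zero noise: members of a cluster are identical
  s0 <- simulate_profiles(2, 5, 20, separation = 0.3, noise_sd = 0, seed = 1)
  for (k in 1:2) {
    rows <- s0$profiles[s0$labels == k, ]
    expect_true(all(apply(rows, 2, function(col) length(unique(col)) == 1)))
  }
  # cluster means are monotone and separated in sup-norm
  m1 <- colMeans(s0$profiles[s0$labels == 1, ])
  m2 <- colMeans(s0$profiles[s0$labels == 2, ])
  expect_true(all(diff(m1) >= 0) && all(diff(m2) >= 0))
  expect_gte(max(abs(m1 - m2)), 0.3)
  # values always inside [0, 1] even with heavy noise
  s1 <- simulate_profiles(3, 20, 15, separation = 0.2, noise_sd = 0.5,
                          seed = 2)
  expect_true(all(s1$profiles >= 0 & s1$profiles <= 1))
  # infeasible separation errors
  expect_error(simulate_profiles(5, 2, 10, separation = 0.5, noise_sd = 0),
               "infeasible")
})
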