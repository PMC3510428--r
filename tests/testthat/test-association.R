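test_that("Dirichlet-multinomial Bayes factor matches hand-computed values", {
  # m(case) = m(control) = 1/6, m(pooled (2,0,2)) = 1/90 -> BF = 2.5
  r <- snp_bayes_factor(c(2, 0, 0), c(0, 0, 2))
  expect_equal(r$bayes_factor, 2.5, tolerance = 1e-12)
  expect_equal(r$posterior_prob_assoc, 2.5 / 3.5, tolerance = 1e-12)
  # empty data: marginals cancel exactly
  expect_equal(snp_bayes_factor(c(0, 0, 0), c(0, 0, 0))$bayes_factor, 1)
  # identical large samples favor the pooled model
  expect_lt(snp_bayes_factor(c(50, 30, 20), c(50, 30, 20))$bayes_factor, 1)
})

test_that("Bayes factor matches the exact factorial form on all tables with N <= 6", {
  tabs <- enumerate_tables(6)
  idx <- expand.grid(i = seq_len(nrow(tabs)), j = seq_len(nrow(tabs)))
  got <- mapply(function(i, j) snp_bayes_factor(tabs[i, ], tabs[j, ])$log_bf,
                idx$i, idx$j)
  want <- mapply(function(i, j) exact_log_bf_unif(tabs[i, ], tabs[j, ]),
                 idx$i, idx$j)
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("Bayes factor is exchangeable in group labels and stable at huge counts", {
  set.seed(1)
  for (rep in 1:20) {
    a <- rmultinom(1, sample(5:200, 1), c(0.5, 0.3, 0.2))[, 1]
    b <- rmultinom(1, sample(5:200, 1), c(0.2, 0.5, 0.3))[, 1]
    expect_equal(snp_bayes_factor(a, b)$log_bf,
                 snp_bayes_factor(b, a)$log_bf, tolerance = 1e-12)
  }
  big <- snp_bayes_factor(c(5e5, 3e5, 2e5), c(2e5, 3e5, 5e5))$log_bf
  expect_true(is.finite(big))
  expect_gt(big, 0)
})

test_that("posterior probability of association is monotone in BF and prior", {
  bfs <- c(0.1, 1, 10, 1000)
  post <- sapply(bfs, function(bf)
    snp_bayes_factor(c(2, 0, 0), c(0, 0, 2), prior = 0.5)$posterior_prob_assoc)
  # direct: posterior = BF*pi/(BF*pi + 1 - pi) increases with pi
  p1 <- snp_bayes_factor(c(2, 0, 0), c(0, 0, 2), prior = 0.1)$posterior_prob_assoc
  p2 <- snp_bayes_factor(c(2, 0, 0), c(0, 0, 2), prior = 0.9)$posterior_prob_assoc
  expect_lt(p1, p2)
  # and with BF at fixed prior, via increasingly discrepant tables
  r_small <- snp_bayes_factor(c(3, 1, 0), c(1, 1, 2))
  r_big <- snp_bayes_factor(c(30, 10, 0), c(10, 10, 20))
  expect_gt(r_big$log_bf, r_small$log_bf)
  expect_gt(r_big$posterior_prob_assoc, r_small$posterior_prob_assoc)
})

test_that("input validation for the Bayes factor", {
  expect_error(snp_bayes_factor(c(-1, 0, 0), c(0, 0, 0)), "nonnegative")
  expect_error(snp_bayes_factor(c(1, 0, 0), c(0, 0, 0), alpha = c(0, 1, 1)),
               "pseudocounts")
  expect_error(snp_bayes_factor(c(1, 0, 0), c(0, 0, 0), prior = 1), "prior")
})

test_that("genotype r2 follows the Pearson definition on dosages", {
  g <- c(0, 1, 2, 0, 1)
  expect_equal(genotype_r2(g, g), 1)
  expect_equal(genotype_r2(c(0, 0, 2, 2), c(0, 2, 0, 2)), 0)
  expect_equal(genotype_r2(g, 2 - g), 1)          # allele flip
  expect_equal(genotype_r2(g, rev(g)), genotype_r2(rev(g), g))  # symmetry
  # pairwise-complete handling of missing and constant vectors
  expect_equal(genotype_r2(c(0, 1, 2, NA), c(0, 1, 2, 0)), 1)
  expect_equal(genotype_r2(c(1, 1, 1, 1), c(0, 1, 2, 0)), 0)
  expect_error(genotype_r2(c(0, 1), c(0, 1, 2)), "length")
})

test_that("rank_and_prune applies the greedy rule with deterministic ties", {
  # A and B perfectly correlated, C orthogonal to both
  dos <- cbind(A = c(0, 0, 2, 2), B = c(0, 0, 2, 2), C = c(0, 2, 0, 2))
  g <- make_geno(dos, snp_ids = c("A", "B", "C"))
  assoc <- data.frame(snp_id = c("A", "B", "C"), chromosome = "1",
                      position = 1:3,
                      posterior_prob_assoc = c(0.9, 0.8, 0.7),
                      stringsAsFactors = FALSE)
  panel <- rank_and_prune(assoc, g, r2_threshold = 0.7)
  expect_equal(panel$snp_ids, c("A", "C"))
  expect_equal(panel$pruned_out, "B")
  # threshold 1.0 with no perfectly correlated pair keeps everything
  dos2 <- cbind(A = c(0, 1, 2, 0), B = c(0, 0, 2, 2), C = c(0, 2, 0, 2))
  panel2 <- rank_and_prune(assoc, make_geno(dos2, snp_ids = c("A", "B", "C")),
                           r2_threshold = 1.0)
  expect_equal(length(panel2$pruned_out), 0L)
  # equal posteriors break ties by (chromosome, position, snp_id)
  assoc$posterior_prob_assoc <- 0.5
  panel3 <- rank_and_prune(assoc, make_geno(dos2, snp_ids = c("A", "B", "C")),
                           r2_threshold = 1.0)
  expect_equal(panel3$snp_ids, c("A", "B", "C"))
  expect_error(rank_and_prune(assoc, g, r2_threshold = 0), "r2_threshold")
  expect_error(rank_and_prune(assoc, g, r2_threshold = 1.5), "r2_threshold")
})

test_that("planted causal SNPs rank above null SNPs on a simulated cohort", {
  sim <- simulate_cohort(sim_spec(
    n_controls = 400, n_cases_per_class = c("100-104" = 400),
    n_snps = 500, n_causal = 25, effect_per_allele = 0.6, ld_rho = 0.2,
    seed = 21))
  assoc <- snp_associations(sim$genotypes, sim$phenotypes)
  panel <- rank_and_prune(assoc, sim$genotypes)
  rank_of <- match(assoc$snp_id, panel$ranking$snp_id)
  is_causal <- assoc$snp_id %in% sim$truth$causal_snp_ids
  expect_lt(mean(rank_of[is_causal]), mean(rank_of[!is_causal]))
})
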