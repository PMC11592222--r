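test_that("weights panels are seeded, degenerate scales work, and QC integrates", {
  cfg <- sim_config(n_snps = 57, seed = 12)
  w1 <- sample_weights_panel(cfg)
  w2 <- sample_weights_panel(cfg)
  expect_identical(w1, w2)                       # determinism
  expect_equal(nrow(w1), 57L)

  w0 <- sample_weights_panel(sim_config(n_snps = 10, beta_sd = 0,
                                        seed = 12))
  expect_equal(w0$beta, rep(0, 10))

  wa <- sample_weights_panel(sim_config(n_snps = 10,
                                        ambiguous_fraction = 1,
                                        seed = 12))
  expect_equal(nrow(filter_ambiguous(wa)$weights), 0L)
  wh <- sample_weights_panel(sim_config(n_snps = 10,
                                        ambiguous_fraction = 0.5,
                                        seed = 12))
  expect_equal(length(filter_ambiguous(wh)$qc$removed_ambiguous), 5L)
})

test_that("genotype draws respect boundary frequencies and HWE proportions", {
  g0 <- simulate_genotypes(rep(0, 3), 20, seed = 13)
  expect_true(all(g0 == 0L))
  g2 <- simulate_genotypes(rep(1, 3), 20, seed = 13)
  expect_true(all(g2 == 2L))

  g <- simulate_genotypes(0.3, 5000, seed = 140)
  prop <- tabulate(g[, 1] + 1L, 3L) / 5000
  hwe <- c(0.49, 0.42, 0.09)
  se <- sqrt(hwe * (1 - hwe) / 5000)
  expect_true(all(abs(prop - hwe) < 3 * se))
})

test_that("cohorts are deterministic under seed, down to the written bytes", {
  cfg <- sim_config(n_snps = 12, n_cases = 40, n_controls = 40, seed = 15)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$genotypes, c2$genotypes)
  expect_identical(c1$phenotypes, c2$phenotypes)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_cohort(c1, d1); p2 <- write_cohort(c2, d2)
  for (f in c("vcf", "phenotypes", "weights"))
    expect_identical(readLines(p1[[f]]), readLines(p2[[f]]))
})

test_that("cohort composition and phenotype bookkeeping match the design", {
  cfg <- sim_config(n_snps = 15, n_cases = 120, n_controls = 130,
                    seed = 16)
  coh <- simulate_cohort(cfg)
  ph <- coh$phenotypes
  expect_equal(sum(ph$status == "case"), 120L)
  expect_equal(sum(ph$status == "control"), 130L)
  expect_equal(nrow(coh$genotypes), 250L)
  # phenotype traits recorded for cases only
  expect_true(all(is.na(ph$n_melanomas[ph$status == "control"])))
  expect_true(all(is.na(ph$eye_color[ph$status == "control"])))
  expect_true(all(!is.na(ph$age_at_sampling)))
  cases <- ph[ph$status == "case", ]
  expect_true(all(cases$n_melanomas[!is.na(cases$n_melanomas)] >= 1))
  expect_true(all(cases$n_melanomas[!is.na(cases$n_melanomas)] <= 4))
  # missingness injected at roughly the configured rates
  na_rate <- mean(is.na(cases$nevi))
  expect_gt(na_rate, 0.08); expect_lt(na_rate, 0.35)
})

test_that("null and non-null effects shape the case-control score difference", {
  # per_sd_or = 1 and all links zero: no systematic case-control gap
  set.seed(17)
  gaps <- replicate(30, {
    cfg <- sim_config(n_snps = 20, n_cases = 100, n_controls = 100,
                      per_sd_or = 1, mpm_gradient = 0,
                      phenotype_assoc = list(eye_light = 0, hair_blonde = 0,
                                             hair_red = 0, phototype_I_II = 0,
                                             sunburns_often = 0, nevi_gt50 = 0,
                                             family_history = 0),
                      seed = sample.int(1e6, 1))
    coh <- simulate_cohort(cfg)
    raw <- compute_prs(coh$genotypes, coh$weights)
    isc <- coh$phenotypes$status == "case"
    ss <- standardize_scores(raw, !isc)
    mean(ss$std[isc])
  })
  expect_lt(abs(mean(gaps)), 3 * sd(gaps) / sqrt(length(gaps)))

  # per_sd_or = 2: cases score higher in nearly every replicate
  set.seed(18)
  higher <- replicate(40, {
    cfg <- sim_config(n_snps = 20, n_cases = 500, n_controls = 500,
                      per_sd_or = 2, seed = sample.int(1e6, 1))
    coh <- simulate_cohort(cfg)
    raw <- compute_prs(coh$genotypes, coh$weights)
    isc <- coh$phenotypes$status == "case"
    mean(raw[isc]) > mean(raw[!isc])
  })
  expect_gte(mean(higher), 0.99)
})

test_that("the MPM count gradient raises the mean score with melanoma count", {
  cfg <- sim_config(n_snps = 30, n_cases = 2000, n_controls = 200,
                    mpm_gradient = log(2), seed = 19)
  coh <- simulate_cohort(cfg)
  raw <- compute_prs(coh$genotypes, coh$weights)
  isc <- coh$phenotypes$status == "case"
  ss <- standardize_scores(raw, !isc)
  nm <- coh$phenotypes$n_melanomas[isc]
  means <- tapply(ss$std[isc], nm, mean)
  # expectation increases with count category; adjacent sampling noise
  # tolerated by requiring an overall upward trend
  expect_gt(cor(as.numeric(names(means)), means, method = "spearman"), 0)
  expect_gt(means[["4"]], means[["1"]])
})

test_that("written cohorts round-trip through the VCF reader", {
  cfg <- sim_config(n_snps = 10, n_cases = 30, n_controls = 30, seed = 20)
  coh <- simulate_cohort(cfg)
  dir <- withr::local_tempdir()
  paths <- write_cohort(coh, dir)
  w <- read_weights(paths[["weights"]])
  res <- read_genotypes_vcf(paths[["vcf"]], w)
  expect_identical(unclass(res$genotypes)[rownames(coh$genotypes),
                                          colnames(coh$genotypes)],
                   unclass(coh$genotypes))
  expect_length(res$qc$snps_missing_from_vcf, 0L)

  ph <- read_phenotypes(paths[["phenotypes"]])
  expect_identical(ph$individual_id, coh$phenotypes$individual_id)

  truth <- jsonlite::read_json(paths[["truth"]])
  expect_equal(truth$config$per_sd_or, coh$truth$config$per_sd_or)
})

test_that("injected low depths are read back as missing under the depth filter", {
  cfg <- sim_config(n_snps = 6, n_cases = 15, n_controls = 15, seed = 21)
  coh <- simulate_cohort(cfg)
  dp <- matrix(100L, nrow(coh$genotypes), ncol(coh$genotypes))
  dp[3, 2] <- 12L; dp[7, 5] <- 29L
  dir <- withr::local_tempdir()
  paths <- write_cohort(coh, dir, dp = dp)
  res <- read_genotypes_vcf(paths[["vcf"]], coh$weights, min_depth = 30)
  got <- unclass(res$genotypes)[rownames(coh$genotypes),
                                colnames(coh$genotypes)]
  expect_true(is.na(got[3, 2]))
  expect_true(is.na(got[7, 5]))
  expect_equal(res$qc$genotypes_set_missing_low_depth, 2L)
  got[3, 2] <- unclass(coh$genotypes)[3, 2]
  got[7, 5] <- unclass(coh$genotypes)[7, 5]
  expect_identical(got, unclass(coh$genotypes))
})

test_that("injected phenotype missingness is excluded with correct per-variable counts", {
  cfg <- sim_config(n_snps = 8, n_cases = 200, n_controls = 50, seed = 22)
  coh <- simulate_cohort(cfg)
  ph <- coh$phenotypes
  isc <- ph$status == "case"
  raw <- compute_prs(coh$genotypes, coh$weights)
  ss <- standardize_scores(raw, !isc)
  s <- strata_summary(ss$std[isc], ph$nevi[isc])
  expect_equal(sum(s$n), sum(!is.na(ph$nevi[isc])))
  expect_setequal(s$stratum, c("<50", ">50"))
})

test_that("an unattainable prevalence errors rather than looping", {
  cfg <- sim_config(n_snps = 5, n_cases = 100, n_controls = 100,
                    per_sd_or = 1,
                    covariate_effects = c(age = 10, male = 0), seed = 23)
  expect_error(simulate_cohort(cfg), "unattainable")
})
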