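test_that("or_2x2 and wald_ci follow the closed forms", {
  expect_equal(or_2x2(70, 30, 49, 58), (70 * 58) / (30 * 49))
  expect_equal(round(or_2x2(70, 30, 49, 58), 2), 2.76)
  expect_equal(round(or_2x2(22, 5, 13, 14), 2), 4.74)
  expect_equal(or_2x2(10, 20, 10, 20), 1.0)

  expect_error(or_2x2(1, 0, 2, 3), "zero cell")
  expect_equal(or_2x2(1, 0, 2, 3, haldane = TRUE),
               (1.5 * 3.5) / (0.5 * 2.5))
  expect_error(or_2x2(1.5, 2, 3, 4), "non-negative integers")

  expect_equal(round(wald_ci(70, 30, 49, 58)[1], 2), 1.56)
  # z -> 0 limit collapses to the point estimate
  expect_equal(wald_ci(70, 30, 49, 58, level = 0),
               rep(or_2x2(70, 30, 49, 58), 2))
  expect_error(wald_ci(0, 30, 49, 58), "positive")

  set.seed(61)
  for (rep in 1:25) {
    tb <- sample(1:40, 4)
    got <- wald_ci(tb[1], tb[2], tb[3], tb[4])
    lor <- log(tb[1]) + log(tb[4]) - log(tb[2]) - log(tb[3])
    se <- sqrt(sum(1 / tb))
    expect_equal(got, exp(lor + c(-1, 1) * qnorm(0.975) * se),
                 tolerance = 1e-12)
  }
})

test_that("a saturated logistic fit on a 2x2 layout reproduces the cross-product OR", {
  layouts <- list(c(70, 30, 49, 58), c(22, 5, 13, 14), c(21, 6, 13, 14),
                  c(8, 11, 5, 17))
  for (tb in layouts) {
    y <- c(rep(1, tb[1]), rep(0, tb[2]), rep(1, tb[3]), rep(0, tb[4]))
    x <- cbind(1, c(rep(1, tb[1] + tb[2]), rep(0, tb[3] + tb[4])))
    fit <- fit_logistic(x, y)
    expect_equal(exp(coef(fit)[2]), or_2x2(tb[1], tb[2], tb[3], tb[4]),
                 tolerance = 1e-8, ignore_attr = TRUE)
    # Wald CI from the fit equals the closed-form interval
    s <- summary(fit)$table[2, ]
    expect_equal(c(s$or_low, s$or_high),
                 wald_ci(tb[1], tb[2], tb[3], tb[4]), tolerance = 1e-6)
  }
})

test_that("the IRLS optimum beats a brute-force coefficient grid on tiny data", {
  y <- c(0, 0, 1, 0, 1, 1, 0, 1)
  x <- cbind(1, c(-1.2, -0.8, -0.5, 0.1, 0.4, 0.9, -0.2, 1.5))
  fit <- fit_logistic(x, y)
  ll <- function(b) {
    p <- plogis(drop(x %*% b))
    sum(y * log(p) + (1 - y) * log1p(-p))
  }
  grid <- expand.grid(b0 = seq(-4, 4, 0.05), b1 = seq(-4, 4, 0.05))
  best <- max(apply(grid, 1, ll))
  expect_gte(fit$loglik + 1e-9, best)
  expect_equal(fit$loglik, ll(coef(fit)), tolerance = 1e-12)
  expect_true(fit$converged)
})

test_that("separation and singular designs are errors", {
  y <- c(0, 0, 0, 1, 1, 1)
  x_sep <- cbind(1, c(-3, -2, -1, 1, 2, 3))
  expect_error(fit_logistic(x_sep, y), "separation")
  x_sing <- cbind(1, 1:6, 2 * (1:6))
  expect_error(fit_logistic(x_sing, y), "singular")
  expect_error(fit_logistic(cbind(1, rnorm(4)), c(1, 1, 1, 1)),
               "both classes")
})

test_that("decile_or_table reproduces published crude odds ratios from counts", {
  ex <- expand_counts(melanoma_decile_counts(), reference = "5-6")
  tab <- decile_or_table(ex$labels, ex$outcome)
  ors <- setNames(tab$or, tab$group)
  expect_equal(round(ors[["10"]], 2), 2.76)
  expect_equal(round(ors[["9"]], 2), 1.71)
  expect_equal(round(ors[["8"]], 2), 1.26)
  expect_equal(round(ors[["1"]], 2), 0.39)
  expect_equal(round(tab$ci_low[tab$group == "10"], 2), 1.56)

  mp <- expand_counts(mpm_decile_counts(), reference = "1")
  mtab <- decile_or_table(mp$labels, mp$outcome)
  expect_equal(round(mtab$or[mtab$group == "10"], 2), 4.74)
  expect_equal(round(mtab$or[mtab$group == "5"], 2), 3.77)
})

test_that("empty groups are dropped with a warning and the reference must be populated", {
  lab <- factor(c("ref", "ref", "a", "a", "b", "b"),
                levels = c("ref", "a", "b", "ghost"))
  y <- c(0, 1, 0, 1, 1, 0)
  expect_warning(tab <- decile_or_table(lab, y), "ghost")
  expect_setequal(tab$group, c("a", "b"))
  lab2 <- factor(rep(c("a", "b"), 3), levels = c("ref", "a", "b"))
  expect_error(decile_or_table(lab2, y), "reference")
})

test_that("null decile CIs cover OR 1 at roughly the nominal rate", {
  set.seed(62)
  n_rep <- 150
  cover <- numeric(0)
  for (r in seq_len(n_rep)) {
    lab <- factor(sample(rep(1:5, each = 60)), levels = 1:5)
    y <- rbinom(300, 1, 0.5)
    tab <- decile_or_table(lab, y)
    cover <- c(cover, tab$ci_low <= 1 & tab$ci_high >= 1)
  }
  expect_gt(mean(cover), 0.92)
  expect_lt(mean(cover), 0.98)
})

test_that("per_sd_or recovers a simulated continuous effect and is scale-stable", {
  set.seed(63)
  n <- 3000
  z <- rnorm(n)
  y <- rbinom(n, 1, plogis(-0.2 + log(1.5) * z))
  est <- per_sd_or(z, y)
  expect_true(est$ci_low < 1.5 && 1.5 < est$ci_high)

  # rescaling the score then re-standardizing leaves the OR unchanged
  z2 <- standardize_scores(setNames(z * 7, seq_len(n)), y == 0)$std
  est2 <- per_sd_or(z2, y)
  # not identical (re-centering on controls), but the per-SD effect is
  # equivariant: coefficient scales exactly with the SD used
  raw_fit <- fit_logistic(cbind(1, z * 7), y)
  expect_equal(coef(raw_fit)[2] * 7, coef(attr(est, "fit"))[2],
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_gt(est2$or, 1)

  # null: OR near 1
  y0 <- rbinom(n, 1, 0.4)
  est0 <- per_sd_or(z, y0)
  expect_true(est0$ci_low < 1 && 1 < est0$ci_high)
})

test_that("decile ORs trend upward under a positive continuous effect", {
  set.seed(64)
  trend_pos <- 0L
  n_rep <- 25
  for (r in seq_len(n_rep)) {
    cfg <- sim_config(n_snps = 25, n_cases = 300, n_controls = 300,
                      per_sd_or = 1.8, seed = 7000 + r)
    coh <- simulate_cohort(cfg)
    raw <- compute_prs(coh$genotypes, coh$weights)
    isc <- coh$phenotypes$status == "case"
    ss <- standardize_scores(raw, !isc)
    sch <- decile_scheme(decile_cutpoints(ss$std[!isc]),
                         merge = list("5-6" = c(5, 6)), reference = "5-6")
    tab <- decile_or_table(assign_deciles(ss$std, sch), as.numeric(isc))
    dec <- as.numeric(sub("-.*", "", tab$group))
    if (cor(dec, tab$or, method = "spearman") > 0)
      trend_pos <- trend_pos + 1L
  }
  expect_gte(trend_pos / n_rep, 0.95)
})
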