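#' Configuration for the synthetic cohort generator
#'
#' Collects every knob of the generator with defaults chosen to emulate
#' the structure of a single-centre melanoma case-control series: 270
#' cases and 296 controls; a 57-SNP panel; cases older at sampling
#' (mean 56.8, SD 13.4) than controls (41.1, SD 12.1); sex frequencies
#' 42.6% male in cases and 72.3% in controls; about two thirds of cases
#' with more than one primary melanoma; and light-phenotype categories
#' whose prevalence increases with the standardized score.
#'
#' @param n_snps Number of SNPs in the panel. Default 57.
#' @param maf_range Range of the effect-allele frequency, drawn uniform
#'   per SNP. Default `c(0.1, 0.5)`.
#' @param beta_sd SD of per-SNP log odds ratios, drawn Normal(0,
#'   `beta_sd`). Default 0.15, a typical GWAS effect scale for common
#'   variants.
#' @param ambiguous_fraction Fraction of SNPs given a strand-ambiguous
#'   (A/T or C/G) allele pair, to exercise QC. Default 0.
#' @param n_cases,n_controls Cohort sizes. Defaults 270 and 296.
#' @param per_sd_or Odds ratio of case status per population-SD of the
#'   true score. Default 1.8, matching a case-control shift of about 0.6
#'   SD in the standardized score.
#' @param covariate_effects Named vector `c(age = , male = )` of log odds
#'   ratios entering the disease model.  When both are zero (default),
#'   age and sex are instead drawn conditional on the realized status
#'   with the case/control distributions above, reproducing the marginal
#'   imbalance of a referral series without a causal covariate effect.
#' @param mpm_gradient Log odds of each additional primary melanoma per
#'   SD of score. Default `log(1.41)`.
#' @param mpm_base Baseline log odds of an additional primary at score 0.
#'   Default `qlogis(0.6)`.
#' @param phenotype_assoc Named list of per-SD log odds ratios linking
#'   the score to the light-phenotype level of each categorical trait
#'   (`eye_light`, `hair_blonde`, `hair_red`, `phototype_I_II`,
#'   `sunburns_often`, `nevi_gt50`, `family_history`).
#' @param age_dx_slope Years of earlier diagnosis per SD of score.
#'   Default 2.5.
#' @param na_rates Named vector of missing-data rates injected into the
#'   case phenotype columns. Defaults follow the per-variable missing
#'   fractions of a real counseling questionnaire (about 13% for
#'   pigmentation traits, 21% for nevus counts).
#' @param ld_block_size,ld_block_r Optional block-LD mode: SNPs are laid
#'   out in consecutive blocks of `ld_block_size` whose members copy the
#'   block's first SNP with probability `ld_block_r` per genotype
#'   (approximate pairwise r-squared `ld_block_r^2`). Default: no LD,
#'   independent SNPs.
#' @param seed Integer seed driving every draw.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_snps = 57,
                       maf_range = c(0.1, 0.5),
                       beta_sd = 0.15,
                       ambiguous_fraction = 0,
                       n_cases = 270,
                       n_controls = 296,
                       per_sd_or = 1.8,
                       covariate_effects = c(age = 0, male = 0),
                       mpm_gradient = log(1.41),
                       mpm_base = stats::qlogis(0.6),
                       phenotype_assoc = list(eye_light = 0.45,
                                              hair_blonde = 0.37,
                                              hair_red = 0.85,
                                              phototype_I_II = 0.55,
                                              sunburns_often = 0.48,
                                              nevi_gt50 = 0.26,
                                              family_history = 0),
                       age_dx_slope = 2.5,
                       na_rates = c(eye_color = 0.126, hair_color = 0.126,
                                    phototype = 0.126, sunburns = 0.137,
                                    nevi = 0.207),
                       ld_block_size = 1L,
                       ld_block_r = 0,
                       seed = 1L) {
  stopifnot(n_snps >= 1, length(maf_range) == 2L,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            beta_sd >= 0, ambiguous_fraction >= 0, ambiguous_fraction <= 1,
            n_cases + n_controls >= 20, per_sd_or > 0,
            mpm_gradient >= 0, ld_block_size >= 1,
            ld_block_r >= 0, ld_block_r <= 1)
  structure(as.list(environment()), class = "sim_config")
}

# one seed per documented substream so adding draws to one stream never
# perturbs another
substream <- function(seed, label) {
  offsets <- c(weights = 101L, genotypes = 211L, status = 307L,
               phenotypes = 401L, vcf = 503L)
  set.seed((as.integer(seed) %% 1000000L) * 1009L + offsets[[label]])
}

#' Draw a random per-SNP weights panel
#'
#' Random biallelic SNPs on chromosomes 1-22 with effect sizes drawn
#' Normal(0, `beta_sd`) and a configurable fraction of strand-ambiguous
#' allele pairs.  Effect-allele frequencies are attached as attribute
#' `"freq"`.
#'
#' @param config A `sim_config`.
#' @return A `prs_weights` table of `config$n_snps` rows.
#' @export
sample_weights_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  substream(config$seed, "weights")
  p <- config$n_snps
  n_amb <- round(config$ambiguous_fraction * p)
  amb <- seq_len(p) <= n_amb   # deterministic placement, random alleles
  pairs_amb <- list(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))
  pairs_ok <- list(c("A", "C"), c("A", "G"), c("C", "A"), c("C", "T"),
                   c("G", "A"), c("G", "T"), c("T", "C"), c("T", "G"))
  alle <- t(vapply(seq_len(p), function(i) {
    if (amb[i]) pairs_amb[[sample.int(4L, 1L)]]
    else pairs_ok[[sample.int(8L, 1L)]]
  }, character(2)))
  w <- data.frame(snp_id = sprintf("rs%06d", seq_len(p)),
                  chrom = as.character(sample.int(22L, p, replace = TRUE)),
                  pos = sample.int(5e7L, p, replace = FALSE),
                  effect_allele = alle[, 1L],
                  other_allele = alle[, 2L],
                  beta = stats::rnorm(p, 0, config$beta_sd),
                  stringsAsFactors = FALSE)
  w <- validate_weights(w)
  attr(w, "freq") <- stats::runif(p, config$maf_range[1],
                                  config$maf_range[2])
  w
}

#' Simulate Hardy-Weinberg genotype dosages
#'
#' Independent dosages `Binomial(2, freq_j)` per individual and SNP, the
#' genotype distribution implied by Hardy-Weinberg equilibrium at each
#' effect-allele frequency.
#'
#' @param freqs Effect-allele frequency per SNP, each in \[0, 1\].
#' @param n Number of individuals.
#' @param seed Integer seed.
#' @param snp_ids,individual_ids Optional dimnames.
#' @return A `prs_genotypes` matrix, `n` x `length(freqs)`.
#' @export
simulate_genotypes <- function(freqs, n, seed = 1L,
                               snp_ids = NULL, individual_ids = NULL) {
  stopifnot(all(freqs >= 0), all(freqs <= 1), n >= 1)
  set.seed(as.integer(seed))
  draw_genotypes(freqs, n, snp_ids, individual_ids)
}

# raw draw on the current RNG state (no reseeding), shared with the
# cohort simulator
draw_genotypes <- function(freqs, n, snp_ids = NULL,
                           individual_ids = NULL,
                           ld_block_size = 1L, ld_block_r = 0) {
  p <- length(freqs)
  dos <- matrix(stats::rbinom(n * p, 2L, rep(freqs, each = n)),
                nrow = n, ncol = p)
  if (ld_block_size > 1L && ld_block_r > 0) {
    block <- (seq_len(p) - 1L) %/% ld_block_size
    for (b in unique(block)) {
      members <- which(block == b)
      if (length(members) < 2L) next
      anchor <- dos[, members[1L]]
      for (j in members[-1L]) {
        copy <- stats::runif(n) < ld_block_r
        dos[copy, j] <- anchor[copy]
      }
    }
  }
  if (is.null(snp_ids)) snp_ids <- sprintf("rs%06d", seq_len(p))
  if (is.null(individual_ids))
    individual_ids <- sprintf("ind_%05d", seq_len(n))
  dimnames(dos) <- list(individual_ids, snp_ids)
  new_genotypes(dos)
}

#' Simulate a retrospective case-control cohort
#'
#' Generates a full synthetic study: a weights panel, Hardy-Weinberg
#' genotypes, and a phenotype table.  Disease status follows a logistic
#' model in the standardized true score (`logit p = alpha +
#' log(per_sd_or) * z` plus any causal covariate terms); the intercept
#' `alpha` is tuned by bisection so the expected case fraction matches
#' the target cohort composition, and individuals are then sampled until
#' exactly `n_cases` cases and `n_controls` controls are collected
#' (retrospective design - odds ratios, not risks, are the estimands).
#' Cases additionally receive a primary-melanoma count (1 to 4+) with a
#' score-dependent gradient, score-linked categorical phenotypes, an age
#' at diagnosis decreasing with the score, and missing phenotype values
#' injected at questionnaire-like rates.  Phenotype traits are recorded
#' for cases only, as in a referral series with anonymous blood-donor
#' controls.
#'
#' @param config A `sim_config`.
#' @return A `prs_cohort` list: `weights`, `genotypes`, `phenotypes`
#'   (data frame with columns `individual_id`, `status`,
#'   `age_at_sampling`, `age_at_diagnosis`, `sex`, `eye_color`,
#'   `hair_color`, `phototype`, `sunburns`, `nevi`, `family_history`,
#'   `n_melanomas`), and `truth` (generating parameters, tuned alpha,
#'   population score mean/SD, per-SNP frequencies, VCF strand
#'   orientation flags).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  weights <- sample_weights_panel(config)
  freqs <- attr(weights, "freq")
  beta <- weights$beta
  mu_score <- sum(beta * 2 * freqs)
  var_score <- sum(beta^2 * 2 * freqs * (1 - freqs))
  if (config$ld_block_size > 1L && config$ld_block_r > 0) {
    # analytic variance ignores block LD; estimate empirically instead
    substream(config$seed, "genotypes")
    gg <- draw_genotypes(freqs, 2000L, weights$snp_id,
                         ld_block_size = config$ld_block_size,
                         ld_block_r = config$ld_block_r)
    sc <- drop(matrix(as.numeric(gg), nrow(gg)) %*% beta)
    mu_score <- mean(sc); var_score <- stats::var(sc)
  }
  eff <- log(config$per_sd_or)
  if (var_score == 0 && eff != 0)
    stop("score has zero variance: a nonzero per-SD effect is unattainable")
  sd_score <- sqrt(var_score)

  causal_cov <- any(config$covariate_effects != 0)
  target <- config$n_cases / (config$n_cases + config$n_controls)

  # tune alpha by bisection on the expected case fraction, using a
  # normal approximation draw of the standardized score
  substream(config$seed, "status")
  ztune <- stats::rnorm(20000L)
  cov_tune <- if (causal_cov) {
    age <- stats::rnorm(20000L, 48, 14)
    male <- stats::rbinom(20000L, 1L, 0.5)
    config$covariate_effects[["age"]] * age +
      config$covariate_effects[["male"]] * male
  } else 0
  f <- function(a) mean(stats::plogis(a + eff * ztune + cov_tune)) - target
  lo <- -30; hi <- 30
  if (f(lo) > 0 || f(hi) < 0)
    stop("unattainable case prevalence given the configured effects")
  for (it in 1:80) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  alpha <- (lo + hi) / 2

  n_total <- config$n_cases + config$n_controls
  batch <- max(n_total, 200L)
  dos_list <- list(); status_all <- integer()
  age_all <- numeric(); male_all <- integer()
  n_case_got <- 0L; n_ctrl_got <- 0L; tries <- 0L
  substream(config$seed, "genotypes")
  repeat {
    tries <- tries + 1L
    if (tries > 50L)
      stop("unattainable case prevalence given the configured effects: ",
           "quota not filled after bounded retries")
    g <- draw_genotypes(freqs, batch, weights$snp_id,
                        ld_block_size = config$ld_block_size,
                        ld_block_r = config$ld_block_r)
    score <- drop(matrix(as.numeric(g), nrow(g)) %*% beta)
    z <- if (sd_score > 0) (score - mu_score) / sd_score else
      rep(0, length(score))
    lin <- alpha + eff * z
    if (causal_cov) {
      age_b <- stats::rnorm(batch, 48, 14)
      male_b <- stats::rbinom(batch, 1L, 0.5)
      lin <- lin + config$covariate_effects[["age"]] * age_b +
        config$covariate_effects[["male"]] * male_b
    } else {
      age_b <- rep(NA_real_, batch); male_b <- rep(NA_integer_, batch)
    }
    st <- stats::rbinom(batch, 1L, stats::plogis(lin))
    need_case <- config$n_cases - n_case_got
    need_ctrl <- config$n_controls - n_ctrl_got
    take <- c(which(st == 1L)[seq_len(min(need_case, sum(st == 1L)))],
              which(st == 0L)[seq_len(min(need_ctrl, sum(st == 0L)))])
    if (length(take)) {
      dos_list[[length(dos_list) + 1L]] <- unclass(g)[take, , drop = FALSE]
      status_all <- c(status_all, st[take])
      age_all <- c(age_all, age_b[take])
      male_all <- c(male_all, male_b[take])
      n_case_got <- n_case_got + sum(st[take] == 1L)
      n_ctrl_got <- n_ctrl_got + sum(st[take] == 0L)
    }
    if (n_case_got == config$n_cases && n_ctrl_got == config$n_controls)
      break
  }

  ord <- order(-status_all)       # cases first, stable
  dos <- do.call(rbind, dos_list)[ord, , drop = FALSE]
  status <- status_all[ord]
  age <- age_all[ord]; male <- male_all[ord]
  ids <- ifelse(status == 1L,
                sprintf("case_%04d", cumsum(status == 1L)),
                sprintf("ctrl_%04d", cumsum(status == 0L)))
  rownames(dos) <- ids
  genotypes <- new_genotypes(dos)
  score <- drop(matrix(as.numeric(genotypes), nrow(genotypes)) %*% beta)
  z <- if (sd_score > 0) (score - mu_score) / sd_score else
    rep(0, length(score))

  substream(config$seed, "phenotypes")
  n <- length(status)
  is_case <- status == 1L
  if (!causal_cov) {
    age <- ifelse(is_case, stats::rnorm(n, 56.8, 13.4),
                  stats::rnorm(n, 41.1, 12.1))
    male <- ifelse(is_case, stats::rbinom(n, 1L, 0.426),
                   stats::rbinom(n, 1L, 0.723))
  }
  pa <- config$phenotype_assoc
  bern <- function(base_p, lor) {
    p <- stats::plogis(stats::qlogis(base_p) + lor * z)
    as.integer(stats::runif(n) < p)
  }
  eye <- ifelse(bern(0.53, pa$eye_light) == 1L, "light", "dark")
  red <- bern(0.089, pa$hair_red)
  blonde <- bern(0.373 / (1 - 0.089), pa$hair_blonde)
  hair <- ifelse(red == 1L, "red",
                 ifelse(blonde == 1L, "blonde", "brown/black"))
  photo <- ifelse(bern(0.53, pa$phototype_I_II) == 1L, "I-II", "III-IV")
  sunb <- ifelse(bern(0.558, pa$sunburns_often) == 1L, "often",
                 "rarely/never")
  nevi <- ifelse(bern(0.463, pa$nevi_gt50) == 1L, ">50", "<50")
  famh <- ifelse(bern(0.604, pa$family_history) == 1L, "yes", "no")

  # primary-melanoma count: sequential logistic steps, capped at 4+
  p_more <- stats::plogis(config$mpm_base + config$mpm_gradient * z)
  n_mel <- rep(NA_integer_, n)
  n_mel[is_case] <- 1L
  for (k in 1:3) {
    grow <- is_case & !is.na(n_mel) & n_mel == k &
      stats::runif(n) < p_more
    n_mel[grow] <- k + 1L
  }
  age_dx <- ifelse(is_case,
                   49.6 - config$age_dx_slope * z +
                     stats::rnorm(n, 0, 14),
                   NA_real_)

  pheno <- data.frame(individual_id = ids,
                      status = ifelse(is_case, "case", "control"),
                      age_at_sampling = round(age, 1),
                      age_at_diagnosis = round(age_dx, 1),
                      sex = ifelse(male == 1L, "M", "F"),
                      eye_color = eye, hair_color = hair,
                      phototype = photo, sunburns = sunb, nevi = nevi,
                      family_history = famh, n_melanomas = n_mel,
                      stringsAsFactors = FALSE)
  pheno_cols <- c("age_at_diagnosis", "eye_color", "hair_color",
                  "phototype", "sunburns", "nevi", "family_history",
                  "n_melanomas")
  pheno[!is_case, pheno_cols] <- NA
  for (col in names(config$na_rates)) {
    hit <- is_case & stats::runif(n) < config$na_rates[[col]]
    pheno[hit, col] <- NA
  }

  substream(config$seed, "vcf")
  ref_is_effect <- stats::runif(nrow(weights)) < 0.5

  structure(list(weights = weights, genotypes = genotypes,
                 phenotypes = pheno,
                 truth = list(config = config, alpha = alpha,
                              score_mean = mu_score, score_sd = sd_score,
                              freq = freqs,
                              per_sd_log_or = eff,
                              vcf_ref_is_effect = ref_is_effect)),
            class = "prs_cohort")
}

#' @export
print.prs_cohort <- function(x, ...) {
  cat("Synthetic case-control cohort:",
      sum(x$phenotypes$status == "case"), "cases,",
      sum(x$phenotypes$status == "control"), "controls,",
      nrow(x$weights), "SNPs\n")
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Emits the three pipeline inputs plus the generating truth: a VCF
#' v4.2 with GT and DP per sample, a phenotype TSV, a weights TSV, and a
#' JSON file of the generating parameters.  Per-SNP VCF strand
#' orientation (whether REF is the effect or the other allele) follows
#' the flags drawn at simulation time, so roughly half the sites
#' exercise the dosage flip on re-reading.
#'
#' @param cohort A `prs_cohort`.
#' @param dir Output directory (created if needed).
#' @param dp Either a single depth written for every genotype (default
#'   100) or a matrix of per-individual x per-SNP depths matching the
#'   dosage matrix.
#' @return Named character vector of the four file paths.
#' @export
write_cohort <- function(cohort, dir, dp = 100L) {
  stopifnot(inherits(cohort, "prs_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- cohort$weights
  g <- cohort$genotypes
  paths <- c(weights = file.path(dir, "weights.tsv"),
             vcf = file.path(dir, "genotypes.vcf"),
             phenotypes = file.path(dir, "phenotypes.tsv"),
             truth = file.path(dir, "truth.json"))
  write_weights(w, paths[["weights"]])

  if (is.matrix(dp)) {
    stopifnot(all(dim(dp) == dim(g)))
    dpm <- dp
  } else {
    dpm <- matrix(as.integer(dp), nrow(g), ncol(g))
  }
  ref_is_effect <- cohort$truth$vcf_ref_is_effect
  ord <- order(w$chrom, w$pos)
  lines <- c("##fileformat=VCFv4.2",
             "##source=melprs_synthetic_cohort",
             paste0("##FORMAT=<ID=GT,Number=1,Type=String,",
                    "Description=\"Genotype\">"),
             paste0("##FORMAT=<ID=DP,Number=1,Type=Integer,",
                    "Description=\"Read depth\">"),
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                     "FILTER", "INFO", "FORMAT", rownames(g)),
                   collapse = "\t"))
  gt_str <- c("0/0", "0/1", "1/1")
  body <- vapply(ord, function(j) {
    ref <- if (ref_is_effect[j]) w$effect_allele[j] else w$other_allele[j]
    alt <- if (ref_is_effect[j]) w$other_allele[j] else w$effect_allele[j]
    dosage <- g[, j]
    alt_count <- if (ref_is_effect[j]) 2L - dosage else dosage
    cells <- ifelse(is.na(alt_count), "./.",
                    gt_str[alt_count + 1L])
    cells <- paste0(cells, ":", dpm[, j])
    paste(c(w$chrom[j], w$pos[j], w$snp_id[j], ref, alt, ".", "PASS",
            ".", "GT:DP", cells), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), paths[["vcf"]])

  utils::write.table(cohort$phenotypes, paths[["phenotypes"]],
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  tr <- cohort$truth
  tr$config <- unclass(tr$config)
  jsonlite::write_json(tr, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}

#' Read a phenotype table written by [write_cohort()]
#'
#' @param path Path to the phenotype TSV.
#' @return Data frame with character phenotype columns and numeric ages
#'   and melanoma counts; `NA` for missing.
#' @export
read_phenotypes <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, na.strings = "NA")
}
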