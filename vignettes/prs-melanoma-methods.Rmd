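---
title: "Methods: polygenic risk score analysis for melanoma case-control studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: polygenic risk score analysis for melanoma case-control studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(melprs)
```

## The problem and the model

Cutaneous melanoma risk has a substantial polygenic component: dozens of
common variants, individually weak, act additively on the log-odds
scale.  A polygenic risk score (PRS) aggregates them as a weighted
allele count.  For individual $j$ with effect-allele dosages
$x_{ij} \in \{0, 1, 2\}$ at SNPs $i = 1, \dots, p$ and per-allele log
odds ratios $\beta_i$ taken from genome-wide association studies,

$$\mathrm{PRS}_j = \sum_{i=1}^{p} \beta_i \, x_{ij}.$$

The raw score has no absolute scale — it shifts with the panel and the
$\beta$ source — so it is standardized against the control series of
the study: $z_j = (\mathrm{PRS}_j - \bar s_C)/\mathrm{sd}_C$, with mean
and SD computed on controls only.  Controls then have mean 0 and SD 1
by construction, and every effect is expressed "per control SD".  The
SD uses the $n-1$ denominator, the default of mainstream statistical
software.

Downstream, the package answers the questions such a study asks:

* **Decile risk stratification.** Cases and controls are binned on the
  deciles of the control score distribution, and each decile's odds of
  being a case are contrasted with a reference decile via logistic
  regression — crude, and adjusted for age at sampling (continuous)
  and sex (binary indicator).  The melanoma analysis merges deciles 5
  and 6 into the reference group; the merge is a plain label-merge
  step, so the multiple-primary analysis (reference decile 1, no
  merge) reuses the same machinery.
* **Per-SD odds ratio.** The score kept continuous: the odds ratio per
  one control-SD increase, from a univariate logistic fit.
* **Discrimination.** AUC of a model's in-sample fitted probabilities,
  and the paired DeLong test for the AUC gain when covariates join the
  score (or the score joins the covariates).  In-sample fitted values
  are used deliberately: the question is apparent discrimination on
  the same cohort, not external validity.
* **Phenotype associations.** Kruskal–Wallis rank tests comparing the
  score distribution across phenotypic strata (eye/hair color,
  phototype, sunburn frequency, nevus count, family history, number of
  primary melanomas).  No multiple-testing adjustment is applied, and
  missing phenotype values are excluded per comparison (pairwise, not
  listwise).

## Panel quality control

Two SNP-level filters precede scoring.

*Strand-ambiguous SNPs* — allele pairs {A,T} or {C,G} — are removed
outright: these pairs are their own reverse complement, so a strand
mix-up between the genotyping assay and the weights source cannot be
detected from the alleles, and a silent flip corrupts the score.
"Ambiguous" is implemented as exactly this palindromic-pair rule, the
standard meaning in PRS quality control.

*LD pruning* removes one SNP of every pair whose dosage $r^2$ exceeds
a threshold (default 0.45).  $r^2$ is the squared Pearson correlation
of dosages over complete pairs (composite LD) — phase is not available
from unphased VCFs and is not needed for this purpose.  The pruning
pass is greedy in (chromosome, position) order and keeps the SNP with
the larger $|\beta|$ of a violating pair (ties: the earlier one),
retaining the more informative marker.  On exit no retained pair
exceeds the threshold; the test suite asserts this invariant on
block-correlated simulations.

Genotypes are read from VCF with orientation resolved against the
weights table: when the effect allele is the VCF REF, the ALT count is
flipped.  A site whose REF/ALT matches the weights only on the
opposite strand is a hard error rather than a rescue — after ambiguous
SNPs are gone this indicates corrupted input, and a wrong silent guess
is worse than a stop.  Per-sample read depths below `min_depth`
(default 30×, a stringent amplicon-sequencing threshold) set the
genotype missing.  Chromosome strings compare verbatim; an opt-in flag
strips a `chr` prefix on both sides.

Missing dosages enter the score under a switchable policy: the default
imputes the SNP's mean non-missing dosage (keeping every individual in
the analysis); `error` refuses.  With no missing values the two
policies agree exactly.

## Numerical choices

* **Quantile rule.** Decile cut points (and the reported quartiles)
  use linear interpolation between order statistics
  (`stats::quantile` type 7).  The convention matters when reproducing
  per-decile control counts; it is stated so discrepancies can be
  diagnosed rather than guessed.
* **Tie-breaking.** Decile intervals are left-open, right-closed: a
  score exactly at a cut point falls in the lower decile.
  Deterministic and documented, nothing more.
* **Logistic fits.** Maximum likelihood by IRLS (tolerance $10^{-12}$,
  at most 50 iterations), covariance from the inverse observed
  information, Wald $z$ and two-sided normal p-values.  Singular
  designs and complete/quasi-complete separation (diverging
  coefficients with boundary fitted values) are errors, not warnings:
  the Wald machinery is meaningless there.
* **Confidence intervals.** Wald throughout,
  $\exp(\hat\beta \pm 1.959964\,\mathrm{SE})$ — this is what
  reproduces the printed crude intervals of published decile tables
  from their counts.  Profile likelihood is out of scope.
* **Zero cells.** A 2×2 odds ratio with an empty off-diagonal cell is
  an error by default; the Haldane–Anscombe 0.5 correction is
  available behind an explicit flag for exploration, and is never used
  in any reported quantity.
* **AUC ties.** The Mann–Whitney estimator counts ties as 0.5, both in
  the AUC and inside the DeLong placement values, so the two are
  always consistent.
* **Degenerate inputs.** Constant score vectors make decile cut points
  collapse (warning) and the Kruskal–Wallis statistic undefined
  (error, since the tie correction zeroes its denominator); $r^2$
  against a monomorphic SNP is an error rather than 0/0.

## The synthetic cohort generator

Individual-level data of this kind cannot ship with a package, so the
generator produces cohorts with the statistical structure the analysis
assumes, and every stage is exercised against them.

Genotypes are Hardy–Weinberg draws: dosage $\sim$ Binomial(2, $f_i$)
with per-SNP effect-allele frequencies uniform on a configurable range
(default 0.1–0.5).  SNPs are independent by default; an optional
block-copy mode induces high pairwise LD solely to exercise the
pruning code.  Case status follows a logistic disease model in the
standardized true score, $\mathrm{logit}\,P(\text{case}) = \alpha +
\log(\mathrm{OR}_{SD}) \, z$, with $\alpha$ tuned by bisection so the
expected case fraction matches the target cohort composition; the
generator then samples until exactly the requested numbers of cases
and controls are collected.  The design is deliberately retrospective
(case–control): odds ratios, not absolute risks, are the estimands
throughout this kind of study.

Default conditions mirror a published single-centre melanoma series:
270 cases, 296 controls, a 57-SNP panel, case age at sampling
Normal(56.8, 13.4) versus control Normal(41.1, 12.1), sex 42.6% male
in cases versus 72.3% in controls, and roughly two thirds of cases
with more than one primary melanoma.  The default per-SD odds ratio is
1.8, chosen once from the observed case–control score shift of about
0.58 control-SD in such a series.  Cases receive a primary-melanoma
count through sequential logistic steps — each additional primary
occurs with log-odds `mpm_base` $+$ `mpm_gradient` $\cdot z$, capped
at 4+ — with `mpm_gradient` defaulting to $\log(1.41)$ (the per-SD
MPM odds ratio such studies report) and `mpm_base` set so the marginal
single/multiple split lands near one third / two thirds.  Categorical
phenotypes (eye and hair color, phototype, sunburns, nevi, family
history) are Bernoulli draws whose log-odds shift with $z$ by
trait-specific amounts fixed once from the score gaps observed between
phenotype strata (about 0.45 for light eyes, 0.85 for red hair, 0.55
for phototype I–II, 0.48 for frequent sunburns, 0.26 for >50 nevi, 0
for family history); age at diagnosis decreases by 2.5 years per SD.
Phenotypes are recorded for cases only — controls in such series are
anonymous blood donors — and missing values are injected into the case
columns at questionnaire-like rates (12.6% for pigmentation traits,
13.7% for sunburns, 20.7% for nevus counts).

Two modelling points deserve a flag.  First, the covariate terms of
the disease model and the status-conditional age/sex distributions are
mutually exclusive parameterizations (specifying both would be
circular): with `covariate_effects` at their zero default, age and sex
are drawn conditional on realized status to reproduce the marginal
imbalance of a referral series; setting nonzero effects switches to
causal draws made before status.  Second, randomness is split into
substreams (weights, genotypes+status, phenotypes, VCF orientation) so
that, for a fixed seed, adding a phenotype column never perturbs the
genotype draws; written cohorts are byte-identical across runs.

What the generator does **not** emulate: realistic allele-frequency
spectra, population structure, linkage patterns of real chromosomes,
or the joint distribution of phenotypes beyond their marginal link to
the score.  Tests passing on these cohorts therefore validate the
statistical machinery — estimator identities, invariants, coverage,
power under known effects — not the biology of any real population.

## Verification strategy and problem sizes

Every estimator is checked two ways: against an independent oracle
(brute-force pair counting for the AUC, a stratified bootstrap for the
DeLong p, hand rank-sum computation and a permutation null for
Kruskal–Wallis, dot products for the score, closed-form cross-product
odds ratios for the logistic path, a coefficient grid search for the
IRLS optimum) and against published decile/risk-factor count tables
whose crude odds ratios recompute exactly.  The DeLong implementation
is additionally cross-checked against pROC.  Simulation-based checks
use sizes chosen to keep the full suite under a minute while leaving
comfortable statistical margins: 200 replicates of 1000+1000
individuals at 50 SNPs for confidence-interval coverage of the per-SD
odds ratio (observed coverage about 93–96%), 40 replicates for the
monotone decile-OR trend, 10,000 bootstrap draws at n = 60 for the
DeLong comparison, 20,000–50,000 permutations at n ≤ 21 for
Kruskal–Wallis.

## Known limitations

* Additive, LD-unaware scoring only: no shrinkage or LD-aware PRS
  methods, no imputation, no indel or multi-allelic support.
* Wald inference everywhere; small-sample or sparse-data settings
  (zero cells, separation) fail loudly instead of being patched.
* In-sample AUCs are optimistic by construction; no cross-validation
  or optimism correction is provided.
* The chi-square approximation of the Kruskal–Wallis p is used at all
  group sizes (the permutation comparison lives in the test suite);
  for groups smaller than ~5 it is rough.
* Standardizing by the control sample's SD makes the per-SD odds
  ratio conditional on that sample; under strong selection the
  control SD slightly underestimates the population SD, a bias
  visible only as a percent-level shift at realistic effect sizes.
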