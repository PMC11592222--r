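#' Odds ratios by decile group from a logistic fit
#'
#' Fits one logistic regression with indicator columns for every
#' non-reference group (plus optional covariates) and reports each
#' group's odds ratio versus the reference with its Wald confidence
#' interval and two-sided p-value.  Without covariates this reproduces
#' the crude cross-product odds ratios of the corresponding 2x2 tables;
#' with covariates it gives the adjusted odds ratios.
#'
#' @param labels Factor of group labels (reference level first), e.g.
#'   from [assign_deciles()].
#' @param outcome Binary outcome vector (1 = case).
#' @param covariates Optional numeric matrix or data frame of adjustment
#'   covariates (e.g. age as continuous, sex as 0/1), same rows as
#'   `labels`.
#' @param level Confidence level for the Wald intervals. Default 0.95.
#' @return A `prs_or_table` data frame with one row per non-reference
#'   group: `group`, `n_case`, `n_control`, `or`, `ci_low`, `ci_high`,
#'   `p`.  The underlying `prs_logit` is attached as attribute `"fit"`.
#' @export
decile_or_table <- function(labels, outcome, covariates = NULL,
                            level = 0.95) {
  labels <- as.factor(labels)
  outcome <- as.numeric(outcome)
  stopifnot(length(labels) == length(outcome), all(outcome %in% c(0, 1)))
  ref <- levels(labels)[1L]
  if (sum(labels == ref, na.rm = TRUE) == 0L)
    stop("reference group '", ref, "' is empty")
  empty <- levels(labels)[tabulate(labels, length(levels(labels))) == 0L]
  if (length(empty)) {
    warning("omitting empty group(s): ", paste(empty, collapse = ", "))
    labels <- droplevels(labels)
  }
  x <- stats::model.matrix(~labels)
  colnames(x) <- c("(Intercept)", levels(labels)[-1L])
  if (!is.null(covariates)) {
    cv <- as.matrix(as.data.frame(covariates))
    storage.mode(cv) <- "double"
    stopifnot(nrow(cv) == length(outcome))
    x <- cbind(x, cv)
  }
  fit <- fit_logistic(x, outcome)
  grp <- levels(labels)[-1L]
  s <- summary(fit, level = level)$table[grp, , drop = FALSE]
  out <- data.frame(group = grp,
                    n_case = as.integer(table(labels[outcome == 1])[grp]),
                    n_control = as.integer(table(labels[outcome == 0])[grp]),
                    or = s$or, ci_low = s$or_low, ci_high = s$or_high,
                    p = s$p, row.names = NULL)
  structure(out, class = c("prs_or_table", "data.frame"),
            reference = ref, fit = fit)
}

#' @export
print.prs_or_table <- function(x, digits = 2, ...) {
  cat("Odds ratios vs reference group '", attr(x, "reference"), "'\n",
      sep = "")
  df <- data.frame(group = x$group, n_case = x$n_case,
                   n_control = x$n_control,
                   `OR (95% CI)` = sprintf("%.*f (%.*f, %.*f)", digits,
                                           x$or, digits, x$ci_low,
                                           digits, x$ci_high),
                   p = signif(x$p, 3), check.names = FALSE)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write an odds-ratio table as TSV
#'
#' @param x A `prs_or_table`.
#' @param path Output path.
#' @param digits Rounding for the formatted OR column. Default 2.
#' @return `path`, invisibly.
#' @export
write_or_table <- function(x, path, digits = 2) {
  stopifnot(inherits(x, "prs_or_table"))
  df <- as.data.frame(x)
  df$or_ci <- sprintf("%.*f (%.*f, %.*f)", digits, x$or, digits,
                      x$ci_low, digits, x$ci_high)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Per-standard-deviation odds ratio of a continuous score
#'
#' Univariate (or covariate-adjusted) logistic regression of a binary
#' outcome on a standardized score; the reported odds ratio is the
#' multiplicative change in odds per one reference-SD increase of the
#' score.
#'
#' @param std_scores Numeric vector of standardized scores.
#' @param outcome Binary outcome vector (1 = event).
#' @param covariates Optional adjustment covariates, as in
#'   [decile_or_table()].
#' @param level Confidence level. Default 0.95.
#' @return One-row `prs_or_table` labelled `"per_sd"`.
#' @export
per_sd_or <- function(std_scores, outcome, covariates = NULL,
                      level = 0.95) {
  std_scores <- as.numeric(std_scores)
  outcome <- as.numeric(outcome)
  stopifnot(length(std_scores) == length(outcome))
  x <- cbind("(Intercept)" = 1, score = std_scores)
  if (!is.null(covariates)) {
    cv <- as.matrix(as.data.frame(covariates))
    storage.mode(cv) <- "double"
    x <- cbind(x, cv)
  }
  fit <- fit_logistic(x, outcome)
  s <- summary(fit, level = level)$table["score", ]
  structure(data.frame(group = "per_sd",
                       n_case = sum(outcome == 1),
                       n_control = sum(outcome == 0),
                       or = s$or, ci_low = s$or_low, ci_high = s$or_high,
                       p = s$p, row.names = NULL),
            class = c("prs_or_table", "data.frame"),
            reference = "continuous", fit = fit)
}

#' Expand grouped case/control counts to individual-level vectors
#'
#' Utility for reanalyzing published decile or risk-factor tables that
#' report only counts: reconstructs per-individual group labels and
#' outcomes so that the logistic-fit path can be applied to printed
#' tables.
#'
#' @param counts Data frame with columns `group`, `n_case`, `n_control`.
#' @param reference Label of the reference group.
#' @return List with `labels` (factor, reference level first) and
#'   `outcome` (0/1 vector).
#' @export
expand_counts <- function(counts, reference) {
  stopifnot(all(c("group", "n_case", "n_control") %in% names(counts)))
  g <- as.character(counts$group)
  stopifnot(reference %in% g)
  labels <- rep(g, times = counts$n_case + counts$n_control)
  outcome <- unlist(Map(function(nc, nn) c(rep(1L, nc), rep(0L, nn)),
                        counts$n_case, counts$n_control))
  list(labels = factor(labels, levels = c(reference,
                                          setdiff(g, reference))),
       outcome = as.numeric(outcome))
}
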