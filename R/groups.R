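#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square p-value on g-1
#' degrees of freedom, as implemented by [stats::kruskal.test()].  All
#' values identical is an error: the tie correction drives the
#' denominator to zero and the statistic is undefined.
#'
#' @param groups List of two or more non-empty numeric vectors.
#' @return A `kw_result` list: `H`, `df`, `p_value`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (any(vapply(groups, length, integer(1)) == 0L))
    stop("every group must be non-empty")
  pooled <- unlist(groups, use.names = FALSE)
  if (length(pooled) < 3L) stop("need a total of at least 3 values")
  if (length(unique(pooled)) == 1L)
    stop("all values identical: Kruskal-Wallis statistic undefined")
  kt <- stats::kruskal.test(groups)
  structure(list(H = unname(kt$statistic), df = unname(kt$parameter),
                 p_value = kt$p.value),
            class = "kw_result")
}

#' @export
print.kw_result <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4f, df = %d, p = %.4g\n",
              x$H, x$df, x$p_value))
  invisible(x)
}

#' Score distribution summaries by phenotypic stratum
#'
#' Per-stratum n, mean (SD) and median (Q1, Q3) of a score, plus a
#' Kruskal-Wallis comparison across the strata.  Individuals with a
#' missing stratum are excluded from this comparison only (pairwise, not
#' listwise, deletion); empty strata are dropped with a warning.
#' Quartiles use linear interpolation between order statistics, the same
#' quantile rule as [decile_cutpoints()].
#'
#' @param scores Numeric score vector.
#' @param strata Factor or character vector of phenotype categories,
#'   `NA` allowed.
#' @return A `strata_summary` object: a data frame with one row per
#'   stratum (`stratum`, `n`, `mean`, `sd`, `median`, `q1`, `q3`) and
#'   the `kw_result` attached as attribute `"kw"` (NULL when fewer than
#'   two strata remain).
#' @export
strata_summary <- function(scores, strata) {
  stopifnot(length(scores) == length(strata))
  keep <- !is.na(strata) & !is.na(scores)
  scores <- scores[keep]
  strata <- as.factor(strata)[keep]
  present <- levels(strata)[tabulate(strata, length(levels(strata))) > 0L]
  if (length(present) < length(levels(strata))) {
    warning("omitting empty stratum(s): ",
            paste(setdiff(levels(strata), present), collapse = ", "))
    strata <- droplevels(strata)
  }
  by_s <- split(scores, strata)
  tab <- data.frame(
    stratum = names(by_s),
    n = vapply(by_s, length, integer(1)),
    mean = vapply(by_s, mean, numeric(1)),
    sd = vapply(by_s, function(v)
      if (length(v) < 2L) NA_real_ else stats::sd(v), numeric(1)),
    median = vapply(by_s, stats::median, numeric(1)),
    q1 = vapply(by_s, function(v)
      unname(stats::quantile(v, 0.25, type = 7)), numeric(1)),
    q3 = vapply(by_s, function(v)
      unname(stats::quantile(v, 0.75, type = 7)), numeric(1)),
    row.names = NULL)
  kw <- if (length(by_s) >= 2L) kruskal_wallis(by_s) else NULL
  structure(tab, class = c("strata_summary", "data.frame"), kw = kw)
}

#' @export
print.strata_summary <- function(x, digits = 3, ...) {
  df <- data.frame(stratum = x$stratum, n = x$n,
                   `mean (SD)` = sprintf("%.*f (%s)", digits, x$mean,
                                         ifelse(is.na(x$sd), "-",
                                                sprintf("%.*f", digits,
                                                        x$sd))),
                   `median (Q1, Q3)` = sprintf("%.*f (%.*f, %.*f)",
                                               digits, x$median, digits,
                                               x$q1, digits, x$q3),
                   check.names = FALSE)
  print(df, row.names = FALSE)
  kw <- attr(x, "kw")
  if (!is.null(kw))
    cat(sprintf("Kruskal-Wallis p = %.4g\n", kw$p_value))
  invisible(x)
}

#' Write a strata summary as TSV
#'
#' @param x A `strata_summary`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_strata_summary <- function(x, path) {
  stopifnot(inherits(x, "strata_summary"))
  df <- as.data.frame(x)
  kw <- attr(x, "kw")
  df$kw_p <- if (is.null(kw)) NA_real_ else kw$p_value
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
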