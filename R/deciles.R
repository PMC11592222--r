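#' Decile cut points of a reference score distribution
#'
#' The nine 10%, 20%, ..., 90% empirical quantiles of the reference
#' vector, using linear interpolation between order statistics
#' (`stats::quantile` type 7).  Binning a distribution on the cut points
#' of its own sample therefore puts n/10 (+/- 1) individuals in each bin.
#'
#' @param reference_scores Numeric vector of at least 10 scores.
#' @return Numeric vector of 9 non-decreasing cut points.
#' @export
decile_cutpoints <- function(reference_scores) {
  reference_scores <- reference_scores[!is.na(reference_scores)]
  if (length(reference_scores) < 10L)
    stop("need at least 10 reference scores for decile cut points")
  cp <- unname(stats::quantile(reference_scores, probs = seq(0.1, 0.9, 0.1),
                               type = 7))
  if (any(diff(cp) == 0))
    warning("tied decile cut points: the reference distribution is too ",
            "discrete for distinct deciles")
  cp
}

#' Build a decile grouping scheme
#'
#' Combines cut points with an optional merge of adjacent deciles (the
#' melanoma analysis merges deciles 5 and 6 into a single reference
#' group) and names the reference group for odds-ratio contrasts.
#'
#' @param cutpoints 9 ascending cut points, from [decile_cutpoints()].
#' @param merge Named list mapping a group label to the integer deciles it
#'   absorbs, e.g. `list("5-6" = c(5, 6))`.  Default: no merging.
#' @param reference Label of the reference group (a merged label or a
#'   decile number as character). Default `"1"`.
#' @return A `decile_scheme` list.
#' @export
decile_scheme <- function(cutpoints, merge = NULL, reference = "1") {
  stopifnot(length(cutpoints) == 9L, !is.unsorted(cutpoints))
  labels <- as.character(1:10)
  if (!is.null(merge)) {
    stopifnot(is.list(merge), !is.null(names(merge)))
    for (lab in names(merge)) {
      d <- merge[[lab]]
      stopifnot(all(d %in% 1:10))
      labels[d] <- lab
    }
  }
  if (!reference %in% labels)
    stop("reference group '", reference, "' not among group labels")
  structure(list(cutpoints = as.numeric(cutpoints),
                 labels = labels, reference = reference),
            class = "decile_scheme")
}

#' Assign scores to decile groups
#'
#' Left-open, right-closed binning: a score lands in decile `d` when
#' `cutpoint[d-1] < score <= cutpoint[d]` (with implicit -Inf and +Inf
#' ends), so a score exactly at a cut point falls in the lower decile.
#' Merged group labels are applied afterwards.
#'
#' @param scores Numeric vector.
#' @param scheme A `decile_scheme` (or a bare 9-vector of cut points, in
#'   which case no merging is applied).
#' @return Factor of group labels with the reference level first.
#' @export
assign_deciles <- function(scores, scheme) {
  if (!inherits(scheme, "decile_scheme"))
    scheme <- decile_scheme(scheme)
  dec <- 1L + vapply(scores,
                     function(s) sum(scheme$cutpoints < s), integer(1))
  lab <- scheme$labels[dec]
  lev <- unique(scheme$labels)
  factor(lab, levels = c(scheme$reference, setdiff(lev, scheme$reference)))
}
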