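#' Transition counts by source state
#'
#' Row sums of a transition matrix: how many transitions each life-habit
#' state gave rise to.  Under `grouping = "permanent_merged"` the cementing
#' and nestling categories are collapsed into a single "permanent"
#' category (as both source and sink) before summing, reducing the number
#' of categories with very low counts.
#'
#' @param tm a `"transition_matrix"`.
#' @param grouping `"six_state"` (default) or `"permanent_merged"`.
#' @return named integer vector of per-source counts (names are habit
#'   labels, with `"permanent"` for the merged category).
#' @examples
#' source_counts(scallop_transition_counts(), "permanent_merged")
#' @export
source_counts <- function(tm, grouping = c("six_state", "permanent_merged")) {
  grouping <- match.arg(grouping)
  if (grouping == "permanent_merged") tm <- merge_permanent(tm)
  m <- unclass(tm)
  attr(m, "total") <- NULL
  counts <- as.integer(rowSums(m))
  codes <- as.integer(rownames(tm))
  labels <- habit_label(codes)
  if (grouping == "permanent_merged") labels[codes == 1L] <- "permanent"
  stats::setNames(counts, labels)
}

#' Chi-square test of uniform transition-source frequencies
#'
#' Tests the null hypothesis that a transition is equally likely to
#' originate from any of the m categories: expected count `total/m` per
#' category, Pearson statistic `sum((obs - exp)^2 / exp)` on `m - 1`
#' degrees of freedom, upper-tail p-value from the asymptotic chi-squared
#' distribution.  Categories with zero observed transitions stay in the
#' category set and contribute `(0 - exp)^2 / exp`.  No continuity
#' correction is applied.
#'
#' @param counts named vector of per-source transition counts, as from
#'   [source_counts()].
#' @param grouping optional label recorded in the result.
#' @return an object of class `"htest"` with `statistic` (X-squared),
#'   `parameter` (df), `p.value`, and the observed and expected counts.
#' @examples
#' chi_square_uniform(source_counts(scallop_transition_counts()))
#' @export
chi_square_uniform <- function(counts, grouping = NULL) {
  if (any(counts < 0)) stop("negative counts")
  total <- sum(counts)
  if (total <= 0) stop("total transition count is zero")
  m <- length(counts)
  if (m < 2) stop("need at least two categories")
  expected <- total / m
  stat <- sum((counts - expected)^2 / expected)
  df <- m - 1
  structure(
    list(
      statistic = c("X-squared" = stat),
      parameter = c(df = df),
      p.value = stats::pchisq(stat, df, lower.tail = FALSE),
      observed = counts,
      expected = stats::setNames(rep(expected, m), names(counts)),
      method = "Chi-square test of uniform transition-source frequencies",
      data.name = if (is.null(grouping)) "source counts"
                  else paste0("source counts (", grouping, ")"),
      grouping = grouping
    ),
    class = "htest"
  )
}
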