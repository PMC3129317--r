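#' Group transition records into origin events per derived state
#'
#' Every transition record is one independent origin of its derived
#' (`to`) state; the origin's ancestral state is the record's `from`
#' state -- the state assigned to the parent node of the branch on which
#' the derived state first appears.
#'
#' @param records a `"transition_records"` data frame.
#' @return a named list (names = derived-state codes), each element a data
#'   frame with columns `parent`, `child`, `ancestral`.
#' @export
collect_origins <- function(records) {
  if (nrow(records) == 0) return(stats::setNames(list(), character(0)))
  out <- split(
    data.frame(parent = records$parent, child = records$child,
               ancestral = records$from),
    records$to
  )
  out[order(as.integer(names(out)))]
}

#' Classify repeated origins as parallel or convergent
#'
#' Uses the phylogenetic definitions: two independent origins of the same
#' derived state are *parallel* when they arise from the same ancestral
#' state, and *convergent* when their ancestral states differ.  Every
#' unordered pair of origins is labelled; a derived state is summarised as
#' `"unique"` (one origin), `"parallel"` (all ancestors identical),
#' `"convergent"` (all ancestors pairwise different) or `"both"` (a
#' mixture).
#'
#' @param origins output of [collect_origins()].
#' @return a data frame of class `"origin_classification"`: one row per
#'   derived state with `derived`, `n_origins`, `ancestors`
#'   (semicolon-joined codes), `parallel_pairs`, `convergent_pairs`,
#'   `summary`.  The pairwise labels are attached as attribute `"pairs"`
#'   (a list of data frames).
#' @export
classify_origins <- function(origins) {
  states <- names(origins)
  if (length(states) == 0) {
    out <- data.frame(derived = integer(0), n_origins = integer(0),
                      ancestors = character(0),
                      parallel_pairs = integer(0),
                      convergent_pairs = integer(0),
                      summary = character(0), stringsAsFactors = FALSE)
    attr(out, "pairs") <- list()
    class(out) <- c("origin_classification", "data.frame")
    return(out)
  }
  pairs_detail <- list()
  rows <- lapply(states, function(s) {
    anc <- origins[[s]]$ancestral
    m <- length(anc)
    if (m >= 2) {
      pr <- utils::combn(m, 2)
      lab <- ifelse(anc[pr[1, ]] == anc[pr[2, ]], "parallel", "convergent")
      pairs_detail[[s]] <<- data.frame(
        origin_a = pr[1, ], origin_b = pr[2, ],
        ancestor_a = anc[pr[1, ]], ancestor_b = anc[pr[2, ]],
        label = lab, stringsAsFactors = FALSE
      )
      np <- sum(lab == "parallel")
      nc <- sum(lab == "convergent")
      summary <- if (nc == 0) "parallel"
        else if (np == 0 && length(unique(anc)) == m) "convergent"
        else "both"
    } else {
      np <- 0L
      nc <- 0L
      summary <- "unique"
    }
    data.frame(derived = as.integer(s), n_origins = m,
               ancestors = paste(anc, collapse = ";"),
               parallel_pairs = np, convergent_pairs = nc,
               summary = summary, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "pairs") <- pairs_detail
  class(out) <- c("origin_classification", "data.frame")
  out
}

#' @export
print.origin_classification <- function(x, ...) {
  y <- as.data.frame(x)
  y$derived <- habit_label(y$derived)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Count origins arising from a given ancestral state
#'
#' By default counts every origin event whose ancestral state is `state`
#' (the row-sum arithmetic used when reporting how many transitions a
#' progenitor state generated).  With `partnered_only = TRUE` only origins
#' that share both derived and ancestral state with at least one other
#' origin -- strict parallel cases -- are counted.
#'
#' @param origins output of [collect_origins()].
#' @param state ancestral state code or label.
#' @param partnered_only count only origins with a parallel partner.
#' @return integer count.
#' @export
count_parallel_from_state <- function(origins, state,
                                      partnered_only = FALSE) {
  code <- habit_code(state)
  counts <- vapply(origins, function(o) {
    n <- sum(o$ancestral == code)
    if (partnered_only && n < 2) 0L else as.integer(n)
  }, integer(1))
  sum(counts)
}
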