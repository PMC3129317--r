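#' Life-habit state coding
#'
#' The canonical coding of scallop (Pectinidae) life habits as a categorical
#' character: `0` unknown behaviour (treated as missing data), `1` cementing,
#' `2` byssal attaching, `3` free-living, `4` recessing, `5` gliding and `6`
#' nestling.  Code 0 is never a reconstructable state: taxa coded 0 enter the
#' likelihood and parsimony machinery as missing.
#'
#' @return A data frame with columns `code` (integer 0--6) and `label`.
#' @examples
#' habit_states()
#' @export
habit_states <- function() {
  data.frame(
    code = 0:6,
    label = c("unknown", "cementing", "byssal", "free-living",
              "recessing", "gliding", "nestling"),
    stringsAsFactors = FALSE
  )
}

#' Human-readable label for a state code
#'
#' Codes 0--6 map to the life-habit vocabulary; any other code falls back to
#' `"state_<code>"` so that generic simulated characters print sensibly.
#'
#' @param code integer vector of state codes.
#' @return character vector of labels, same length as `code`.
#' @examples
#' habit_label(c(2, 3, 9))
#' @export
habit_label <- function(code) {
  tab <- habit_states()
  out <- tab$label[match(code, tab$code)]
  miss <- is.na(out)
  out[miss] <- paste0("state_", code[miss])
  out
}

#' Map a state label back to its code
#'
#' Accepts either codes (returned unchanged) or labels such as
#' `"free-living"`.  The merged category `"permanent"` (cementing +
#' nestling) is not a single code and is handled by the functions that
#' accept a grouping argument.
#'
#' @param state integer codes or character labels.
#' @return integer vector of codes.
#' @keywords internal
habit_code <- function(state) {
  if (is.numeric(state)) return(as.integer(state))
  tab <- habit_states()
  code <- tab$code[match(state, tab$label)]
  if (anyNA(code)) {
    stop("unknown state label(s): ",
         paste(state[is.na(code)], collapse = ", "))
  }
  as.integer(code)
}

#' Normalise taxon names
#'
#' Trims surrounding whitespace and collapses internal runs of spaces or
#' tabs to single underscores, so that names written in different Newick
#' dialects match.
#'
#' @param x character vector of taxon names.
#' @return normalised character vector.
#' @export
normalize_taxon <- function(x) {
  x <- gsub("^'(.*)'$", "\\1", trimws(x))  # Newick-quoted labels
  gsub("[ \t]+", "_", trimws(x))
}

#' Construct a character matrix for a categorical trait
#'
#' Bundles a named vector of state codes with its state space.  Codes `0` or
#' `NA` are flagged as missing and excluded from the state space.  The state
#' space defaults to the sorted set of observed non-missing codes; supply
#' `state_space` explicitly when the full set of possible states is known
#' (e.g. for simulated characters where some states happen not to be
#' observed at the tips).
#'
#' @param codes named integer vector, one entry per taxon; names are taxon
#'   names (normalised with [normalize_taxon()]).
#' @param state_space optional integer vector of all possible non-missing
#'   codes; must contain every observed non-missing code.
#' @return An object of class `"habit_character"`: a list with elements
#'   `codes`, `missing` (logical), `state_space` and `k`.
#' @examples
#' habit_character(c(A = 2, B = 0, C = 3))
#' @export
habit_character <- function(codes, state_space = NULL) {
  if (is.null(names(codes)) || any(!nzchar(names(codes)))) {
    stop("'codes' must be a named vector (taxon names)")
  }
  nm <- normalize_taxon(names(codes))
  if (anyDuplicated(nm)) {
    stop("duplicate taxon names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  codes <- as.integer(codes)
  names(codes) <- nm
  missing <- is.na(codes) | codes == 0L
  observed <- sort(unique(codes[!missing]))
  if (is.null(state_space)) {
    state_space <- observed
  } else {
    state_space <- sort(unique(as.integer(state_space)))
    if (any(state_space == 0L)) stop("state_space must not contain code 0")
    if (!all(observed %in% state_space)) {
      stop("observed codes outside supplied state_space: ",
           paste(setdiff(observed, state_space), collapse = ", "))
    }
  }
  structure(
    list(codes = codes, missing = missing,
         state_space = state_space, k = length(state_space)),
    class = "habit_character"
  )
}

#' @export
print.habit_character <- function(x, ...) {
  cat("Categorical character: ", length(x$codes), " taxa, k = ", x$k,
      " states (", paste(habit_label(x$state_space), collapse = ", "),
      ")\n", sep = "")
  if (any(x$missing)) {
    cat("  missing/unknown: ", sum(x$missing), " taxa\n", sep = "")
  }
  invisible(x)
}

## internal: codes -> 1..k indices in the state space (NA for missing)
char_index <- function(char) {
  idx <- match(char$codes, char$state_space)
  idx[char$missing] <- NA_integer_
  names(idx) <- names(char$codes)
  idx
}
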