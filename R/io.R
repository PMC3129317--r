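#' Read a rooted phylogeny from a Newick file
#'
#' Thin wrapper around [ape::read.tree()] with the validation this pipeline
#' needs: unique tip names, finite non-negative branch lengths, and clamping
#' of absent or near-zero branch lengths to `min_branch_length` so that the
#' Mk transition probability matrix stays non-singular on consensus trees
#' with zero-length branches.  The tree is taken as rooted as written; no
#' re-rooting is performed and polytomies are kept.
#'
#' @param path path to a Newick file (or a Newick string via `text`).
#' @param min_branch_length branch lengths below this value (or absent) are
#'   set to it for likelihood use; parsimony ignores lengths.  Must be > 0.
#' @param text optional Newick string, used instead of `path`.
#' @return An [ape::phylo] object.  The number of clamped branches is
#'   attached as attribute `"clamped"`.
#' @examples
#' tr <- read_habit_tree(text = "((A:1,B:1):1,C:2);")
#' @export
read_habit_tree <- function(path = NULL, min_branch_length = 1e-8,
                            text = NULL) {
  stopifnot(min_branch_length > 0)
  if (is.null(text)) {
    if (!file.exists(path)) stop("tree file not found: ", path)
    tree <- tryCatch(ape::read.tree(path),
                     error = function(e) stop("malformed Newick in '", path,
                                              "': ", conditionMessage(e)))
  } else {
    tree <- tryCatch(ape::read.tree(text = text),
                     error = function(e) stop("malformed Newick: ",
                                              conditionMessage(e)))
  }
  if (is.null(tree)) stop("malformed Newick: parser returned no tree")
  validate_habit_tree(tree, min_branch_length)
}

#' Validate and normalise a phylogeny
#'
#' Checks tip-name uniqueness and branch-length sanity, normalises tip
#' names with [normalize_taxon()], and clamps absent/short branch lengths
#' to `min_branch_length`.
#'
#' @inheritParams read_habit_tree
#' @param tree an [ape::phylo] object.
#' @return the validated tree, with attribute `"clamped"` (count).
#' @export
validate_habit_tree <- function(tree, min_branch_length = 1e-8) {
  if (!inherits(tree, "phylo")) stop("'tree' must be an ape \"phylo\" object")
  tree$tip.label <- normalize_taxon(tree$tip.label)
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip names: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  }
  n_edge <- nrow(tree$edge)
  if (is.null(tree$edge.length)) {
    message("tree has no branch lengths; all set to ", min_branch_length)
    tree$edge.length <- rep(min_branch_length, n_edge)
    clamped <- n_edge
  } else {
    if (any(!is.finite(tree$edge.length))) {
      stop("non-finite branch lengths in tree")
    }
    if (any(tree$edge.length < 0)) stop("negative branch lengths in tree")
    short <- tree$edge.length < min_branch_length
    clamped <- sum(short)
    if (clamped > 0) {
      message(clamped, " branch length(s) below ", min_branch_length,
              " clamped for likelihood use")
      tree$edge.length[short] <- min_branch_length
    }
  }
  attr(tree, "clamped") <- clamped
  tree
}

#' Write a phylogeny to a Newick file
#'
#' @param tree an [ape::phylo] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_habit_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a life-habit character matrix
#'
#' Reads the taxon-to-state table, either a headered CSV with columns
#' `taxon,state_code` or a NEXUS data block (read-only, via
#' [ape::read.nexus.data()]).  Codes must be in 0--6 under the life-habit
#' coding; code 0 marks unknown behaviour and becomes missing data.  Every
#' tip of `tree` must have an entry; entries for taxa not on the tree are
#' dropped with a warning so the character's taxon set always equals the
#' tree's tip set.
#'
#' @param path path to the character file.
#' @param tree the [ape::phylo] the character will be analysed on.
#' @param format `"auto"` (by extension), `"csv"` or `"nexus"`.
#' @return A [habit_character()] object covering exactly the tree's tips.
#' @export
read_character_matrix <- function(path, tree,
                                  format = c("auto", "csv", "nexus")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("character file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.nex(us)?$", path, ignore.case = TRUE))
      "nexus" else "csv"
  }
  if (format == "csv") {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("taxon", "state_code")
    if (!all(need %in% names(tab))) {
      stop("character CSV must have columns 'taxon' and 'state_code'")
    }
    codes <- suppressWarnings(as.integer(tab$state_code))
    if (anyNA(codes) & !anyNA(tab$state_code)) {
      stop("non-integer state codes in ", path)
    }
    names(codes) <- tab$taxon
  } else {
    nex <- ape::read.nexus.data(path)
    codes <- vapply(nex, function(x) {
      v <- suppressWarnings(as.integer(x[1]))
      if (is.na(v)) NA_integer_ else v
    }, integer(1))
  }
  names(codes) <- normalize_taxon(names(codes))
  bad <- !is.na(codes) & (codes < 0L | codes > 6L)
  if (any(bad)) {
    stop("state codes outside 0-6 for: ",
         paste(names(codes)[bad], collapse = ", "))
  }
  tips <- normalize_taxon(tree$tip.label)
  absent <- setdiff(tips, names(codes))
  if (length(absent) > 0) {
    stop("tree tips without a character entry: ",
         paste(absent, collapse = ", "))
  }
  extra <- setdiff(names(codes), tips)
  if (length(extra) > 0) {
    warning("dropping ", length(extra),
            " character entries not on the tree: ",
            paste(extra, collapse = ", "))
    codes <- codes[names(codes) %in% tips]
  }
  habit_character(codes[tips])
}

#' Write a character matrix as CSV
#'
#' @param char a [habit_character()] object.
#' @param path output CSV path (columns `taxon,state_code`).
#' @return `path`, invisibly.
#' @export
write_character_matrix <- function(char, path) {
  utils::write.csv(
    data.frame(taxon = names(char$codes), state_code = char$codes,
               row.names = NULL),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}
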