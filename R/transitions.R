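#' Resolve per-node state assignments from ancestral state sets
#'
#' Turns per-node state sets (ML best-state sets or parsimony MPR sets)
#' into single-state assignments for transition counting.  Resolved nodes
#' (singleton sets) take their state.  Ambiguous nodes are handled by
#' policy:
#' * `"inherit_parent"` -- an ambiguous node takes its parent's assigned
#'   state when that state is in its own set (this realises a minimal
#'   number of implied changes along the path); otherwise it stays
#'   unassigned.
#' * `"skip_branch"` -- ambiguous nodes stay unassigned and branches
#'   touching them contribute no transition.
#'
#' @param state_sets list of state-code vectors, one per node (tips first,
#'   ape numbering), e.g. `best_sets` of a `"habit_asr"` or `state_sets` of
#'   a `"parsimony_asr"`.
#' @param tree the corresponding [ape::phylo].
#' @param policy `"inherit_parent"` (default) or `"skip_branch"`.
#' @return list with `state` (integer per node, `NA` = unassigned) and
#'   `inherited` (logical: assignment came from the parent, not a singleton
#'   set).
#' @export
assign_states <- function(state_sets, tree,
                          policy = c("inherit_parent", "skip_branch")) {
  policy <- match.arg(policy)
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  if (length(state_sets) != nn) {
    stop("state_sets must have one entry per node (", nn, ")")
  }
  root <- nt + 1L
  if (length(state_sets[[root]]) == 0) stop("empty state set at root")
  state <- rep(NA_integer_, nn)
  inherited <- rep(FALSE, nn)
  singleton <- lengths(state_sets) == 1L
  if (singleton[root]) state[root] <- state_sets[[root]][1]
  post <- ape::reorder.phylo(tree, "postorder")
  E <- post$edge[rev(seq_len(nrow(post$edge))), , drop = FALSE]  # preorder
  for (e in seq_len(nrow(E))) {
    p <- E[e, 1L]
    ch <- E[e, 2L]
    if (singleton[ch]) {
      state[ch] <- state_sets[[ch]][1]
    } else if (policy == "inherit_parent" && !is.na(state[p]) &&
               state[p] %in% state_sets[[ch]]) {
      state[ch] <- state[p]
      inherited[ch] <- TRUE
    }
  }
  list(state = state, inherited = inherited)
}

#' Enumerate state transitions along branches
#'
#' One record per branch whose two endpoints are assigned different states.
#' Branches with an unassigned endpoint contribute no record: this is the
#' minimum-transition convention -- no change is invented at a node the
#' reconstruction could not place.  Terminal branches count, so a derived
#' state confined to a single species is still an origin.
#'
#' @param assignment result of [assign_states()] (or a bare integer vector
#'   of per-node states with `NA` for unassigned).
#' @param tree the [ape::phylo] the assignment lives on.
#' @param ingroup optional character vector of tip names delimiting a
#'   monophyletic ingroup; only branches within that clade are kept,
#'   including the branch subtending the clade root (a state change on that
#'   branch belongs to the ingroup's history).
#' @return data frame of class `"transition_records"` with columns
#'   `parent`, `child`, `from`, `to`, `resolved` (both endpoints were
#'   singleton sets rather than inherited).
#' @export
enumerate_transitions <- function(assignment, tree, ingroup = NULL) {
  if (is.list(assignment)) {
    state <- assignment$state
    inherited <- assignment$inherited
  } else {
    state <- assignment
    inherited <- rep(FALSE, length(state))
  }
  E <- tree$edge
  keep <- !is.na(state[E[, 1]]) & !is.na(state[E[, 2]]) &
    state[E[, 1]] != state[E[, 2]]
  if (!is.null(ingroup)) {
    clade <- clade_nodes(tree, ingroup)
    keep <- keep & E[, 2] %in% clade
  }
  rec <- data.frame(
    parent = E[keep, 1],
    child = E[keep, 2],
    from = state[E[keep, 1]],
    to = state[E[keep, 2]],
    resolved = !(inherited[E[keep, 1]] | inherited[E[keep, 2]])
  )
  class(rec) <- c("transition_records", "data.frame")
  rec
}

## internal: node ids of a clade (MRCA of the given tips plus descendants)
clade_nodes <- function(tree, tips) {
  tips <- normalize_taxon(tips)
  tip_ids <- match(tips, normalize_taxon(tree$tip.label))
  if (anyNA(tip_ids)) {
    stop("ingroup tips not on tree: ",
         paste(tips[is.na(tip_ids)], collapse = ", "))
  }
  if (length(tip_ids) == 1) return(tip_ids)
  mrca <- ape::getMRCA(tree, tip_ids)
  nodes <- mrca
  repeat {
    kids <- tree$edge[tree$edge[, 1] %in% nodes, 2]
    new <- union(nodes, kids)
    if (length(new) == length(nodes)) break
    nodes <- new
  }
  nodes
}

#' Build a transition-count matrix from records
#'
#' Cell `[i, j]` counts records with `from = i`, `to = j`; the diagonal is
#' structurally zero.
#'
#' @param records a data frame of transitions (columns `from`, `to`), as
#'   from [enumerate_transitions()].
#' @param states state codes labelling rows/columns; defaults to the codes
#'   occurring in the records.
#' @return an integer matrix of class `"transition_matrix"` with the total
#'   count as attribute `"total"`.
#' @export
build_transition_matrix <- function(records, states = NULL) {
  if (is.null(states)) states <- sort(unique(c(records$from, records$to)))
  states <- sort(unique(as.integer(states)))
  k <- length(states)
  m <- matrix(0L, k, k, dimnames = list(as.character(states),
                                        as.character(states)))
  if (nrow(records) > 0) {
    bad <- setdiff(unique(c(records$from, records$to)), states)
    if (length(bad) > 0) {
      stop("record states outside the given state set: ",
           paste(bad, collapse = ", "))
    }
    if (any(records$from == records$to)) {
      stop("self-transitions in records")
    }
    tab <- table(factor(records$from, levels = states),
                 factor(records$to, levels = states))
    m <- m + unclass(tab)
    storage.mode(m) <- "integer"
    dimnames(m) <- list(as.character(states), as.character(states))
  }
  structure(m, class = c("transition_matrix", "matrix"),
            total = sum(m))
}

#' @export
print.transition_matrix <- function(x, ...) {
  m <- unclass(x)
  attr(m, "total") <- NULL
  dimnames(m) <- lapply(dimnames(m),
                        function(d) habit_label(as.integer(d)))
  cat("Transition counts (rows = ancestral state, cols = derived):\n")
  print(m)
  cat("Total transitions:", attr(x, "total"), "\n")
  invisible(x)
}

#' Expand a transition-count matrix into unit records
#'
#' Inverse of [build_transition_matrix()] up to branch identity: each count
#' becomes one record with `parent`/`child` set to `NA`.  Used to feed
#' matrices of published counts into [collect_origins()] and the bias
#' tests.
#'
#' @param tm a `"transition_matrix"`.
#' @return a `"transition_records"` data frame.
#' @export
transition_records_from_matrix <- function(tm) {
  states <- as.integer(rownames(tm))
  idx <- which(unclass(tm) > 0, arr.ind = TRUE)
  from <- rep(states[idx[, 1]], unclass(tm)[idx])
  to <- rep(states[idx[, 2]], unclass(tm)[idx])
  rec <- data.frame(parent = NA_integer_, child = NA_integer_,
                    from = from, to = to, resolved = TRUE)
  class(rec) <- c("transition_records", "data.frame")
  rec
}

#' Number of independent origins of a state
#'
#' Column sum of the transition matrix into the state: each inbound
#' transition is one independent derivation.  The merged category
#' `"permanent"` (cementing + nestling) is accepted as well as codes or
#' labels.
#'
#' @param tm a `"transition_matrix"`.
#' @param state a state code, a label such as `"gliding"`, or
#'   `"permanent"`.
#' @return integer count.
#' @examples
#' origins_of_state(scallop_transition_counts(), "free-living")
#' @export
origins_of_state <- function(tm, state) {
  states <- as.integer(rownames(tm))
  if (is.character(state) && identical(state, "permanent")) {
    perm <- intersect(c(1L, 6L), states)
    if (length(perm) == 0) stop("no permanent-attachment states in matrix")
    return(sum(unclass(tm)[, as.character(perm)]))
  }
  code <- habit_code(state)
  if (!code %in% states) stop("state ", state, " not in transition matrix")
  sum(unclass(tm)[, as.character(code)])
}

#' Transitions originating from a state
#'
#' Row sum of the transition matrix: how many times the state acted as the
#' evolutionary progenitor.
#'
#' @inheritParams origins_of_state
#' @return integer count.
#' @export
transitions_from_state <- function(tm, state) {
  states <- as.integer(rownames(tm))
  if (is.character(state) && identical(state, "permanent")) {
    perm <- intersect(c(1L, 6L), states)
    if (length(perm) == 0) stop("no permanent-attachment states in matrix")
    return(sum(unclass(tm)[as.character(perm), ]))
  }
  code <- habit_code(state)
  if (!code %in% states) stop("state ", state, " not in transition matrix")
  sum(unclass(tm)[as.character(code), ])
}

#' Published life-habit transition counts for the Pectinidae
#'
#' The transition counts among scallop life-habit classes reported from
#' ancestral state reconstruction on a multigene phylogeny of the family
#' (17 transitions in total), bundled as a plain-text fixture.  The three
#' transitions from byssal attachment to permanent attachment are stored
#' split by destination as reported: 2 to cementing, 1 to nestling.
#'
#' @return a 6 x 6 `"transition_matrix"` over codes 1--6.
#' @examples
#' tm <- scallop_transition_counts()
#' attr(tm, "total")  # 17
#' @export
scallop_transition_counts <- function() {
  path <- system.file("extdata", "scallop_transition_counts.csv",
                      package = "habitevol", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  rec <- data.frame(parent = NA_integer_, child = NA_integer_,
                    from = rep(tab$from_code, tab$count),
                    to = rep(tab$to_code, tab$count),
                    resolved = TRUE)
  class(rec) <- c("transition_records", "data.frame")
  build_transition_matrix(rec, states = 1:6)
}

#' Merge cementing and nestling into one permanent-attachment category
#'
#' Both habits permanently fix the animal to (or within) its substrate;
#' merging them reduces categories with very low counts.  Rows/columns for
#' codes 1 (cementing) and 6 (nestling) are summed into a single category
#' labelled by code 1.
#'
#' @param tm a `"transition_matrix"` over life-habit codes.
#' @return a `"transition_matrix"` with the merged category first.
#' @export
merge_permanent <- function(tm) {
  states <- as.integer(rownames(tm))
  perm <- intersect(c(1L, 6L), states)
  if (length(perm) < 2) return(tm)
  m <- unclass(tm)
  attr(m, "total") <- NULL
  keep <- setdiff(states, 6L)
  out <- matrix(0L, length(keep), length(keep),
                dimnames = list(as.character(keep), as.character(keep)))
  grp <- ifelse(states == 6L, 1L, states)
  for (i in seq_along(states)) {
    for (j in seq_along(states)) {
      out[as.character(grp[i]), as.character(grp[j])] <-
        out[as.character(grp[i]), as.character(grp[j])] + m[i, j]
    }
  }
  structure(out, class = c("transition_matrix", "matrix"),
            total = sum(out))
}
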