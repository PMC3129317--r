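#' Unordered parsimony reconstruction (Sankoff with unit costs)
#'
#' Minimum number of state changes for an unordered multistate character on
#' a rooted tree, together with the full most-parsimonious-reconstruction
#' (MPR) state set at every node: the states a node takes in at least one
#' minimum-change labelling.  Implemented as Sankoff dynamic programming
#' with a 0/1 step matrix (equivalent to generalised Fitch), which handles
#' polytomies exactly -- consensus-tree multifurcations do not inflate the
#' score.  Branch lengths are ignored.  Missing tips (code 0) contribute the
#' full state set at no cost.
#'
#' With unit costs the per-child contribution to a parent in state `s` is
#' `min(down[c, s], 1 + min_s' down[c, s'])`, and the up-pass mirrors it, so
#' no explicit k x k step matrix is needed.
#'
#' @param tree a rooted [ape::phylo]; polytomies allowed.
#' @param char a [habit_character()] covering the tree's tips.
#' @return An object of class `"parsimony_asr"`: list with `score` (minimum
#'   number of changes), `state_sets` (list of state-code vectors, one per
#'   node, tips included) and `tree`.
#' @examples
#' tr <- ape::read.tree(text = "((A,B),C);")
#' sankoff_parsimony(tr, habit_character(c(A = 1, B = 2, C = 1)))$score
#' @export
sankoff_parsimony <- function(tree, char) {
  k <- char$k
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  tips <- normalize_taxon(tree$tip.label)
  if (!all(tips %in% names(char$codes))) {
    stop("tree tips without character entries: ",
         paste(setdiff(tips, names(char$codes)), collapse = ", "))
  }
  idx <- char_index(char)[tips]
  if (all(is.na(idx))) stop("no scored tips: every tip is missing")
  if (k < 1) stop("empty state space")

  INF <- nn + 1  # larger than any attainable score
  down <- matrix(0, nn, k)
  for (i in seq_len(nt)) {
    if (!is.na(idx[i])) {
      down[i, ] <- INF
      down[i, idx[i]] <- 0
    }
  }

  post <- ape::reorder.phylo(tree, "postorder")
  E <- post$edge
  root <- nt + 1L

  ## contribution of each non-root node to its parent, capped at min + 1
  contrib <- matrix(0, nn, k)
  for (e in seq_len(nrow(E))) {
    p <- E[e, 1L]
    ch <- E[e, 2L]
    w <- pmin(down[ch, ], min(down[ch, ]) + 1)
    contrib[ch, ] <- w
    down[p, ] <- down[p, ] + w
  }
  score <- min(down[root, ])

  ## up-pass: cost of the rest of the tree given this node's state
  children <- vector("list", nn)
  for (e in seq_len(nrow(E))) {
    children[[E[e, 1L]]] <- c(children[[E[e, 1L]]], E[e, 2L])
  }
  up <- matrix(0, nn, k)
  for (v in unique(rev(E[, 1L]))) {
    cs <- children[[v]]
    tot <- up[v, ] + down[v, ]
    for (ch in cs) {
      B <- tot - contrib[ch, ]  # parent's cost excluding this child
      up[ch, ] <- pmin(B, min(B) + 1)
    }
  }

  ## states feasible in an MPR are exactly those with down + up == score
  full <- down + up
  sets <- apply(full, 1, function(v) char$state_space[v == score],
                simplify = FALSE)

  structure(list(score = as.integer(round(score)), state_sets = sets,
                 tree = tree),
            class = "parsimony_asr")
}

#' @export
print.parsimony_asr <- function(x, ...) {
  nt <- length(x$tree$tip.label)
  cat("Unordered parsimony reconstruction: score =", x$score, "\n")
  amb <- sum(lengths(x$state_sets[(nt + 1):length(x$state_sets)]) > 1)
  cat("  ", amb, "internal node(s) with MPR ambiguity\n")
  invisible(x)
}

#' Compare likelihood and parsimony reconstructions node by node
#'
#' A node "agrees" when its ML best-state set (after the log-likelihood
#' decision rule) and its parsimony MPR set share at least one state.
#'
#' @param ml a `"habit_asr"` from [mk_marginal_asr()].
#' @param mp a `"parsimony_asr"` from [sankoff_parsimony()] on the same
#'   tree and character.
#' @param path optional path to write the per-node table as TSV.
#' @return list with `table` (per-node data frame: `node_id`,
#'   `ml_best_set`, `mp_state_set`, `agree`) and `agreement` (fraction of
#'   nodes agreeing).
#' @export
compare_reconstructions <- function(ml, mp, path = NULL) {
  if (!identical(ml$tree$tip.label, mp$tree$tip.label) ||
      !identical(ml$tree$edge, mp$tree$edge)) {
    stop("reconstructions are not on the same tree")
  }
  nn <- length(mp$state_sets)
  agree <- vapply(seq_len(nn), function(i) {
    length(intersect(ml$best_sets[[i]], mp$state_sets[[i]])) > 0
  }, logical(1))
  tab <- data.frame(
    node_id = seq_len(nn),
    ml_best_set = vapply(ml$best_sets, paste, "", collapse = ";"),
    mp_state_set = vapply(mp$state_sets, paste, "", collapse = ";"),
    agree = agree,
    stringsAsFactors = FALSE
  )
  if (!is.null(path)) {
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  list(table = tab, agreement = mean(agree))
}
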