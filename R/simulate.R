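#' Simulate a pure-birth (Yule) tree
#'
#' Forward simulation of the Yule process: starting from two lineages at
#' the root, the waiting time to the next speciation with `m` extant
#' lineages is exponential with rate `m * birth_rate`, and a uniformly
#' chosen lineage splits.  After the n-th lineage appears, one further
#' exponential waiting time (rate `n * birth_rate`) is added so that tips
#' are sampled between the n-th and (n+1)-th events; the expected
#' root-to-tip depth is then `sum_{i=2}^{n} 1 / (birth_rate * i)`.
#'
#' @param n_tips number of tips (>= 2).
#' @param birth_rate speciation rate per lineage per unit time (> 0).
#' @param seed optional integer; when given, `set.seed()` is called so the
#'   tree is reproducible.
#' @return a rooted, binary, ultrametric [ape::phylo] with tips
#'   `t1..tn`.
#' @examples
#' tr <- simulate_yule_tree(16, 1, seed = 1)
#' @export
simulate_yule_tree <- function(n_tips, birth_rate = 1, seed = NULL) {
  n_tips <- as.integer(n_tips)
  if (n_tips < 2) stop("n_tips must be >= 2")
  if (birth_rate <= 0) stop("birth_rate must be > 0")
  if (!is.null(seed)) set.seed(seed)

  ## one row per lineage: parent lineage (0 = root), birth and end times
  max_l <- 2L * n_tips
  parent <- integer(max_l)
  t_start <- numeric(max_l)
  t_end <- numeric(max_l)
  alive <- logical(max_l)
  nl <- 2L
  parent[1:2] <- 0L
  alive[1:2] <- TRUE
  now <- 0
  m <- 2L
  while (m < n_tips) {
    now <- now + stats::rexp(1, birth_rate * m)
    live <- which(alive[seq_len(nl)])
    i <- live[sample.int(length(live), 1)]
    t_end[i] <- now
    alive[i] <- FALSE
    parent[nl + 1:2] <- i
    t_start[nl + 1:2] <- now
    alive[nl + 1:2] <- TRUE
    nl <- nl + 2L
    m <- m + 1L
  }
  now <- now + stats::rexp(1, birth_rate * m)
  t_end[alive] <- now

  ## translate lineages to an ape edge matrix
  is_tip <- alive[seq_len(nl)]
  tipnum <- integer(nl)
  tipnum[is_tip] <- seq_len(n_tips)
  node_of <- integer(nl)  # internal node created when a lineage splits
  splitters <- which(!is_tip)
  splitters <- splitters[order(t_end[splitters])]
  node_of[splitters] <- n_tips + 1L + seq_along(splitters)
  edge <- matrix(0L, nl, 2)
  for (j in seq_len(nl)) {
    edge[j, 1] <- if (parent[j] == 0L) n_tips + 1L else node_of[parent[j]]
    edge[j, 2] <- if (is_tip[j]) tipnum[j] else node_of[j]
  }
  tree <- structure(
    list(edge = edge, edge.length = t_end[seq_len(nl)] - t_start[seq_len(nl)],
         tip.label = paste0("t", seq_len(n_tips)), Nnode = n_tips - 1L),
    class = "phylo"
  )
  ape::reorder.phylo(tree, "cladewise")
}

#' Simulate a k-state character along a tree with a recorded history
#'
#' Event-level (Gillespie) simulation of the Mk1 process: along each
#' branch, waiting times between changes are exponential with total rate
#' `(k - 1) * rate`, and each change picks uniformly among the other
#' `k - 1` states.  Every change is recorded, so the true number and order
#' of changes per branch -- not just the endpoints -- is available as
#' ground truth.
#'
#' @param tree a rooted [ape::phylo] with branch lengths.
#' @param k number of states (>= 2); states are coded `1..k`.
#' @param rate instantaneous change rate (>= 0).
#' @param root_state starting state at the root, or `NULL` to draw from
#'   the stationary (uniform) distribution.
#' @param seed optional integer for `set.seed()`.
#' @return An object of class `"simulated_history"`: list with `tree`,
#'   `node_states` (integer per node, ape numbering), `char` (a
#'   [habit_character()] of the tip states with `state_space = 1:k`),
#'   `changes` (data frame `parent`, `child`, `from`, `to`, `time` --
#'   time measured from the start of the branch), `rate`, `k`.
#' @export
simulate_mk_character <- function(tree, k, rate, root_state = NULL,
                                  seed = NULL) {
  k <- as.integer(k)
  if (k < 2) stop("k must be >= 2")
  if (!is.finite(rate) || rate < 0) stop("rate must be finite and >= 0")
  if (!is.null(seed)) set.seed(seed)
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  root <- nt + 1L
  state <- rep(NA_integer_, nn)
  state[root] <- if (is.null(root_state)) sample.int(k, 1)
                 else as.integer(root_state)
  if (state[root] < 1L || state[root] > k) stop("root_state outside 1..k")

  post <- ape::reorder.phylo(tree, "postorder")
  E <- post$edge[rev(seq_len(nrow(post$edge))), , drop = FALSE]  # preorder
  len <- rev(post$edge.length)
  total_rate <- (k - 1) * rate
  ch_parent <- integer(0); ch_child <- integer(0)
  ch_from <- integer(0); ch_to <- integer(0); ch_time <- numeric(0)
  for (e in seq_len(nrow(E))) {
    p <- E[e, 1L]
    child <- E[e, 2L]
    s <- state[p]
    pos <- 0
    if (total_rate > 0) {
      repeat {
        pos <- pos + stats::rexp(1, total_rate)
        if (pos > len[e]) break
        cand <- seq_len(k)[-s]
        s_new <- cand[sample.int(k - 1L, 1)]
        ch_parent <- c(ch_parent, p); ch_child <- c(ch_child, child)
        ch_from <- c(ch_from, s); ch_to <- c(ch_to, s_new)
        ch_time <- c(ch_time, pos)
        s <- s_new
      }
    }
    state[child] <- s
  }
  char <- habit_character(stats::setNames(state[seq_len(nt)],
                                          tree$tip.label),
                          state_space = seq_len(k))
  structure(
    list(tree = tree, node_states = state, char = char,
         changes = data.frame(parent = ch_parent, child = ch_child,
                              from = ch_from, to = ch_to, time = ch_time),
         rate = rate, k = k),
    class = "simulated_history"
  )
}

#' @export
print.simulated_history <- function(x, ...) {
  cat("Simulated Mk1 history: k =", x$k, ", rate =", format(x$rate),
      ",", nrow(x$changes), "changes on",
      length(x$tree$tip.label), "tips\n")
  invisible(x)
}

#' True transition matrix of a simulated history
#'
#' Net ancestor-to-descendant changes read off the true node states: one
#' record per branch whose endpoint states differ.  (Branches carrying two
#' or more changes contribute their net endpoint change, matching what any
#' endpoint-based reconstruction can recover; the full event list is in
#' `history$changes`.)
#'
#' @param history a `"simulated_history"`.
#' @return a `"transition_matrix"` over states `1..k`.
#' @export
true_transition_matrix <- function(history) {
  rec <- enumerate_transitions(history$node_states, history$tree)
  build_transition_matrix(rec, states = seq_len(history$k))
}

#' Simulate a dataset shaped like the scallop study
#'
#' An 81-tip Yule tree carrying a six-state character that starts from a
#' byssal-attaching root (code 2), with the change rate set so that the
#' expected number of character changes on the tree is `target_changes`
#' (the expected Gillespie event count is `(k-1) * rate * total branch
#' length`, so the rate follows in closed form).  This emulates the scale
#' of the empirical analysis: ~81 ingroup species, six habit classes,
#' byssal-dominant ancestry and on the order of 17 changes.
#'
#' @param seed optional integer for `set.seed()`.
#' @param n_tips number of tips (default 81).
#' @param k number of states (default 6).
#' @param target_changes expected number of changes on the tree
#'   (default 17).
#' @param root_state root state code (default 2, byssal attaching).
#' @param birth_rate Yule speciation rate (default 1).
#' @return list with `tree`, `char`, `history` (the
#'   `"simulated_history"`) and `rate` (the tuned true rate).
#' @examples
#' d <- make_study_like_dataset(seed = 1)
#' table(d$char$codes)
#' @export
make_study_like_dataset <- function(seed = NULL, n_tips = 81, k = 6,
                                    target_changes = 17, root_state = 2,
                                    birth_rate = 1) {
  if (!is.null(seed)) set.seed(seed)
  tree <- simulate_yule_tree(n_tips, birth_rate)
  total_len <- sum(tree$edge.length)
  rate <- target_changes / ((k - 1) * total_len)
  history <- simulate_mk_character(tree, k, rate, root_state = root_state)
  list(tree = tree, char = history$char, history = history, rate = rate)
}
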