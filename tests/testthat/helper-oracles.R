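# Independent oracles: exhaustive enumeration over all labelings of the
# unobserved nodes.  Deliberately brute force and structured nothing like
# the pruning/dynamic-programming code they check.

# all labelings of `free` node slots; returns likelihood summed over them
oracle_loglik <- function(tree, char, rate) {
  k <- char$k
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  idx <- match(char$codes, char$state_space)[match(tree$tip.label,
                                                   names(char$codes))]
  idx[char$missing[match(tree$tip.label, names(char$codes))]] <- NA
  P <- lapply(seq_len(nrow(tree$edge)), function(e) {
    mk_transition_prob(mk_model(k, rate), tree$edge.length[e])
  })
  free <- c(which(is.na(idx)), (nt + 1):nn)
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), length(free))))
  tot <- 0
  lab <- integer(nn)
  lab[seq_len(nt)] <- idx
  for (g in seq_len(nrow(grid))) {
    lab[free] <- grid[g, ]
    pr <- 1 / k
    for (e in seq_len(nrow(tree$edge))) {
      pr <- pr * P[[e]][lab[tree$edge[e, 1]], lab[tree$edge[e, 2]]]
    }
    tot <- tot + pr
  }
  log(tot)
}

# per-node, per-state sums of labeling likelihoods (unnormalised marginals)
oracle_marginals <- function(tree, char, rate) {
  k <- char$k
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  idx <- match(char$codes, char$state_space)[match(tree$tip.label,
                                                   names(char$codes))]
  idx[char$missing[match(tree$tip.label, names(char$codes))]] <- NA
  P <- lapply(seq_len(nrow(tree$edge)), function(e) {
    mk_transition_prob(mk_model(k, rate), tree$edge.length[e])
  })
  free <- c(which(is.na(idx)), (nt + 1):nn)
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), length(free))))
  marg <- matrix(0, nn, k)
  lab <- integer(nn)
  lab[seq_len(nt)] <- idx
  for (g in seq_len(nrow(grid))) {
    lab[free] <- grid[g, ]
    pr <- 1 / k
    for (e in seq_len(nrow(tree$edge))) {
      pr <- pr * P[[e]][lab[tree$edge[e, 1]], lab[tree$edge[e, 2]]]
    }
    for (v in seq_len(nn)) marg[v, lab[v]] <- marg[v, lab[v]] + pr
  }
  marg / rowSums(marg)
}

# exhaustive minimum-change score and MPR sets
oracle_parsimony <- function(tree, char) {
  k <- char$k
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  idx <- match(char$codes, char$state_space)[match(tree$tip.label,
                                                   names(char$codes))]
  idx[char$missing[match(tree$tip.label, names(char$codes))]] <- NA
  free <- c(which(is.na(idx)), (nt + 1):nn)
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), length(free))))
  lab <- integer(nn)
  lab[seq_len(nt)] <- idx
  scores <- integer(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    lab[free] <- grid[g, ]
    scores[g] <- sum(lab[tree$edge[, 1]] != lab[tree$edge[, 2]])
  }
  best <- min(scores)
  sets <- vector("list", nn)
  for (v in seq_len(nn)) sets[[v]] <- integer(0)
  for (g in which(scores == best)) {
    lab[free] <- grid[g, ]
    for (v in seq_len(nn)) sets[[v]] <- union(sets[[v]], lab[v])
  }
  list(score = best,
       state_sets = lapply(sets, function(s) sort(char$state_space[s])))
}

# random rooted tree with branch lengths, possibly with a polytomy
random_case_tree <- function(n_tips, polytomy = FALSE) {
  tr <- ape::rtree(n_tips, rooted = TRUE)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 1.5)
  if (polytomy && n_tips >= 4) {
    tr <- ape::di2multi(tr, tol = stats::quantile(tr$edge.length, 0.25))
    if (is.null(tr$edge.length)) tr$edge.length <- rep(0.5, nrow(tr$edge))
    tr$edge.length <- pmax(tr$edge.length, 0.05)
  }
  tr
}

random_case_char <- function(tree, k, p_missing = 0) {
  n <- length(tree$tip.label)
  codes <- sample.int(k, n, replace = TRUE)
  codes[stats::runif(n) < p_missing] <- 0L
  # ensure at least two distinct observed states
  if (length(unique(codes[codes > 0])) < 2) {
    codes[1] <- 1L
    codes[2] <- 2L
  }
  habit_character(stats::setNames(codes, tree$tip.label),
                  state_space = seq_len(k))
}
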