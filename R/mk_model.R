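#' Single-rate Markov k-state (Mk1) model
#'
#' The Mk1 model is a continuous-time Markov chain on k unordered states in
#' which every state-to-state change shares one instantaneous rate `r`.  The
#' generator Q has off-diagonal entries `r` and diagonal `-(k-1) r`, so its
#' transition probabilities have the closed form used throughout this
#' package (see [mk_transition_prob()]).
#'
#' @param k number of states (>= 1).
#' @param rate instantaneous change rate per unit branch length (>= 0).
#' @return An object of class `"mk_model"`.
#' @examples
#' mk_model(6, 0.05)
#' @export
mk_model <- function(k, rate) {
  k <- as.integer(k)
  if (k < 1) stop("k must be >= 1")
  if (!is.finite(rate) || rate < 0) stop("rate must be finite and >= 0")
  structure(list(k = k, rate = rate), class = "mk_model")
}

#' @export
print.mk_model <- function(x, ...) {
  cat("Mk1 model: k =", x$k, "states, rate =", format(x$rate), "\n")
  ll <- attr(x, "loglik")
  if (!is.null(ll)) cat("  log-likelihood at fitted rate:", format(ll), "\n")
  invisible(x)
}

#' Mk1 transition probability matrix
#'
#' For the symmetric one-rate model the matrix exponential of `Q t` is
#' available in closed form:
#' `P_ii(t) = 1/k + ((k-1)/k) exp(-k r t)` and
#' `P_ij(t) = 1/k - (1/k) exp(-k r t)` for `i != j`.  Rows sum to 1; as
#' `t -> Inf` all entries tend to the stationary value `1/k`.
#'
#' @param model an [mk_model()] (or a list with elements `k` and `rate`).
#' @param t branch length (>= 0).
#' @return a `k x k` stochastic matrix.
#' @examples
#' mk_transition_prob(mk_model(2, 1), 1)[1, 2]  # (1 - exp(-2)) / 2
#' @export
mk_transition_prob <- function(model, t) {
  if (!is.finite(t) || t < 0) stop("branch length t must be finite and >= 0")
  k <- model$k
  e <- exp(-k * model$rate * t)
  P <- matrix((1 - e) / k, k, k)
  diag(P) <- (1 + (k - 1) * e) / k
  P
}

## Shared pruning engine.
##
## Computes conditional ("down") partial likelihoods by Felsenstein pruning
## in scaled arithmetic, and optionally the "up" (outside) partials needed
## for marginal ancestral reconstruction.  Works on binary and multifurcating
## rooted trees.  Tips with missing states carry an all-ones partial.
##
## Marginals: with D[v,s] the likelihood of the data below node v given
## state s, and U[v,s] the likelihood of everything outside v's subtree
## (including the root prior), the joint likelihood of the data with node v
## fixed in state s is D[v,s] * U[v,s]; summing over s at any node recovers
## the tree likelihood.  U is propagated root-to-tip: for child c of v with
## lifted sibling vectors W_b[s] = sum_{s'} P_{s s'}(t_b) D[b, s'],
##   U[c, s'] = sum_s P_{s' s}(t_c) * U[v, s] * prod_{b != c} W_b[s].
## Exclude-one products use prefix/suffix products (no division, safe with
## zero entries at rate ~ 0).
mk_engine <- function(tree, char, rate, marginals = FALSE,
                      min_branch_length = 1e-8) {
  k <- char$k
  if (k < 2) stop("likelihood requires k >= 2 observed states")
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  tips <- normalize_taxon(tree$tip.label)
  if (!all(tips %in% names(char$codes))) {
    stop("tree tips without character entries: ",
         paste(setdiff(tips, names(char$codes)), collapse = ", "))
  }
  idx <- char_index(char)[tips]

  post <- ape::reorder.phylo(tree, "postorder")
  E <- post$edge
  len <- post$edge.length
  if (is.null(len)) len <- rep(min_branch_length, nrow(E))
  len <- pmax(len, min_branch_length)
  root <- nt + 1L

  ## per-edge P matrices
  D <- matrix(1, nn, k)
  for (i in seq_len(nt)) {
    if (!is.na(idx[i])) {
      D[i, ] <- 0
      D[i, idx[i]] <- 1
    }
  }
  lscD <- numeric(nn)
  W <- matrix(0, nn, k)  # lifted vector of each non-root node (scaled as D[child])

  for (e in seq_len(nrow(E))) {
    p <- E[e, 1L]
    ch <- E[e, 2L]
    P <- mk_transition_prob(list(k = k, rate = rate), len[e])
    w <- as.vector(P %*% D[ch, ])
    W[ch, ] <- w
    D[p, ] <- D[p, ] * w
    lscD[p] <- lscD[p] + lscD[ch]
    m <- max(D[p, ])
    if (!is.finite(m) || m <= 0) {
      stop("numerical failure in pruning at node ", p)
    }
    D[p, ] <- D[p, ] / m
    lscD[p] <- lscD[p] + log(m)
  }

  pi0 <- rep(1 / k, k)
  lik_root <- sum(D[root, ] * pi0)
  loglik <- log(lik_root) + lscD[root]
  if (!is.finite(loglik)) stop("non-finite log-likelihood at root")

  out <- list(loglik = loglik, k = k, rate = rate,
              state_space = char$state_space)
  if (!marginals) return(out)

  ## children lists and edge lengths per child
  children <- vector("list", nn)
  len_of <- numeric(nn)
  for (e in seq_len(nrow(E))) {
    p <- E[e, 1L]
    children[[p]] <- c(children[[p]], E[e, 2L])
    len_of[E[e, 2L]] <- len[e]
  }

  U <- matrix(0, nn, k)
  lscU <- numeric(nn)
  U[root, ] <- pi0
  ## preorder = reverse postorder on parents
  parents_pre <- unique(rev(E[, 1L]))
  for (v in parents_pre) {
    cs <- children[[v]]
    m <- length(cs)
    ## prefix/suffix products of W over children of v
    pre <- matrix(1, m + 1L, k)
    for (j in seq_len(m)) pre[j + 1L, ] <- pre[j, ] * W[cs[j], ]
    suf <- matrix(1, m + 1L, k)
    for (j in rev(seq_len(m))) suf[j, ] <- suf[j + 1L, ] * W[cs[j], ]
    sum_lsc <- sum(lscD[cs])
    for (j in seq_len(m)) {
      ch <- cs[j]
      A <- U[v, ] * pre[j, ] * suf[j + 1L, ]
      P <- mk_transition_prob(list(k = k, rate = rate), len_of[ch])
      u <- as.vector(P %*% A)  # P symmetric: P^T = P
      sc <- max(u)
      if (sc <= 0 || !is.finite(sc)) {
        stop("numerical failure in up-pass at node ", ch)
      }
      U[ch, ] <- u / sc
      lscU[ch] <- lscU[v] + (sum_lsc - lscD[ch]) + log(sc)
    }
  }

  ## lscD/lscU have length nrow and recycle down columns: per-row offsets
  lnM <- log(D) + log(U) + lscD + lscU
  prob <- exp(lnM - apply(lnM, 1, max))
  prob <- prob / rowSums(prob)
  colnames(lnM) <- colnames(prob) <- as.character(char$state_space)
  out$ln_marginal <- lnM
  out$prob <- prob
  out
}

#' Log-likelihood of a character on a tree under Mk1
#'
#' Probability of the tip data given the tree and model, computed by
#' Felsenstein's post-order pruning algorithm in scaled arithmetic, with a
#' uniform `1/k` prior over states at the root.  Missing tips (code 0)
#' contribute an all-ones partial likelihood; if every tip is missing the
#' likelihood is 1 (log-likelihood 0).
#'
#' @param tree a rooted [ape::phylo]; polytomies allowed.
#' @param char a [habit_character()] whose taxa cover the tree's tips.
#' @param model an [mk_model()]; its `k` must equal `char$k`.
#' @param min_branch_length floor applied to branch lengths.
#' @return the log-likelihood (a scalar).
#' @export
mk_tree_loglik <- function(tree, char, model, min_branch_length = 1e-8) {
  if (model$k != char$k) {
    stop("model k (", model$k, ") does not match character k (", char$k, ")")
  }
  mk_engine(tree, char, model$rate,
            marginals = FALSE, min_branch_length = min_branch_length)$loglik
}

#' Maximum-likelihood estimate of the Mk1 rate
#'
#' One-dimensional bounded optimisation of [mk_tree_loglik()] over the rate,
#' on a log scale, within `[1e-8, 1000 / tree height]`.  An invariant
#' character (fewer than two observed states) has no information about the
#' rate: the lower bound is returned with a warning.
#'
#' @inheritParams mk_tree_loglik
#' @param lower,upper optional bracket for the rate; the default upper bound
#'   is `1000 / max root-to-tip height`.
#' @return an [mk_model()] with the fitted rate; the achieved log-likelihood
#'   is attached as attribute `"loglik"`.
#' @export
mk_fit <- function(tree, char, lower = 1e-8, upper = NULL,
                   min_branch_length = 1e-8) {
  n_states <- length(unique(char$codes[!char$missing]))
  if (n_states < 2) {
    warning("invariant character: rate set to lower bound")
    mod <- mk_model(max(char$k, 1L), lower)
    attr(mod, "loglik") <- if (char$k >= 2) {
      mk_engine(tree, char, lower,
                min_branch_length = min_branch_length)$loglik
    } else 0
    return(mod)
  }
  if (is.null(upper)) {
    height <- max(ape::node.depth.edgelength(tree))
    if (!is.finite(height) || height <= 0) height <- 1
    upper <- 1000 / height
  }
  f <- function(lr) {
    mk_engine(tree, char, exp(lr),
              min_branch_length = min_branch_length)$loglik
  }
  opt <- stats::optimize(f, interval = log(c(lower, upper)), maximum = TRUE,
                         tol = 1e-8)
  rate <- exp(opt$maximum)
  mod <- mk_model(char$k, rate)
  attr(mod, "loglik") <- opt$objective
  mod
}

#' Marginal ancestral state reconstruction under Mk1
#'
#' For every node (internal nodes and tips) computes the marginal likelihood
#' of each state -- the likelihood of all tip data with that node fixed in
#' that state, integrating over all other nodes -- by a two-pass
#' (down/up) algorithm equivalent to re-rooting at each node.  Marginal
#' probabilities are the normalised marginal likelihoods.  The
#' log-likelihood decision rule (see [apply_lnl_rule()]) is applied with the
#' given threshold to produce a best-state set per node: states whose log
#' marginal likelihood falls more than `threshold` units below the node's
#' best state are rejected; the rest are retained, and a node is "resolved"
#' when a single state survives.
#'
#' @inheritParams mk_tree_loglik
#' @param model an [mk_model()], or `NULL` to fit the rate first with
#'   [mk_fit()].
#' @param threshold log-likelihood difference above which a state is
#'   rejected (default 2.0; a difference exactly equal to the threshold is
#'   kept, i.e. ambiguous).
#' @return An object of class `"habit_asr"`: list with `tree`, `model`,
#'   `log_likelihood`, `ln_marginal` (nodes x states, natural log),
#'   `prob` (normalised marginals), `best_sets` (list of state-code vectors
#'   per node), `resolved` (logical per node) and `threshold`.
#' @export
mk_marginal_asr <- function(tree, char, model = NULL, threshold = 2,
                            min_branch_length = 1e-8) {
  if (is.null(model)) model <- mk_fit(tree, char,
                                      min_branch_length = min_branch_length)
  if (model$k != char$k) stop("model k does not match character k")
  eng <- mk_engine(tree, char, model$rate, marginals = TRUE,
                   min_branch_length = min_branch_length)
  best <- apply_lnl_rule(eng$ln_marginal, threshold,
                         state_space = char$state_space)
  structure(
    list(tree = tree, model = model, log_likelihood = eng$loglik,
         ln_marginal = eng$ln_marginal, prob = eng$prob,
         best_sets = best, resolved = lengths(best) == 1L,
         threshold = threshold, state_space = char$state_space),
    class = "habit_asr"
  )
}

#' @export
print.habit_asr <- function(x, ...) {
  nt <- length(x$tree$tip.label)
  internal <- (nt + 1):(nt + x$tree$Nnode)
  cat("Mk1 marginal ancestral state reconstruction\n")
  cat("  rate =", format(x$model$rate),
      " lnL =", format(x$log_likelihood), "\n")
  cat("  ", sum(x$resolved[internal]), "of", length(internal),
      "internal nodes resolved at dlnL threshold", x$threshold, "\n")
  invisible(x)
}

#' Log-likelihood decision rule for ancestral states
#'
#' Per node, keeps every state whose natural-log marginal likelihood lies
#' within `threshold` units of that node's best state.  A difference
#' strictly greater than the threshold rejects the worse state; a difference
#' exactly equal to it is ambiguous (both states kept).  A singleton
#' surviving set means the node is resolved.
#'
#' @param ln_marginal numeric matrix (nodes x states) of log marginal
#'   likelihoods, or a `"habit_asr"` object.
#' @param threshold positive log-likelihood difference (default 2.0).
#' @param state_space codes labelling the columns; defaults to the column
#'   names of the matrix.
#' @return a list, one integer vector of surviving state codes per node.
#' @examples
#' apply_lnl_rule(rbind(c(-10, -12.5), c(-10, -11)), 2,
#'                state_space = c(2, 3))
#' @export
apply_lnl_rule <- function(ln_marginal, threshold = 2, state_space = NULL) {
  if (inherits(ln_marginal, "habit_asr")) {
    state_space <- ln_marginal$state_space
    ln_marginal <- ln_marginal$ln_marginal
  }
  if (threshold <= 0) stop("threshold must be > 0")
  if (is.null(state_space)) {
    state_space <- as.integer(colnames(ln_marginal))
  }
  apply(ln_marginal, 1, function(v) {
    state_space[max(v) - v <= threshold]
  }, simplify = FALSE)
}

#' Export a reconstruction as a node table
#'
#' @param asr a `"habit_asr"` object.
#' @param path optional path; when given, the table is written as TSV.
#' @return a data frame with one row per node: `node_id`, `parent_id`,
#'   `label` (tip name or empty), one probability column per state
#'   (`p_<code>`), `best_state_set` (semicolon-joined codes) and `resolved`.
#' @export
asr_table <- function(asr, path = NULL) {
  tree <- asr$tree
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  parent <- rep(NA_integer_, nn)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  tab <- data.frame(
    node_id = seq_len(nn),
    parent_id = parent,
    label = c(tree$tip.label, rep("", tree$Nnode)),
    stringsAsFactors = FALSE
  )
  probs <- round(asr$prob, 6)
  colnames(probs) <- paste0("p_", asr$state_space)
  tab <- cbind(tab, probs)
  tab$best_state_set <- vapply(asr$best_sets, paste, "", collapse = ";")
  tab$resolved <- asr$resolved
  if (!is.null(path)) {
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  tab
}
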