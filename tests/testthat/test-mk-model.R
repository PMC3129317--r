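test_that("Mk transition probabilities match limits and the matrix exponential", {
  # no-change limit
  expect_equal(mk_transition_prob(mk_model(4, 0), 5), diag(4))
  # stationary limit
  P <- mk_transition_prob(mk_model(4, 1), 1e6)
  expect_equal(P, matrix(0.25, 4, 4), tolerance = 1e-9)
  # k = 2 closed form
  expect_equal(mk_transition_prob(mk_model(2, 1), 1)[1, 2],
               (1 - exp(-2)) / 2, tolerance = 1e-12)
  # independent oracle: numerical exponential of Q via eigen decomposition
  for (k in c(2, 3, 6)) {
    r <- 0.37
    t <- 0.9
    Q <- matrix(r, k, k)
    diag(Q) <- -(k - 1) * r
    eg <- eigen(Q, symmetric = TRUE)
    Pnum <- eg$vectors %*% diag(exp(eg$values * t)) %*% t(eg$vectors)
    expect_equal(mk_transition_prob(mk_model(k, r), t), Pnum,
                 tolerance = 1e-10)
    expect_equal(rowSums(mk_transition_prob(mk_model(k, r), t)),
                 rep(1, k), tolerance = 1e-12)
  }
  expect_error(mk_transition_prob(mk_model(2, 1), -1), ">= 0")
})

test_that("pruning log-likelihood matches closed forms on tiny trees", {
  # two tips in different states: lnL = log(0.5 * 2 * P11(1) * P12(1))
  tr <- read_habit_tree(text = "(A:1,B:1);")
  ch <- habit_character(c(A = 1, B = 2))
  expected <- log(0.5 * 2 * ((1 + exp(-2)) / 2) * ((1 - exp(-2)) / 2))
  expect_equal(mk_tree_loglik(tr, ch, mk_model(2, 1)), expected,
               tolerance = 1e-9)
  expect_equal(expected, -1.4047, tolerance = 1e-4)

  # all tips missing: all-ones partials, likelihood 1
  tr3 <- read_habit_tree(text = "((A:1,B:1):1,C:2);")
  ch0 <- habit_character(c(A = 0, B = 0, C = 0), state_space = 1:3)
  expect_equal(mk_tree_loglik(tr3, ch0, mk_model(3, 0.5)), 0,
               tolerance = 1e-12)

  expect_error(mk_tree_loglik(tr, habit_character(c(A = 2, B = 2)),
                              mk_model(1, 1)), "k >= 2")
})

test_that("pruning equals exhaustive enumeration on random trees", {
  set.seed(101)
  for (rep in 1:30) {
    k <- sample(c(2, 3, 6), 1)
    n <- sample(3:6, 1)
    tr <- random_case_tree(n, polytomy = rep %% 3 == 0)
    ch <- random_case_char(tr, k, p_missing = 0.15)
    rate <- stats::runif(1, 0.05, 1.5)
    expect_equal(mk_tree_loglik(tr, ch, mk_model(k, rate)),
                 oracle_loglik(tr, ch, rate), tolerance = 1e-8)
  }
})

test_that("log-likelihood is invariant under child-order permutation", {
  set.seed(7)
  tr <- random_case_tree(6)
  ch <- random_case_char(tr, 3)
  ll <- mk_tree_loglik(tr, ch, mk_model(3, 0.4))
  nt <- length(tr$tip.label)
  for (node in (nt + 1):(nt + tr$Nnode)) {
    tr2 <- tryCatch(ape::rotate(tr, node), error = function(e) NULL)
    if (is.null(tr2)) next
    expect_equal(mk_tree_loglik(tr2, ch, mk_model(3, 0.4)), ll,
                 tolerance = 1e-10)
  }
})

test_that("stationary limit of the likelihood matches the closed form", {
  # as r -> Inf every branch mixes completely: each non-missing tip
  # contributes 1/k independently
  set.seed(11)
  tr <- random_case_tree(6)
  ch <- random_case_char(tr, 3, p_missing = 0.2)
  n_obs <- sum(!ch$missing)
  expect_equal(mk_tree_loglik(tr, ch, mk_model(3, 500)),
               n_obs * log(1 / 3), tolerance = 1e-6)
})

test_that("rate estimation recovers truth and is locally optimal", {
  # invariant character: no information, lower bound with warning
  tr <- read_habit_tree(text = "((A:1,B:1):1,C:2);")
  expect_warning(fit <- mk_fit(tr, habit_character(c(A = 2, B = 2, C = 2))),
                 "invariant")
  expect_equal(fit$rate, 1e-8)

  # local optimality of the maximiser
  set.seed(3)
  tr <- random_case_tree(12)
  ch <- random_case_char(tr, 3)
  fit <- mk_fit(tr, ch)
  ll <- function(r) mk_tree_loglik(tr, ch, mk_model(3, r))
  expect_gte(attr(fit, "loglik") + 1e-9, ll(fit$rate * 0.5))
  expect_gte(attr(fit, "loglik") + 1e-9, ll(fit$rate * 2))

  # simulation-based recovery: true r = 0.5, 128-tip tree, 50 characters
  tree <- simulate_yule_tree(128, 1, seed = 77)
  set.seed(78)
  rhat <- vapply(1:50, function(i) {
    h <- simulate_mk_character(tree, k = 4, rate = 0.5)
    mk_fit(tree, h$char)$rate
  }, numeric(1))
  expect_gte(stats::median(rhat), 0.35)
  expect_lte(stats::median(rhat), 0.70)
})

test_that("fit and marginals agree with an independent implementation", {
  skip_if_not_installed("phytools")
  tree <- simulate_yule_tree(40, 1, seed = 15)
  h <- simulate_mk_character(tree, k = 3, rate = 0.3, seed = 16)
  ch <- h$char
  x <- stats::setNames(as.character(ch$codes), names(ch$codes))
  fit_ref <- phytools::fitMk(tree, x, model = "ER", pi = "equal")
  fit <- mk_fit(tree, ch)
  expect_equal(fit$rate, unname(fit_ref$rates), tolerance = 1e-4)
  expect_equal(attr(fit, "loglik"), as.numeric(stats::logLik(fit_ref)),
               tolerance = 1e-6)
  anc <- phytools::ancr(fit_ref)
  asr <- mk_marginal_asr(tree, ch, mk_model(3, unname(fit_ref$rates)))
  nt <- length(tree$tip.label)
  expect_equal(unname(as.matrix(anc$ace)),
               unname(asr$prob[(nt + 1):(nt + tree$Nnode), ]),
               tolerance = 1e-8)
})

test_that("marginal reconstruction matches the exhaustive oracle", {
  set.seed(202)
  for (rep in 1:10) {
    k <- sample(2:3, 1)
    tr <- random_case_tree(5, polytomy = rep %% 4 == 0)
    ch <- random_case_char(tr, k, p_missing = 0.1)
    rate <- stats::runif(1, 0.1, 1)
    asr <- mk_marginal_asr(tr, ch, mk_model(k, rate))
    expect_equal(asr$prob, oracle_marginals(tr, ch, rate),
                 tolerance = 1e-8, ignore_attr = TRUE)
    # marginal probabilities are proper per node
    expect_equal(rowSums(asr$prob), rep(1, nrow(asr$prob)),
                 tolerance = 1e-9)
    expect_true(all(asr$prob >= 0 & asr$prob <= 1))
    # summing the joint marginal likelihood over states at any node
    # recovers the tree likelihood
    expect_equal(log(rowSums(exp(asr$ln_marginal))),
                 rep(asr$log_likelihood, nrow(asr$prob)),
                 tolerance = 1e-8)
  }
})

test_that("symmetric two-tip reconstruction puts equal mass on both states", {
  tr <- read_habit_tree(text = "(A:1,B:1);")
  ch <- habit_character(c(A = 1, B = 2))
  asr <- mk_marginal_asr(tr, ch, mk_model(2, 0.7))
  expect_equal(unname(asr$prob[3, ]), c(0.5, 0.5), tolerance = 1e-12)
})

test_that("near-invariant data give confident reconstructions", {
  set.seed(9)
  tr <- random_case_tree(8)
  ch <- habit_character(stats::setNames(rep(2L, 8), tr$tip.label),
                        state_space = c(2L, 3L))
  asr <- mk_marginal_asr(tr, ch, mk_model(2, 0.01))
  nt <- 8
  internal <- (nt + 1):(nt + tr$Nnode)
  expect_true(all(asr$prob[internal, "2"] > 0.99))
})

test_that("the log-likelihood decision rule keeps ties and near-ties", {
  lnM <- rbind(c(-10, -12.5), c(-10, -11), c(-10, -12))
  sets <- apply_lnl_rule(lnM, 2, state_space = c(1L, 2L))
  expect_equal(sets[[1]], 1L)              # difference 2.5 > 2: rejected
  expect_equal(sets[[2]], c(1L, 2L))       # difference 1.0: ambiguous
  expect_equal(sets[[3]], c(1L, 2L))       # exactly 2.0: still ambiguous
  expect_error(apply_lnl_rule(lnM, 0), "> 0")
})

test_that("asr_table exports one labelled row per node", {
  tr <- read_habit_tree(text = "((A:1,B:1):1,C:2);")
  ch <- habit_character(c(A = 2, B = 2, C = 3))
  asr <- mk_marginal_asr(tr, ch, mk_model(2, 0.3))
  path <- withr::local_tempfile(fileext = ".tsv")
  tab <- asr_table(asr, path)
  expect_equal(nrow(tab), 5)
  expect_true(all(c("p_2", "p_3", "best_state_set", "resolved") %in%
                    names(tab)))
  reread <- utils::read.delim(path)
  expect_equal(nrow(reread), 5)
})
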