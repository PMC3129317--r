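---
title: "Reconstructing life-habit evolution: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing life-habit evolution: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(habitevol)
```

## The question and the data

Scallops (Pectinidae) display six adult life habits -- cementing, byssal
attaching, free-living, recessing, gliding and nestling -- and the family
is a model for asking how often ecological modes re-evolve, and whether
repeated origins follow *parallel* trajectories (same ancestral state) or
*convergent* ones (different ancestral states).  `habitevol` implements
that analysis as a pipeline over two inputs: a rooted phylogeny with
branch lengths (Newick) and a species-to-habit table coded
`0` = unknown, `1` = cementing, `2` = byssal attaching, `3` = free-living,
`4` = recessing, `5` = gliding, `6` = nestling.  Code 0 is missing data:
such species enter every computation with an uninformative (all-ones or
all-states) contribution and are never themselves reconstructed as a
state.

## The Mk1 model

Ancestral states are estimated under the one-parameter Markov k-state
model: a continuous-time Markov chain in which every change between any
two of the k observed states shares a single instantaneous rate $r$.  The
generator has off-diagonal entries $r$ and diagonal $-(k-1)r$, giving the
closed-form transition probabilities

$$P_{ii}(t) = \tfrac{1}{k} + \tfrac{k-1}{k}e^{-krt},\qquad
  P_{ij}(t) = \tfrac{1}{k} - \tfrac{1}{k}e^{-krt},$$

which `mk_transition_prob()` evaluates directly (the test suite checks
them against a numerical matrix exponential).  The model is symmetric and
unordered: it encodes no hypothesis about which habit transitions are
easy, which is exactly why a *bias* in reconstructed transitions is
interpretable downstream.

The tree likelihood is computed by Felsenstein's post-order pruning with
per-node rescaling in log space (trees of ~90 tips with near-zero
consensus branches underflow otherwise), and the root is closed with a
uniform $1/k$ prior over the observed state space -- the conventional
default when no stationary argument favours any state.  The rate is
estimated once for the whole tree and character by bounded 1-D
maximisation of the log-likelihood on $[10^{-8}, 1000/\mathrm{height}]$,
searched on a log scale (`mk_fit()`).  Two degenerate regimes are worth
knowing about: an invariant character carries no rate information (the
lower bound is returned with a warning), and very small or conflict-free
datasets can place the maximum in the saturated regime ($r$ large, all
assignments ambiguous), which is the correct maximum-likelihood answer
even if it looks pathological -- fix the rate explicitly if you want a
didactic reconstruction on a toy tree.

## Marginal reconstruction and the decision rule

For every node the package computes the *marginal* likelihood of each
state: the probability of all tip data with that node clamped, obtained
in one extra root-to-tip pass over "outside" partial likelihoods
(equivalent to re-rooting at every node, but linear time).  Summing the
per-state marginal likelihoods at any node recovers the tree likelihood
-- an identity the tests assert at every node.  Normalised, these are the
per-node probabilities users plot as pies.

Best-state sets then follow a log-likelihood-ratio rule with threshold
2.0 (configurable): a state is rejected at a node when its log marginal
likelihood falls *more than* 2.0 units below the node's best state; a
difference of exactly 2.0 is retained as ambiguous.  A node is "resolved"
when a single state survives.  The rule is applied to marginal
likelihoods; applying it to normalised probabilities would give identical
sets, since the normaliser is constant within a node.

## Parsimony cross-check

`sankoff_parsimony()` implements unordered parsimony as Sankoff dynamic
programming with unit costs, which generalises Fitch to multifurcating
trees without inflating scores at polytomies.  It reports the exact
minimum number of changes and, via a second pass, the full MPR set at
every node -- the states attained in at least one minimum-change
labelling -- rather than a single ACCTRAN/DELTRAN resolution, so
ambiguity is reported instead of hidden.  Missing tips contribute all
states at no cost.  The tests verify both score and MPR sets against
exhaustive enumeration of all labellings on small trees and the score
against an independent implementation (phangorn).

## From reconstructions to transitions

Transition counting needs one state per node.  Resolved nodes take their
state.  Ambiguous nodes are handled by policy:

* `inherit_parent` (default): an ambiguous node adopts its parent's
  assigned state when that state is in its own surviving set.  This
  propagates states tipward and realises a minimal number of changes
  *among parent-propagation completions*.  It is not guaranteed to be a
  global minimum over all completions of the ambiguous sets -- a parent
  state can be inherited into a node whose children all favour the other
  state -- which is why both policies are exposed.
* `skip_branch`: ambiguous nodes stay unassigned.  Branches touching
  them contribute nothing, so this count is a provable lower bound on
  the count under *every* consistent completion (the tests check this
  exhaustively on small trees).

One record is emitted per branch whose assigned endpoint states differ;
terminal branches count, because single-species origins are real
origins.  Records aggregate into a from-state x to-state count matrix;
column sums are origins of a state, row sums are the transitions a state
generated.  An optional ingroup restriction keeps branches inside a named
clade plus the branch subtending its root, so a change on the stem of the
family is attributed to the family.

## Parallel versus convergent origins

Each inbound transition is one origin event whose ancestral state is the
state assigned to the parent node of the branch where the derived state
appears.  For a derived state with $m \ge 2$ origins, every unordered
pair of origins is labelled *parallel* (equal ancestral states) or
*convergent* (different); the per-state summary is `unique`, `parallel`,
`convergent` (all ancestors pairwise distinct) or `both`.  Pairs are the
primitive because real datasets mix trajectories -- in the scallop
counts, gliding has four origins, two from recessing and two from byssal
ancestors, hence 2 parallel and 4 convergent pairs and a summary of
`both`.  `count_parallel_from_state()` defaults to row-sum arithmetic
(every origin from the given ancestor counts); the stricter
`partnered_only` variant drops origins with no same-ancestor partner.
On the bundled counts the two conventions give 12 and 10 for byssal
ancestors respectively -- the package exposes both rather than
adjudicating.

## The progenitor-bias test

Under no constraint, each habit class should be equally likely to be the
source of a transition.  `chi_square_uniform()` tests this with the
Pearson statistic against uniform expected counts `total/m`, df $= m-1$,
asymptotic upper-tail p-value, no continuity correction.  Categories with
zero observed transitions stay in the category set -- dropping them would
bias the test toward uniformity.  Two groupings are built in: all six
habit classes, and a five-category version merging cementing and nestling
into "permanent attachment" to reduce sparse cells.  On the bundled
scallop counts these give $X^2 = 37.0$ (df 5) and $X^2 = 28.0$ (df 4).
With 17 transitions over 5--6 categories the asymptotic approximation is
imperfect; a simulation test in the suite confirms the type-I error at
$\alpha = 0.05$ stays in a loose [0.03, 0.08] band, and an exact
multinomial test is a documented extension point rather than a default.

## What the simulator emulates

`simulate_yule_tree()` is a forward pure-birth process: with $m$
lineages the next speciation arrives after an $\mathrm{Exp}(m\lambda)$
wait, and a final $\mathrm{Exp}(n\lambda)$ segment is appended after the
$n$-th lineage so the expected root-to-tip depth is exactly
$\sum_{i=2}^{n} 1/(\lambda i)$ (the tests check the Monte-Carlo mean
against this closed form).  `simulate_mk_character()` is an event-level
Gillespie simulation -- exponential waits at total rate $(k-1)r$, uniform
choice among the other states -- so the *entire* change history per
branch is recorded, not just endpoints.  That is the point: transition
enumeration can be tested against true change lists, and parsimony
against the true count (always a lower bound).

`make_study_like_dataset()` packages the study conditions: 81 tips, six
states, a byssal-attaching root (the inferred ancestral condition for
the family), and the rate set so the expected number of changes on the
simulated tree is 17 -- since the expected event count on a fixed tree is
$(k-1)\,r\,L$ for total branch length $L$, the rate follows in closed
form rather than by search.  Under these settings byssal attachment is
the modal tip state in well over 80% of replicates, echoing the 52%
byssal share in the empirical sample.

What the simulator does *not* emulate: extinction (pure birth only),
trait-dependent diversification, rate heterogeneity across lineages or
states, and the phylogenetic uncertainty of a real consensus tree
(simulated trees are binary and fully resolved).  Passing recovery tests
on these simulations therefore validates the machinery, not the claim
that any real dataset satisfies the Mk1 assumptions.

## Numerical choices

* Branch lengths of zero or absent are clamped to `min_branch_length`
  ($10^{-8}$ by default) for likelihood work; $P(t)$ is singular only in
  the limit, and consensus trees routinely carry near-zero branches.
  Parsimony ignores lengths entirely.
* All likelihood work is done with per-node rescaling and log-space
  bookkeeping; marginal log-likelihoods are exact up to floating point,
  and `-Inf` entries (impossible states at observed tips) are handled
  naturally by the decision rule.
* The up-pass computes exclude-one-child products by prefix/suffix
  multiplication, not division, so zero partials at rate ~0 cannot
  produce NaNs.
* Ties at the decision threshold are kept ambiguous ("greater than"
  rejects); MPR membership uses exact integer equality of cost sums.

## Problem sizes in the tests

The exhaustive oracles enumerate all $k^{\text{free nodes}}$ labellings,
so oracle-backed tests run on trees of up to 6 tips with $k \le 6$ (at
most $6^5$ terms), over 100 likelihood cases and 500 parsimony cases.
Simulation-backed checks use 50 replicates at the full study scale (81
tips, $k = 6$) for rate and history recovery, 200 trees for the Yule
depth expectation, and 500 replicates for the Poisson mean of the change
count; the full suite completes in well under a minute on a laptop-class
core.

## Known limitations

* A resolved node is not necessarily a correct node.  At study-like
  signal levels (roughly one expected change per ten branches), a pair
  of changes -- e.g. a derived state reverting on a long branch -- can
  make the wrong state *more likely* at a node by more than the 2.0
  threshold.  In the recovery experiments this is rare (resolved-node
  accuracy is ~99%) but it means a dataset whose nodes are all resolved
  can still yield a transition matrix differing from truth in a cell or
  two.  Treat "resolved" as "decisive given the model", not as
  certainty.
* The minimum-transition convention undercounts when ambiguity is
  widespread: branches with unassigned endpoints are silently excluded,
  which is the intended reading of a "minimum of N transitions" claim
  but should be remembered when comparing counts across datasets.
* The Mk1 model's single rate is a strong assumption; states that are
  easy to leave and states that are absorbing are averaged into one
  parameter.  The observed progenitor bias is detected *despite* this
  symmetry, not modelled by it.  Asymmetric-rate models are out of scope
  here.
* With the state space taken from observed tip states, a state present
  in the history but absent at the tips is invisible to the analysis;
  supply `state_space` explicitly in `habit_character()` when the full
  space is known a priori.
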