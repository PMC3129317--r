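# habitevol

Ancestral state reconstruction and convergence analysis for categorical
life-habit traits on phylogenies.

Scallops (Bivalvia: Pectinidae) exhibit six adult life habits —
cementing, byssal attaching, free-living, recessing, gliding and
nestling — and five of the six have evolved repeatedly.  `habitevol`
implements the full analysis that turns a rooted phylogeny plus a
species-to-habit table into evolutionary conclusions:

1. **Mk1 likelihood ancestral state reconstruction** — the one-parameter
   Markov k-state model (every change shares one rate *r*; transition
   probabilities `P_ii(t) = 1/k + ((k−1)/k)e^(−krt)`,
   `P_ij(t) = 1/k − (1/k)e^(−krt)`), Felsenstein pruning with per-node
   scaling, ML rate estimation, marginal per-node state probabilities,
   and a likelihood-ratio decision rule (states more than 2.0 log units
   worse than the best are rejected; smaller differences are ambiguous).
2. **Unordered parsimony** (Sankoff with unit costs, polytomy-safe) with
   full most-parsimonious-reconstruction sets, as a cross-check.
3. **Transition enumeration** — per-branch ancestor→descendant state
   changes under a minimum-transition convention, aggregated into a
   from×to count matrix; origins of a state are its column sums.
4. **Parallel vs convergent classification** — pairs of independent
   origins of the same derived state are *parallel* when their ancestral
   states match and *convergent* otherwise.
5. **Progenitor-bias chi-square test** — are transitions equally likely
   to originate from every habit class?  Pearson X² against uniform
   expectations, in six-state and merged-permanent groupings.
6. **Simulators with recorded truth** — forward Yule trees and
   event-level (Gillespie) Mk character histories, so every stage is
   testable against known ancestral states and change lists.

Written for phylogenetic comparative biologists; trees are plain
`ape::phylo` objects and all heavy conventions follow the
ape/phangorn/phytools ecosystem.

## Worked example

The package bundles the published transition counts among scallop life
habits (17 transitions read off an ML reconstruction over an 81-species
phylogeny):

```r
library(habitevol)
tm <- scallop_transition_counts()
print(tm)
#> Transition counts (rows = ancestral state, cols = derived):
#>             cementing byssal free-living recessing gliding nestling
#> cementing           0      0           0         0       0        0
#> byssal              2      0           6         1       2        1
#> free-living         0      1           0         1       0        0
#> recessing           0      0           0         0       2        0
#> gliding             0      0           1         0       0        0
#> nestling            0      0           0         0       0        0
#> Total transitions: 17

origins_of_state(tm, "free-living")   # 7 independent origins
transitions_from_state(tm, "byssal")  # 12 transitions from byssal ancestors

chi_square_uniform(source_counts(tm, "six_state"))
#> 	Chi-square test of uniform transition-source frequencies
#> data:  source counts
#> X-squared = 37, df = 5, p-value = 5.989e-07

classify_origins(collect_origins(transition_records_from_matrix(tm)))
#>      derived n_origins     ancestors parallel_pairs convergent_pairs    summary
#>    cementing         2           2;2              1                0   parallel
#>       byssal         1             3              0                0     unique
#>  free-living         7 2;2;2;2;2;2;5             15                6       both
#>    recessing         2           2;3              0                1 convergent
#>      gliding         4       2;2;4;4              2                4       both
#>     nestling         1             2              0                0     unique
```

Reading the output: byssal attachment is the progenitor of 12 of the 17
transitions (X² = 37.0 on 5 df — far from uniform), free-living arose
seven times (six in parallel from byssal ancestors, once from a gliding
ancestor), recessing arose twice convergently (byssal and free-living
ancestors), gliding four times along both parallel and convergent
trajectories, and nestling is a unique origin.

On simulated data with known truth:

```r
d <- make_study_like_dataset(seed = 7)   # 81 tips, k = 6, byssal root,
                                         # rate tuned to E[changes] = 17
fit <- mk_fit(d$tree, d$char)
fit$rate                                 # 0.0321 (true rate 0.0553)
asr <- mk_marginal_asr(d$tree, d$char, fit)
print(asr)
#> Mk1 marginal ancestral state reconstruction
#>   rate = 0.03209612  lnL = -48.18216
#>    79 of 80 internal nodes resolved at dlnL threshold 2
```

The whole pipeline (read → fit → reconstruct → count → classify → test,
with all artifacts written to a directory) is one call:

```r
run_habit_pipeline("tree.nwk", "habits.csv", "out/")
```

or from a shell via `inst/scripts/run_pipeline.R`.

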