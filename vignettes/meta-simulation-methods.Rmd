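---
title: "Meta-simulation benchmarking of ML method selection: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Meta-simulation benchmarking of ML method selection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metasimbn)
```

## The problem

A practitioner with a small tabular dataset (a few hundred rows, say) must
choose among candidate machine-learning methods. Benchmarking directly on
the small sample is unbiased — the sample really does come from the system
of interest — but carries high variance: a different draw of the same size
can reverse the apparent ranking. An alternative is to *calibrate a
simulator from the data*: infer a discrete Bayesian network (structure plus
conditional probability tables, CPTs) from the limited sample, then
benchmark the candidates on as much synthetic data as desired. This trades
variance for a bias that depends on how faithfully the inferred
data-generating process (DGP) reflects the true one.

Whether that trade is worth making cannot be decided on real data, because
the truth is unknown there. `metasimbn` therefore runs a *meta-simulation*:
a known discrete Bayesian network plays the role of the true DGP, so every
strategy can be scored against the asymptotic ground truth.

## The three estimators

Let `Acc(M, D)` be the test-set accuracy of method `M` trained and tested
on dataset `D`, with `K` candidate methods in total. The framework computes:

* **Ground truth** `mu_true(M)`: the mean of `Acc(M, D_i)` over `n_truth`
  independent train/test pairs drawn from the true network — an estimate of
  the method's asymptotic performance on this prediction problem.
* **Limited-real (practitioner)** `mu_prac(M)`: the mean over
  `n_practitioner` limited datasets, each of `n_train + n_test` rows drawn
  from the true network. Each limited dataset represents one practitioner's
  reality.
* **SL-based** `mu_L(M)` for each structure learner `L`: per practitioner,
  learn a DAG from the limited data, fit CPTs by maximum likelihood,
  draw `n_sl` fresh synthetic train/test pairs from the fitted network,
  and average; then average across practitioners (a double mean).

Derived comparisons:

* **bias** `delta_L(M) = mu_L(M) - mu_true(M)` (positive = accuracy
  overestimated);
* **centred performance** `mu~_X(M) = mu_X(M) - mean_k mu_X(M_k)`, which
  isolates the *relative* ordering from any shared absolute bias and sums
  to zero across methods by construction;
* **ranks** `r_X(M)` with rank 1 for the best method (ties receive the
  average rank), computed per practitioner repetition, and summarised
  against the true ranking by exact-match fraction and mean absolute rank
  displacement.

All randomness descends from a single root seed through a counter-based
sub-seeding scheme (`derive_seed()`), so a run is bit-reproducible and any
single repetition can be re-run in isolation. The default root seed is 42.

## Study conditions and defaults

The defaults encode the standard study configuration: `n_train = 200`,
`n_test = 200`, `n_practitioner = 10`, `n_sl = 500`, `n_truth = 1000`,
root seed 42, and no inner cross-validation folds (each dataset is a single
train/test split). Runs at those repetition counts on repository-scale
networks take many hours; the shipped desk preset
(`inst/extdata/desk-config.yaml`) and the test suite use the same dataset
sizes but scaled-down repetition counts (`n_truth` 50–200,
`n_sl` 10–20), which keep a full run in the minutes range on one CPU while
leaving the estimators' structure untouched. The Monte-Carlo error these
choices induce is what the stochastic tolerances in the test suite reflect.

One deliberate sharing decision: the same `n_practitioner` limited datasets
feed the limited-real strategy *and* every structure learner, making the
comparison paired. Each practitioner's full `n_train + n_test` rows are
used to learn the structure and fit the CPTs (a practitioner calibrating a
simulator would not hold data back from it); the limited-real strategy
itself respects the train/test split. This split of responsibilities is
configurable in `sl_estimate()` callers but is the package default.

Level domains during CPT fitting are taken from the factor levels carried
by the data, which for forward-sampled data are the ground-truth
declarations. A rare level unobserved in 400 rows therefore keeps its slot
in the state space (with a zero or smoothed probability) instead of
silently shrinking the fitted network's domain — the practitioner is
assumed to know the variable codebook.

## The candidate methods

Five candidates ship by default, deliberately including a
hyperparameter-variant pair so that "method selection" includes tuning:

| id | family | notes |
|----|--------|-------|
| `rf` | random forest | 100 trees (`ranger`) |
| `dt_gini` | decision tree | Gini impurity split criterion (`rpart`) |
| `dt_entropy` | decision tree | information-gain criterion (`rpart`) |
| `mlp` | multilayer perceptron | one hidden layer of 8 units, weight decay 1e-3, 150 iterations (`nnet`) |
| `adaboost` | AdaBoost (SAMME) | 50 depth-1 stumps, implemented in-package |

Features are one-hot encoded over the *declared* level domain, in variable
order then level order, so the design matrix is identical across train,
test, real, and synthetic data; categorical codes never acquire a spurious
ordering. `nnet` has no default topology, so the hidden-layer size and
iteration cap are package choices sized to a few hundred rows of one-hot
inputs; convergence chatter is logged as messages, not raised. The SAMME
boosting loop is implemented directly (weighted stumps over the binary
one-hot columns, `alpha = log((1-err)/err) + log(K-1)`) and is exercised by
the same chance-level and constant-target tests as the library-backed
methods. A single-class training target yields a majority-class constant
predictor rather than an error, since degenerate small samples do occur at
these sizes.

## Structure learning from first principles

The four learners cover the three families discussed in the
structure-learning literature, and are implemented in the package rather
than delegated:

* **`hc`** — greedy hill-climbing over add/delete/reverse single-edge
  moves from the empty graph, scored by the decomposable BIC
  `loglik - (k_child - 1) * prod(k_parents) * log(n) / 2`, with family
  scores cached and ties broken lexicographically on
  (operation, parent, child) so runs need no randomness.
* **`tabu`** — the same move space, but score-worsening moves are allowed
  while inverse moves sit on a fixed-length tabu list (default length 10,
  with an equal cap on consecutive worsening moves); the best DAG visited
  is returned, so tabu never scores below hill-climbing on the same data.
* **`pc.stable`** — the order-independent skeleton phase (neighbour sets
  frozen per conditioning-set size, default cap 3), G-squared conditional
  independence tests at `alpha = 0.05`, v-structure orientation from the
  recorded separating sets, and Meek rules R1–R3 to closure. Rule R4 is
  omitted: it can only fire when orientations are injected as background
  knowledge, which this pipeline never does.
* **`mmhc`** — max-min parents-and-children per node (forward phase on the
  maximum p-value over conditioning subsets, backward false-positive
  removal, mutual-confirmation symmetry), then hill-climbing restricted to
  the surviving pairs.

The G-squared test drops contingency rows/columns with zero stratum
marginals and reduces the degrees of freedom accordingly — the standard
sparse-table correction, which keeps p-values conservative at `n = 200`.
The conditioning-set cap of 3 reflects the same sample-size reality: larger
tables cannot be populated at these sizes.

Constraint-based output is a partially directed graph; before it can serve
as a DGP it is extended to a DAG with the Dor–Tarsi consistent-extension
algorithm, falling back to deterministic name-order orientation (skipping
any orientation that would close a cycle) when no consistent extension
exists. The fallback makes the extension total, at the cost of possibly
leaving the intended equivalence class — acceptable for a sampling DGP,
and flagged in the function documentation.

`max_parents` defaults to 8: repository networks of interest have small
in-degrees, and the cap bounds the CPT blow-up a misguided move could
cause. The learner registry is open (`register_learner()`), so further
algorithms slot in without touching the orchestrator.

## Fidelity diagnostics

Structural fidelity is the structural Hamming distance between adjacency
matrices, with a reversal counting one edit. Because score-equivalent
learners are free to return *any* member of the correct Markov-equivalence
class, raw-DAG SHD has an irreducible floor equal to the number of
reversible edges — it can even rise with `n` as ties resolve arbitrarily.
`shd(..., cpdag = TRUE)` therefore compares completed partially directed
graphs (equivalence classes) instead, and that is the scale on which the
structure-recovery convergence test operates. The plain adjacency variant
remains the default reporting scale.

Distributional fidelity is the mean over variables of the base-2
Jensen–Shannon divergence between per-variable empirical marginals, a value
in [0, 1]. The joint JS divergence is intractable for networks with dozens
of nodes (the joint support is exponential), and the per-variable average
is the scale on which synthetic-vs-real divergences in the low hundredths
are meaningfully compared. The choice of the marginal variant and log base
is a package decision, documented rather than inherited.

## The fixture generator

`random_dag()` draws DAGs acyclic by construction (edges only forward along
a random node permutation, in-degree capped), and `random_cpts()` fills in
CPT rows from a symmetric Dirichlet: concentration `alpha` near 0.1 gives
near-deterministic dependencies (strong signal), large `alpha` gives
near-uniform rows (weak signal). Four hand-specified toys with documented
exact marginals anchor the oracle tests:

* `chain3` (`A -> B -> C`, `P(B=1) = 0.62`, `P(C=1) = 0.534`),
* `collider3` (`A -> C <- B`; the collider CPT is deliberately asymmetric,
  `P(C=1|ab) = 0.10, 0.90, 0.60, 0.95`, so both parents are *marginally*
  dependent on `C` — an XOR-style CPT would make the marginal dependence
  invisible to the skeleton phase of constraint-based learners),
* `sprinkler4` (the classic cloudy/sprinkler/rain/wet network), and
* `hub5` (a hub with four children of graded signal strength; the hub has
  the largest Markov boundary and is the automatic prediction target,
  mirroring the rationale of choosing targets that generate variance among
  ML methods).

What the fixtures emulate is the *mechanics* of the study — ancestral
sampling, identifiable structure, a prediction target with informative and
uninformative features. What they do not emulate is the scale and
parameter heterogeneity of repository networks with 76–223 nodes: passing
tests on fixtures show the estimators, learners, and diagnostics are
correct, not that any particular repository-scale SHD or bias figure will
be reproduced. Repository networks in BIF format are consumed directly by
`read_bif()` when available.

## Numerical choices and degenerate inputs

* CPT rows must sum to 1 within 1e-9 internally; BIF files are accepted at
  1e-4 (repository files print few digits) and renormalised.
* A parent configuration never observed during fitting receives a uniform
  distribution over the child's levels (with `pseudo_count = 0`, the
  default); Laplace smoothing is available via `pseudo_count`.
* Exact inference (`exact_marginals()`) refuses joint state spaces above
  1e6 configurations — it is a test oracle, not an inference engine.
* Score ties in hill-climbing break lexicographically; undirected-edge
  orientation ties in `pdag_to_dag()` break by node-name order. Both are
  documented determinism contracts, not claims of optimality.
* Greedy search is genuinely fallible: on `sprinkler4` at large `n` the
  climb provably ends in a six-edge local optimum that scores below the
  true DAG (every single-move neighbour is no better). This is a property
  of greedy score search, reproduced faithfully rather than patched, and
  is one reason the meta-simulation treats learned structures as they are
  — bias included — instead of assuming recovery.

## Known limitations

* Discrete variables only; no continuous or conditional-Gaussian nodes,
  and no latent-variable models.
* Four learners, one representative per family plus tabu; additional
  hybrids can be registered but are not shipped.
* Accuracy is the only benchmarking metric wired through the estimators
  (the record structure is metric-agnostic, so extensions are mechanical).
* The desk-scale repetition counts trade Monte-Carlo precision for
  runtime; conclusions about fine accuracy differences (below ~1 point)
  need the full-scale counts.
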