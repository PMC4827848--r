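---
title: "Knowledge-constrained causal discovery of miRNA targets: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knowledge-constrained causal discovery of miRNA targets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cider)
```

## The problem

MicroRNAs (miRNAs) repress mRNAs post-transcriptionally, and
transcription factors (TFs) regulate miRNAs transcriptionally. Matched
miRNA/mRNA expression profiles carry a causal signal about who regulates
whom, but correlation-based target prediction confuses direct regulation
with co-expression induced by shared upstream regulators. `cider` treats
target prediction as causal discovery: it learns a causal Bayesian
network over the profiled genes, lets experimentally validated
interactions constrain that network, and ranks candidate targets by an
intervention-calculus estimate of how much an mRNA would change if the
miRNA's expression were intervened on.

The package deliberately consumes an *already filtered* expression
matrix (differential-expression analysis and probe/ID harmonization are
upstream concerns) together with plain-text interaction tables of two
kinds: TF-to-miRNA (`tf_mirna`) and miRNA-to-mRNA (`mirna_mrna`).

## The model and the learning procedure

We assume an acyclic linear structural-equation model with jointly
Gaussian-like expression values: each gene is a weighted sum of its
parents plus independent noise. Under this model conditional
independencies identify the graph up to its Markov-equivalence class,
represented by a partially directed graph (CPDAG).

Structure learning follows the constraint-based recipe with one
addition, the *constant edge*:

1. Start from the complete undirected graph and mark every knowledge
   record as a constant edge. Constant edges are never tested for
   removal and never re-oriented; their direction is the knowledge
   direction (regulator to target).
2. Remove non-constant edges whose endpoints test conditionally
   independent (Fisher-z partial-correlation test) given some subset of
   their neighbourhoods, with conditioning sets growing from size 0 to
   `max_cond_size`. Constant edges stay in the neighbourhoods, so a
   validated regulator can enter a conditioning set and expose a
   spurious dependence elsewhere — this is the mechanism by which even a
   handful of knowledge edges removes false positives.
3. Orient v-structures with the separating-set criterion: for an
   unshielded triple i - j - k, orient i -> j <- k exactly when j is
   absent from the recorded separating set of (i, k).
4. Complete orientations with the four standard propagation (Meek)
   rules, which direct every edge whose orientation is forced by "no new
   v-structure" and "no directed cycle".

We use the order-independent (PC-stable) deletion variant: within each
conditioning-set size the neighbourhoods are frozen, so the output does
not depend on the order in which gene columns arrive. All iteration
orders are lexicographic in gene identifiers, which makes every run
reproducible and permutation-invariant.

### Conflict handling

Finite samples produce inconsistent CI verdicts, so mechanically
applying orientation rules can demand both directions for one edge or
close a directed cycle. Knowledge always wins over a conflicting
v-structure (constant edges are inviolable, and the conflict is
logged). Purely data-driven conflicts are resolved conservatively:
the edge is left (or reverted to) undirected rather than aborting the
run; `orientation_closure()` retains a strict mode (`on_conflict =
"error"`) that surfaces genuinely contradictory inputs, e.g. knowledge
whose edges would form a directed cycle.

## Causal-effect estimation

For jointly normal variables, the total causal effect of a cause X on an
effect Y in a known DAG is the coefficient of X in the OLS regression of
Y on X and the *parents of X* — adjusting for the cause's parents blocks
every back-door path while leaving all directed paths open. If Y is
itself a parent of X the effect is zero by definition. Regressions
include an intercept and run on the native expression scale, so effects
are expression change per unit expression change.

The printed form of this estimator in the source literature garbles the
adjustment set (it reads as the *effect's* parents, which would be
circular because those can include the cause itself); we follow the
intervention-calculus construction and adjust for the cause's parents.

Because the learned graph is only a CPDAG (plus knowledge), the parent
set of a miRNA is ambiguous: any subset of its undirected neighbours
that creates no new v-structure at the miRNA is a possible parent set.
The effect is therefore a *set* of values, and `causal_effect_bound()`
reports the one with minimum absolute value — a lower bound on the
effect magnitude. Enumeration is local (subsets of the cause's
neighbours) rather than global (orienting the whole graph), which is
exact on CPDAGs and is validated against the global
`enumerate_consistent_dags()` oracle in the test suite; on graphs
further constrained by knowledge it is the standard local
approximation. Admissible subsets are exactly the cliques among
eligible neighbours, so the enumeration never explodes on hub genes.
Ties in the minimum are broken by the deterministic enumeration order
(by subset size, then lexicographically).

A consequence worth knowing: a true target connected by an edge that
remains *undirected* gets a bound of zero (one admissible orientation
makes the target a parent of the miRNA). Knowledge and v-structures are
what rescue such edges — this is precisely why performance grows with
the amount of knowledge.

## The simulator

`generate_network()` / `generate_expression()` emulate the benchmark
design: a random topological order, independent forward edges, roles
miRNA / TF-mRNA / mRNA, and only role-admissible edges (TFs regulate
anything; miRNAs regulate mRNAs including TF-coding ones; plain mRNAs
regulate nothing). Edge weights are uniform on [-1, -0.1] U [0.1, 1],
intercepts are N(0, 1), and each gene is its parents' weighted sum plus
a non-Gaussian error term.

Choices the benchmark description leaves open, fixed here once:

* **Noise**: Uniform(-1, 1) by default (bounded, symmetric, simple);
  Laplace and Student-t(5) are available alternatives.
* **Role proportions**: 10% miRNA, 10% TF-mRNA, 80% mRNA.
* **Density**: when `edge_prob` is not given it is chosen so regulated
  genes average `mean_in_degree = 2` regulators. Much sparser networks
  leave most true edges undirected (zero bounds, see above), much
  denser ones are unrealistic for a differentially-expressed panel.
* **Scale**: the full design is 50 networks of ~1000 nodes with 250 and
  500 samples. The test suite and the reproduction script run a reduced
  profile (8–20 networks of 100 nodes, 250 samples) so a complete run
  finishes in minutes on one CPU; the properties asserted (constant-edge
  retention, sweep monotonicity, baseline ordering) are scale-free.

`sample_knowledge()` reveals a fraction of the true edges per
interaction type as prior knowledge. For a fixed seed the permutation is
drawn once and truncated, so subsets are *nested* along the fraction
grid — a sweep is monotone in information by construction, and observed
F-score gains are attributable to the knowledge rather than resampling
noise.

## Evaluation

Score matrices become predictions either per miRNA (`top_k_targets()`,
the real-data convention with k around 50–150) or globally
(`top_n_global()`). Simulation benchmarks use the global rule with N
equal to the number of true miRNA-to-mRNA edges, which makes precision =
recall = F and removes the arbitrary cutoff from method comparisons.
F is the harmonic mean of precision and recall; ground truth is the true
miRNA-to-mRNA edge set. When knowledge and evaluation databases overlap
on real data, `separate_knowledge_from_ground_truth()` removes the
overlap from the knowledge so nothing is both input and answer.

The baselines mirror common practice: absolute Pearson correlation;
lasso regression of each mRNA on all miRNAs with seeded 5-fold
cross-validated penalty; and a pseudo-knock-out Z-score that treats each
miRNA's minimum-expression sample as its knock-out and scores mRNAs by
their standardized deviation in that sample (the exact normalization of
the knock-out heuristic is not pinned down in the literature; the
single-sample z-score is the standard reading).

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.01 | CI-test significance level; smaller = sparser graphs |
| `max_cond_size` | 3 | largest conditioning set; bounds runtime on ~1000-node panels |
| `max_parent_sets` | 10000 | guard on local parent-set enumeration |
| `mean_in_degree` | 2 | simulator density when `edge_prob` is unset |
| `k` | free | per-miRNA prediction cutoff on real data |

The CI significance level is not dictated by the method; 0.01 balances
false edges (which dilute rankings) against missed edges (which zero
out bounds) at the 250-sample scale. `max_cond_size = 3` truncates the
PC search; with sparse true graphs larger sets almost never change the
result but cost combinatorially more tests.

## What the simulations do and do not show

Passing the simulated benchmarks shows the machinery is correct under
its own assumptions: linearity, acyclicity, no latent confounding, no
measurement error, i.i.d. samples, and knowledge that is literally true.
Real expression data violate all of these to some degree — saturating
regulation is nonlinear, feedback loops exist, batch effects confound,
and databases contain false positives. The causal-effect step mitigates
knowledge false positives (a constant edge unsupported by the data earns
a small effect and ranks low), but no simulation here certifies
behaviour under confounding or feedback. Cyclic models, latent-variable
(FCI-style) edges, count-based noise and time-course designs are out of
scope.

## Reduced-profile defaults used by the checks

The packaged tests and `scripts/acceptance.R` use: oracle equivalence on
50 random 7-node equivalence classes; constant-edge retention on 20
(tests) / 5 (script) 100-node networks with 25% knowledge; effect
recovery over 100 / 50 two-node simulations with weight 0.7 and
n = 5000; a sweep of 10 / 8 networks at fractions 0 / 0.25 / 0.5; CI
calibration on 200 / 50 null 20-node datasets with n = 1000; and
pattern recovery on 20 ten-node DAGs with n = 10000.
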