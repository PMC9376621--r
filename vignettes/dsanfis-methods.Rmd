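---
title: "Dominant-set initialized fuzzy classification: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dominant-set initialized fuzzy classification: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsanfis)
```

## The problem and the model

`dsanfis` builds binary classifiers for tabular clinical data — subjects in
rows, numeric attributes in columns, one 0/1 outcome — that remain readable by
a clinician. The motivating application is dementia screening from
demographic, cognitive and MRI-derived measures (age, education,
socio-economic status, MMSE, normalized whole-brain volume, atlas scaling
factor), but nothing in the package is specific to that cohort.

The model is a zero-order Takagi–Sugeno–Kang (TSK) fuzzy rule base. Rule
$d$ reads

$$\text{If } x_1 \text{ is } A_1^d \text{ and } \dots \text{ and } x_n
\text{ is } A_n^d, \text{ then } z_d,$$

where each $A_k^d$ is a Gaussian membership function
$\mu(x) = \exp\{-(x - c_{dk})^2 / 2\sigma_{dk}^2\}$ and $z_d$ is a scalar
consequent. Inference fires every rule by the product T-norm
$w_d = \prod_k \mu_{A_k^d}(x_k)$, normalizes
$\bar w_d = w_d / \sum_{d'} w_{d'}$, and outputs the convex combination
$z = \sum_d \bar w_d z_d$, thresholded at $0.5$ for a class and read directly
as a confidence. Because each antecedent is "feature $k$ is around $c_{dk}$",
the fitted model can be rendered as plain sentences (`render_rule_base()`)
and audited rule by rule.

The two design problems any such system faces are *how many rules* and
*where to put them*. Both are answered by graph clustering rather than by the
analyst.

## Dominant-set initialization

Subjects are connected in a complete edge-weighted graph with Gaussian
affinities $a_{ij} = \exp(-d_{ij}^2 / \sigma^2)$ over the normalized
features, zero diagonal. A *dominant set* is a subset $S$ whose recursively
defined node weights $W_S(i)$ are all positive (internal homogeneity) while
every outside node has non-positive extension weight $W_{S\cup\{i\}}(i)$
(maximality). Dominant sets are in correspondence with the strict local
maximizers of the quadratic program

$$\max_{z \in \Delta} f(z) = z^\top A z, \qquad
\Delta = \{z \ge 0, \textstyle\sum_i z_i = 1\},$$

whose support $\{i : z_i > 0\}$ identifies the member subjects. The program
is solved by replicator dynamics,
$z_i \leftarrow z_i (Az)_i / (z^\top A z)$, which provably stays on the
simplex with a non-decreasing objective; on 0/1 adjacency matrices the
maximum value is $1 - 1/\omega(G)$ (the Motzkin–Straus clique bound), which
the test suite uses as an exact oracle.

Clustering proceeds by *peeling off*: extract one dominant set, delete its
nodes, repeat on the remaining subgraph until fewer than `min_remaining`
nodes survive or the dynamics degenerate. The cluster count is therefore an
output, and leftover nodes form a residual "clutter" group instead of being
forced into a cluster. Each cluster (and, by default, the residual) becomes
one rule: centers are the per-feature cluster means, widths the population
standard deviations (denominator $|S_d|$), and the initial consequent the
majority class of the cluster.

## Hybrid ANFIS learning

The initialized rule base only reflects unsupervised structure, so a
supervised refinement follows, with the rule count and feature set frozen.
Each epoch of `anfis_fit()` runs

1. a **forward least-squares pass**: with premises fixed, the output is
   linear in the consequents with design matrix $\bar W$ (rows = normalized
   firing vectors), so the consequents are set to the least-squares solution.
   The minimum-norm solution via SVD covers rank deficiency (two rules firing
   identically). Training SSE cannot increase in this step, which the suite
   asserts;
2. a **backward gradient pass**: one batch gradient-descent step on the
   centers and widths, with analytic gradients through the membership,
   product, normalization and output layers (verified against central finite
   differences to $10^{-5}$). Widths are re-floored after the step.

The gradient objective is the *mean* squared error rather than the raw sum,
so `learning_rate` behaves consistently across sample sizes; this is a pure
scaling choice absorbed into the rate. Consequents become unconstrained
reals during training — they act as rule confidences — so classification
confidence is clamped into $[0.5, 1]$.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `sigma2` | `"auto_dist_var"` | kernel bandwidth $\sigma^2$; the automatic rule uses the variance of the upper-triangle pairwise Euclidean distances. The phrase "variance of the pairwise distances" is ambiguous between distances and squared distances, so `"auto_sqdist_var"` and explicit numeric values are also accepted. |
| `support_eps` | `1e-5` | numeric realization of the theoretical support criterion $z_i > 0$; small against the $1/M$ barycenter scale. |
| `max_iter`, `min_increment` | 1000, `1e-8` | replicator stopping: iteration cap and minimal objective gain. The theory names the criteria but no values; these defaults balance support sharpness against cost. Oracle-grade runs in the tests use `min_increment = 0` with a larger cap because the support of a weakly attached node can decay slowly even after the objective has converged. |
| `min_remaining` | 2 | peeling stops below this; survivors become the residual clutter group. |
| `include_residual` | `TRUE` | clutter becomes a final rule (it carries diagnostic signal); set `FALSE` to drop it. |
| `sigma_floor` | 0.01 | minimum Gaussian width on [0,1]-normalized features. The population-SD formula yields $\sigma = 0$ for singleton or degenerate clusters, which would make the membership ill-defined. |
| `mf_convention` | `"half"` | $\exp\{-(x-c)^2/2\sigma^2\}$, the standard Gaussian membership; `"plain"` drops the $1/2$. Both appear in the fuzzy-systems literature; worked fitted rules in this tradition print the half form, hence the default. |
| `epochs`, `learning_rate` | 50, 0.01 | hybrid learning budget and premise step size. |

## Preprocessing

Categorical attributes are mapped to 0/1 codes and enter the Euclidean
distance as ordinary coordinates. Missing values are mean-imputed **before**
min-max normalization, so stored means live on the raw scale and are
directly comparable to published cohort summaries. Normalization maps each
column through $(x - x_{\min})/(x_{\max} - x_{\min})$ using extrema of the
data the state was *fitted* on; inside cross-validation the state is fitted
on the training fold only, so test-fold values may fall outside $[0,1]$ and
are transformed linearly without clamping (and never error). Constant
columns normalize to 0 rather than erroring, which keeps small synthetic
folds flowing. Redundant attribute pairs (e.g. an intracranial-volume
measure that is a deterministic reciprocal of the atlas scaling factor) are
*reported* by `correlation_screen()` at a configurable $|r|$ threshold;
dropping a column is a deliberate analyst decision via `drop_cols`, never
automatic.

## Evaluation harness

`stratified_folds()` deals each class's shuffled members across folds so
per-fold class counts deviate from exact proportionality by at most one, and
rotates the surplus across classes so total fold sizes stay within one of
each other (373 subjects at $k = 10$ gives folds of 37–38). `repeated_cv()`
derives run seeds `base_seed + r - 1`, fits the entire pipeline inside each
training fold (preprocessing statistics included — no leakage; a
global-fit comparison can be run by preprocessing before calling it), and
reports per-fold accuracies, per-run means with across-fold SDs, the
across-run mean and SD (both spreads are reported because they answer
different questions), pooled confusion counts, and the mean rule count.
`optimize = FALSE` gives the unsupervised ablation in which the
cluster-initialized rules classify directly. All randomness passes through
`withr::with_seed()`, so identical seeds give byte-identical reports and the
session RNG is never disturbed.

## What the synthetic generators do and do not emulate

`make_blobs()` draws isotropic Gaussian blobs with known memberships plus
uniform clutter, clipped to the unit cube — the geometry the clustering
stage is designed for. The default specification (three 25-point blobs,
spread 0.02, pairwise separations of 0.65–0.78, one negative and two
positive) is the package's canonical fixture: at these separations peeling
recovers the blobs exactly (adjusted Rand index 1) and training reaches
accuracy 1.0. Exactness is *not* scale-free: as the within-blob spread
grows toward the kernel bandwidth scale (e.g. spread 0.05 under the
automatic bandwidth), dominant sets begin to split blobs into a dense core
plus satellites — internal homogeneity is a stricter demand than "drawn
from the same Gaussian". This is a property of the method worth knowing in
practice, not a failure of the implementation; the dedicated tests pin the
exact-recovery regime and the vignette records the sensitivity.

`make_oasis_like()` reproduces the *marginal* structure of a longitudinal
MRI dementia cohort — Age $77.0 \pm 7.6$ on $[60, 98]$, EDUC
$14.6 \pm 2.9$, SES integers 1–5 around 2.5, a left-skewed MMSE with median
29 and range $[4, 30]$, nWBV $0.730 \pm 0.037$, ASF $1.195 \pm 0.138$, an
eTIV column built as a noisy reciprocal of ASF so that correlation
screening has a near-collinear pair to flag, and missingness confined to
SES and MMSE at the published rates ($19/373$ and $2/373$). The outcome is
Bernoulli with logit $3\,s(-\text{MMSE}) + 2\,s(-\text{nWBV}) - 0.25$
($s$ = standardize), chosen once to give roughly 45% prevalence and a
recoverable signal in the two attributes most correlated with diagnosis in
such cohorts. What it does **not** emulate is the *joint* clumpiness of
real patient data: a near-Gaussian 7-dimensional cloud has much weaker
dominant-set structure than a real cohort, so peeling yields several dozen
small clusters rather than the compact ~14-rule bases reported on real
data (we verified this is driven by the data geometry, not the bandwidth
rule — it persists across bandwidth choices). Passing results on this
generator therefore demonstrate the harness's correctness and determinism,
not clinical-level accuracy or rule-base compactness.

## Numerical choices and degenerate inputs

- **Firing underflow.** Inputs far from every rule can underflow the raw
  firing product; normalization then falls back to uniform $1/D$ with a
  classed warning. The internal training path normalizes in log space
  (softmax with row-max subtraction), which cannot underflow.
- **Replicator degeneracy.** If $z^\top A z = 0$ at any iterate (edgeless
  support), the run is flagged rather than erroring; extraction then falls
  back to a flagged singleton at the maximum-degree node and peeling stops,
  leaving survivors in the residual.
- **Maximality ties.** The external dominant-set condition treats an
  extension weight of exactly zero as non-extending. On unweighted graphs
  such ties arise structurally (a path graph's edges) and the non-strict
  reading is what recovers the maximal-clique correspondence; on random
  weighted graphs ties have measure zero.
- **Majority ties.** A cluster with equally many positive and negative
  members takes the class more frequent in the full training labels —
  deterministic and best by prior.
- **Degenerate LSE.** Rank-deficient $\bar W$ (duplicate rules) takes the
  SVD minimum-norm solution, so duplicated rules share one consequent
  instead of producing wild cancelling pairs.
- **JSON round trips.** Model, rule-base and preprocessing state serialize
  with 17 significant digits, which round-trips doubles bit-exactly.

## Problem sizes used by the checks

The shipped tests and the acceptance script run entirely on generated data:
the 75-point blob fixture; random graphs of 4–12 nodes for the replicator,
enumeration and Motzkin–Straus oracles (exhaustive dominant-set enumeration
is exponential and capped at 12 nodes; the brute-force weight recursion is
a diagnostic tool, never the pipeline path); 80–373-row cohort-like tables
for preprocessing and cross-validation. These sizes were chosen so every
oracle is exact and the full suite runs in well under a minute while still
exercising each contract at the tolerance its arithmetic supports.

## Known limitations

- Binary outcomes only; the consequent coding anchors 0 = negative and
  1 = positive. Multi-class severity grading is out of scope.
- No out-of-sample *cluster* assignment: new subjects are scored by the
  fuzzy rules, not attached to clusters.
- The rule count is sensitive to the kernel bandwidth and to how clumpy the
  data are; on weakly structured data the rule base can grow large enough
  to lose the interpretability advantage. Inspect `glance()` output and
  consider an explicit `sigma2` when this matters.
- Exhaustive dominant-set verification is exponential and exists for
  testing and diagnostics on small graphs only.
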