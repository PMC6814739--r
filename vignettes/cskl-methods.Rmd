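---
title: "Comparing omics datasets with the curated symmetric KL divergence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing omics datasets with the curated symmetric KL divergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cskl)
```

## The problem

Public repositories hold thousands of transcriptomics and methylation
studies, each a samples × variables matrix with a few dozen samples and
tens of thousands of variables. Two studies of related biology should show
related *co-expression structure* even when their sample-level values are
not comparable. `cskl` quantifies this: it treats each dataset as an
empirical zero-mean Gaussian after per-variable standardization, compresses
its covariance, and measures a divergence between the compressed
distributions. On top of the divergence it builds a significance test, a
feature-level explanation of any similarity, and dataset- and disease-level
similarity networks.

Only datasets measuring the same variable set (one *platform*) are
compared; `align_platform()` enforces a shared, lexicographically ordered
variable intersection.

## Model and divergence

Each dataset is standardized variable-wise (mean 0, sd 1 with the m−1
denominator), so its covariance coincides with its correlation matrix and
has total variance n. Because m ≪ n the sample covariance is rank
deficient; we assume a low-rank-plus-isotropic structure

$$\Sigma_P = P\,\Lambda^P P^{\mathsf T} + \sigma_P I,$$

with orthonormal principal axes \(P\), eigenvalues \(\lambda^P_i\), and an
isotropic noise floor. `decompose()` obtains the axes from the thin SVD of
the m × n standardized matrix (the n × n covariance is never formed). The
number of retained axes is the smallest \(c_P\) whose raw eigenvalues reach
\(\alpha n\); the retained eigenvalues are rescaled by one constant to sum
to exactly \(\alpha n\) and the noise floor is \(\sigma = 1-\alpha\).

The divergence between two representations sharing \(\alpha\) is

$$\mathrm{cSKL}(\Sigma_P,\Sigma_Q) = \frac{1}{2(1-\alpha)}
\Big[2\alpha n - \sum_{i,j}\lambda^P_i\,(P_i^{\mathsf T}Q_j)^2
               - \sum_{i,j}\lambda^Q_j\,(P_i^{\mathsf T}Q_j)^2\Big],$$

the eigenvalue-weighted squared projections of each dataset's scaled axes
onto the other's subspace. It is symmetric, non-negative, zero exactly at
\(P=Q\), at most \(\alpha n/(1-\alpha)\) for orthogonal subspaces, and does
not satisfy the triangle inequality. Representations are cached
(`write_representation()`), so a collection of N datasets costs N
decompositions plus cheap pairwise cross-products.

### Numerical choices

* **Eigenvalue normalization target.** We normalize the retained
  eigenvalues to sum to \(\alpha n\) (the fraction \(\alpha\) of the total
  variance n), not to \(\alpha\) itself. With the per-variable reading the
  self-divergence vanishes identically — a property the test suite asserts
  exactly — and the component-count rule and the normalization are mutually
  consistent.
* **Denominator m−1.** Standardization and eigenvalues use the unbiased
  denominator. The choice is immaterial after renormalization (any global
  eigenvalue rescaling is absorbed), but it is stated for reproducibility.
* **Tie and rank guards.** An eigenvalue sum that reaches the \(\alpha n\)
  threshold to within 1e-9 (relative) counts as reaching it; components
  with eigenvalue below 1e-10 are never retained.
* **Clamping.** Floating-point noise can push the bracketed term a hair
  past zero in either direction; values in (−1e-9, 1e-9) snap to 0, values
  below −1e-6 indicate a broken invariant and raise an error.
* **Zero-variance variables** have no z-score; they are dropped with a
  warning by default (`zero_variance_policy = "drop"`), or raise an error.
  Missing values are always a load-time error: no silent imputation.

### The compression level α

\(\alpha\) is the fraction of per-variable variance given to the principal
axes (default **0.5**). Larger values retain more, less reliably estimated
axes; smaller values compress harder. The operating default is anchored by
the sibling-split experiment below — at \(\alpha = 0.5\) the standard
synthetic collection reaches perfect sibling recovery — and
`sibling_alpha_sweep()` re-runs the same selection procedure across an
\(\alpha\) grid on any collection of interest.

The approximation quality of cSKL relative to the exact Gaussian symmetric
KL, \(\tfrac12\,\mathrm{tr}(\Sigma_P^{-1}\Sigma_Q +
\Sigma_Q^{-1}\Sigma_P) - n\) (`exact_skl_gaussian()`), depends on the model
assumptions holding: dominant low-rank structure and a *shared* isotropic
residual matched to \(1-\alpha\). The test suite probes this in the one
regime where both quantities are computable and comparable — n = 5,
m = 500, \(\alpha = 0.99\), single-factor correlation matrices with
residual variance 0.005 — and finds Spearman rank agreement above 0.9
across 105 pairs. Outside the model class (e.g. generic well-conditioned
correlation matrices) the exact SKL is dominated by the smallest
eigendirections, which the truncated form deliberately ignores, and the
agreement degrades; cSKL is an ordering of structural similarity, not an
estimate of the exact SKL.

## Significance: semi-parametric bootstrap

Testing exact distribution equality is pointless here — no two studies
share a population — so the test asks instead whether a pair is *more
similar to each other than to the pooled background*. Let J be the pool of
all standardized profiles of the platform (`build_pool()`). For a pair
(P, Q) with observed divergence \(s\), each of `n_iterations` (default
199) bootstrap draws takes a matched-size pseudo-dataset from the pool
without replacement, standardizes and decomposes it at the same \(\alpha\),
and records its divergence to P and to Q. The one-sided p-value per side is
\((1 + \#\{d_b \le s\})/(B+1)\) — never zero — and the two sides combine
conjunctively as \(\max(p_P, p_Q)\) (an intersection–union test: both
sides must beat the background). Benjamini–Hochberg q-values
(`adjust_fdr()`, delegating to `stats::p.adjust`) control FDR across all
pairs of a platform; edges with q < 0.05 are called significant.

Three design knobs the procedure exposes rather than hides:

* **Draw size** — `mean_of_pair` (default) draws round((m_P+m_Q)/2)
  profiles for both sides; `per_side` matches each partner's size.
* **Exclusion** — the draw standing in for the partner of P excludes P's
  own profiles (otherwise overlap would deflate the null divergence), but
  does *not* exclude Q's: the background is the pool of all samples.
* **Combination** — the max over the two sides. The intersection–union
  construction is conservative: under the null its p-value is
  stochastically *at least* uniform, with near-uniformity when the two
  sides agree (they share the observed statistic).

**Calibration.** The null hypothesis of this test is "P and Q are no more
similar to each other than to the pool". We calibrate by simulating
exactly that null: all datasets of a platform drawn independently from one
common planted covariance, so a matched-size pool draw is an i.i.d. copy
of the partner dataset and the per-side p-values are uniform on the
attainable grid by exchangeability. On 200 such null pairs (10 collections
of 40 datasets, n = 100, m = 40, 199 iterations) the combined p-values
pass a Kolmogorov–Smirnov uniformity test at level 0.01, with the expected
slight conservative tilt from the max-combination. Note a configuration
that is *not* the test's null: if every dataset has its own independent
low-rank covariance, pool draws are mixtures with flatter spectra than any
coherent dataset, the null divergences sit systematically below the
observed one, and p-values concentrate near 1. The test is then
conservative — harmless for error control, but not uniform; calibration
claims must be read against the test's own null.

## Explaining a similarity: B(k) and W(k)

To attribute an observed similarity to k concrete variables, the
divergence is recomputed with the axis cross-products restricted to a
selected variable set S (`restricted_objective()`):

$$\frac{1}{2(1-\alpha)}\Big[2\alpha n - \sum_{i,j}
  (\lambda^P_i + \lambda^Q_j)\,(P_i^{\mathsf T}\,\mathrm{diag}(S)\,Q_j)^2\Big].$$

With S all ones this equals the unrestricted divergence; minimizing over
all \(\binom{n}{k}\) selectors yields the *best-explaining* set B(k),
maximizing yields the *worst* W(k). The combinatorial problem is attacked
through its bilinear relaxation over two selectors (T, S): with one fixed,
the objective is linear in the other's indicator entries, so each
half-step is an exact top-k selection of per-variable coefficients
(`explain_pair()`). Iteration stops when the selection repeats or a
2-cycle appears (the better selector of the cycle is kept). Because the
relaxed form is positive semidefinite in the selector pair, the diagonal
objective never decreases along the iterations — asserted on every run via
the convergence trace.

* **Initialization and restarts.** A deterministic greedy start (top-k
  unary scores \(\sum_{ij} (\lambda^P_i+\lambda^Q_j) P_{vi}^2 Q_{vj}^2\))
  plus `n_restarts` seeded random restarts (default 3, sized for
  n ~ 10^4). On deliberately small, rugged instances (n = 12, k = 3) the
  exhaustive-comparison experiments run 25 restarts — at that size a
  restart costs microseconds — and match the brute-force optimum on ≥ 90%
  of instances while never beating it.
* **Ties** in the top-k step break by ascending variable index, making
  results reproducible.
* **k is the user's choice**; there is no default. `explanation_curve()`
  contrasts B(k) with uniformly random k-sets along a k-grid — the
  optimized curve must dominate (lie below) the random mean.
* **Set explanations** (`explain_set()`) optimize the *sum* of the
  restricted objectives of several pairs with one shared selector, summing
  the per-variable linear coefficients across pairs.
* `jaccard()` compares selections, e.g. between explanation sets obtained
  on different platforms for the same disease.

## Networks

`build_dataset_network()` turns significant pairs into an undirected
igraph (nodes = datasets, edges carry cskl, p, q), optionally truncated to
the most significant edges — ranked by ascending q, ties by ascending
divergence, then lexicographic pair IDs, since significance alone does not
define a total order. `build_disease_network()` aggregates: every
significant cross-disease dataset pair adds one count to its label pair's
edge weight; within-disease edges are discarded, edges below `min_weight`
pruned. One label per dataset (first wins, with a warning).
`merge_networks()` sums weights across platforms — no variable alignment
is needed at the label level. GraphML export/import round-trips all
attributes; TSV edge lists are ordered by descending weight (disease) or
ascending q (dataset).

## Sibling-split self-validation

`sibling_recovery_experiment()` randomly halves every dataset over
samples, re-standardizes and decomposes each half independently, computes
all pairwise divergences agnostic to the split, and reports the fraction
of halves whose nearest neighbour is their own sibling. Halves of one
dataset are samples from one distribution, so a sound divergence should
pair them up. Each half gets its own standardization (means and sds are
dataset-level statistics, and a half is a dataset in its own right); rank
ties break lexicographically and are flagged. On the standard synthetic
collection the recovery fraction at \(\alpha = 0.5\) is 1.0 — the
desk-scale analogue of validating the measure on a large public
collection — and `scripts/acceptance.R` recomputes it from scratch.

## The synthetic collection generator

`generate_collection()` emulates the structure the method targets:
*platforms* of aligned variables; *disease groups* sharing a planted
covariance; per-dataset heterogeneity; optional *cross-links* (a factor
shared by two groups over a stated variable subset) with known ground
truth for significance, network, and explanation tests.

Data are zero-mean Gaussian with covariance \(LL^{\mathsf T} + \sigma^2 I\)
(sampled exactly via the factor construction, never forming the n × n
matrix). Defaults, fixed once for the standard collection:

| parameter | default | rationale |
|---|---|---|
| groups × datasets | 4 × 5 | a small landscape with several diseases |
| n | 500 | m ≪ n holds while tests run in seconds |
| m | 60 | typical public-study size; halves of 30 remain decomposable |
| rank | 5 | few dominant co-expression programs per disease |
| signal_fraction | 0.4 | structure touches a minority of variables |
| strength | 3 | structure carries 75% of total variance |
| jitter | 0.25 | relative loading perturbation between studies of one disease |
| cross-link strength | 8 | per-shared-variable factor variance comparable to group structure |

What the generator does *not* emulate: platform-specific intensity
distributions, batch effects, probe-annotation noise, non-Gaussian tails,
and mean shifts (standardization removes means anyway). Passing tests
therefore demonstrate correctness of the machinery and sane behaviour in
the assumed model class, not performance on any real repository.

## Problem sizes used by the test suite

Unit tests run on matrices up to 60 × 500; the acceptance-style checks use
the standard collection (20 datasets, n = 500), 200 bootstrap-calibration
pairs (n = 100, m = 40, 199 iterations each), 50 brute-force explanation
instances (n = 12, all 220 selectors enumerated), and 105 oracle-agreement
pairs (n = 5, m = 500). The whole suite completes in a few minutes on one
CPU.

## Known limitations

* cSKL compares *covariance* structure only; datasets differing in means
  or marginal scales but not correlation are indistinguishable by design.
* The bootstrap test's background is the platform's own pool: with very
  few datasets per platform the null draws are dominated by the tested
  pair's neighbours and power drops (`bootstrap_p_value` refuses pools
  smaller than the draw size).
* The alternating optimizer is a local method; for small k and adversarial
  structure it can miss the global optimum (restarts mitigate; the
  brute-force cross-check quantifies the gap at toy scale).
* The exact-SKL oracle is meaningful only in near-full-rank regimes;
  at realistic n ≫ m the exact SKL does not exist (singular covariances)
  and no numerical agreement is claimed.
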