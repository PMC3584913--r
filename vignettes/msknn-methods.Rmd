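---
title: "Multi-source kNN function prediction: models, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-source kNN function prediction: models, choices, limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msknn)
```

## The prediction model

Protein function prediction is a multi-label classification problem over an
ontology DAG: a protein carries a set of terms, and carrying a term implies
carrying all of its ancestors up to the namespace root (the true-path rule).
`msknn` predicts by label transfer: the score of a (protein, term) cell is
the similarity-weighted count of the query's $k$ nearest annotated
neighbours that carry the term,
$$\mathrm{score}(p,f)=\sum_{p'\in N_k(p)}\mathrm{sim}(p,p')\,
I\!\left(f\in\mathrm{functions}(p')\right).$$

Its assumptions are explicit and worth stating:

* **Guilt by association.** Proteins similar in sequence, co-expression or
  interaction partners tend to share function. Each source captures a
  different, partial aspect of this.
* **Nonnegative, bounded similarity.** Every source is normalised to
  $[0,1]$ (identity / 100, Pearson correlation clipped at 0, interaction
  indicator), so per-source scores are bounded by $k$ and comparable across
  proteins.
* **Annotation absence is treated as negative** during weight learning —
  a known weakness discussed below.

The semantic variant replaces the indicator by Lin similarity between the
neighbour's terms and the target,
$$\mathrm{linsim}(f,f')=\frac{2\log p_{ms}(f,f')}
{\log p(f)+\log p(f')},$$
with $p_{ms}$ the minimum annotation probability over the pair's common
ancestors (each term's closure includes the term itself, so
$\mathrm{linsim}(f,f)=1$; when the terms meet only at the root,
$p_{ms}=1$ and the similarity is 0). The log base cancels; natural logs are
used.

### Term probabilities across namespaces

A subtle point: the estimator of $p(f)$ uses a **per-namespace
denominator** — the number of proteins with at least one annotation in the
term's namespace. With a global denominator, a protein annotated only with
biological processes would deflate the molecular-function root below
probability 1, breaking both the parent-monotonicity of $p$ at the top of
the DAG and the analytic limit $\mathrm{linsim}=0$ for root-only-related
pairs. Zero-count terms are floored at `epsilon` (default `1e-9`) so
logarithms stay finite; two distinct probability-1 terms are defined to
have similarity 0 (they share no information), while $f=f'$ is 1 by
convention.

## Integration schemes

**Fixed averaging (MS-kNN).** One third sequence, one third PPI, and
$1/(3J)$ times the sum over $J$ expression datasets. Two deliberate
conventions: (a) a source that does not cover a protein contributes 0
while the coefficients stay $1/3$ — proteins seen by several sources score
systematically higher, encoding increased confidence; (b) when a whole
source type is absent from a run the default is the same zero rule
(`renormalize = TRUE` opts into reweighting by the number of provided
groups, for non-benchmark use).

**Learned weights (MS-W-kNN).** Weights $w$ on the probability simplex
minimise the total hinge violation of rank constraints: for each training
protein, each annotated term $y$ and each unannotated-but-known term
$\bar y$, the integrated score of $y$ should not fall below that of
$\bar y$. This is a linear program in $(w,\xi)$. The implementation
eliminates the slacks analytically ($\xi=\max(0,-w^\top d)$) and minimises
the resulting convex piecewise-linear loss exactly with a cutting-plane
loop; each small master LP is solved by `pracma::linprog`. Two choices
make the output reproducible:

* *Negative set.* Candidate negatives are terms annotated in at least one
  training protein (a never-annotated term is uninformative); the full
  pair set is quadratic, so at most `max_pairs` (default 10000) pairs are
  kept under a fixed seed.
* *Degenerate optima.* Flat faces of the objective are canonicalised by a
  $10^{-9}$-scaled secondary pull towards the uniform vector, so reruns
  return the same point.

Two properties of this objective deserve emphasis, because they explain
behaviour that looks surprising at first:

* it is **not scale-invariant** — a source whose scores are tiny in
  magnitude (e.g. a sparse PPI channel, or a zero-signal expression
  channel after correlation clipping) incurs almost no hinge violations,
  and weight drifts towards it as a pure shrinkage direction;
* **absence-as-negative** penalises sources that correctly up-rank
  functions that are merely unannotated rather than absent.

Both push the learned variants below plain averaging on realistic data,
consistent with the empirical observation that motivated keeping plain
MS-kNN as the production predictor.

**Cluster weights (MS-CW-kNN).** The same program solved independently per
ontology cluster — namespaces (`"root"` level) or the direct children of
the roots (`"first"` level, multi-parent terms tie-broken to the
lexicographically smallest first-level ancestor). Only pairs whose
positive and negative terms both lie in a cluster train that cluster's
weights; a cluster with no pairs falls back to uniform. A cluster's
weights apply to all of its descendant terms.

## Evaluation measures

* **Term-centric AUC** is the Mann–Whitney rank statistic per term (ties
  0.5), macro-averaged over terms annotating at least `min_count` test
  proteins (default 15; assessments on larger corpora have used 25).
  Single-class terms are *undefined* (`NA`) and excluded from the macro
  average rather than coerced to 0.5 — a constant predictor therefore
  scores exactly 0.5, which is also the analytic value for the Priors
  baseline.
* **Threshold sweep:** at each threshold, above-threshold terms are
  propagated to the root and per-protein precision/recall computed against
  the propagated gold set. Proteins with no prediction at a threshold are
  excluded from the precision average at that threshold (a convention the
  original assessment leaves unstated).
* **Top-N:** the N best-scoring terms per protein, expanded to include
  ties at the N-th score, zero scores never retained. The retained set is
  *not* propagated — precision and recall are on the scores as submitted.
* **Weighted threshold:** identical mechanics with each term counted by
  its information content, $-\log$ of its annotation frequency in a
  reference corpus (natural log; frequency floored at `epsilon`).

All three sweeps default to a grid of 101 quantiles of the score
distribution — kNN scores are unnormalised sums, so a fixed $[0,1]$ grid
would collapse onto a few points. Each sweep returns its raw curve plus a
trapezoidal area over the recall-ordered precision curve; the exact
area convention behind historically reported numbers is not recoverable,
which is why the curves themselves are first-class outputs and any other
convention can be recomputed from them.

## The synthetic generator

`synthetic_config()` plants an additive latent-module world — the simplest
structure under which kNN label transfer provably works:

| parameter | default | meaning |
|---|---|---|
| `n_proteins` | 300 | proteins in the corpus |
| `n_terms` | 60 | terms across the two namespaces (MF-like, BP-like) |
| `dag_branching` | 3 | children per internal term; 10% of terms get a second parent |
| `n_modules` | 6 | latent functional modules; each owns ~4 characteristic leaves per draw |
| `n_samples` | 40 | expression samples |
| `signal` | (seq .8, expr .6, ppi .6) | per-source strength of planted signal |
| `coverage` | (1.0, 0.46, 0.20) | per-source protein coverage |
| `seed` | 1 | master seed; all draws derive from it |

Sequence identity is baseline noise plus a bonus proportional to shared
leaf annotations (scaled to [0, 100], rounded to 4 decimals); expression
rows mix the module profile with Gaussian noise (rounded to 6 decimals);
PPI edges are drawn with probability elevated for annotation-sharing
pairs. The coverage defaults echo the situation in real corpora, where
sequence is universal while expression platforms and interaction
databases cover progressively smaller subsets — which is exactly what
makes the fixed-average missing-source rule matter. Defaults were chosen
once as the package's standard study conditions; the bundled property
tests run on them.

What the generator does **not** emulate: sequence evolution (identities
are not tree-structured), microarray platform artefacts, annotation bias
toward well-studied proteins, and the heavy-tailed term-frequency
distribution of real GO corpora. A test passing on planted data certifies
the machinery (scoring, integration, optimisation, evaluation), not
biological performance; absolute AUC levels on real corpora depend on
data the package deliberately does not ship.

## Numerical and degenerate-input choices

* Neighbour lists exclude zero-similarity proteins (no padding) and the
  query itself; ties at the cut break by lexicographic protein id.
* An uncovered query yields an all-zero, flagged score row — never an
  error — so integration can apply the zero rule.
* Identity matrices must be symmetric within `1e-6` (they are averaged
  with their transpose); entries outside [0, 100] are hard errors.
* Constant expression profiles are dropped from coverage with a warning;
  duplicate profile ids (multi-probe genes) are averaged first.
* Negative correlations are clipped at 0 by default
  (`keep_negative = TRUE` to explore raw values); clipping is required
  for the $[0,k]$ score bound.
* Gotcha uses base-10 logs of E-values, clamps $E\ge 1$ to contribute 0,
  and by default propagates raw scores cumulatively to the root (each
  ancestor accumulates its descendants).
* The cutting-plane loop certifies optimality by upper/lower-bound
  agreement (`1e-10` relative); an all-zero difference matrix short-cuts
  to the uniform vector.
* Training annotations are used raw (leaf-level) in the semantic variant
  by default to avoid double-counting ancestors; propagate first to get
  closure-based voting.

## Known limitations

* The rank-loss formulation inherits the absence-as-negative and
  scale-sensitivity issues above; plain averaging is the recommended
  default, matching how the method is used in practice.
* Only `is_a` edges are honoured; `part_of` and other relations are
  ignored, so closures are the minimal true-path ones.
* The evaluation module targets the four measures described here;
  later-generation metrics (F-max, semantic distance) are out of scope.
* Problem sizes in the bundled tests (tens to hundreds of proteins,
  dozens of terms) were chosen as the package's standard desk-scale
  study conditions; all operations are dense-matrix based and scale to a
  few thousand proteins, beyond which sparse indexing would be needed.
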