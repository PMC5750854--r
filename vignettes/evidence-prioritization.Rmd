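---
title: "Multi-source evidence integration and gene prioritization with EviRank"
author: "EviRank authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-source evidence integration and gene prioritization with EviRank}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(EviRank)
```

## The problem

Susceptibility genes for complex phenotypes such as nicotine addiction are
reported by methodologically unrelated study types: genetic association
analyses, genome-wide linkage scans, expression profiling under nicotine
exposure, and decades of single-gene experimental literature. Each source
contributes a candidate list with its own false-positive and
false-negative character, and the lists overlap only partially. Given such
lists plus a small curated set of genes whose involvement is considered
established (the *core* genes), the task is to produce one ranking of all
candidates in which genes supported by the more informative sources — as
judged by where they place the core genes — rise to the top.

## Model

A gene is encoded as a binary vector over the $N \ge 2$ evidence
categories: $S_i = 1$ if source $i$ reported it, else $0$; every gene in
the matrix carries at least one positive indicator (it entered through at
least one source). The combined score is

$$S_{\mathrm{combined}} \;=\; \sum_{i=1}^{N} w_i\, S_i,
\qquad w_i \ge 0,\;\; \sum_i w_i = 1 .$$

Rankings are invariant to positive rescaling of $w$, so the simplex
constraint removes a flat direction from the search space rather than
restricting what rankings are achievable; nonnegativity encodes the
"contribution" semantics of a weight. With simplex weights every score
lies in $[0,1]$, and equals $1$ exactly for a gene present in all
categories.

### Objective

The description of a good weight vector — core genes "near the top" —
leaves the functional form open. We use the **mean fractional
tie-averaged rank** of the core set $C$ among all $M$ genes:

$$E(w) \;=\; \frac{1}{|C|} \sum_{g \in C} \frac{\bar r_g(w)}{M},$$

where $\bar r_g$ is the rank of $g$ under descending score, tied scores
receiving the mean of the positions they jointly occupy. We chose this
form because it is scale-free in $M$, has no tuning constants, and is
affinely equivalent to the Mann–Whitney $U$ statistic separating core
from non-core score distributions. Its range is $(0, 1]$; the minimum
$(|C|+1)/(2M)$ is attained exactly when the core genes occupy the top
$|C|$ positions without ties against non-core genes. Tie-averaging inside
the objective matters: with few categories many genes share identical
evidence rows, and an objective based on arbitrary stable sort positions
would reward accidents of ordering.

### Optimization

$E(w)$ is piecewise constant in $w$ (it changes only when two genes swap
rank order), so gradient methods do not apply and we use **simulated
annealing**:

* start at uniform weights $w_i = 1/N$;
* propose by adding $\mathcal{N}(0, \sigma^2)$ noise to one random
  coordinate, clipping negatives to zero and renormalizing onto the
  simplex (an all-zero proposal is redrawn);
* accept with probability $\min(1, e^{-\Delta E / T})$;
* cool geometrically, $T \leftarrow cT$, after each block of proposals;
* report the best-ever visited weights, so the best-objective trace is
  non-increasing by construction.

Defaults: $T_0 = 1$, $c = 0.95$, 50 proposals per block, 100 blocks
(5000 evaluations), $\sigma = 0.1$, seed 42. With these settings
instances with up to six categories solve in seconds; every parameter is
exposed through `saConfig()`. All randomness flows from the single seed,
and a rerun with the same seed reproduces weights, objective and trace
exactly.

As an independent check the package ships `gridOracle()`, which
exhaustively enumerates all weight compositions at resolution `step`
(all nonnegative multiples of `step` summing to 1) and returns the best.
The test suite requires the annealer to do at least as well as the grid
on every tested instance — the annealer searches the continuum containing
the grid, so falling behind it indicates a defect.

### Numerical choices

* Weight normalization compensates division rounding so the stored
  weights sum to *exactly* 1 in double precision; combined scores are
  clamped to $[0,1]$ against sub-ulp overshoot. This keeps the "score of
  an all-ones gene is exactly 1" invariant assertable with `identical()`.
* Display order breaks score ties by ascending symbol, making every
  output file deterministic; the objective itself never depends on sort
  stability because of tie-averaging.
* Grid enumeration order is fixed (first coordinate ascending,
  recursively), and only strict improvements replace the incumbent, so
  the oracle's reported argmin is deterministic under ties.

## Input contract and degenerate inputs

`readEvidenceCSV()` reads the upload format: a header row naming the
sources, one column of gene symbols per source, the **last column holding
the core gene set**. Columns may have unequal length; empty cells are
skipped; duplicate symbols within a column collapse; symbols are matched
exactly after normalization (uppercase, trimmed, internal whitespace
collapsed) with no alias expansion at this layer. Duplicate category
names are an error because weights are keyed by category.

A core symbol that appears in no source column violates the "at least one
indicator" property. Dropping it silently would bias the optimized
weights by truncating the gold standard, so it is kept as an all-zero row
(score 0 under any weights, counted by the objective) and a warning is
emitted and recorded in the object metadata. If every gene shares one
identical evidence row, all scores tie and the objective is the constant
$(M+1)/(2M)$ for every weight vector — the optimizer returns that value
rather than pretending to discriminate.

## Threshold selection

The method deliberately leaves the prioritization cutoff to the user,
supported by two tabular diagnostics (plot wrappers are a thin optional
layer; tests target the tables, since pixels are not assertable):

* `scoreDistribution()` — equal-width bins over $[0,1]$ (default 20,
  enough to resolve the distinct score levels reachable with a handful of
  categories; last bin closed) with per-bin counts of all genes and of
  core genes. A useful weight vector shows the core mass piled in the
  high-score bins.
* `thresholdCurve()` — per rank: the score and the cumulative number of
  core genes at or above it. Under good weights the coverage curve
  saturates early.

Three threshold policies express the choices this curve supports:
`"cover-core"` (smallest score cutoff flagging a fraction $q$ of the core
set; default $q = 1$), `"top-k"`, and `"score-cutoff"`.

## Literature co-occurrence screening

The single-gene experimental literature is too large to curate, so
involvement is screened by co-occurrence: for each gene, every alias is
paired with every phenotype phrase (defaults *nicotine, nicotinic,
tobacco, smoking*), and a pair scores a hit for each document whose
title+abstract contains both terms as **case-insensitive whole-word token
matches** (tokens split on non-alphanumerics, hyphens separating). Online
retrieval semantics — MeSH expansion, field weighting — cannot be
reproduced on a local corpus; the whole-word rule was chosen as the
transparent, deterministic approximation. No fuzzy matching is attempted:
aliases match literally after normalization, avoiding silent false
positives.

Per-pair counts are pooled by **summation**, mirroring the convention in
which separately issued alias queries returning 106 and 9 hits are
reported as 115; a document matched by several pairs counts once per
pair. Because distinct-publication counting is the statistically cleaner
variant, the report always carries `distinct_docs` alongside the summed
`total_hits`; the summed figure drives triage. Genes triage into
`auto_include` (`total_hits >= minHits`, default 5), `manual_review`
(1 to `minHits - 1`; the matched document ids are emitted as the review
worklist, since the review itself is human work), and `excluded` (0).

## Synthetic data

The generators exist so every stage is testable without network access,
and their defaults define the conditions under which the package's
properties are verified.

`genEvidenceMatrix()` draws each indicator Bernoulli with a per-category
background rate, additively boosted (capped at 1) for a designated core
subset — categories differing in how strongly they enrich true genes is
exactly the structure the weight search exploits. All-zero rows are
repaired by setting one uniformly chosen category to 1; repair was chosen
over rejection sampling because it always terminates and distorts
per-category rates less at low probabilities (the repair count is
recorded in metadata, and rate-calibration tests use settings where
repair cannot fire). The benchmark scales used by the tests and the
acceptance script — 300 genes × 3 categories with 20 core genes for
annealer-vs-oracle comparisons, and 500 genes × 4 categories with 30 core
genes and a +0.6 boost confined to category 1 (background 0.1) for
planted-weight recovery — are small enough to run in seconds per instance
while leaving the rank statistics well away from small-sample noise.

`genCorpus()` plants an exact number of documents per (alias, phrase)
pair and pads with noise documents drawn from a filler vocabulary that is
screened against all alias and phrase tokens, so accidental co-occurrence
is impossible and count recovery is exact rather than probabilistic.

What the generators do **not** emulate: correlated membership across
categories, realistic abstract language, citation structure, alias
ambiguity between genes, or retrieval-engine semantics. Passing tests
therefore demonstrate correctness of the algorithms under the stated
generative model, not performance on real PubMed-derived data.

## Limitations

* The objective treats all core genes equally; no confidence weighting of
  the gold standard.
* Binary indicators discard within-source effect sizes and study counts.
* Simulated annealing is the only optimizer (with the grid as oracle);
  no p-values accompany the ranks.
* The co-occurrence screen is a desk-scale stand-in for online retrieval
  and inherits none of its recall.
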