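---
title: "Association-based CLR network inference: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Association-based CLR network inference: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Given a normalized expression compendium — an $n \times m$ matrix of $n$
genes measured over $m$ hybridizations or libraries — coexpression-style
reverse engineering scores every unordered gene pair for association and
keeps the pairs whose association stands out against the background. At
genome scale the pair count $n(n-1)/2$ is the dominant cost (a 36,000-gene
genome needs over 600 million unordered evaluations), which is why the
pipeline is organized around a balanced pair-partition plan that lets
workers share the load without ever changing the answer.

clrnet implements that pipeline end to end: seven pairwise association
estimators, the context-likelihood-of-relatedness (CLR) background
correction, pair-level z-scoring and thresholding into Cytoscape-importable
edge lists, seed-based subnetwork extraction, and a synthetic benchmark
harness with ROC/AUC and confusion-table evaluation.

# The model

## Association estimators

All estimators are symmetric functions of two length-$m$ profiles.

* **Pearson, Spearman, Kendall.** Classical correlations; Spearman is
  Pearson on mean ranks, Kendall is the tie-corrected $\tau_b$. Pearson and
  Spearman go through `stats::cor()`; Kendall is computed by an
  $O(m \log m)$ merge-sort inversion count because the quadratic reference
  implementation dominates genome-scale runtimes (the test suite verifies
  equality with `stats::cor(method = "kendall")` to $10^{-12}$, ties
  included).
* **Theil–Sen score.** The Theil–Sen estimator is a robust slope, not a
  correlation, so a bounded symmetric score is constructed: standardize
  both profiles, take the median $\beta_{yx}$ of all pairwise slopes
  $(y_j - y_i)/(x_j - x_i)$ and symmetrically $\beta_{xy}$, and report
  $\operatorname{sign}(\beta_{yx})\min(1, \sqrt{\beta_{yx}\beta_{xy}})$,
  or 0 when the two medians disagree in sign. On standardized profiles an
  exact linear relation gives $\pm 1$, and the geometric mean penalizes
  asymmetric, outlier-driven fits.
* **Weighted rank correlation.** A weighted product-moment correlation of
  the two rank vectors, with weight $m - r + 1$ at rank $r$ so agreement
  among strongly expressed samples counts more. Each observation's weight
  is the mean of its two per-profile rank weights, which keeps the score
  symmetric in its arguments; the weight-by-rank vector is an exposed
  parameter because the literature offers several variants and no single
  canonical one.
* **Mutual information.** Plug-in MI in bits from an equal-width joint
  histogram, default $\lceil\sqrt{m}\rceil$ bins per axis clamped to
  $[2, 20]$. Equal-width binning is deterministic and keeps the estimator
  swappable; with tens to a few hundred samples the bin default trades
  variance against resolution in the usual $\sqrt{m}$ way.
* **MIC.** The maximal information coefficient: maximize
  $I(a \times b\ \text{grid}) / \log_2 \min(a, b)$ over grid resolutions
  with $a \cdot b \le \max(m^{0.6}, 4)$. Grids with two rows (or two
  columns) are optimized *exactly* by an $O(m^2)$ sweep over both cut
  points; finer grids use the standard approximation — equipartition one
  axis, optimize the other by dynamic programming over clump boundaries,
  with at most $c \cdot a$ candidate clumps ($c = 15$). The exact
  two-row sweep matters at small $m$, where the admissible grid set is
  tiny and the equipartition approximation can miss the optimum.

Zero-variance profiles score 0 under every estimator — a constant probe
carries no association evidence, and returning 0 rather than `NA` keeps
every downstream matrix finite.

## CLR background correction

For gene $i$, let $\mu_i, \sigma_i$ be the mean and sample standard
deviation of its off-diagonal association scores. Each pair $(i, j)$ gets
the rectified background z-scores
$u_i = \max(0, (a_{ij} - \mu_i)/\sigma_i)$ (0 when $\sigma_i = 0$) and
$u_j$ likewise, combined in quadrature:
$z_{ij} = \sqrt{u_i^2 + u_j^2}$. Backgrounds are full rows — no trimming —
because nothing in the method description calls for one.

**Magnitude evidence.** By default the correction operates on $|a_{ij}|$.
A strong negative correlation is strong evidence of a (repressive)
regulatory link; feeding signed scores through the rectifier would discard
exactly those pairs. On the packaged simulator (whose topologies contain
roughly 30% repression edges) signed evidence drops rank-based CLR to AUC
$\approx 0.71$ while MI-CLR stays near $0.90$; magnitude evidence restores
parity (all methods $0.89$–$0.92$), which is the regime the original
server's published comparison describes. `evidence = "signed"` is
available for data where direction matters.

## Pair z-scores and thresholding

Across a large network the CLR scores of all pairs are approximately
normal, so they are standardized against their own mean and standard
deviation, and the network cutoff is applied on that z-scale (the
case-study cutoffs 4.3 and 3.8 live here). Ties at the cutoff are kept
($\ge$, not $>$). A constant score matrix standardizes to all zeros rather
than erroring, so degenerate inputs flow through to an empty or complete
edge list depending on the cutoff.

## The partition plan and parallel execution

Row $i$ (0-based) owns the pairs $\{i, (i+d) \bmod n\}$ for
$d = 1..\lfloor (n-1)/2 \rfloor$; for even $n$ the antipodal pairs at
$d = n/2$ belong to the rows $i < n/2$. Every unordered pair is owned by
exactly one row, per-row loads differ by at most one, and rows are dealt
round-robin to workers. The published index formulas for this scheme
contain typographical inconsistencies (a missing comparator, interval ends
that cannot all be simultaneously right), so the implementation follows
the circular scheme they evidently describe and the tests verify the
coverage/uniqueness/balance invariants exhaustively for all $n \le 40$
instead of re-deriving the printed arithmetic.

Parallelism is an optimization with a contract: a pair's value never
depends on which worker computes it, and assembly is by fixed index, so
`infer_network()` output is byte-identical for 1, 2, 4 or 8 workers. The
default is 1 worker.

## Subnetwork extraction

* `snbuilder_extract()` — seed-neighborhood expansion. Round 1 admits the
  seeds' direct neighbors (the "baiting" step that makes a single seed
  useful); later rounds admit a candidate when at least a fraction
  (default 0.5) of its neighbors are already members, or when it touches
  two or more seeds. Rounds evaluate against the member set at round
  start, so the result is order-independent; default two rounds. The
  round-1 admission is a deliberate design choice: under the bare
  fraction rule a lone seed inside a clique would recruit nothing, which
  contradicts how seed-baiting tools behave.
* `gena_extract()` — greedy cohesion growth. Cohesion of a node set is
  $W_{in}/(W_{in} + W_{out})$ with edge z-scores as weights; the
  neighbor that maximizes cohesion is added while cohesion strictly
  improves and the module is under `max_size` (default 100). Ties break
  lexicographically. This produces the small, cohesive modules the
  original tool is known for, and the test suite checks it never returns
  a larger module than neighborhood expansion on the packaged fixtures.

Both algorithms are reimplementations in the spirit of their namesakes;
the deployed originals' exact scoring rules are not published, so the
precise greedy rules above are this package's own, with their parameters
exposed.

## The synthetic benchmark

`make_seed_topology()` emulates a curated regulatory seed network:
$\ge 12\%$ source genes, one to three regulators per regulated gene chosen
by preferential attachment (heavy-tailed out-degrees, verified against an
equal-density Erdős–Rényi control), $\approx 30\%$ repression, DAG by
construction. Each edge fixes Hill-transfer parameters at creation:
$K \sim U(0.2, 0.8)$, $h \in \{1, 2, 4\}$.

`simulate_expression()` draws source activities from $U(0.05, 1)$ per
sample, propagates activity as the product of per-edge Hill terms
(activation $x^h/(K^h + x^h)$, repression $K^h/(K^h + x^h)$), applies
multiplicative log-normal biological noise (default sd 0.1) at every gene
so it propagates downstream, and measures $\log_2$ activity plus additive
Gaussian experimental noise (default sd 0.1). In the zero-noise limit
every direct regulator–target pair is exactly monotone
(Spearman $\pm 1$), which anchors the simulator tests. Default noise
levels were chosen once so that the small-versus-large-compendium contrast
is visible at a few replicates, and were not revisited.

What the simulator does *not* reproduce: probe-level effects,
normalization artifacts, multi-regulator logic beyond the multiplicative
AND, feedback (cycles are broken), and the particular parameter settings
of the original published generator — absolute benchmark AUCs are
therefore comparable only qualitatively, not numerically, with the
published figure.

`run_benchmark()` follows the published design: Group A compendia of
30–90 samples, Group B of 100–1000, 50-gene subnetworks sampled from a
200-gene master topology by neighbor addition, every method scored by AUC
against the sampled topology's undirected skeleton, means reported per
group. One replicate is one compendium dataset; the packaged acceptance
run uses 3 replicates per size (21 Group A and 30 Group B datasets per
method), which keeps a full 7-method sweep inside a few minutes of one
CPU. MIC is restricted to compendia of at most 200 samples by default
(`mic_max_m`), reflecting its cost growth; its group means are over those
sizes.

Observed behavior on this harness: all seven methods land in a narrow AUC
band (about 0.89–0.92 at default noise), Group B means exceed Group A
means for every method, and everything clears the 0.5 random-guessing
floor decisively. The narrowness of the band means the *ordering among
the rank-flavored methods is not stable* — differences of a few thousandths
of AUC are sampling noise at this scale — so the package treats "all
association variants reach MI-CLR-like accuracy" as the reproducible
claim, not any particular podium order.

## Evaluation

`roc_auc()` is the Mann–Whitney rank statistic with ties counted ½; the
tests verify it equals the trapezoidal area under the threshold-sweep
curve (`roc_curve()`) to $10^{-9}$ and matches pROC. Reference edges are
undirected: association scores carry no direction.

Confusion reporting follows the published convention: `(TP, FP)` rescaled
to sum 100, `(TN, FN)` likewise, then sensitivity $TP/(TP{+}FN)$,
specificity $TN/(TN{+}FP)$ and accuracy $(TP{+}TN)/200$, displayed at one
decimal with half-up rounding. The published formula sheet prints
specificity as $FP/(FP{+}TN)$, but the published table's own values are
consistent only with $TN/(TN{+}FP)$; the table wins.
`evaluate_subnetwork()` draws the TN/FN sample from the network complement
"adjusted to the same size" uniformly at random under an explicit seed,
since the original sampling rule is unspecified.

# Numerical choices and degenerate inputs

* Input values are taken as-is: the reader neither log-transforms nor
  renormalizes, and nothing downstream assumes a particular scale. Whether
  a compendium arrives in log or linear units mostly matters for Pearson;
  the rank-based estimators (Spearman, Kendall, weighted rank, MIC) are
  invariant under any strictly increasing per-gene transform, which the
  tests verify.
* Missing values are rejected at load, never imputed: every estimator
  assumes complete profiles.
* Matrices are validated for unique gene IDs, finite values, $n \ge 2$,
  $m \ge 3$.
* Expression and edge files are written at 15 significant digits so write
  → read round trips are exact.
* All randomness flows through explicit `seed` arguments; package
  functions save and restore the caller's RNG state. Seeds derived
  internally stay below $2^{31}$.
* Ties: average ranks in Spearman/weighted-rank; $\tau_b$ corrections in
  Kendall; MIC never splits tied values across a grid cell boundary;
  edges tied at the cutoff are kept; subnetwork tie-breaks are
  lexicographic.

# Problem sizes used in the packaged checks

Unit tests run on matrices up to $n = 100$ genes; oracle-equivalence
sweeps use 100 randomized instances with $n \le 20$, $m \le 50$ plus
exhaustive partition checks for $n \le 40$; the benchmark acceptance run
is 3 replicates of the full two-group design (51 compendium datasets,
each analyzed by all 7 methods). These sizes were chosen so the complete suite documents
the method's behavior at desk scale; the pipeline itself has no hard size
limits beyond memory for the $n \times n$ matrices.

# Known limitations

* The CLR variant is the standard rectified-quadrature formulation; the
  original server's exact variant is not printed anywhere recoverable.
* MIC above the two-row level is the usual approximation, not the exact
  statistic; the exact-at-small-$m$ behavior is a property of the added
  two-row sweep.
* The subnetwork algorithms are faithful in spirit, not bit-compatible
  with the unpublished originals.
* Benchmark AUCs characterize the packaged simulator, not any published
  absolute figure; only qualitative orderings and trends transfer.
* No probe mapping, normalization, or enrichment analysis: inputs are
  assumed normalized, outputs are plain edge lists and node sets.
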