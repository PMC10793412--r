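---
title: "Methods and modeling choices in glycohub"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and modeling choices in glycohub}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycohub)
```

`glycohub` chains six analysis stages — differential-expression
meta-analysis, pathway enrichment, bipartite hub ranking, pathway-activity
association, single-cell communication scoring, and co-expression network
propagation — into a workflow for finding glycosyltransferase ("glycogene")
hubs upstream of extracellular-matrix (ECM) dysregulation and their
downstream cell–cell signaling. This vignette documents the statistical
model behind each stage, the tunable parameters and their defaults, the
numerical choices, what the synthetic-data generators do and do not
emulate, and the design decisions we made where more than one reasonable
convention exists.

## Input conventions

Bulk matrices are genes × samples on a **log scale**. The meta-analysis
works on standardized mean differences, so any monotone within-gene scale
is formally acceptable, but skewed raw counts would violate the
approximate-normality behind the effect-size variance formula; we
therefore require log-scale input and leave upstream normalization
(library-size correction, batch adjustment) to dedicated tools. Gene
identifiers are case-sensitive symbols; no alias mapping is attempted.
Single-cell inputs are non-negative integer counts with required cell-type
and condition labels — clustering and annotation are upstream of this
package, matching the common situation where labels from the original
study are reused.

## Random-effects meta-analysis

For gene *j* in stratum *i* (a cohort × region combination in which both
arms have at least 2 samples) we compute Hedges' g with the Hedges–Olkin
variance. Strata are combined with inverse-variance weights
$w_i = 1/(se_i^2 + \tau^2)$. The between-stratum variance $\tau^2$ is
estimated by restricted maximum likelihood via Fisher scoring on the
restricted score
$U(\tau^2) = \tfrac12\left[\sum w_i^2 r_i^2 - \sum w_i + \sum w_i^2 / \sum w_i\right]$
(residuals $r_i$ about the weighted mean), with at most 100 iterations,
tolerance $10^{-8}$ on the step, and a floor at zero; when the score at
zero is non-positive the estimate snaps exactly to the boundary, which is
what makes REML and DerSimonian–Laird agree to numerical precision
whenever Cochran's Q is at or below its degrees of freedom. Non-convergence
falls back to DerSimonian–Laird with a warning. A single stratum passes
through as a fixed-effect result with $\tau^2 = 0$. Our implementation is
cross-checked in the test suite against `metafor::rma` on random inputs
and against a brute-force grid maximizer of the restricted likelihood.

Two choices deserve explicit mention. First, all cohort × region strata
are combined per gene by default; because a region-by-region analysis is
an equally defensible reading of multi-region designs, `cohort_effects()`
exposes the per-stratum table so callers can combine any subset. Second,
when a glycogene table is supplied, Benjamini–Hochberg correction runs
over the glycogene universe (the screen is a glycogene screen); passing
`universe = "global"` corrects over all genes first and filters after.
With only two or three strata per gene, $\tau^2$ is estimated very noisily
— a well-known property of random-effects models at small k, visible in
our power simulations — which is why the planted-truth tests use three
cohorts.

## Enrichment

`ora_hypergeom()` is the textbook one-sided hypergeometric test against an
all-gene background, BH-corrected across sets, with a deterministic
(q, p, name) sort so "top 30" extraction is reproducible.

`gsea_preranked()` implements the classic weighted Kolmogorov–Smirnov
running sum with weight exponent 1 (the default of mainstream GSEA
implementations; our ES agrees with `fgsea::calcGseaStat` to 1e-12 in the
tests). Score ties are broken by gene name so rankings are deterministic.
Because the input is a preranked effect-size list, the permutation null
permutes **gene labels** (random same-size sets), not phenotypes; the
normalized enrichment score divides ES by the mean |null ES| of the same
sign and the p-value is the same-sign exceedance with the +1 correction,
so $p \ge 1/(n_{perm}+1)$.

The dual post-hoc test asks, for each (glycosylation pathway, enriched
pathway) pair, whether the glyco-pathway is over-represented *within* the
enriched pathway (hypergeometric, universe = all meta-analyzed genes) and
whether its members carry larger absolute combined effects than the
pathway's remaining members (Wilcoxon rank-sum). The second operand is not
uniquely determined by common practice; comparing against the enriched
pathway's other members is the stricter, more local choice, and
`wilcoxon_background = "genome"` switches to the global alternative. BH
runs within each test family separately (a joint correction across the two
families would mix p-values with different nulls), and a pair passes only
if **both** q-values are at or below the threshold, inclusively.

## Hub ranking

The bipartite graph links significantly enriched pathways (default GSEA
q < 0.05) to the differentially expressed glycogenes they contain. A
glycogene's degree is its number of incident **pathways**; genes are
ranked by competition ranking with lexicographic tie order, and the
maximal-degree gene is the functional hub (all tied genes are returned
with a flag). We deliberately use the pathway-count reading of "degree" —
counting genes connected to a pathway would rank pathways, not genes, and
could not single out a hub gene.

## Pathway-activity association

The ECM outcome is the **mean** expression of the ECM signature (union of
member genes of every pathway whose name contains "ECM", "Extracellular"
or "Collagen", case-insensitively) per sample; candidate pathway activity
enters as the first principal component(s) of the standardized member
submatrix. The association p-value is a permutation F-test (outcome
permuted across samples, default 999 permutations); per-stratum p-values
are combined with Fisher's method across **all** strata at once (grouping
flags let callers combine within cohort instead). Predictor genes shared
with the ECM signature are excluded before fitting so the association
cannot be driven by literal gene overlap. Strata with fewer than 10
samples are skipped: a one-PC regression on fewer samples is dominated by
noise.

This stage is an ordinary-PCA approximation of adaptive elastic-net sparse
pathway PCA ("AES-PCA"-style supervised approaches): the sparsity
refinement is a property of specific implementations rather than of the
method's logic, and plain PCA keeps the permutation test exact and
dependency-free. This is a named deviation; results are association
p-values of the same interpretation, not numerically identical estimates.

Eigengene activities fix the sign by positive correlation with the member
mean (PCA signs are otherwise arbitrary), are centered to zero mean, and
are invariant to gene order and to per-gene constant shifts —
all verified as properties in the tests.

## Single-cell stage

Normalization is $\ln(1 + 10^4 c / \text{total})$ per cell. Highly
variable genes use a variance-stabilizing-transform-style standardized
variance: a degree-2 polynomial trend of log10 variance on log10 mean
(deterministic, unlike a loess fit), standardization by the trend SD, and
clipping at $\sqrt{n_{cells}}$. Marker detection shares the exact Wilcoxon
implementation with the bulk dual test (one code path, asserted in the
tests) and reports $\log_2$ fold changes of de-logged means with
$\epsilon = 10^{-9}$.

The ligand–receptor score is a deliberately simple mass-action saturation
$\bar L \bar R / (K_h + \bar L \bar R)$ on mean normalized expression
(geometric mean across receptor subunits), with $K_h = 0.5$ exposed.
Full communication frameworks add trimean summaries, co-factors and
pathway aggregation; we model only the core monotone saturating
relationship, which is what the planted-truth recovery actually needs, and
attach significance by permuting cell-type labels. This simplification is
a named deviation, and $K_h$, the permutation count and the score
threshold are all configurable.

## Network propagation

The co-expression network over one annotated cell type uses unsigned soft
adjacency $|cor|^\beta$ with $\beta = 8$ by default (the customary value
for unsigned networks; `fit_scale_free_beta()` scans $\beta \in 1..20$ by
scale-free fit when data suggest otherwise; no metacell aggregation is
performed — the network is built on the cells of the chosen type
directly). The topological overlap matrix follows the standard formula,
cross-checked against a cubic-time oracle to 1e-12. Edges are kept if
their weight is **strictly above** the percentile threshold (default
90th), computed with linear-interpolation quantiles over the strict upper
triangle — unique pairs, not the full symmetric matrix, so each edge
counts once.

The random walk with restart column-normalizes the weight matrix (the
convention of mainstream RWR packages; dangling nodes receive self-loops),
restarts uniformly over the seeds with probability $r = 0.7$, and iterates
to an L1 tolerance of $10^{-10}$ (cap $10^4$ iterations; non-convergence
is an error, not a silent result). The fixed point is verified against the
direct linear solve $(I - (1-r)W)p = rp_0$ and is independent of the
starting vector; seed mass increases strictly with $r$. Restart
probability and tolerance are exposed because published analyses rarely
state them; $r = 0.7$ keeps the walk local enough that a planted 30-gene
module is recovered at high overlap while still ranking multi-step
neighbors.

## Synthetic data: what it emulates, and what it does not

`simulate_bulk()` draws Gaussian log-expression per cohort × region with
planted standardized shifts (a DE gene's case arm moves by
$\delta \times SD$), an optional bivariate-Gaussian correlated pair, and
an optional latent "driver" pathway whose per-sample activity linearly
drives the ECM signature genes at a stated coefficient and noise SD.
Defaults mirror a three-cohort, seven-region brain study at desk scale
(20 samples per arm per stratum, 500 genes, 40 glycogenes).
`simulate_pathways()` builds a collection in which "enrichable" sets carry
a stated fraction of planted DE genes, the hub glycogene appears in
exactly its specified number of sets, and decoys in at most theirs.
`simulate_single_cell()` draws negative-binomial counts (gene-specific
means, common dispersion 2) with the planted ligand/receptor multiplied by
`fold_up` in sender/receiver cells and a log-normal latent factor shared
by module genes within one cell type; the planted ligand and receptor
start from the midpoint of the baseline mean range so the planted
communication is defined by the fold-up itself rather than by a lucky
draw of baselines.

These generators reproduce the *statistical structure* each stage assumes
— not real data. They have no batch effects, no cohort-specific
normalization artifacts, no correlated background beyond what is planted,
binary case/control labels rather than graded neuropathology, and no
doublets or ambient contamination in the single-cell counts. Passing
planted-truth tests therefore demonstrates that the machinery recovers the
signal it models under its own assumptions, not that those assumptions
hold in any particular cohort. Truth records are plain lists serializable
to JSON (`write_truth()`) so external tooling can consume them.

## Numerical choices and degenerate inputs

Zero p-values entering Fisher's method are clamped to the smallest
positive double with a warning. Zero pooled SD, empty arms, zero-variance
correlation inputs, zero-total cells, empty universes, and absent seeds
are all hard errors naming the offending entity; zero-variance genes are
*dropped with a warning* where a network can still be built. All
randomized operations take an explicit integer seed and restore the
caller's RNG state, so no global RNG state leaks; identical seeds give
identical results everywhere, which the tests assert.

## Problem sizes used in the shipped simulations

The test and acceptance simulations run at deliberately modest sizes
chosen as the smallest at which each stage's statistical behavior is
cleanly visible: 100–500 genes, 15–50 samples per arm, two or three
cohorts, 30 pathways, 100–250 cells per type, 100–500 permutations, and
10–200 replicates per property. These are package choices, documented so
that users scaling up to cohort-sized data know the defaults were
validated at desk scale.

## Known limitations

* Random-effects $\tau^2$ at k ≤ 3 strata is noisy; per-gene inference
  inherits that noise (wider intervals, occasional power loss).
* The enrichment stage assumes preranked scores are exchangeable across
  genes under the null; correlated genes within sets make the gene-label
  permutation null anti-conservative, as with any preranked GSEA.
* The ligand–receptor model ignores subunit stoichiometry, co-factors and
  spatial context.
* The pathway-association stage reports associations of pathway PCs, not
  sparse gene-level loadings.
* No gene-identifier mapping: symbol mismatches silently reduce overlap
  (readers warn when query genes fall outside the universe).
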