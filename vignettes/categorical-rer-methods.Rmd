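---
title: "Associating relative evolutionary rates with categorical traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Associating relative evolutionary rates with categorical traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(catrer)
```

## The problem

Convergent evolution provides natural replicates of phenotype
acquisition: when unrelated lineages acquire the same trait and the same
genes shift their evolutionary rate on exactly those lineages, that
co-occurrence is evidence of a genotype–phenotype link. Rate-based
comparative methods quantify this with **relative evolutionary rates
(RERs)**: per-branch, per-gene residuals of branch length after removing
genome-wide expectations. A positive RER means the gene evolves faster
than expected on that branch.

Most rate-convergence machinery assumes a binary foreground/background
split. Traits like mammalian diet are non-ordinal with three or more
states, and binarizing them forces an arbitrary choice (one state versus
the rest, or dropping a state entirely), changes the ancestral
reconstruction, and can split a real signal across several pairwise
contrasts. `catrer` treats the trait as genuinely categorical in all
four stages: ancestral reconstruction, branch labeling, association
testing, and the permutation null.

## RER computation

For gene $g$ with mapped branch lengths $x_{bg}$ and genome-wide
expected lengths $e_b$:

1. **Expectation.** $e_b$ is estimated iteratively: each gene column is
   divided by its least-squares projection scale
   $c_g = \sum_b x_{bg} e_b / \sum_b e_b^2$ onto the current
   expectation, then the expectation is re-averaged across genes. At
   most 20 iterations, convergence when the maximum relative change
   drops below $10^{-6}$. If all genes are exact multiples of one
   vector, the first iteration is already the fixed point.
2. **Per-gene normalization.** Each column is divided by its projection
   scale, which makes RERs exactly invariant to multiplying a gene's
   lengths by any positive constant.
3. **Transform and winsorization.** By default both gene lengths and
   expectations are square-root transformed (variance stabilization for
   length-like quantities), and the 3 most extreme values per tail of
   each are clamped to the adjacent value. Winsorization happens after
   the transform and before the regression; clamping both sides of the
   regression keeps a perfectly proportional gene at exactly zero
   residuals.
4. **Weighted regression.** RERs are the residuals of a weighted linear
   regression of transformed gene lengths on transformed expectations.
   Weights are inverse per-branch variances estimated from the
   cross-gene spread of a first unweighted pass, floored at their 5th
   percentile so no branch gets unbounded weight.

Genes with fewer than 10 species (configurable, minimum 3) are dropped;
missing branches stay missing — an RER is `NA` exactly where the gene
lacks the branch.

## Ancestral reconstruction under a CTMM

The trait evolves along the master tree (branch lengths = average
genome-wide rates) as a continuous-time Markov chain with generator
$Q$: off-diagonal rates non-negative, rows summing to zero, and
$P(t) = e^{Qt}$. Rate models tie the off-diagonal entries: ER (one
shared rate), SYM ($K(K-1)/2$), ARD ($K(K-1)$), or any custom integer
index matrix. Likelihoods come from Felsenstein pruning with per-node
rescaling; $e^{Qt}$ is computed from one eigendecomposition of $Q$ per
likelihood evaluation (with a Padé `expm` fallback when $Q$ is
numerically defective), since the optimizer evaluates thousands of
branch kernels.

Fitting maximizes the pruning likelihood over log-rates. Rate surfaces
of richer models are multimodal, so multi-parameter models use 5
Nelder-Mead starts drawn log-uniformly on $[10^{-3}, 10]$ divided by
tree height, seeded for determinism; one-parameter models use bounded
Brent optimization. Nested models are compared by likelihood-ratio
tests ($2\Delta \ln L$ against $\chi^2$ with the parameter-count
difference as df, richer model adopted at $\alpha = 0.05$); nesting is
verified structurally from the index matrices (every tie of the richer
model must be a tie of the simpler one).

Design choices that the data do not force, and how they were made:

* **Root prior**: flat $1/K$ by default, with stationary and
  user-supplied options. A flat prior is the common default and is
  recorded in every output so the choice is auditable.
* **Marginal vs joint**: the default reconstruction is the marginal
  two-pass posterior (downward pruning pass, upward evidence pass,
  normalized product); a joint max-product reconstruction is available
  behind `type = "joint"`. Marginals are what the per-node probability
  vectors mean.
* **Tie-break**: ML state ties resolve to the lowest registry index,
  deterministically.
* **Branch labeling**: a branch carries the ML state of its **child**
  node (tips: the observed state), because the branch's rate is measured
  on the lineage ending at that child.
* **Zero-length branches** get an identity transition matrix and no
  other special-casing.

## Association tests

Per gene, RER values on all branches (terminal and internal) are grouped
by branch category label. The default omnibus test is Kruskal–Wallis
with tie correction; the effect size is $\varepsilon^2 = H/(n-1)$ with
$n$ the number of branches used — an identity asserted to machine
precision in the test suite. Post hoc Dunn tests report pairwise $Z$
from mean-rank differences with tie-corrected variance; $Z > 0$ means
the first category of the pair (registry order) has the larger mean
rank, i.e. faster evolution. A parametric alternative (one-way ANOVA
with $\eta^2 = SS_b/(SS_b + SS_w)$, Tukey HSD post hoc) sits behind
`method = "anova"`. The Kruskal–Wallis statistic is computed by an
internal formula — unit-tested against `stats::kruskal.test` — because
the identical code path must score hundreds of permulation draws
cheaply; ANOVA and Tukey delegate to `stats`.

The Dunn multiple-comparison adjustment is Benjamini–Hochberg across the
$K(K-1)/2$ pairs within a gene by default (Holm and others available via
`adjust`); the choice is recorded in the scan's attributes since
different conventions exist. Genes need `min_per_category` (default 2)
branches in every category, else they are skipped and listed.

## Permulations

Parametric p-values on phylogenetically autocorrelated branch data are
not trustworthy; the package's null model is **permulations** —
simulations constrained to the observed phenotype distribution:

1. **Rejection sampling.** Phenotypes are simulated from the fitted
   CTMM down the master tree; a draw is accepted only if every
   category's extant count is within `ceiling(r × observed)` of the
   observed count. `r = 0` (default) demands exact equality. The
   relaxed criterion is monotone in `r`, reduces to exact matching at
   `r = 0`, and is recorded in the permulation set's metadata; `r = 0.1`
   gives order-of-magnitude speedups as categories multiply (the
   acceptance script measures roughly a 10–20x attempt reduction on the
   40-species, 3-category synthetic study).
2. **Internal permutation.** Simulated internal states are discarded; a
   uniform permutation of the *observed reconstruction's* internal
   states is placed on the internal nodes, conserving the multiset.
3. **Annealing.** A swap proposal (two internal nodes with differing
   states) is accepted when it improves the full-labeling
   log-likelihood, or with probability $e^{\Delta/T}$ otherwise, with
   $T$ cooled geometrically (default $T_0 = 1$, factor 0.95,
   $\min(100 \cdot n_{\text{internal}}, 10^4)$ steps). The best labeling
   visited is returned, so the result never has lower likelihood than
   the start, and the multiset is conserved throughout. On small trees
   the annealer recovers the exhaustive-enumeration optimum in ≥95% of
   seeded runs (tested).

Each draw is seeded as `seed + i`, making a permulation set bit-identical
under the same configuration. Empirical p-values are proportions of null
statistics at least as extreme as the observed one: one-sided (≥) for
omnibus effect sizes — the omnibus test is one-sided — and two-sided by
absolute value for signed post hoc statistics. A p of exactly zero is
reported as the raw proportion, flagged, and displayed as `< 1/N`; no
add-one correction is applied by default (a `(b+1)/(N+1)` estimator is
available via `add_one`).

## Enrichment

Genes are ranked by `-log10 p` (omnibus) or by the signed post hoc score
(pair mode, most positive to most negative, ties broken by gene id).
Pathway enrichment is a Wilcoxon rank-sum of member scores against
non-members — one-sided for omnibus ranks, two-sided for signed ranks —
with BH-FDR across pathways and size bounds of [10, 500] members after
intersection with scanned genes (standard practice; genes absent from
the scan are dropped from pathways rather than imputed at low rank).
Fold-enrichment curves divide the cumulative member fraction among the
top $k$ by the pathway's overall fraction; the curve ends at exactly 1,
and the barcode marks member positions.

Permulation-corrected pathway p-values rescore every draw's gene
statistics through the same rank-then-Wilcoxon pipeline and compare the
observed standardized rank-sum to the null ones. This is what absorbs
rank clustering: a block of genes sharing branch-level noise (an
olfactory-receptor-like family) rides up and down the ranking together,
inflating parametric enrichment, but it does the same under every
permulated labeling, so its empirical p stays unremarkable. The
acceptance suite demonstrates both halves on 20 planted 25-gene blocks.

## Site screen

For a protein alignment, each column yields per-category residue sets
(gap characters and X excluded; a lineage with a gap is ignored at that
site). The between-category similarity score is the **minimum pairwise
Jaccard index** (mean available behind `method = "mean"`); the score is
not canonical, so it is explicit in the configuration and output. Sites
at or below the threshold are then checked for clade confounding: the
most invariant category's majority residue is scored as a
presence/absence character by Fitch small parsimony, and the minimum
number of state changes is the number of independent origins. One origin
means one clade explains the difference — flagged, not silently removed.
Coordinates are 1-based alignment columns, with reference-sequence
positions added when a reference row is named.

## Synthetic data

The generator produces the study conditions the tests run under:

* **Master tree**: random rooted topology, exponential branch lengths
  with mean 0.1 — the scale of genome-average substitution rates on
  mammalian-like trees.
* **Phenotype**: simulated down the master tree under an ER generator
  with rate 1 by default (about 0.1 expected changes per branch),
  returning true internal states for recovery scoring.
* **Gene trees**: length of branch $b$ in gene $g$ is
  $\text{master}_b \times \text{scale}_g \times \text{noise}_{gb}
  \times m^{[g \text{ affected}, b \text{ on target}]}$, with lognormal
  per-branch noise (sd 0.3, mean 1), lognormal gene scale (log-sd 0.2),
  multiplier $m = 3$ on the target category's branches for a seeded 10%
  of genes. Multiplicative lognormal noise is positive and scale-free,
  matching the regression-residual framework of RERs.
* **Correlated blocks**: `correlate_gene_blocks()` multiplies block
  members by shared per-branch noise, emulating coherent gene families.

What the generator does *not* emulate: gene-tree estimation error,
alignment error, heterotachy within categories, selection acting on the
phenotype, and non-Markovian trait evolution. Passing tests therefore
show that the machinery is correct and calibrated under its own model,
not that real data meet the model's assumptions.

## Problem sizes and numerical choices

The test suite and acceptance script run at deliberately chosen desk
scales: null calibration uses 40 species × 500 genes × 200 permulations;
planted-shift detection uses 100 species × 500 genes; likelihood oracles
enumerate all assignments on trees of up to 6 tips (200 random
instances, agreement to $10^{-9}$); ER rate recovery uses 20 replicates
of 500-tip trees. Published analyses at this method's natural scale run
~19,000 genes and 10,000 permulations; the statistics are identical,
only the Monte Carlo resolution differs (empirical p granularity 1/200
here versus 1/10,000 there).

Other numerical decisions: transition matrices are clamped to
non-negative entries and renormalized after the eigendecomposition
(round-off guard); pruning uses per-node max-rescaling with accumulated
log scale factors; annealing log transition probabilities are floored at
$10^{-300}$; the rejection sampler's attempt budget defaults to
$100 \times N$ per draw and fails loudly, advising a larger relaxation,
rather than silently degrading.

## Known limitations

* The rejection sampler's acceptance rate collapses as categories
  multiply and the phenotype clusters on the tree; the relaxed criterion
  is the mitigation, and exact-count permulation of 5–6 categories on
  large trees may be impractical.
* Empirical p-values inherit 1/N granularity; pathway conclusions at
  p ≈ 1/N need larger N.
* Branch labels are hard ML calls; reconstruction uncertainty is
  available in the node probability vectors but is not propagated into
  the association tests.
* The site screen's similarity score ignores residue counts within a
  category (a set-based score); a single aberrant sequence can enlarge
  a category's set.
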