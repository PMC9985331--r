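---
title: "Co-expression guilt-by-association for lncRNAs: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-expression guilt-by-association for lncRNAs: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncoex)
```

# The inference problem

Long non-coding RNAs are numerous and mostly uncharacterized. The one signal
that is abundantly available for them is co-expression: across a large,
heterogeneous corpus of bulk RNA-seq samples, a lncRNA that is consistently
transcribed together with a set of well-annotated genes probably participates
in the same programs. `lncoex` turns that observation into four concrete
estimators — gene-set association, network neighborhoods, subcellular
localization, and cis/trans mode — all driven by a single fitted object, the
prevalence-filtered Pearson correlation matrix.

The key modelling assumption throughout is that the sample corpus is diverse
enough for correlation to reflect shared regulation rather than a single
dominant covariate. Nothing in the package corrects for batch or tissue
composition; that is deliberate (the heterogeneity is the signal source) but
it means conclusions inherit whatever structure the corpus has.

# The correlation fit

`coexpression()` takes raw counts, removes genes with zero reads in every
sample, applies `log2(x + 1)`, quantile-normalizes across samples, and
computes all pairwise Pearson coefficients. Two numerical choices matter:

* **Pseudocount.** Counts contain zeros, so the log transform uses
  `log2(x + 1)`. The +1 keeps zeros at zero, which the prevalence filter
  relies on.
* **Quantile-normalization ties.** Tied values within a sample receive the
  mean of the reference distribution at their rank positions (the
  mean-of-ranks dialect, via `limma::normalizeQuantiles(ties = TRUE)`). With
  ties, sorted columns agree up to tie collapsing; on continuous data they
  agree to machine precision.

**The prevalence filter.** Lowly expressed genes produce misleadingly high
correlations — two genes each detected in three of 6000 samples can correlate
perfectly by accident. A pair (i, j) is therefore only scored when
`max(prev_i, prev_j) >= theta`, where `prev_g` is the fraction of samples
with normalized value > 0; otherwise `r[i, j]` is exactly 0. The default
`theta = 0.3` is exposed as a parameter. Prevalence is computed on
*normalized* values; because quantile normalization maps the zero rank to
the reference minimum, zero-positivity is preserved whenever every sample
contains at least one zero, which holds for any realistic counts matrix.

Two degenerate cases are pinned down explicitly: a constant
(zero-variance) gene has no defined correlation direction, so it gets r = 0
with *all* partners, including itself — we prefer an exact, filter-like zero
over NaN even though it costs the unit diagonal for such genes; and the
filter produces exact zeros, not small values, so downstream consumers can
treat 0 as "not scored".

# Gene-set association and its null

For query g and term T, the statistic is the mean PCC between g and the
members of T present in the fit, with g excluded from T if it is a member
(self-correlation 1 would bias every term containing the query). Raw mean
PCCs are not comparable across terms of different size and composition, so
each term carries its own null: the mean PCC of *every* background gene with
that term. The z-score of the query against that per-term mean and sample SD
(denominator n − 1) is mapped through the normal CDF to right- and
left-tailed p-values; `p_right + p_left = 1` exactly.

Two readings of "per-term null" were possible: the distribution of the
statistic over all background query genes (adopted), or a size-matched
random-set null per query. The first is self-calibrating — a term whose
genes are promiscuously correlated with everything gets a wide null and is
not rewarded — and requires no extra sampling; the second conflates set size
with composition. When a term's null SD is zero (all background genes score
identically, only possible in tiny or degenerate fits) the score is flagged
`degenerate` and given p = 0.5 on both tails rather than an infinite z.

No multiple-testing correction is applied across terms: the scores are used
as a ranking, and the per-term nulls already put them on a common scale.
Consumers who need family-wise control can apply `p.adjust` to the returned
column.

# Network construction

The neighborhood view around a seed gene takes the 100 most positively
correlated genes (signed r, descending), initializes with each node's three
strongest incident edges, drops edges below weight 0.3, and then prunes:
while the average degree is ≥ 3, every hub (> 10 edges) loses its weakest
unprotected edge; if no hub exists, the single globally weakest unprotected
edge goes. The seed's five strongest edges — chosen before any dropping —
are immune to both the weight cut and the pruning, so the seed is never
orphaned. Hubs are re-identified at each iteration (the threshold defines
what a hub *is*, not a frozen set), one removal per hub per sweep. All ties
break lexicographically on (weight, sorted gene pair), making the algorithm
deterministic; every sweep removes at least one edge or stops, so it
terminates. Whether protected seed edges count toward the average-degree
stopping rule was an open choice; they do, since the rule describes the
rendered network.

# Localization scoring

For each query, all universe genes (fit ∩ RCI table, plus the queries) are
ranked by correlation with the query, ascending, ranks scaled as
`(position − 1) / (G − 2)` so the strongest correlate scores 1 and the
weakest 0 (ties share mean positions). Scaled ranks are multiplied by
measured CN RCIs where present and summed; missing RCIs contribute nothing.
Per cell line, raw sums are min-max normalized across the scored queries and
shifted to [−0.5, 0.5], mirroring the RCI convention (positive =
cytoplasmic).

Design choices worth stating:

* **Self-exclusion.** A query's own measured RCI never enters its sum. With
  self-correlation 1, the query's own label would otherwise enter at maximal
  weight and leak into the evaluation, inflating AUROC. This is a deliberate
  leakage guard.
* **Per-cell-line normalization.** RCI gene coverage differs between cell
  lines, so raw sums live on different scales; min-max is applied within
  each cell line rather than globally.
* **Negative correlates.** Anti-correlated genes sit near rank 0 and still
  contribute (small) weight; they are retained as stated by the rank
  construction rather than zeroed.
* A single query makes min-max degenerate; the score is set to 0 with a
  warning. A cell line with no measured RCI in the universe is an error.

Evaluation labels queries with measured RCI > +1 cytoplasmic (positive) and
< −1 nuclear (negative), ignores the uncommitted middle, and computes AUROC
by the Mann–Whitney rank identity (midranks give ties half credit), which a
test verifies against exhaustive pair counting. Reporting keeps the top five
cell lines by AUROC.

# cis/trans, perturbations, profiles

A partner among a gene's top-100 positive correlates is **cis** if it shares
the gene's chromosome, **trans** otherwise — chromosome identity only, no
distance band, strand ignored. Partners lacking annotation leave both the
numerator and denominator, so cis% + trans% = 100 exactly, per gene and in
cohort aggregates (mean ± sample SD). Class restriction (coding-only,
lncRNA-only) is applied before truncation to k, matching the semantics of
per-class summaries.

Perturbation signatures are gene sets labeled `_up`/`_down`. Queries are
ranked per signature by mean PCC, the top 1000 retained, and the mapping
inverted into an ordered per-query library; the inversion is exactly the
retained-pair relation, which a round-trip test enforces. Report tables
order by right-tailed p (the per-signature z against the query cohort),
while the mean-PCC order defines retention.

Sample labeling is a three-tier text search (cell type → tissue →
cell line) over lowercased, symbol-stripped text. Vocabulary terms shorter
than five characters match only at word boundaries, and cell-line names of
≤ 3 characters are searched as `"<name> cell"` — both guards against false
positives in free-text descriptions. Same-tier multi-matches are left
unlabeled and flagged for manual resolution rather than resolved by a
heuristic. Group statistics drop groups below 20 samples (a parameter;
10 is the conventional choice for sparser corpora such as mouse cell lines).

# The synthetic generator

`generate_counts()` plants modules with a latent-factor Gaussian model on the
log2 scale: module genes are `sqrt(rho) * factor + sqrt(1 - rho) * noise`,
exponentiated and rounded to non-negative integer counts. Defaults — 500
genes × 200 samples, five modules of 20 genes, rho = 0.9, latent SD 1 around
a base log2 expression of 6, 30% lncRNA flags, 10 chromosomes, RCI effect
±2 with SD 0.2 over 5 cell lines and 10% missingness — are desk-scale
conditions under which the planted structure is unambiguous: realized
within-module PCC ≈ 0.86, RCI classes separated by 10 noise SDs. The
companion generators emit a gene-set library whose planted terms are exactly
the module memberships (background terms are rejection-sampled never to
contain a whole module), an RCI table keyed to the first (cytoplasmic) and
second (nuclear) modules, and a knockdown-style differential-expression
table for a chosen module. All randomness flows through the single
`random_seed`, so outputs are bit-identical across runs.

What the generator does **not** emulate: library-size variation,
negative-binomial dispersion, batch effects, correlated module overlap, or
the heavy-tailed prevalence spectrum of real corpora. Passing tests on these
fixtures therefore establish *algorithmic correctness* — the estimators
recover structure that is present by construction — not field performance on
real data, whose signal-to-noise is far worse and whose nulls are not
Gaussian.

# Problem sizes and tolerances in the test suite

The suite runs fitted matrices of 25–500 genes and 30–200 samples: large
enough that empirical correlations concentrate (at 200 samples the standard
error of a null PCC is ≈ 0.07), small enough that the whole suite and the
reproduction script finish in well under a minute each. Exact-arithmetic
claims (tail-sum Fisher p, AUROC pair counting, cis + trans = 100, GMT round
trips) are asserted with `expect_identical` or tolerance 1e-9–1e-12;
oracle-equivalence claims (naive two-pass Pearson, hand-recomputed z-scores)
at 1e-10–1e-12; stochastic recovery claims (planted-term rank 1 in ≥ 95% of
20 seeds, localization AUROC ≥ 0.95) at the rates the planted effect sizes
make essentially deterministic.

# Known limitations

* Dense matrix algebra: the fit is O(G²) memory; corpus-scale gene counts
  (> 20k genes) need chunked computation that this package does not provide.
* The expression reader accepts TSV only.
* The per-term normal null is an approximation; for very small backgrounds
  the empirical null is discrete and the tails are approximate.
* Manual curation steps that real pipelines interleave (alias resolution,
  ambiguous sample labels) are represented as optional override inputs, not
  reproduced.
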