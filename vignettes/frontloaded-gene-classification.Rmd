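---
title: "Classifying frontloaded nitrogen-responsive genes in contrasting genotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying frontloaded nitrogen-responsive genes in contrasting genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(frontloadr)
```

## The question the pipeline answers

Two near-isogenic lines (NILs) that differ sharply in nitrogen use
efficiency (NUE) — coded `HI` (high-NUE) and `LO` (low-NUE) here — are
profiled by bulk RNA-seq under normal nitrogen (`N1`) and nitrogen
deficiency (`N0`), with biological replicates in each of the four
genotype × treatment cells. The interesting biology sits in the genes that
respond to deficiency in *one* genotype only. Among the genes that respond
only in the low-NUE line, two expression geometries are distinguished for
the high-NUE line:

* **Frontloaded genes** — already expressed at a high level in `HI`
  relative to `LO` under normal nitrogen (fold-change ratio > 2), and at a
  comparatively *lower* level under deficiency (ratio < 0.5). The high-NUE
  line "pre-pays" the stress response, so it has less need to induce these
  genes when nitrogen runs out.
* **Relatively upregulated genes** — the mirror image: lower relative
  expression under normal nitrogen (ratio < 0.5), higher under deficiency
  (ratio > 2).

The package computes the whole chain from a gene-level count matrix to
these two classes, with explicit bookkeeping at every exclusion step, and
ships a negative-binomial simulator with planted gene archetypes so each
stage can be validated against known truth.

## The contrast quartet

Everything downstream consumes four two-group contrasts, all oriented from
the focal genotype's point of view (numerator first):

| name             | comparison             | role                              |
|------------------|------------------------|-----------------------------------|
| `focal_response` | `N0_focal vs N1_focal` | nitrogen response of the focal NIL|
| `other_response` | `N0_other vs N1_other` | nitrogen response of the other NIL|
| `between_n1`     | `N1_focal vs N1_other` | genotype difference, normal N     |
| `between_n0`     | `N0_focal vs N0_other` | genotype difference, deficiency   |

A gene is a DEG in a contrast when its BH-adjusted p-value is below
`alpha = 0.05` **and** `|log2 fold change| >= 1`. The fold-change bound is
inclusive by default (a `strict_fc` flag switches to a strict inequality);
with count data and a pseudocount the boundary is attainable, so the
convention matters and is stated in the output metadata.

## Differential-expression engine

Counts are normalized by median-of-ratios size factors (the midpoint
convention is used for the median of an even number of ratios; if no gene
is positive in every sample, column-sum normalization is used with a
warning). Group means are means of normalized counts, and

$$\log_2 \mathrm{FC} = \log_2\frac{\bar{x}_{num} + \varepsilon}{\bar{x}_{den} + \varepsilon},
\qquad \varepsilon = 1,$$

so fold changes are defined even at zero counts.

P-values come, by default, from a moderated pooled-variance t-statistic
with a mean–variance trend (limma's `lmFit`/`eBayes(trend = TRUE)`) on
`log2(normalized count + 1)`. The choice is driven by the design size: at
two or three replicates per group an unmoderated per-gene t-test has so few
residual degrees of freedom (about two, for Welch) that even 4-fold
expression differences are frequently unrecoverable after FDR adjustment —
in our recovery experiments the per-contrast sensitivity for 4-fold
between-genotype effects was roughly 0.72 for Welch against 0.99+ for the
moderated statistic, at identical false-positive control. A plain Welch
engine remains available (`engine = "welch"`), and externally computed
tables from any engine (e.g. a negative-binomial Wald test) can be injected
via `read_contrast_table()`, which recomputes the DEG flags from the
thresholds and flows through the identical downstream contracts.

Genes whose two groups both have zero sample variance are decided exactly
(p = 1 when the group means are equal, 0 otherwise); this keeps degenerate
inputs well-defined and makes hand-built fixtures with exact replicate
counts fully traceable.

Nothing beyond this is modeled: no dispersion shrinkage on the count scale,
no independent filtering, no fold-change shrinkage, no outlier replacement.
Users who need those properties should import their DE tables.

## The classification pipeline

For a focal genotype, `classify_frontloaded()` runs six stages:

1. **Genotype-specific response.** DEGs of the *other* genotype's response
   contrast minus DEGs of the focal response, each tagged with its
   direction in the other genotype.
2. **Expression filter.** Genes whose focal-genotype mean normalized count
   stays below `expression_floor = 1` in *both* treatments are set aside as
   not expressed. The floor of one normalized count is a deliberately
   permissive convention for "detected at all"; it is configurable.
3. **Trend filter.** Genes whose DE-table `log2fc` sign disagrees with the
   sign of the raw normalized-mean difference in either between-genotype
   contrast are set aside as trend-inconsistent, as are genes whose
   other-genotype mean is zero in both treatments (an undefined expression
   ratio without the pseudocount). With internally computed tables the sign
   rule cannot fire (the fold change is derived from the same means); it
   exists for externally estimated, possibly shrunken, fold changes. There
   is no community-standard definition of "inconsistent trends" for this
   bookkeeping; the sign-agreement rule is this package's documented
   default and the filter can be disabled (`trend_filter = FALSE`).
4. **Direction split.** Remaining (classifiable) genes split by their
   other-genotype direction: upregulated ones are frontload candidates,
   downregulated ones are relative-upregulation candidates.
5. **Between-genotype significance.** Candidates must be DEGs in *both*
   between-genotype contrasts.
6. **Ratio rules.** With $r_{N1}$ and $r_{N0}$ the pseudocounted
   focal/other normalized-mean ratios per treatment, a candidate is
   *frontloaded* iff $r_{N1} > 2$ and $r_{N0} < 0.5$, and *relatively
   upregulated* iff $r_{N1} < 0.5$ and $r_{N0} > 2$. The comparisons are
   strict. Candidates failing a ratio rule keep the label
   `candidate_unclassified` rather than disappearing, so the count chain
   from the specific set to the final classes is always auditable.

The ratios are recomputed from normalized group means rather than taken
from the DE engine's fold-change estimate, because they must be defined
(and comparable) for every candidate regardless of how the DE table was
produced; `ratio_source = "log2fc"` switches to `2^log2fc` from the
between-genotype tables when an externally estimated ratio is preferred.

Every stage's removal count lands in a `bookkeeping` object whose
invariants (`classifiable = specific − not expressed − trend-inconsistent
= up + down`, `final ≤ candidates ≤ direction class`) are enforced at
construction.

```{r}
m <- simulate_counts(default_sim_config(seed = 1))$counts
res <- classify_frontloaded(m, contrast_quartet(m, "HI"), "HI")
res$bookkeeping
```

## The synthetic generator

`simulate_counts()` draws independent negative-binomial counts with
variance $\mu + \phi\mu^2$ around planted cell means, under the emulated
study design: 2 genotypes × 2 nitrogen levels × 3 biological replicates.
Archetypes plant the geometries the classifier is meant to find; with
baseline $m$, between-genotype fold $b$ and response fold $r$, a
`frontloaded_in_HI` gene has cell means $(bm, bm, m, rm)$ in the order
(`HI_N1`, `HI_N0`, `LO_N1`, `LO_N0`): ratio $b$ under N1, $b/r$ under N0,
and a response confined to `LO`. The defaults are $m = 100$ (a moderately
expressed gene), $b = 4$, $r = 16$, $\phi = 0.05$ — effect sizes a factor
of two beyond the classification thresholds (2, 0.5), so that recovery is
testable at three replicates while remaining sensitive to genuine
implementation errors; the margins are configurable to probe sensitivity.
The default 2000-gene mix is 120/80 frontloaded/relatively-upregulated per
focal genotype, 300 shared-response, 300 constitutive-difference and 1000
null genes. Depth factors default to 1; a log-normal option (sdlog 0.2)
mimics realistic library-size variation.

The generator deliberately omits several properties of real RNA-seq:
per-gene dispersion trends, GC/length bias, batch effects, correlated
genes, and isoform-level variation. Passing recovery tests therefore
demonstrates that the *algorithmic chain* is correct under its stated
model, not that any particular biological dataset would yield particular
classes.

## Numerical and reporting conventions

* QC percentages (clean/raw, mapped/clean, uniquely-mapped/mapped) are
  rounded half-up to two decimals, matching how sequencing reports print
  them.
* FPKM is `count × 10^9 / (length_bp × library_size)`; the library size
  defaults to the column sum but accepts explicit mapped-fragment totals,
  since publications differ on whether the denominator counts uniquely or
  totally mapped fragments.
* In two-set Venn summaries, genes significant in both contrasts with
  opposite directions stay inside the common count and are reported as
  `inconsistent_common` (the parenthetical convention of two-set DEG
  diagrams); `drop_inconsistent = TRUE` removes them from both sets before
  the arithmetic instead, which preserves `|A| = common + unique_A`.
* Term enrichment is the upper-tail hypergeometric probability
  $P(X \ge k)$; the raw p at `alpha = 0.05` decides the `enriched` flag
  (mirroring common practice in transcriptome reports), with BH-adjusted
  values always emitted alongside for users who prefer corrected calls.
* qPCR relative expression is `2^-ddCt`; technical-replicate Ct values are
  averaged before the subtraction, and the calibrator condition must be
  designated explicitly in the Ct table, since conventions vary.

## Problem sizes used by the test suite

The shipped tests validate the arithmetic stages against hand-computed and
brute-force enumerated values (BH step-up, Venn regions, hypergeometric
tails, on ~100 randomized small instances each), and the statistical chain
on simulations of 2000 genes × 12 samples: one planted-class run per focal
genotype for recovery (sensitivity and precision ≥ 0.8 per class), and
twenty all-null runs for false-positive control (zero frontloaded labels
and a BH discovery fraction below the nominal 5%). These sizes were chosen
to give stable pass/fail behaviour across seeds at the default effect
sizes.

## Known limitations

* The default DE engine tests log-scale means with moderated variances; it
  is not a count-model likelihood and will differ in detail from
  negative-binomial engines near zero counts. Import external tables when
  exact parity with such engines matters.
* The trend filter's sign-agreement rule is one reasonable formalization
  of "inconsistent expression trends"; alternative conventions would move
  a handful of genes between `excluded_trend` and the classifiable set.
* Classification quality degrades gracefully but noticeably below three
  replicates per group or above dispersions of ~0.3 at the default effect
  sizes; the simulator is the intended tool for mapping that regime before
  applying the classifier to a new design.
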