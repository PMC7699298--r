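---
title: "Methods: trend-based screening of miRNA regulatory effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trend-based screening of miRNA regulatory effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirtrend)
```

## The scientific question

A microRNA that suppresses the cancer-stem-cell (CSC) phenotype should
leave a characteristic footprint in expression data: genes it *promotes*
rise monotonically as its activity is pushed from inhibited, through
endogenous (control), to over-expressed (mimic), and genes it *inhibits*
fall along the same gradient. When the same cell line is profiled both as
an adherent monolayer and as CSC-enriched colonospheres, a credible
regulatory target should behave the same way in both contexts. mirtrend
implements this screen and the quantitative stages that typically surround
it in a biomarker study: pooled small-RNA-seq group comparison, relative
qPCR quantification, and random-effects meta-analysis of public cohorts,
plus gene-set enrichment of the screen hits.

## The trend screen

### Statistic

For one gene, samples are grouped by the ordered treatment factor
(inhibitor < control < mimic; a four-arm design with separate mimic and
inhibitor controls is handled by pooling the two control arms, or
equivalently by assigning them tied middle ranks — for the
Jonckheere–Terpstra statistic the two encodings count identical
cross-group pairs). The Jonckheere–Terpstra (JT) statistic is

$$ JT = \sum_{a<b} \#\{x \in a,\, y \in b : x < y\} + \tfrac12\,\#\{x = y\}, $$

summed over ordered group pairs. Ties count one half to each side, which
makes the complement identity exact: the statistic computed on the
reversed group order plus the original equals the total number of
cross-group pairs.

### Empirical p-values

Significance is assessed by permuting treatment labels. The Monte-Carlo
p-value uses the add-one convention \((b+1)/(B+1)\), where \(b\) counts
permutations with a statistic at least as extreme in the tested direction,
so reported p-values are never exactly zero. For small designs an exact
mode enumerates all distinguishable label assignments (for example, 90 for
three groups of two, 1680 for three groups of three) and returns the exact
tail proportion. Tests are one-sided in the direction fitted for the gene
(the sign of the Spearman correlation between treatment rank and
expression, pooled across contexts, with an exact-zero correlation broken
toward "promoted"). Fitting the direction and testing on the same data is
deliberate — it mirrors how such screens are run in practice — but users
who need selection-free inference should either fix the direction a
priori or split replicates between fitting and testing; the per-gene
functions accept an explicit `direction` argument for exactly this
purpose.

### Per-context and transition-combined tests

Each gene receives a JT p-value within each context (monolayer, CSC) and a
combined p-value over the six context-by-treatment groups ordered
context-major: monolayer inhibitor, control, mimic, then CSC inhibitor,
control, mimic. For inhibited genes the monotone *decreasing* alternative
is evaluated on the same layout (rather than reversing the group order),
which keeps the complement identity and the direction semantics aligned.

The combined test offers two permutation nulls, and the distinction
matters:

- **Stratified** (default): treatment labels are shuffled within each
  context independently, preserving the context blocking of the design.
  Because every monolayer group precedes every CSC group in the layout,
  the cross-context pair counts are *invariant* under such permutations;
  the stratified combined test therefore pools the evidence of the two
  within-context trends and is insensitive to between-context level
  shifts. This is the right default when colonosphere culture itself
  shifts overall expression for reasons unrelated to the miRNA.
- **Unstratified**: all labels are shuffled jointly. The test then also
  demands a *progressive* ordering across the monolayer-to-CSC
  transition: a gene trending within both contexts whose CSC levels fall
  back below the monolayer maximum loses significance. Use this null when
  the scientific claim is specifically "progressively regulated through
  the transition".

This is a genuine fork in the method's design: a single test cannot both
block out context-level shifts and test for progression across them. The
package exposes both and defaults to the blocked null.

### The working-hypothesis flag and multiple testing

A gene is flagged *consistent with the working hypothesis* when its
fitted direction is identical in both contexts and both per-context trends
are significant at `alpha` after the selected multiple-testing treatment:
`"bh"` (Benjamini–Hochberg within each context, the default), `"none"`
(raw empirical p), or `"maxt"` (Westfall–Young max-T family-wise
correction, in which all genes share a single permutation stream and the
null distribution of the maximum standardized directional JT across genes
calibrates each gene's adjusted p; in this mode raw per-gene p-values are
computed from the shared stream as well). In the default modes each gene
draws its permutations from a child stream keyed by a hash of its gene id,
so per-gene results are reproducible regardless of gene order or subsetting.

### Operating characteristics and granularity

JT permutation p-values are discrete. With three replicates per cell the
within-context test has only 1680 distinguishable assignments; the largest
attainable tail probability not exceeding 0.05 is 0.0369, so at a nominal
0.05 the per-context test operates at an effective level near 0.038 —
valid but conservative. The combined transition test (18 samples, about
2.8 million stratified assignments) has a much finer null and attains a
level near 0.042–0.05. Users testing very small designs should prefer the
exact mode and read attained levels off `n_assignments`. Under the
package's default synthetic conditions (log2 noise sd 0.5, three
replicates per cell), the combined per-gene test detects a planted
consistent trend of 1.5 noise-sd per step with power above 0.95, while
the stricter joint flag (both contexts individually significant, same
direction) sits near 0.8; at 2 noise-sd per step the joint flag recovers
more than 80% of planted genes.

## Pooled small-RNA-seq comparison

Raw pooled counts are normalised with trimmed-mean-of-M-values (TMM)
scale factors, computed by the method's reference implementation (edgeR)
with its canonical defaults: reference sample chosen by upper-quartile
proximity to the mean, 30% two-tailed trim on M-values, 5% on A-values,
inverse-variance weighting, zero-count features excluded, factors rescaled
to geometric mean 1. Normalised values are counts per million of the
effective (factor-adjusted) library. One caveat worth knowing: because the
inverse-variance weights are functions of raw counts, a pure depth change
in one sample moves its factor slightly (about 1–2% in typical tables) —
depth invariance is close but not exact.

Group fold changes are `log2(mean_b / mean_a)`; with pooled libraries the
printed tables are often raw pool averages, so the worked examples use raw
mode (`use_normalized = FALSE`). A zero group mean is an error by default
rather than silently pseudocounted, since pool counts in scope are large
and pseudocounts would distort the worked examples. Per-feature tests are
the pooled-variance Student t (Welch behind a flag) and the one-way
fixed-effects F; both follow an explicit epsilon convention at zero
within-group variance (p = 1 when the means also coincide, p = 0
otherwise, the infinite-statistic limit). BH adjustment is `p.adjust`'s
step-up rule behind a validated wrapper. The stool-style abundance filter
retains a feature when its within-group median strictly exceeds 20 reads
in at least one group.

## Relative qPCR quantification

The 2^-ddCt method: replicates are averaged per (sample, assay); per
condition, dCt is the mean target Ct minus the reference aggregate, where
multiple reference assays are combined as the arithmetic mean of their
per-assay Ct means (equivalent to a geometric mean of the linear
quantities, the standard mean-expression-value normalisation); ddCt
subtracts the calibrator condition, and the fold change is 2^-ddCt, so
the calibrator is 1 by construction and any global Ct shift cancels.
Group comparisons are Student t-tests on per-sample dCt values — the
approximately normal scale — never on fold changes, which are log-normal.
Efficiency-corrected quantification and standard curves are out of scope.

## Random-effects meta-analysis

Per study, Hedges' g with the small-sample correction
\(J = 1 - 3/(4\,df - 1)\) and the standard large-sample variance; pooling
by DerSimonian–Laird moments (\(\tau^2 = \max(0, (Q - df)/C)\)) with a
symmetric normal-quantile 95% interval (1.96, not Knapp–Hartung, matching
the symmetric intervals such studies print). An unstandardized
mean-difference mode (`effect = "logfc"`) is available for log-scale
expression summaries. A known property, visible in this package's own
simulations and deliberately not papered over: with few studies (k = 5)
and moderate heterogeneity (I² near 0.7) the DL z-interval covers the true
effect in roughly 90% of repetitions, not 95%. Users needing calibrated
small-k intervals should use a Knapp–Hartung-type adjustment, which is out
of scope here precisely because the symmetric z-interval is what the
studies being emulated report.

## Weighted Kolmogorov–Smirnov enrichment

Screen hits are ranked by signed significance (`-log10` of the combined
empirical p, positive for promoted genes). Walking the ranking, the
running sum gains \(|s|^p / \sum_{set} |s|^p\) at set members and loses
\(1/(N - m)\) elsewhere; the enrichment score is the signed maximum
deviation. Exponent 1 is the method's standard weighting; exponent 0 gives
the classical Kolmogorov–Smirnov form, under which the running sum for a
set occupying the top half of a ten-gene ranking climbs to exactly 1
before returning to 0. If every set member scores zero the increments fall
back to the unweighted form rather than dividing by zero. The default
null permutes set membership over the ranked universe (with an exact
combinatorial mode for small universes); a design-aware sample-permutation
null is available through a ranking-generator callback that re-runs the
screen on permuted designs. Normalized enrichment scores and cross-set
FDR, as in full GSEA, are deliberately not provided — per-set ES and
empirical p are what this style of analysis reports.

## Synthetic data: what it emulates and what it does not

The generators produce every input type with known ground truth, under a
single run seed fanned out to child streams by a fixed affine map modulo a
prime below 2^31 (`seed + 97561 * stream`), so partial re-runs reproduce
bit-identically.

- **Pooled counts**: negative-binomial counts (Poisson at dispersion 0)
  around log-normal baseline abundances; defaults emulate a three-group
  serum-pool design sequenced in duplicate with library size 5e6 and
  dispersion 0.05, one planted miRNA falling to 0.64x and 0.55x of the
  healthy level in tumor and metastatic pools, and all other miRNAs flat.
- **Expression studies**: additive Gaussian noise on the log2 scale
  (microarray convention) around planted monotone treatment trends,
  default noise sd 0.5 log2 units, three replicates per
  context-treatment cell; inconsistent genes reverse direction in the
  second context; baselines are uniform on 4–12 log2 units.
- **Ct tables**: constant-reference, shifted-target design with known
  true fold change 2^(-shift); noiseless by default so round trips are
  exact.
- **Meta-analysis summaries**: per-study true effects
  `true_smd + N(0, tau2)`, arm means from their exact normal sampling
  distributions and arm sds from scaled chi-square, defaults five studies
  of 80–120 per arm around an SMD of 1.01 with tau2 = 0.05.

What passing tests on these generators shows is that the estimators
recover what was planted under their own model assumptions. What they do
not show: robustness to probe-level artifacts, batch effects,
normalisation failures, count outliers from degraded samples, or
correlated genes — real microarray and small-RNA-seq data violate the
independence and distributional assumptions here in ways the synthetic
module intentionally does not model.

## Numerical conventions collected

- Permutation p-values: add-one rule, never exactly 0; exact modes return
  the exact tail proportion (at least 1/#assignments).
- Ties in JT: one half per side; direction ties in classification break
  toward "promoted".
- Zero-variance test degeneracies: p = 1 for coincident means, p = 0
  otherwise (epsilon 1e-12).
- Exact-enumeration caps: 250,000 assignments (JT), 250,000 memberships
  (enrichment); beyond that Monte-Carlo is required.
- `n_perm` below 100 warns; below 1 errors.
- Flat genes are flagged degenerate and excluded from screening rather
  than given an arbitrary direction.

## Problem sizes used by the shipped checks

The packaged tests and the acceptance script size their simulations to
single-CPU friendliness while keeping Monte-Carlo error well inside the
asserted bands: 2000 null genes at 1000 permutations for the type-I check,
500 planted genes for power, 1000 repetitions for meta-analysis coverage
and enrichment calibration, and 10,000 permutations where agreement with
exact enumeration is asserted. These sizes are the package's own choice of
precision-versus-runtime balance.

## Known limitations

- The in-sample direction fit makes the default screen a discovery tool,
  not a confirmatory test; use fixed directions for confirmation.
- Per-context JT granularity at three replicates makes nominal levels
  conservative (see above).
- DL interval under-coverage at small k (see above).
- TMM depth invariance is approximate under the canonical weighting.
- The enrichment sample-permutation null is only as design-aware as the
  ranking generator supplied to it.
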