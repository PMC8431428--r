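---
title: "Classifying expression inheritance in hybrid-parent triads"
author: "triadex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying expression inheritance in hybrid-parent triads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triadex)
```

# The question and the model

An F1 hybrid and its two inbred parents (a *triad*: female parent F, male
parent M, hybrid H) are profiled by bulk RNA-seq with replicated libraries,
typically at more than one developmental time point. For each gene we ask
where the hybrid's expression sits relative to the parental range. Three
pairwise differential-expression tests — F vs M, F vs H, M vs H — each give
a three-valued relation (higher / lower / no difference), and the triple of
relations determines one of twelve classes:

| classes | category | meaning |
|---|---|---|
| 1–2 | additive | parents differ; hybrid significantly between them |
| 3–4 | ELD-F | parents differ; hybrid indistinguishable from the female parent |
| 5–6 | ELD-M | parents differ; hybrid indistinguishable from the male parent |
| 7–9 | down-overdominant | hybrid significantly below both parents |
| 10–12 | up-overdominant | hybrid significantly above both parents |

All three relations "no difference" is *conserved*; the remaining triples
(e.g. the hybrid equal to one parent but below the other while the parents
do not differ) are internally inconsistent at the chosen significance level
and are reported as *unclassified* rather than forced into a class. Within a
category, the numeric index encodes the parent sub-pattern; we place the
parents-equal sub-pattern first (classes 7 and 10), which is an internal
convention — any analysis conclusions should rest on categories, and the
package's own tests assert categories, not indices.

Two symmetries are built in and audited by tests: relabelling the parents
maps 1↔2, 3↔5, 4↔6, 8↔9, 11↔12 and fixes 7 and 10 (`swap_parents`), and the
rule table is total and exclusive over all 27 relation triples.

# The differential-expression engine

The engine is deliberately self-contained and fully specified, so the
classifier's behaviour is reproducible from this document alone.

**Normalisation.** Median-of-ratios size factors: for sample *s*,
`sf_s = median_g counts[g,s] / geomean_g`, over genes positive in every
sample. Size factors are defined up to a common scale; only their ratios
matter downstream.

**Dispersion.** Counts are modelled as negative binomial with
`Var = μ + αμ²`. The genewise estimator (`estimate_dispersion`) is method of
moments: the within-group variance of normalised counts, pooled across
replicate groups after centring each group, solved for α and floored at
1e-8. A *group* here is a genotype × time-point cell, and the estimator can
pool over all cells of a triad rather than only the two groups of one
comparison — dispersion is a property of the gene, so using all residual
degrees of freedom (12 in the default design, rather than 4) is strictly
better. Even so, a genewise moment estimate at 2–3 replicates is noisy
enough that plugging it straight into a Wald statistic both loses power
(when α is overestimated) and miscalibrates (when it hits the floor). The
pipeline therefore defaults to a *trended* dispersion
(`dispersion_trend`): a robust lowess fit of the genewise estimates against
the log mean, evaluated at each gene's mean. This is the standard remedy at
low replication in the established count-based engines. The cost is that a
dispersion-outlier gene (true α far above the trend) receives an optimistic
standard error; with ≥ 10 or so replicates, `dispersion_fit = "genewise"`
avoids that assumption.

**Wald test.** For a comparison named "A vs B", `log2fc = log2(m_B/m_A)` of
normalised group means, so for the parent-vs-hybrid comparisons "up" always
means higher in the hybrid. If either group mean is zero, 0.5 is added to
*both* means first — fold changes stay finite and genes observed in both
groups are untouched. The standard error comes from the delta method:
`Var(m) = (Σ_s μ/L_s + αμ²n)/n²` per group at the fitted means (L_s the
size factors), transformed to the log2 scale; the Wald statistic is
referred to the standard normal, and p-values are Benjamini–Hochberg
adjusted across all genes of the comparison (`adjust_bh`, the step-up
`min_{j≥i} p_(j)·m/j` formula). Genes with all-zero counts in both groups
are reported flat with p = 1.

**DEG rule.** `call_degs` uses adjusted p < 0.05 and |log2fc| ≥ 1. Both
thresholds are arguments everywhere they appear.

# Thresholds for the classifier: universe vs relations

The classifier makes a deliberate distinction between two uses of the DE
results:

* the **universe** — which genes are classified at all — is the set of
  DEGs (adjusted p < 0.05 *and* |log2fc| ≥ 1) in at least one of the three
  comparisons; everything else is reported conserved;
* the **relations** fed to the rule table default to significance only
  (adjusted p < 0.05, any fold change; `lfc_relation = 0`).

The reason is arithmetic, not convenience: an additive gene whose parents
differ by Δ log2 units has its hybrid at the arithmetic mid-parent, which
is only `log2(2 / (1 + 2^-Δ))` log2 units above the low parent and
`-log2((1 + 2^-Δ)/2)` below the high one — at Δ = 2, that is 1.32 and 0.68
respectively. A |log2fc| ≥ 1 gate
on the relations would therefore make strict intermediacy (classes 1–2)
*structurally undetectable* for any parental gap below about 2·τ, collapsing
additive genes into ELD regardless of replication. Significance-only
relations keep additivity detectable while the universe gate still controls
which genes enter the analysis. Users who want the fully gated behaviour can
set `lfc_relation = 1`.

# The simulator and what passing tests mean

`simulate_triad_counts` draws independent NB counts with
`μ[g,s] = μ_role(g)·L_s`, library factors log-uniform on [0.7, 1.4], and
plants each gene in one of six modes: conserved (μ_H = μ_F = μ_M), additive
(parents 2 log2 units apart, hybrid at the arithmetic mid-parent), ELD-F /
ELD-M (hybrid at one parent), and up-/down-overdominance (hybrid one effect
size above the higher / below the lower parent). Parent order within a mode
is uniform, including the parents-equal sub-pattern for the overdominant
modes (required for classes 7 and 10 to occur). Defaults — 2000 genes, 3
replicates, 2 time points, baseline 2^7 counts with 2 log2 units of
between-gene spread, dispersion 0.05, effect 2 log2 units, half the genes
conserved and the remainder spread evenly over the five non-conserved modes
— represent a typical replicated triad experiment at moderate sequencing
depth. One seed governs a bundle; identical configuration and seed give
byte-identical outputs, which the test suite checks at file level.

The truth table records the expected means and the class obtained by
applying the rule table to them, so planted classes are consistent with the
classifier by construction; what the tests actually measure is whether the
*statistical* pipeline recovers them from noisy counts. Under the default
conditions, ≥ 85% of planted non-conserved genes receive their planted
category, ≤ 10% (empirically < 1%) of conserved genes leak into the DEG
universe, and an all-conserved transcriptome yields an adjusted-rejection
fraction within the FDR bound.

The simulator deliberately omits several features of real data: genes are
independent (no co-expression), dispersion does not trend with the mean,
there are no gene-length or GC effects, no outlier samples, and planted
means are shared across time points. Passing tests therefore demonstrate
correctness of the statistical machinery under the stated model, not
robustness to, e.g., correlated genes or batch effects; the plug-in
interface (`nb_wald_test`'s `dispersion` and `size_factors` arguments, and
the acceptance of externally computed DE tables by `classify_triad`) is the
escape hatch for data that violate the model.

# Phenotypic heterosis

For each trait and time point, `MPH = (F1 − MP)/MP × 100` and
`HPH = (F1 − HP)/HP × 100`, with MP the parental average and HP the larger
parent mean; HPH ≤ MPH whenever the parents differ. Both indices are
undefined when the corresponding parental value is zero and are then
reported missing rather than infinite. The test of heterosis pairs parent
replicates by index into pseudo-mid-parent values `MP_i = (F_i + M_i)/2`
and runs a Welch two-sample t-test of the hybrid replicates against them:
this propagates parental variability into the test rather than treating the
mid-parent as a known constant (the `one-sample` alternative is provided
for comparison with analyses that do). With zero variance on both sides the
test degenerates and is flagged, returning p = 1 for equal means and p = 0
otherwise.

Group comparisons across genotypes use one-way ANOVA with Tukey's HSD at
5%, summarised as a compact-letter display (groups sharing a letter are not
significantly different). The display is built by a greedy insert-and-absorb
pass over the non-different pairs in decreasing-mean order with ties broken
by input order, which is deterministic; on null simulations the family-wise
error of the whole procedure stays at the nominal level (tested at 1000
replicates, 5 groups).

# Enrichment and qPCR validation

Over-representation of a gene set (typically the up- or down-overdominant
class) against an annotation map uses the upper-tail hypergeometric
probability `P(X ≥ k)` with BH adjustment across terms and the rich factor
k/K. The background defaults to all genes of the count matrix, not the DEG
universe — a DEG-conditioned background asks a different question (is the
term over-represented among DEGs *given* differential expression) and is
easy to construct by passing the universe explicitly. Terms with fewer than
`min_term = 2` background genes are skipped as degenerate.

qPCR validation follows the 2^−ΔΔCT method: per-sample ΔCT against the
reference gene, replicate aggregation at the ΔCT level (the standard
choice; aggregating raw CTs first differs only when replicate reference CTs
vary), calibration against a designated genotype, so the calibrator is
exactly 1. The calibrator is a required argument — there is no sensible
default, and making it implicit invites silent mistakes. Concordance with
RNA-seq is reported as the fraction of within-gene genotype contrasts with
agreeing direction plus a Spearman correlation over the shared points; both
platforms must be expressed relative to the same calibrator for the
correlation to be meaningful across genes.

# Numerical choices and edge cases

* Dispersion floor 1e-8 (rather than 0) keeps the NB variance formula valid
  and the Poisson limit numerically stable.
* The conditional pseudo-count (0.5 added only when a group mean is zero)
  trades a small bias in zero-involved fold changes for finiteness; fully
  observed genes are never touched.
* BH is applied per comparison (each pairwise test is its own family),
  matching how per-comparison DEG counts are reported in this literature.
* Time points are analysed independently throughout; no information is
  shared across them except (optionally) the dispersion pooling described
  above.
* `classify_triad` requires the three DE tables to cover identical genes in
  identical order and refuses otherwise, rather than joining silently.
* All result files are plain TSV with fixed column orders, and the manifest
  contains no timestamps, so a fixed input bundle reproduces byte-identical
  output.

# Problem sizes used by the test suite

The suite exercises the pipeline at 150–2000 genes, 3 replicates, 2 time
points, with Monte-Carlo checks at 10^4+ draws and 1000-replicate null
simulations for the FWER and BH properties; these sizes give stable
stochastic margins for every property tested while keeping a full run in
well under a minute of CPU.
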