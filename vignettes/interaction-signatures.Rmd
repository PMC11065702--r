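---
title: "Interaction signatures: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interaction signatures: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stimsig)
```

This vignette is the package's own account of the statistics it
implements: the models and their assumptions, the tunable parameters and
why their defaults are what they are, what the synthetic-data generator
does and does not emulate, and the numerical and design choices that were
genuinely open.

## The model

All modeling happens on log2 counts per million,
`log2((count + 0.5) / (lib * factor + 1) * 1e6)`, with TMM normalization
factors and the low-expression filter (mean log2-CPM below zero) applied
first. The half-count and one-read offsets keep zeros finite and are the
convention under which the precision weights below are derived; scale
invariance holds up to those offsets.

For each gene `fit_expression()` fits a weighted linear model. In the
stimulation × mutant design the fixed effects are a condition factor
(unstimulated baseline), a genotype factor (wild type baseline) and their
interaction, so the three coefficient families read directly as: the
wild-type stimulation response, the mutant effect in unstimulated cells,
and the change of the stimulation response caused by the mutant. The
experiment identifier can enter as fixed dummy columns or as a
one-variance-component random intercept.

Observation weights follow the voom recipe: per-gene unweighted least
squares, a lowess trend of the square-root residual standard deviation
against mean log2-count (span 0.5), and weights equal to the trend
prediction at each fitted value raised to the power −4. Fitted square-root
standard deviations are clamped below at 1e−3: on small simulated data the
lowess trend can touch zero, and the clamp bounds the weights without
affecting realistic inputs. The weights reproduce `limma::voom` to
machine precision on the same inputs (checked in the test suite), but the
hypothesis tests here are plain weighted least squares with t-tests on the
residual degrees of freedom — deliberately no empirical-Bayes moderation
of variances, which is out of scope for this engine.

The random-intercept fit maximizes the profile likelihood over the
batch-to-residual variance ratio. Because batches partition samples, the
covariance inverse and log-determinant have closed Woodbury/determinant-
lemma forms, so each evaluation is linear in the sample count; the
one-dimensional search uses Brent's method (golden-section bracketing with
parabolic steps) at tolerance 1e−8 on the interval [0, 1e4], with the
boundary value at zero checked explicitly. Estimates match `lme4::lmer`
with `REML = FALSE`. Wald t-tests use the residual degrees of freedom of
the fixed part; Satterthwaite-type corrections are noted as out of scope,
so mixed-model p-values at very small batch counts should be read as
approximate. Standard errors scale the generalized residual sum of
squares by `n − p` rather than the ML `n`, which makes the fit collapse
exactly onto the fixed-mode answer when the batch variance is zero. If
the batch factor is confounded with the design, the fit falls back to
fixed mode without the batch term and warns.

P-values are BH-adjusted across genes separately within each coefficient.
The alternative — pooling all coefficient families into one adjustment —
is defensible, but per-coefficient adjustment is the convention of the
limma/dream reporting functions this engine mirrors, and keeps the
significance of one coefficient family from being driven by signal in
another.

## The five-signature classifier

Genes with interaction `padj < alpha` (default 0.05) are grouped by
dominance at ratio 2 ("twofold greater" in absolute log2FC, strict
inequality so exact equality falls to the not-greater branch, which makes
boundary behaviour deterministic). Interaction dominating both mains is
`de_novo`; neither, `minor`; dominating only the mutant effect sends the
gene to the mutant-modifies-stimulation pair (2/3 by sign agreement with
the stimulation effect); dominating only the stimulation effect to the
stimulation-modifies-mutant pair (4/5 by sign agreement with the mutant
effect). A zero main effect can never tie — any nonzero interaction
strictly dominates it — so the sign branches never see `sign(0)`; a zero
interaction with significant p (pathological) lands in `minor`.
Prevalence fractions are computed over all interaction-significant genes,
`minor` included, and reversion shares divide the group-3 (or group-5)
count by the genes with a significant stimulation (or mutant) main
effect, using adjusted p-values at the same alpha.

## Sample QC

Stage one applies hard metric thresholds (strict "below" fails): for RNA,
1e6 reads, 0.5 alignment rate, 0.3 exome rate; for ATAC-style region
counts, 5e6 reads, 1e3 peaks, 0.5 alignment rate, 0.025 FRiP. Stage two
computes each sample's mean Spearman correlation with its replicates on
the filtered log2-CPM matrix (the feature set used downstream; the choice
of feature space was open and this matches the analysis matrix). The
cutoff is the mean cross-pair correlation between two clearly distinct
reference cell types, or the fixed value 0.5 for cultured samples, where
culture effects make the derived cutoff unusable. Samples below the
cutoff are excluded, except: groups of three or fewer are kept whole, and
when fewer than three samples of a larger group survive, the three with
the highest mean pairwise correlation are kept instead (exhaustive over
triples; ties broken by lexicographic sample id for determinism).
Singleton groups pass with a warning — there is nothing to correlate
against. A useful property of the rescue rule, visible in the tests: when
one corrupted sample drags its replicates' mean correlations below the
cutoff, the best triple is still the three clean samples, so the rule
recovers exactly the right set.

## Gene modules and similarity maps

Strongly differential genes (`padj < 0.05` and `|log2FC| > 2` in at least
one coefficient) form a genes × coefficients log2FC matrix; entries a
gene was not tested in are imputed as zero (absence of evidence of
effect, and it keeps the matrix complete). The kNN graph (Euclidean,
k = 15 — the default neighbourhood size of the UMAP stack whose "default
parameters" the analysis mirrors; configurable) connects mutual or
one-sided nearest neighbours, with distance ties broken by row order.
Communities come from walktrap (t = 4 steps, the named function's
default), cut at maximum modularity; isolated vertices become singletons.
Any 2-D layout is cosmetic: clustering is a deterministic function of the
graph and t alone, which the tests assert. Contrast similarity maps use
classical (Torgerson) MDS on one minus the Spearman correlation of log2FC
vectors; the embedding is defined up to rotation and reflection, so tests
compare distance matrices, not coordinates.

## Enrichment statistics

Genes are ranked by `-log10(p) · sign(log2FC)` (zero p clamped to the
smallest positive double; ties broken by |log2FC|, then gene id). Fisher
tests are two-sided exact tests summing hypergeometric probabilities no
larger than the observed table's; the reported odds ratio is the sample
estimate `ad/bc`, not the conditional MLE. The preranked running-sum
score adds `|stat|^exponent` (normalized) at hits and subtracts
`1/(N − m)` at misses; its null permutes gene labels — with only ranked
statistics available there is nothing else to permute — and p-values use
the matching-sign tail with a +1 pseudo-count, so they can never be zero.
The normalized score divides by the mean magnitude of same-sign null
scores. CERNO is the closed-form Fisher combination of ranks against
chi-squared with 2m degrees of freedom. The sampling overlap test draws
the null overlap of query-sized uniform sets directly from its
hypergeometric distribution; NES is defined as observed over mean null
overlap — the minimal definition consistent with a "normalized enrichment
score", stated here as this package's convention — and the two-sided p
doubles the smaller tail (+1 pseudo-count, capped at 1). Because the
overlap is integer-valued, this p is discrete: with small sets (say a
universe of a few thousand and sets of a few hundred) it takes few enough
values that a KS test correctly rejects exact uniformity for any
implementation. Calibration is therefore assessed at transcriptome-like
sizes (universe 20000, query 1000, reference 4000), where the support is
rich and the p-values are uniform to KS tolerance.

## The synthetic-data generator

The generator emulates the structure the analysis assumes: genotypes ×
cell types × conditions × replicates, batches assigned round-robin over
replicates, log-normal library sizes, negative-binomial counts with
`variance = mu + phi·mu^2` and gene-wise log-normal `phi` (median 0.1 by
default — a typical bulk RNA-seq biological dispersion), baseline log2
means N(5, 2), and per-gene cell-type offsets (SD 2 log2 units beyond the
first cell type: distinct lineages share housekeeping structure but
diverge strongly in lineage-specific genes, giving cross-cell-type
Spearman correlations well below replicate correlations, as the QC cutoff
construction requires).

Planted genes receive a coefficient triple from their archetype. The
interaction magnitude is uniform on [1, 3] log2 units. Main effects are
canonical: a main effect that must not be dominated has magnitude
uniform on [1, 1.5] times the interaction — the natural reading of the
groups, e.g. full reversion means the interaction cancels a comparable
stimulation response — and a dominated main effect is uniform on
[0, 0.2]; de-novo genes have exactly zero mains. Dominance margins
therefore scale with the interaction and are at least 0.5 log2 units
everywhere (the configurable floor is 0.1), chosen up front so that
labels are identifiable relative to the coefficient standard error
(~0.46 log2 at 4 replicates and phi = 0.1); with margins near the floor,
label recovery would be a coin flip at the dominance boundaries for any
classifier. The wild-type stimulation response is shared across mutant
genotypes — it is the same wild-type cells — so one triple per gene
applies to every mutant, keeping the generating model self-consistent.
Batch offsets shared across genes are pure depth shifts and vanish under
CPM normalization; per-gene batch structure, the kind a random intercept
absorbs, is the `batch_gene_sd` switch.

What the generator does not emulate: transcript-length effects, GC and
mapping biases, count correlations between genes, outlier dispersion
genes, and mean-dependent dispersion trends. Passing recovery tests on
this generator therefore shows the machinery is correct and calibrated
under its stated model, not that real data meet that model.

## Problem sizes used by the tests and acceptance script

Calibration uses 2000 null genes in a two-genotype, three-replicate
design. Effect recovery uses 300 genes with 100 planted main effects
(|β| in [1, 3], 4 replicates, phi = 0.1) over 50 seeds (20 in the
acceptance script), giving mean absolute error ~0.20 log2 and 95% CI
coverage ~0.95. Signature-label recovery uses the study-style stimulation
layout — wild type plus eight mutants, two conditions, four replicates,
600 genes with 8% planted per archetype — where detection power at
interaction magnitudes near 1 is the binding constraint; measured
recovery is ~0.83 of planted genes, and conditional on the interaction
being detected, ~0.98. With a single mutant (16 samples) unconditional
recovery drops to ~0.79, a power ceiling of the design, not a classifier
property. Module recovery uses three archetypes of 100 genes with
centroid separation at least five within-archetype standard deviations
(adjusted Rand ~0.98). QC uses 2000 genes, two cell types, four
replicates and one injected shuffled sample per group (sensitivity 1.0,
false exclusions 0 across seeds).

## Known limitations

Mixed-model degrees of freedom are approximate (no Satterthwaite); no
empirical-Bayes variance moderation; enrichment gene sets must be
supplied as files (no database retrieval); region-count (ATAC-style)
matrices run through the same engine with region ids in place of gene
ids, with no region-specific modeling; and the 2-D embeddings are for
display only.
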