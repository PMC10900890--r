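---
title: "Methods: phenotyping, quantifying and mapping cobamide producers"
author: "cobatlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phenotyping, quantifying and mapping cobamide producers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cobatlas)
```

## The model

Cobamides (the vitamin B12 cofactor family) are synthesized de novo through
more than 30 enzymatic steps. The pathway splits into an aerobic and an
anaerobic corrin-ring branch — differing in oxygen requirement and the
timing of cobalt insertion — followed by a shared nucleotide-loop assembly.
Some ring enzymes are orthologous between the branches and are detected by a
single profile HMM; the catalog stores those once, under `ring_shared`, and
expands them into *both* branches at scoring time.

A genome's capability is scored from its gene-presence profile, obtained by
filtering profile-HMM hits at E ≤ 1e-6 (the cutoff is inclusive: "cutoff set
at" is read as retaining the boundary, and it is a parameter). For a profile
with ring fractions $f_a, f_n$ and loop fraction $f_l$:

$$ f = \frac{\max(f_a, f_n)\,n_{ring} + f_l\,n_{loop}}{n_{ring} + n_{loop}} $$

where the weights are the family counts of the winning branch (including
shared families) and the loop section. Ties between branches break to
aerobic — a stable, documented choice that only matters when the two
fractions are exactly equal, in which case the weighted score is identical
either way.

### Phenotype criteria are a reconstruction

The four categories (very-likely / likely / possible / non-producer) are
assigned by thresholds on $f$. Published criteria for such categories are
rarely stated in full, so the shipped defaults
— 0.8 / 0.6 / 0.4 — are an explicit reconstruction, stored in an editable
YAML file (`inst/extdata/criteria_default.yaml`) and carried as a
`PhenotypeCriteria` object. Everything downstream depends only on the
category labels, so replacing the criteria file reproduces any variant of
the scheme. An optional `requireLoop` switch additionally demands at least
one nucleotide-loop family for any producer call, for users who want a
marker-gene-style constraint; it defaults to off because the weighted score
already penalizes a missing loop section.

The 13 cobamide-dependent enzyme families (methionine synthase MetH, class
II ribonucleotide reductase, methylmalonyl-CoA mutase, and so on) that
define a *user*, and the 40 universal single-copy families used for read
recruitment, are likewise shipped as editable catalog data. The
biosynthesis and user memberships are curated stand-ins at the level of
family identity; the counts (13 and 40) and the structure of the vocabulary
are fixed by the analysis design.

## Quality filtering

MAG quality is `completeness − 5 × contamination`, and the filter keeps
scores *strictly* above 50 ("higher than 50"). Completeness is validated to
[0, 100] %, contamination to ≥ 0 %.

## Marker database and abundance

Coverage of a single-copy family is the fraction of producer genomes with at
least one hit; the top 15 families by coverage (ties broken
lexicographically for determinism) form the database, keeping the
best-bit-score sequence per (genome, family) with ties broken to the
smallest protein id. Either "best sequence per MAG" or "best per
(MAG, family)" is a defensible convention; the package uses per-(MAG, family) so each
genome contributes a full marker panel for read recruitment — the
alternative would leave one sequence per genome and make length
normalization family-confounded.

Protein inputs are length-normalized to base pairs (aa × 3) so RPKM is on a
common scale:

$$ \mathrm{RPKM} = \frac{\text{reads}}{\text{length}/10^3 \cdot \text{mapped}/10^6} $$

Genome abundance is the **mean** RPKM over the genome's markers (default),
not the sum: a genome missing some of the 15 families is then not penalized
linearly for database incompleteness. `method = "sum"` implements the strict
additive reading; both are exposed because either aggregation is defensible
before taxon profiling. Sample producer abundance sums over
genomes and is reported raw and log2-transformed with a data-driven
pseudocount — half the smallest nonzero value — which is scale-free and
avoids −∞ without dominating small abundances.

## Statistics

* **Rarefaction** subsamples each sample without replacement to the minimum
  row sum (vegan's `rrarefy` behind the module surface), with the seed
  recorded in the output attributes. Shannon uses the natural log.
* **Mantel tests** correlate lower triangles (Pearson) and permute one
  matrix's row/column order jointly. The p-value is one-sided upper with
  add-one smoothing, $p = (1 + \#\{r_{perm} \ge r_{obs}\})/(B + 1)$,
  B = 999 by default; an exact mode enumerates all $n!$ permutations for
  small n. One-sided upper is the standard choice for the positive
  association claims the test supports here.
* **Rank-sum tests** are exact by enumeration of all group assignments when
  $n_A + n_B \le 12$ — including ties, via average ranks and
  $p = 2\min(P(W \le w), P(W \ge w))$ capped at 1 — and use the
  tie-corrected normal approximation (no continuity correction) otherwise.
  Base R's `wilcox.test` declines exact computation under ties; it serves as
  the independent cross-check for the tie-free and large-sample regimes.
* **Volcano analysis** compares pathway discovery rates between producer and
  nonproducer MAGs with the Haldane correction $(k + 0.5)/(n + 1)$, so the
  log2 fold change is defined when a rate is zero — a choice this package
  makes explicitly. p-values are BH-adjusted (`p.adjust`); following
  the standard contrast, nonproducer MAGs that are also nonusers should be
  excluded by the caller before the contrast.
* **Outliers** use Tukey fences from the five-number summary — matching
  `boxplot.stats` hinges rather than interpolated quantiles — and are
  applied exactly once; re-application could flag more points and is
  deliberately absent from every code path.

## Spatial prediction

Surface samples are kept (marine ≤ 100 m, soil ≤ 30 cm; missing depth is
treated as surface). Tuning evaluates every combination of variable-subset
size, `ntree` and `mtry` by 10-fold cross-validated RMSE with fold
assignment fixed by the seed. Within each training fold, recursive feature
elimination drops the variable with the lowest permutation importance
(`%IncMSE`), re-ranking after each elimination; a fixed reference forest
configuration does the ranking so the elimination path is computed once per
fold rather than once per grid point. Ties in RMSE break to fewer
variables, then fewer trees, then smaller `mtry` — preferring the smaller
model. Default grids (ntree {250, 500, 1000}, mtry {p/3, √p, p/2}, sizes
{3, 5, 8, p}) are pragmatic defaults intended to be overridden per habitat.
The response defaults to log2 with the data-driven pseudocount for
consistency with the regression analyses; the transform is configurable.

Prediction covers every grid cell with complete covariates at 0.2°
(configurable); cells with any missing covariate stay `NA` and are never
imputed. Uncertainty is the standard deviation of per-tree predictions
(coefficient of variation also emitted). Latitudinal profiles average cells
in 1° bands.

## The synthetic-data generator

Every generator is a pure function of a `SyntheticDesign` and its mandatory
seed; truth tables accompany every fixture and are read only in assertions.

* **Genomes**: the designed phenotype fixes a completeness band kept 0.03
  clear of the criteria thresholds, so integer family counts cannot straddle
  a boundary; present families are drawn uniformly from the chosen branch
  (plus shared) and loop. Because shared families count toward both
  branches, the weighted completeness of such a draw is exactly k/N
  regardless of how the draw splits between ring and loop. Hit multiplicity
  is `1 + Poisson(1.74)` — mean 2.74 hits per detected gene, the
  multiplicity observed in real MAG annotation. Decoy hits are drawn
  log-uniform in (1e-6, 1e-2] to exercise the cutoff boundary.
* **Marker counts**: reads per (genome, marker) are Poisson with mean
  proportional to mixture proportion × marker length, normalized to the
  sample depth — an idealized quantifier with no mapping ambiguity.
* **Communities**: log-normal taxon abundances with multinomial sampling;
  **pathway matrices**: Bernoulli presence with planted producer/nonproducer
  rate gaps; **covariates**: deterministic smooth fields over (lat, lon)
  (temperature-, radiation- and pH-like), two pure-noise variables to
  exercise feature elimination, and a Gaussian latitudinal response peak of
  bandwidth 10° at the designed latitude.

What passing tests therefore show: the pipeline's bookkeeping, estimators
and tests are correct *under their own assumptions* — presence-based
classification with calibrated hit multiplicity, unambiguous read
assignment, exchangeable nulls, smooth covariate response surfaces. What
they do not show: robustness to annotation error, incomplete assembly,
read-mapping ambiguity between near-identical markers (the package does not
deduplicate near-identical sequences), phylogenetic
correlation, or covariate collinearity structure in real environmental
layers.

## Problem sizes and numerical choices

The shipped test suite runs on deliberately small instances: ≤ 50 genomes,
≤ 30 samples, rasters at 2–10°, forests of 100–250 trees, 500–2000 null
replicates with 499–999 permutations — sizes at which every stochastic
check has stable Monte Carlo error while the whole suite completes in about
a minute. Exact enumeration oracles cap at 8 items (permutations) and 12
observations (rank sums). Distance matrices are asserted symmetric with
zero diagonals on every output; relative-abundance rows must sum to 1
within 1e-9; floating-point boundary comparisons in permutation counts use
a 1e-12 slack so that `r_perm = r_obs` counts as an exceedance.

## Known limitations

The phenotype criteria, the exact memberships of the 13 user families and
the biosynthesis catalog, the environmental covariate sets, and the tuned
hyperparameter values are reconstructions or stand-ins, clearly marked and
configurable. Salvage-pathway phenotyping, lower-ligand prediction,
dereplication, read mapping, NMDS/PERMANOVA ordination and cartography are
out of scope; external tools' outputs are consumed as files.
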