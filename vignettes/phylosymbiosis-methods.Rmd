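---
title: "Quantifying phylosymbiosis in coupled microbiome–metabolome surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying phylosymbiosis in coupled microbiome-metabolome surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylosym)
```

## The question

Gut microbial communities differ sharply between host species. Whether those
taxonomic differences matter functionally is contested: under *functional
redundancy*, taxonomically distinct communities would still produce similar
gene repertoires and metabolite pools; under *functional diversity*, the
chemistry should track the taxonomy. A second, related question is
*phylosymbiosis*: whether the dissimilarity structure of host-associated
profiles — microbial or chemical — recapitulates the host phylogeny.

`phylosym` packages the statistical chain needed to answer both questions
from sample-by-feature abundance tables (16S amplicon counts, untargeted
LC-type and GC-type metabolomics peak areas, predicted function profiles,
targeted SCFA panels), per-sample host metadata, and a host phylogeny. It
also ships a generative simulator with controllable phylosymbiotic signal,
used throughout the test suite for calibration and power checks.

## Statistical procedures

### Dissimilarity and ordination

Bray–Curtis dissimilarity \(d(x,y)=\sum_i |x_i-y_i| / \sum_i (x_i+y_i)\) is
the working currency; Jaccard on presence/absence is available behind the
same interface as a robustness metric. A pair of all-zero samples gets
distance 0 (with a warning) rather than NaN so matrices stay valid.

Principal coordinates analysis Gower-centers \(-D^2/2\) with the centering
projector \(J = I - \mathbf{1}\mathbf{1}^\top/n\) and eigendecomposes the
result. Coordinates are returned for eigenvalues above `1e-10`; negative
eigenvalues — expected for Bray–Curtis — are *reported, not corrected*,
because downstream tests handle them explicitly. A Lingoes correction is
available as a switch for users who need a fully Euclidean embedding. Axes
are oriented so the largest-magnitude coordinate on each axis is positive,
making runs comparable.

### Sequential PERMANOVA

The total sum of squares of a dissimilarity matrix is
\(SS_T=\sum_{i<j} d_{ij}^2/n = \mathrm{tr}(G)\) with \(G = J(-D^2/2)J\).
Terms enter in the stated order (Type I): term \(k\)'s SS is
\(\mathrm{tr}(H_k G)\) where \(H_k\) projects onto the directions the term's
design columns add beyond the preceding model, and its df is the rank added.
The rank and the orthonormal increment are taken from an SVD of the
residualized design columns (singular values above `1e-8` relative to the
largest), which is robust where pivoted-QR diagonals are not; aliased terms
get df 0 and an undefined F. Significance permutes sample identities (rows
and columns of \(D\) jointly, free exchangeability — the simplest scheme for
unrestricted designs) with every term recomputed;
\(p = (1+\#\{F^* \ge F\})/(1+n_{perm})\), so \(p \ge 1/(n_{perm}+1)\) and is
never zero. On a Euclidean distance matrix of univariate data the pseudo-F
equals the classical one-way ANOVA F to `1e-9`, which the test suite asserts
along with SS/df additivity on every constructed table.

Ordering matters for interpretation: with host traits entered as diet, gut
morphology, mammalian order, then host species, the species term reports
only the between-species variation *not* explained by the coarser factors —
on the bundled 25-species/101-sample preset its df is 18 and the residual df
75, determined entirely by the design.

### Dispersion homogeneity

PERMANOVA compares centroids under an assumption of comparable group
dispersions, so a PERMDISP-style diagnostic is included: the matrix is
embedded by principal coordinates *retaining* negative axes, each sample's
distance to its group centroid is
\(\sqrt{\max(0,\; d_{real}^2 - d_{imag}^2)}\), and group equality of those
distances is tested with a one-way F. The permutation null relabels samples
and **recomputes centroids and distances** for every permutation. Permuting
the fixed distances (as some implementations do) is anticonservative,
because distances within a group share an estimated centroid; recomputation
keeps the test calibrated under exchangeability, which the acceptance suite
verifies empirically. Group centroids (not spatial medians) are used for
closed-form testability. Size-1 groups are excluded with a warning.

### Mantel tests

The Mantel statistic is the Pearson (default) or Spearman correlation of the
strictly-lower-triangle vectors of two matrices over the same samples,
aligned by id. The null permutes one matrix's sample labels; p is one-sided
upper. For Spearman, triangles are rank-transformed once up front — a label
permutation only rearranges the pair values, so every permuted statistic is
a Pearson correlation of fixed ranks.

### Tree congruence

Sample or species profiles are clustered with Ward's method via
`stats::hclust`; `ward.D2` is the default (its objective is well defined on
dissimilarities treated as squared-Euclidean surrogates) and `ward.D` is a
switch, since legacy "Ward" analyses are ambiguous between the two. Species
are represented by per-feature medians before clustering.

Baker's Gamma is defined here as the Spearman rank correlation (average
ranks for ties) between the two trees' pair statistics, where a pair's
statistic is the number of leaves in the smallest cluster (or clade)
containing both. This convention depends only on topology, so the index is
invariant to monotone transformations of merge heights. The cophenetic
Pearson correlation is computed alongside; when one side is a phylogeny its
patristic matrix plays the cophenetic role. Significance comes from
shuffling one tree's leaf labels (`n = 999` by default) with a one-sided
upper p — phylosymbiosis predicts positive congruence, so the lower tail is
not of interest. Both indices are always reported because "tree correlation"
in the literature can mean either.

### Differential features

The discovery chain runs strictly in order: (1) PCA (feature-centered, no
unit-variance scaling, SVD) on the logged table; (2) candidates = features
in the top or bottom `percentile` of loadings, *per component
independently* for PC1 and PC2 (pooling tails across components would let a
high-variance component crowd out the other); (3) IndVal on the candidates
only, per factor: specificity \(A = m_{gf}/\sum_h m_{hf}\) with
group-equalized means (the `indval.g` correction, default, so unbalanced
groups do not dominate), fidelity \(B\) = detection fraction within the
group, statistic \(\sqrt{AB}\) maximized over groups, p by permuting group
labels; (4) Bonferroni with `m` = the number of candidates tested per
factor — correcting over the candidate list, not the full feature table,
matches the procedure's logic of shortlisting first. A manual exclusion
list (e.g. suspected storage-buffer artifacts) can be applied before
reporting.

One numerical interaction deserves emphasis: the smallest attainable
adjusted p is \(m/(n_{perm}+1)\). With hundreds of candidates,
`n_perm = 999` can make significance *unreachable*; the permutation count
must outrun the candidate count divided by \(\alpha\). This is why
indicator-species analyses are conventionally run with very large
permutation counts, and why `n_perm` is a first-class argument everywhere.

## The synthetic study generator

The generator is first-class, tested code. Its defaults emulate a zoo-scale
mammalian survey:

* **Design preset**: 25 species, 101 samples with uneven per-species counts
  (1 to 16), five mammalian orders, three diet groups, three gut
  morphologies, and two documented diet-within-order divergences
  (omnivorous vs carnivorous Carnivora; herbivorous gorilla among
  omnivorous primates). The accompanying stand-in phylogeny is ultrametric
  with depth 100 (arbitrary time units) and honors the ordinal groupings;
  real divergence dates are deliberately not reproduced. Collection times
  are seeded uniform draws on [0, 14] hours, independent of all signals,
  reflecting that this covariate should explain essentially nothing.
* **Microbiome**: per feature, a root log-abundance \(\sim N(0,1)\) evolves
  along the tree by Brownian motion with variance `sigma2_phy` per unit
  branch length (default 0.05); samples add \(N(0,\texttt{sigma2\_ind})\)
  noise (default 0.5); per sample, values below the
  `1 - microbe_detect_fraction` quantile (default keeps 25%) are zeroed;
  survivors are softmaxed and counts drawn multinomially at
  `seq_depth = 21000`. Brownian motion + softmax + multinomial is the
  simplest process producing phylosymbiosis, compositionality, and count
  noise at once; quantile thresholding is a rank-preserving stand-in for
  zero inflation without a separate occupancy layer. With 1000 features and
  25% detection, a few hundred features are detected per sample at
  realistic depth.
* **LC-type metabolome** (default 10,029 features, 11.5% detected per
  sample): features are partitioned into roles — microbiome-driven (sparse
  non-negative mixing of microbial log-abundances, density
  `mixing_density = 0.05`), phylogeny-driven (their own Brownian traits),
  diet-driven (a planted shift inside one diet group), background (constant,
  also emitted in three blank samples for the background filter), and pure
  noise — plus an always-present internal standard whose value carries a
  per-sample instrument drift that multiplies all features, making
  internal-standard normalization meaningful.
* **GC-type metabolome** (default 347 features, ~131 detected per sample): a
  large shared core present in most samples with log-normal abundance
  variation, a few planted group-enriched fermentation-product analogues
  (default: 6 features up in omnivores, log-effect 3), sporadic noise
  features, a ribitol-like internal standard, and per-feature balance scores
  (high for core/enriched, lower for noise) so the 50% balance filter has
  something to do.
* **Function profiles**: each microbial feature contributes its relative
  abundance to `function_fan_in` functions (default 20) from a pool of
  `n_functions` (default 200). The many-to-one map collapses taxonomic
  turnover: fan-in equal to the pool size gives identical profiles
  (complete redundancy), fan-in 1 with a large pool is a pure relabeling,
  and intermediate values reproduce the observed pattern in which function
  profiles are far more similar between samples than the communities that
  generate them.
* **SCFA panel**: per-sample acetate/propionate/butyrate concentrations
  drawn around per-diet-group molar ratios (defaults 75:15:10 herbivore,
  60:25:15 carnivore, 73:7:21 omnivore — the last planting the distinctive
  low-propionate omnivorous-Carnivora profile) with log-normal scatter.

Every generator draw descends from one config seed via the documented
splitting rule `sub-seed = (seed + 104729 · stage) mod (2^31 − 1)`; no stage
reads ambient randomness, and identical configs yield byte-identical
outputs.

**What the generator does not emulate**: mass spectra, retention times,
ionization efficiency, compositional artifacts of relative quantification,
taxon-specific detection bias, overdispersed (beyond-multinomial) count
noise, and ecological interactions between taxa. Passing tests therefore
demonstrate that the *statistical machinery* behaves as specified under a
known generative model — calibrated nulls, monotone power in the planted
signal, exact design-driven degrees of freedom — not that any particular
biological dataset will show these effects.

## Numerical choices

* `log(1 + x)` rather than `log x` after the noise floor, so zeros survive
  the transform; applying the transform twice is refused rather than
  silently compounded.
* The noise floor (default 0.01 normalized abundance) is applied to the
  GC-type layer; for the LC-type layer the default is 0 (normalize and log
  only), with the floor available where a pipeline wants it.
* The background-removal rule — drop a feature when its background mean is
  at least `background_rule_ratio` (default 0.5) times its study mean — is
  this package's own operationalization of "remove background signals";
  both rule and ratio are exposed, and a keep-dietary switch flags rather
  than removes shared food/fecal features, appropriate for polar panels
  whose dietary nutrients are absorbed upstream of the colon.
* Group SCFA summaries use the ratio of group means (stable when individual
  samples have small totals); the mean of per-sample ratios is reported
  alongside.
* PCA runs on all samples rather than species medians — the per-sample
  structure is what the candidate extraction should see; medians are used
  only for species-level tree building.
* Permutation p-values everywhere include the observed statistic:
  \(p=(1+b)/(1+m)\).
* Exact rarefaction uses `lchoose` differences, numerically safe for depths
  in the tens of thousands.
* PERMANOVA rank detection: SVD with a `1e-8` relative threshold (see
  above). PCoA positive-eigenvalue threshold `1e-10`; distance-matrix
  symmetry tolerance `1e-12`.

## Problem sizes used by the test suite

Calibration checks run 1000 replicates per test at 199 permutations each
(24 samples in 3 groups for PERMANOVA/PERMDISP/IndVal, 15 samples for
Mantel, 10-leaf trees for congruence); recovery checks run 50 replicates of
a 15-species × 3-sample study for phylosymbiosis (variance ratio
`sigma2_phy/sigma2_ind = 1000` in the strong arm, 0 in the null arm) and 20
replicates of the preset design with 20 planted features among 1000 for the
differential chain. These sizes were chosen to give binomial standard errors
comfortably inside the asserted bands while keeping the default test run
quick on a laptop.

## Known limitations

* No UniFrac-type phylogenetic beta diversity (the artifact does not model
  an ASV-level phylogeny).
* No restricted or blocked permutation strata; exchangeability is assumed
  free.
* Ward tie-breaking follows `stats::hclust`'s deterministic behavior rather
  than an explicit lexicographic rule; ties are measure-zero for continuous
  data but can occur on constructed instances.
* The dispersion test uses centroids, not spatial medians, and carries the
  usual caveat that unbalanced, heterogeneous designs make PERMANOVA
  conservative when larger groups are also more dispersed.
* Baker's Gamma's convention (smallest-containing-cluster sizes, Spearman
  with average ranks) is fixed and documented here; other implementations
  differ in tie handling, so cross-package numerical agreement is not
  guaranteed.
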