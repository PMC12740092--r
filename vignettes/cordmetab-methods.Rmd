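---
title: "Screening cord-enriched, age-declining plasma metabolites: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening cord-enriched, age-declining plasma metabolites: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cordmetab)
```

# The screening problem

Umbilical cord plasma carries a metabolite repertoire quite unlike adult
plasma, and some of its enriched small molecules are plausible antiaging
factors: compounds abundant at birth whose circulating levels then decline
over the adult lifespan. `cordmetab` implements, as a reusable and fully
tested pipeline, the analysis needed to screen for such compounds in an
untargeted LC--MS feature table from a cross-sectional cohort of cord plasma
plus young, middle-aged and elderly adults. The design it targets is a
cohort of 30 cord / 60 young (18--25 y) / 60 middle-aged (40--55 y) / 60
elderly (65--85 y) biological samples, each injected in technical
triplicate across several acquisition batches, with a pooled QC sample
interleaved.

The pipeline has six stages, run in a fixed order by `run_pipeline()`:

1. **Preprocessing** -- retention-time filter, prevalence filter, outlier
   sample removal, injection aggregation, per-batch median normalization.
2. **Annotation** -- MS1 mass matching against a compound library with a
   composite 0--60 identification score, database-specific acceptance
   rules, and exclusion of exogenous / steroid-hormone classes.
3. **Differential and age-correlation statistics** -- Welch tests of cord
   versus pooled adults, Pearson age correlations, BH false-discovery
   control, the two-step antiaging filter, quadrant grouping and a
   composite rank.
4. **Partial-correlation network** of the top-differing metabolites.
5. **Pathway enrichment** -- permutation global test, hypergeometric
   over-representation, topology impact, cord-relative activity.
6. **Ordination** -- sample PCA and metabolite MDS.

# Statistical model and procedure

## Preprocessing

Features eluting before 30 s are removed: signals that early are dominated
by unretained compounds and the solvent front. The boundary is strict
("less than 30 s" is removed; 30.0 s is kept). A feature is then retained
only if it is observed in at least 70% of the samples of at least one age
group; this keeps compounds that are group-specific (present only in cord,
say) while discarding low-prevalence junk. Missing cells are first-class
(`NA`) throughout -- the prevalence filter counts presence, so a censored
cell must never be silently treated as zero.

Samples whose detection fraction falls below 0.5 are dropped as failed
injections; the published screens this pipeline is built for typically
remove a couple of such samples. Technical triplicates are averaged over
their observed values (a fully missing triple stays missing); pooled-QC
injections are not biological replicates and pass through unchanged, so the
per-metabolite QC coefficient of variation (`qc_cv()`, flag threshold 0.30)
can be computed at any point.

Normalization is per-batch median scaling: within each batch every
metabolite is divided by its own median over non-missing values, so the
within-batch median equals 1 afterwards (enforced to 1e-9 by the test
suite). Metabolites with a zero or undefined batch median are flagged and
left unscaled in that batch rather than silently producing infinities.
Median scaling preserves within-batch rank order, which is why the
downstream composite ranking is invariant to intensity rescaling.

The stage order (RT, prevalence, outlier samples, aggregation,
normalization) is a package decision: the filters' joint effect is
order-independent for features and samples that survive all of them, and
running the sample-level step before aggregation lets a single failed
injection be caught rather than diluted into its replicate mean.

## Annotation scores

The identification score follows the convention of untargeted metabolomics
software: three components, each capped at 20 points, summing to at most
60. The component formulas are package definitions chosen to respect those
caps:

* mass accuracy: `20 * max(0, 1 - |ppm| / 12)` with a 12 ppm tolerance,
  inclusive at the boundary;
* isotope similarity: `20 * max(0, cosine(observed, theoretical envelope))`;
* fragment evidence: `fragmentation_score / 5`, where the fragmentation
  score (0--100) is the percentage of library fragments matched within
  12 ppm.

Acceptance is database-specific: HMDB hits need a composite score of at
least 47 and a fragmentation score of at least 50; METLIN hits need 50 and
40. When several accepted hits share a feature, the highest composite score
wins, ties broken by smallest absolute ppm error, so each feature maps to
at most one compound. Scores are real-valued at the thresholds. Manual
spectral verification is out of scope; acceptance is purely rule-based.
Compounds of exogenous or steroid-hormone classes (corticosteroids,
estrogenic, androgenic and pregnenolone steroids) are excluded after
annotation: around birth these reflect maternal exposure, not neonatal
endogenous metabolism.

## Differential abundance, age correlation, and the two-step filter

All tests run on log2 intensities of the normalized table. The
cord-versus-adult contrast pools the three adult groups and uses Welch's
unequal-variance two-tailed t statistic; fold change is the ratio of the
cord mean to the pooled adult mean on the normalized scale. "Q values" are
Benjamini--Hochberg adjusted p-values (`bh_fdr()`, verified against a
brute-force step-up oracle on every ordering of six p-values).

The age correlation is Pearson's r between log2 intensity and age in
years, with cord samples entering at age 0. Including cord is the package
default (`include_cord = TRUE`): the screen's notion of "declines over the
lifespan" starts at birth, and age 0 is the natural anchor for cord
samples; the alternative adult-only mode is exposed for sensitivity
analyses. The p-value uses the t transform of r with n − 2 degrees of
freedom.

The **top-differing set** takes metabolites with at least a 4-fold
difference in either direction and q < 0.05. The **two-step antiaging
filter** first keeps metabolites negatively correlated with age at
FDR < 0.05, then removes those without a significant cord-to-adult decrease
at the same FDR (equivalently: `r < 0`, `q_age < 0.05`, `q_diff < 0.05`,
cord mean above pooled adult mean). The pro-aging filter is its exact
mirror; the two selections are provably disjoint. Candidates are placed in
four quadrant groups by inclusive cut-offs at fold change 2 and |r| 0.3
(group 1 passes both, group 2 only fold change, group 3 only correlation,
group 4 neither), and ranked by the mean of their fold-change rank and
|r| rank (average ranks on ties; smaller is better). The arithmetic mean of
ranks was chosen as the simplest symmetric integration of the two criteria.

## Regularized partial-correlation network

The network over the top-differing metabolites estimates conditional
associations: edge weights are partial correlations
`w_ij = -theta_ij / sqrt(theta_ii * theta_jj)` from an L1-penalized Gaussian
precision estimate on the correlation scale. The graphical-lasso solver is
implemented in compiled code as block coordinate descent -- each column
update is a lasso solved by cyclic soft-threshold coordinate descent --
with warm starts along the penalty path. At `lambda = 0` it reproduces the
partial correlations of the inverted correlation matrix to 1e-6; at
`lambda >= max |correlation|` the graph is empty; edge count is
non-increasing in the penalty.

Model selection minimizes the extended BIC,
`EBIC = -2 loglik + E log(n) + 4 E gamma log(p)` with `E` the edge count and
`gamma = 0.5`, over 100 log-spaced penalties from the largest absolute
off-diagonal correlation down to 1% of it. The diagonal is not penalized:
with a penalized diagonal the likelihood keeps improving along the whole
path through shrinkage alone, and the criterion can no longer distinguish
support changes -- the standard EBIC-glasso choice, and the one under which
a planted 3-node chain is recovered exactly in the tests. `gamma = 0`
reduces to plain BIC.

Centralities use the inverse-absolute-weight distance `1/|w|`: strength is
the sum of absolute incident weights; closeness the reciprocal of summed
shortest-path distances within the node's connected component (isolated
nodes get 0); betweenness counts the node pairs whose geodesics pass
through the node, fractionally on ties.

The network is fit on log2 normalized intensities across all biological
samples, on at most the 56 top-differing metabolites ranked by absolute
log2 fold change (`network_max_nodes`); whether to fit per group instead is
left to the user via `metabolite_network()`.

## Pathway statistics

The quantitative global test uses the quadratic score
`Q = (y'XX'y) / (m y'y)` with `y` the centered outcome and `X` the
column-standardized member matrix (population-sd standardization, so a
single-member set reduces to `n r^2`). Significance comes from a label
permutation null, `p = (1 + #{Q_perm >= Q_obs}) / (B + 1)`, which makes no
asymptotic assumption; the suite verifies nominal type-I control at
`alpha = 0.05` over 1000 null replicates. The default outcome is the
cord-versus-rest indicator -- the screen's primary contrast -- with an
age-valued mode available. Over-representation of candidate lists is the
hypergeometric upper tail against the annotated background; topology impact
is the matched members' share of total relative betweenness centrality on
the unweighted pathway graph; pathway activity is the member-mean intensity
per group divided by the cord value.

## Ordination

Sample PCA is centered but not scaled (after median normalization all
metabolites live on a comparable scale, and scaling would inflate
near-constant ones); missing cells are mean-imputed per feature. Components
carry a deterministic sign (largest-magnitude loading positive). The
metabolite map is classical (Torgerson) MDS on `1 - Pearson r` between log2
abundance profiles -- metabolites with similar profiles land together --
chosen over iterative stress majorization for determinism.

# The synthetic cohort generator

`simulate_cohort()` generates the study conditions the pipeline assumes,
plus ground-truth labels, so every downstream stage is testable without any
external data. Intensities follow a multiplicative log-normal model: for
metabolite *j* in injection *i* of sample *s*,

```
log2 x = base_j + cordshift_j * [s is cord] + slope_j * age_s
         + delta_{j, batch(s)} + eps,    eps ~ N(0, noise_sd)
```

The cord shift is set to `log2fc + slope * mean(adult ages)` so the planted
cord-vs-adult fold change and the age slope are independently controllable
-- mirroring the two independent criteria of the screen. Defaults: 1000
metabolites split 5% strongly antiaging (log2 fold change 1.5--3, slope
−0.022 to −0.010 per year), 10% weakly antiaging, 10% pro-aging (mirrored),
5% exogenous/steroid (cord-enriched with no age slope -- maternal transfer,
which only class exclusion can remove), 70% null; residual sd 0.8 on the
log2 scale and batch sd 0.3 across 4 batches, values a practitioner would
call typical for plasma LC--MS. Left-censoring replaces each feature's
lowest 5% with missing; 5% of null features become early-RT artifacts and
5% low-prevalence junk (both without library records); two outlier samples
get ~90% dropout; a pooled QC sample is injected 8 times across batches
with one third of the biological noise.

What the generator does **not** emulate: correlated metabolite modules
beyond class-shared effects, nonlinear age trajectories, sex effects,
retention-time drift, adduct/isotope interference, and
intensity-dependent (rather than quantile) censoring. Passing the recovery
tests therefore shows the pipeline implements its stated rules correctly
and has power under realistic noise -- not that real cord-plasma data meet
these assumptions.

`simulate_gaussian_network()` draws from a zero-mean Gaussian with a given
precision matrix and is the ground truth for the network stage.

# Numerical choices and degenerate inputs

* Welch test with both sides constant and equal means: `t = 0`, `p = 1`;
  fewer than 2 observations per side: missing, flagged.
* Zero-variance metabolites in the age correlation: flagged, not 0.
* Fold change with a zero adult mean: flagged missing rather than infinite.
* Glasso convergence: mean absolute change of the working covariance below
  `1e-4` times the mean absolute off-diagonal of S, at most 200 sweeps;
  non-convergence is an error naming the penalty. Edge support is
  symmetrized conservatively (an edge exists only if both column problems
  kept it).
* Permutation p-values are never 0: the observed statistic counts itself.
* The 12 ppm match boundary carries a 1e-9 ppm guard so exact-boundary
  masses are included under floating-point round-off.
* All stochastic code draws from a single seeded stream per call
  (`sim_config(seed = )`, `pipeline_config(seed = )`); re-running with the
  same seed reproduces every output byte for byte.

# Problem sizes used by the test suite

The suite validates on cohorts of 120--1000 metabolites at the full
30/60/60/60 sample design, network recovery at n = 500 on 3--6 nodes,
type-I error over 1000 null replicates at 999 permutations, and
normalization on 100 random fixtures -- sizes chosen so the whole suite
completes in a few minutes on one CPU while keeping every binomial
tolerance meaningful.

# Known limitations

* Annotation is rule-based MS1 + fragment matching; no adduct
  deconvolution, retention-time prediction or spectral-library formats.
* The age model is linear on the log2 scale; nonlinear or sex-stratified
  trajectories are out of scope.
* The global-test outcome encodes the cord contrast as a binary indicator;
  ordinal group codings would weight the adult groups differently.
* Pathway topology comes from user-supplied edge lists; no pathway
  databases are bundled or downloaded.
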