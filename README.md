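# cordmetab

Screening umbilical cord plasma for antiaging metabolite candidates from
untargeted LC–MS metabolomics.

Cord blood plasma differs sharply from adult plasma, and metabolites that
are abundant at birth but decline across adult life are natural candidates
for antiaging factors. `cordmetab` is an R package for analysts running
that screen on a cross-sectional cohort — cord plasma plus young,
middle-aged and elderly adults — starting from a feature-by-sample
intensity table with retention times and m/z values. It covers the whole
path from raw feature QC to ranked candidate lists, and ships a seeded
synthetic cohort generator with ground-truth labels so every stage is
testable without any external data.

## What it computes

Per metabolite *j* with normalized intensities *x* and sample ages *a*:

- **Differential abundance**: Welch's two-tailed t on log2 intensities,
  cord vs the pooled adult groups; fold change
  FC_j = mean(cord) / mean(adults); Benjamini–Hochberg q-values.
- **Age correlation**: Pearson r_j = cor(log2 x_j, a), cord entering at
  age 0, with q-values from the t transform of r.
- **Two-step antiaging filter**: keep metabolites with r_j < 0 at
  FDR < 0.05, then drop those without a significant cord-to-adult decrease
  at the same FDR. The mirrored filter yields pro-aging candidates.
  Candidates are grouped by inclusive cut-offs at FC ≥ 2 and |r| ≥ 0.3 and
  ranked by the mean of their FC rank and |r| rank.
- **Top-differing set**: |log2 FC| ≥ 2 (a 4-fold difference either way)
  at q < 0.05.
- **Partial-correlation network** on the top-differing set: graphical
  lasso (compiled block coordinate descent) with EBIC selection,
  EBIC = −2ℓ + E·log n + 4E·γ·log p, γ = 0.5; edge weights
  w_ij = −θ_ij/√(θ_ii θ_jj); strength, closeness and betweenness on 1/|w|
  distances.
- **Pathway statistics**: permutation global test
  Q = (yᵀXXᵀy)/(m·yᵀy) on member abundances, hypergeometric
  over-representation, betweenness-based topology impact, and
  cord-relative pathway activity.
- **Ordination**: centered PCA of samples and classical MDS of metabolites
  on 1 − Pearson r distances.

Annotation against a compound library uses 12 ppm MS1 matching and a
0–60 composite identification score (mass accuracy, isotope similarity,
fragment pattern; each ≤ 20), accepting HMDB hits at score ≥ 47 with
fragmentation ≥ 50 and METLIN hits at 50/40, then excluding exogenous and
steroid-hormone compound classes.

## Worked example

```r
library(cordmetab)

sim <- simulate_cohort(sim_config(n_metabolites = 300, seed = 5))
print(sim$features)
#> feature_table: 300 features x 638 samples (not normalized)
#>   missing cells: 8.2%

rep <- run_pipeline(sim$features, sim$samples, sim$library, sim$pathways,
                    pipeline_config(seed = 5, permutations = 199), "demo_out")
#> [cordmetab] preprocess: 300 features x 638 columns in
#> [cordmetab] preprocess: 270 features x 216 biological samples out
#> [cordmetab] annotate: 270 accepted, 15 removed as exogenous/steroid, 255 kept
#> [cordmetab] diffstats: 77 significant, 21 top-differing (8 up / 13 down),
#>             45 antiaging, 30 proaging
#> [cordmetab] network: 21 nodes, 151 edges at lambda 0.0162
#> [cordmetab] enrichment: 25/25 pathways significant (global test)
```

The 638 input columns are 210 biological samples in technical triplicate
plus 8 pooled-QC injections; preprocessing removes early-eluting and
low-prevalence features, drops the two planted outlier samples (216
columns = 208 biological samples + 8 QC), averages the triplicates and
median-normalizes per batch. Of the 270 surviving features, 255 map to
endogenous library compounds; 45 pass the two-step antiaging filter.

```r
anti <- read.delim("demo_out/antiaging_candidates.tsv")
head(anti[, c("metabolite_id", "fc", "r_age", "q_age", "group",
              "composite_rank")], 3)
#>   metabolite_id       fc      r_age        q_age group composite_rank
#> 1         C0003 6.607591 -0.8186210 1.984776e-49     1            2.5
#> 2         C0005 7.735444 -0.7023289 2.242058e-31     1            6.5
#> 3         C0007 4.268541 -0.7714039 5.118921e-41     1            6.5
```

The top candidates are group-1 metabolites: several-fold enriched in cord
plasma (`fc`) and strongly negatively correlated with age (`r_age`), with
the composite rank averaging their standing on both criteria. The network
centrality table (`demo_out/network_centralities.tsv`) identifies the most
connected metabolites of the top-differing set; `run_report.json` holds
all stage tallies.

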