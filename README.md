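# aepymorph

Morphometric taxon delimitation for elephant-bird (Aepyornithidae) leg bones
— and, more generally, for any study that must recover discrete morphotypes
from wide tables of linear skeletal measurements riddled with missing values.

Museum series of extinct taxa are mostly broken: ends of bones snap off, so
whole blocks of measurements vanish together, and half the specimens can
exceed 25% missingness. This package implements, as tested and reusable R
functions, the analysis chain used in quantitative revisions of such
material:

1. **Imputation** — iterative-PCA (EM) completion of the measurement matrix
   after unit-variance scaling: missing cells start at column means, are
   repeatedly replaced by a rank-*q* truncated-SVD reconstruction (observed
   cells always restored) until convergence, with optional
   singular-value shrinkage `d (d² − σ̂²)/d²` to curb EM overfitting. The
   rank *q* is chosen by fivefold cross-validation on held-out observed
   cells (minimum MSEP).
2. **Clustering** — PCA of the completed matrix, then finite Gaussian
   mixtures fitted by EM under six covariance families (EII, VII, EEI, VVI,
   EEE, VVV), compared by BIC = 2·logL − m·log n. Principal components enter
   stepwise until BIC separates competing cluster numbers by more than 2
   ("stable"); specimens with classification uncertainty 1 − max posterior
   ≥ 0.05 are excluded. A two-round design first analyses specimens under
   the 25% missingness gate, then re-clusters every specimen at the fixed K.
3. **Taxonomy** — clusters are named by the senior available species name
   (earliest year, then month) among their well-predicted type specimens;
   literature types enter through discrete diagnostic measurement intervals.
   Per-measurement one-way ANOVAs with Bonferroni correction describe the
   clusters.
4. **Body mass** — the Campbell–Marcus allometry
   log₁₀(M in g) = 2.411·log₁₀(least femoral shaft circumference in mm) − 0.065,
   summarized per cluster from observed circumferences only.

A synthetic-data module generates specimen tables with the statistical
structure this analysis assumes — latent groups at published per-taxon range
midpoints, a shared "overall size" factor driving strong positive
correlations, and anatomically structured breakage missingness — so every
stage is testable without museum data.

## Worked example

```r
library(aepymorph)

cfg   <- generator_config("tarsometatarsus", n_per_cluster = 18, seed = 7)
study <- generate_specimens(cfg)
study$dataset
#> specimen_dataset: 72 tarsometatarsus specimens x 44 codes; missingness 7.3% (mean),
#>   9 specimens >= 25% missing

res <- run_pipeline(study$dataset, pipeline_config(seed = 7))
res
#> tarsometatarsus: round-1 n = 63, K = 4 (EII, 1 PCs, stable = TRUE);
#>   round-2 n = 72; excluded by uncertainty: 1
```

Sixty-three specimens pass the missingness gate; cross-validation picks rank
5 for the imputation; the first principal component carries 94.3% of the
variance (overall size); stepped BIC selection declares four clusters stable
on one component, and one specimen is excluded as uncertain. The confusion
table against the generator's truth is diagonal:

```r
r <- res$elements$tarsometatarsus
table(truth = study$labels[match(r$round1$ids, study$dataset$meta$specimen_id)],
      cluster = r$final_assignment$labels)
#>      cluster
#> truth  1  2  3  4
#>     1 16  0  0  0
#>     2  0 15  0  0
#>     3  0  0 15  0
#>     4  0  0  0 17

mass_from_circumference(c(114, 288, 308))
#>   circumference_mm    mass_g   mass_kg
#> 1              114  78378.62  78.37862
#> 2              288 732141.94 732.14194
#> 3              308 860787.15 860.78715
```

The three circumferences are the smallest published *Mullerornis* femur, the
largest *Vorombe* femur (78 and 732 kg at nearest-kg), and the largest femur
ever measured (≈861 kg).

The numbered scripts under `analysis/` run the same workflow as a narrative:
`01_simulate.R` writes the synthetic study tables, `02_impute.R` completes
them and scores the imputation, `03_cluster.R` runs the two-round pipeline,
`04_taxonomy.R` resolves cluster names and literature placements, and
`05_mass.R` tabulates body masses. Each writes its tables under `results/`.

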