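# pbaescreen

Chemometric screening of poly-beta-amino-ester (PBAE) drug-conjugate
libraries for cartilage drug delivery.

## The problem

Cartilage is avascular and its glycosaminoglycan (GAG) matrix is densely
negatively charged, so intra-articular drugs barely enter the tissue before
being cleared from the joint. Cationic PBAE carriers — built
combinatorially from a diacrylate (letter code), an amine (number code) and
an end-capping agent (`e1`/`e2`) — can drive a conjugated steroid into
cartilage by electrostatic partitioning. Screening such a library raises
the questions this package answers quantitatively:

* **Which polymers work?** Uptake ratio of each conjugate against the
  clinical reference formulation, with one-tailed Welch tests and
  significance flags; GAG time-course efficacy with one-way ANOVA and
  Tukey's HSD.
* **What drives performance?** NIPALS partial least squares (PLS)
  regression of log uptake ratios on the polymer descriptor table, with
  scree-based component selection, per-component X/Y variance bookkeeping,
  correlation loading maps and per-descriptor importance profiles.
* **How is the library structured?** Complete-linkage clustering of
  polymers on Manhattan distances between standardized descriptors.
* **How mobile is the polymer?** Diffusion coefficients from
  trans-cartilage permeation traces via the break-through-time (time-lag)
  model: fit R(t) = K·max(0, t − t_lag), then D = δ²/(6·t_lag).

At its core is a from-scratch NIPALS PLS2: per component,
w = X'u/‖X'u‖, t = Xw, q = Y't/t't, u = Yq/q'q to convergence, deflation of
both blocks by t, and Frobenius-share variance bookkeeping
R²X[h] = ‖t·p'‖²/‖X₀‖². With all min(n−1, p) components it reproduces
ordinary least squares to 1e-8, the exactness anchor in the test suite.

Because screening datasets of this kind are typically not deposited, the
package includes seeded generators for every input (descriptor matrix with
block-correlated latent structure, uptake replicates, permeation traces,
GAG time courses) so the whole pipeline runs — and is tested — end to end
with known ground truth.

## Worked example

Simulate a 36-backbone library, fit the PLS model on log uptake ratios,
and select the component count:

```r
library(pbaescreen)

lib <- generate_library(library_sim_config())   # 3 acrylates x 12 amines
std <- standardize_descriptors(lib$descriptors)
m   <- fit_pls(std$z_values,
               log(as.matrix(lib$responses[, c("e1", "e2")])),
               ncomp = 10, max_iter = 10000)
m
#> <pls_model> NIPALS PLS, 36 polymers x 30 descriptors -> 2 response(s), 10 components
#>   X-R2 cum: 0.230 0.373 0.553 0.662 0.812 0.831 0.845 0.858 0.872 0.882
#>   Y-R2 cum: 0.720 0.857 0.909 0.941 0.945 0.958 0.967 0.972 0.975 0.978

suppressWarnings(select_components(rmse_scree(m), m$r2x_cum))
#> <component_selection> inflection of the X-variance curve at h=5
#>   (RMSE elbow at h=2); variance criterion (X-R2 cum >= 80%) gives h=5
```

Five components carry 81% of the descriptor variance and 94% of the
response variance — the generator's five planted latent factors, recovered.
Compare a conjugate against the reference formulation and fit a permeation
trace:

```r
u <- simulate_uptake_experiment(true_ratio = 8, n_reps = 3, cv = 0.1,
                                seed = 2, times = 10)
uptake_ratio(u$uptake_ug_per_mg[u$arm == "conjugate"],
             u$uptake_ug_per_mg[u$arm == "reference"])
#> <uptake_ratio> 7.47 [5.45, 10.2], one-tailed p = 0.000561 (greater), n = 3/3

tl <- 0.4^2 / (6 * 2.667e-3)                     # true lag: 10 min
tt <- seq(0, 10 * tl, length.out = 60)
tr <- simulate_diffusion_trace(D = 2.667e-3, thickness = 0.4, times = tt,
                               noise_sd = 0.005, seed = 3)
fit_breakthrough(tr)
#> <diffusion_fit> hinge: K = 0.006652 /min, t_lag = 9.91 min,
#>   D = 0.00269 mm^2/min (rmse 0.00481)
```

The 8-fold planted enhancement is estimated at 7.5 with a CI covering the
truth, and the diffusion coefficient is recovered within 1%. The full
chain — simulate, validate, cluster, PLS, diffusion, uptake and GAG
statistics, with a reproducibility manifest — is one call:

```r
cfg <- run_config(out_dir = "pbae_run", seed = 7)
manifest <- run_full_analysis(cfg)
```

## Package layout

| | |
|---|---|
| `R/polymer-library.R` | descriptor-table data model, CSV/schema I/O, standardization, validation |
| `R/synthetic-data.R` | seeded generators for every study input |
| `R/clustering.R` | Manhattan distances, complete linkage, Newick/merge-table export |
| `R/pls.R` | NIPALS PLS, scree, component selection, loading maps, importance |
| `R/transport-kinetics.R` | break-through-time fits, lag relation, replicate pooling |
| `R/efficacy-stats.R` | uptake ratios, GAG variation, ANOVA, Tukey HSD |
| `R/pipeline.R` | end-to-end orchestration with manifest |
| `vignettes/pbae-chemometrics.Rmd` | models, assumptions, numerical choices |

The methods vignette documents the statistical models, the component
selection rationale, and what the synthetic study does and does not
emulate.
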