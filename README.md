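# clocklight

Circadian and light-responsive gene expression analysis for
cyanobacteria.

In *Synechococcus elongatus*, the circadian clock activates "dusk
genes" (glycogen breakdown, respiration) through phosphorylation of the
master regulator RpaA, while natural light fluctuations — clear-day
irradiance arcs, cloud-driven shade and high-light pulses, sunset — act
through the phosphorylation state of a second regulator, RpaB.
`clocklight` implements the full analysis chain for dissecting this
interaction:

* **Expression**: median + ORF-length normalization of RNA-seq counts,
  single-component cosinor rhythm fitting, and classification into
  dawn (acrophase 40–189°), dusk (190–360° and 0–39°), and
  non-circadian genes (amplitude threshold 0.15, one-read-per-
  nucleotide expression filter).
* **Clustering**: correlation-distance k-means (k = 8, MATLAB centroid
  convention) over block-z-scored condition series, with the three
  largest dusk clusters named Early/Middle/Late by activation order.
* **ChIP**: Gaussian smoothing (400 bp window, sd 50 bp), 3.5-fold
  enrichment peak calling against a mock control with replicate
  intersection, strand-aware assignment of peaks to promoters within
  500 bp, and Δenrichment–Δexpression correlations.
* **Modeling** — the core of the package: phenomenological Hill
  AND-gate ODE models of dusk-cluster expression,

  dX/dt = B + β · Π f(uᵢ; Kᵢ, Hᵢ) − αX,

  driven by measured (or synthetic) RpaA∼P / RpaB∼P trajectories and
  optional cluster feedback, fitted jointly to the Clear Day and Shade
  pulse conditions by multi-start bounded least squares
  (H ∈ [0,7], β, α ∈ [0,80], B ∈ [0,10], K ∈ [0,1]) and compared by
  AIC = n·ln(RSS/n) + 2k.
* **Synthetic data**: a seeded generator for every pipeline input —
  diel light profiles, regulator phosphorylation dynamics, cosinor-
  structured counts with a truth table, cluster trajectories simulated
  from bundled reference parameter sets, and ChIP tracks with planted
  peaks.

## Worked example

Generate a noisy synthetic data set from the bundled Early-cluster
feedback model (an incoherent feedforward loop: Late represses Early
downstream of joint RpaA∼P/RpaB∼P activation), then ask which model
class explains it best:

```r
library(clocklight)

ds <- simulate_cluster_dataset(noise_sd = 0.05, seed = 1001)
early <- ds$data[ds$data$cluster == "Early",
                 c("condition", "time_h", "value")]
fits <- lapply(list(feedback = ds$models$Early$spec,
                    joint = dusk_model_spec("Early", c("RpaA", "RpaB")),
                    rpaA  = dusk_model_spec("Early", "RpaA"),
                    rpaB  = dusk_model_spec("Early", "RpaB")),
               function(sp) fit_dusk_model(early, ds$regulators, sp,
                                           n_starts = 12, seed = 1))
fits$feedback
#> Dusk cluster model: Early
#>   regulators: RpaA AND RpaB
#>   feedback:   Late (repression)
#>   free parameters: 9
#> Fitted to ClearDay + ShadePulse (50 points, 12 starts, seed 1)
#> Misfit (root-sum-square): 0.315
#> Coefficients:
#>      B   beta  alpha    K_A    H_A    K_B    H_B    K_Y    H_Y
#>  0.781 80.000 14.927  0.881  7.000  0.577  7.000  0.359  2.508

compare_models(fits)
#> Model comparison (ascending AIC):
#>               model cluster k  n error    rss  aic delta_aic
#>  feedback Late rep.   Early 9 50 0.315 0.0989 -293       0.0
#>       RpaA and RpaB   Early 7 50 0.513 0.2634 -248      45.0
#>                RpaA   Early 5 50 0.613 0.3761 -234      58.8
#>                RpaB   Early 5 50 0.720 0.5188 -218      74.9
```

The misfit (root-sum-square deviation between simulation and the 50
fitted points) orders feedback < joint < single-regulator: single
regulators cannot produce circadian gating (the different responses to
the same light drop in afternoon Shade versus Sunset), joint activation
captures most of the dynamics, and the feedback term separates the two
responses. `plot(fits$feedback)` overlays data and best-fit
trajectories per condition; `summary()`, `coef()`, `predict()`,
`residuals()`, and `simulate()` behave as for other fitted-model
objects. `run_pipeline(pipeline_config())` chains every stage on
synthetic data and writes classification, cluster, peak, and fit
tables plus a reproducibility manifest.

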