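---
title: "Phenomenological models of dusk-gene activation under natural light"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenomenological models of dusk-gene activation under natural light}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clocklight)
```

## The biological problem

The cyanobacterium *Synechococcus elongatus* carries a circadian clock
whose main transcriptional output is the activation of *dusk genes* —
genes, including the glycogen-breakdown machinery, whose expression
peaks near the light-to-dark transition. Under constant laboratory
light this activation is driven by the clock-controlled phosphorylation
of the response regulator RpaA. In nature, however, light fluctuates:
irradiance follows a parabolic arc over a clear day, clouds produce
abrupt shade and high-light pulses, and sunset ramps light down before
night. A second OmpR-family regulator, RpaB, is dephosphorylated by
high light and (as the data this package models show) rephosphorylated
when light drops, making RpaB~P a fast readout of light *decreases*.

The package asks, and answers with models and synthetic data, a
quantitative question: can the measured dynamics of just two inputs —
RpaA~P (clock) and RpaB~P (light) — explain the stereotyped responses
of the major dusk-gene clusters across four light regimes (constant
Low Light, Clear Day, a 1-h High Light pulse, a 1-h Shade pulse)?

## The model

Each of the three major dusk clusters (Early, Middle, Late, named by
their order of activation under Low Light) is coarse-grained to one
effective gene with expression $X(t)$, driven through an AND gate at
its promoter:

$$\frac{dX}{dt} = B_X + \beta_X \prod_i f_i(u_i(t)) - \alpha_X X$$

with one Hill factor per input: activation
$f(u, K, H) = (u/K)^H / (1 + (u/K)^H)$ and repression
$f(u, K, H) = 1 / (1 + (u/K)^H)$, where $K$ is the coefficient of
activation/repression (input level at half effect) and $H$ the Hill
coefficient (steepness). The inputs $u_i(t)$ are *measured* (here:
synthetic) trajectories — RpaA~P, RpaB~P, and optionally the expression
of another cluster as a feedback term — each scaled jointly across the
four light conditions to $[0, 1]$. Model topologies considered per
cluster: single-regulator (RpaA-only or RpaB-only, 5 free parameters),
joint activation by both (7), and joint activation plus one
cluster-feedback term (9).

Parameters are fitted inside a fixed box: $H \in [0, 7]$,
$\beta \in [0, 80]$ and $\alpha \in [0, 80]$ (normalized expression per
hour), $B \in [0, 10]$, $K \in [0, 1]$. The misfit is the root of the
summed squared deviations between simulation and data over the fitted
conditions. Fitting is deliberately restricted to Clear Day plus Shade
pulse: the two conditions share an acclimation regime, whereas a joint
fit across all four conditions confounds growth-rate differences
between Low Light- and Clear Day-acclimated cells; the other
conditions remain available through the `conditions` argument for
exploration. Each condition is simulated with its own initial value,
taken as that condition's first observation. Model classes are ranked
by the least-squares AIC, $n \ln(\mathrm{RSS}/n) + 2k$; the AIC formula
for this setting is a package choice, since only the ranking is
scientifically meaningful (the residual count $n$ depends on the
sampling design).

### Numerical choices

* **Integration.** `simulate_cluster()` defaults to adaptive explicit
  Runge-Kutta (deSolve `ode45`, rtol 1e-6, atol 1e-9). Because the ODE
  is linear in $X$ once the exogenous inputs are fixed, the fitting
  path uses an exact-update stepper on a 0.01 h grid (production
  treated as piecewise linear per step; the homogeneous part integrated
  exactly), which is unconditionally stable even at $\alpha = 80$/hr
  and agrees with the adaptive solver to ~1e-4. Both are tested against
  an independent fixed-step Euler oracle.
* **Degenerate Hill limits.** $H = 0$ gives $f \equiv 1/2$ (via
  $0^0 = 1$); $K = 0$ with $u > 0$ gives full activation (repression
  0); $u = K = 0$ gives $1/2$. These are the limits that keep the
  objective continuous on the closed parameter box, so bounded
  optimizers can touch the faces without discontinuities.
* **Multi-start optimization.** Bounded Levenberg-Marquardt
  (minpack.lm) from Latin-hypercube starting points inside the box; 64
  starts by default, seeded and bit-wise reproducible. The objective is
  multi-modal; single starts visibly land in local optima, which is why
  the test suite uses 12-24 starts even for scaled-down problems.
* **Regulator interpolation.** Piecewise linear between measurement
  times (previous-value hold available via `interpolation =
  "constant"`). The parameters themselves are often non-identifiable
  (plateaued Hill terms trade off against $\beta$); trajectories, not
  parameter vectors, are the recovery criterion throughout.

## The upstream pipeline

**Normalization.** Raw counts are median-normalized across samples
(each sample scaled so its median over the genes nonzero in all
samples equals a common reference) and divided by ORF length, giving
reads per nucleotide. The reference is the *lower* median of the
per-sample medians — an actual sample's median, which makes the hand
example in `?normalize_counts` exact; for an odd number of samples it
is the usual median. Rescaling any one sample is absorbed up to a
single global factor (exactly, when that sample does not anchor the
reference).

**Circadian classification.** A single-component cosinor (linear least
squares on the 24-h sine/cosine basis, applied to log2-scale
expression) gives each gene a mesor, amplitude, and acrophase.
Circadian genes need amplitude > 0.15 — the threshold is interpreted
on the log2 scale, which is the scale the rhythms are fitted on — and
at least one read per nucleotide in at least one time point. Dawn genes
have acrophase in [40°, 189°]; dusk genes in [190°, 360°) or [0°, 39°]
(boundaries inclusive); 0° is subjective dawn. Log-ratio pseudocounts
default to half the smallest nonzero normalized value, which slightly
shrinks fitted amplitudes of weakly expressed genes; the
classification margin (planted amplitudes ~0.4 versus threshold 0.15)
absorbs this.

**Clustering.** Dusk genes are clustered by k-means (k = 8 by default,
50 restarts, seeded) with Pearson correlation distance
$d = 1 - r$, rows standardized and centroids re-standardized after
averaging — the centroid convention of MATLAB's correlation-distance
k-means, which the original analysis used. Independent experiment
blocks are z-scored separately (sample sd, $n - 1$) and concatenated
unweighted. The three largest clusters are named Early/Middle/Late by
the first time their Low-Light mean trajectory, rescaled to its own
0-1 range, crosses 0.5; rescaling within the Low Light block matters
because the Late cluster's Low Light plateau sits far below its Clear
Day maximum.

**ChIP analysis.** Per-base signal is smoothed with a Gaussian kernel
(window 400 bp, sd 50 bp; circular convolution on circular genomes),
ip and mock are scaled to equal totals, mock values are floored at the
5th percentile of nonzero mock (ratios to near-zero mock are
unstable), and peaks are maximal runs with ip/mock >= 3.5, at least
50 bp wide, kept only if detected in both replicates (>= 1 bp interval
overlap; replicate-1 coordinates reported). The published analysis
used a custom Peak-Seq variant whose intermediates are not available;
this package implements exactly the printed criteria instead, so
genome-wide peak totals from the original data are not reproduction
targets. A peak targets a gene when the summit is within 500 bp of the
start codon, upstream on the gene's strand, and the gene is the
closest same-strand gene — one candidate per strand, so divergent
promoters can yield two targets. Coordinates are 1-based inclusive in
GFF3, 0-based half-open internally and in bedGraph/BED.

## What the synthetic generator emulates

The generator produces every input the pipeline consumes, as pure
functions of their arguments and a seed:

* **Light** (3-min steps over a 12-h light period): Low Light constant
  at 50 umol photons m-2 s-1; Clear Day as the half-sine
  $600\sin(\pi t/12)$ — smooth, unimodal, peaking at 600 at hour 6,
  near the 50-level at dawn/dusk — standing in for measured clear-sky
  irradiance; High Light pulse = Clear Day values on [8, 9) h over a
  Low Light baseline; Shade pulse = Clear Day / 10 on [8, 9) h.
* **Regulators**: RpaA~P is a light-insensitive logistic ramp (0.2 to
  1.0 raw units, centered at hour 6, time constant 1.5 h) identical in
  all conditions — the clock is unaffected by these light
  fluctuations. RpaB~P moves opposite to light: /3.1 within 15 min of
  high-light onset, x1.9 within 15 min of shade onset, x1.7 across the
  hour 10-12 sunset ramp, relaxing back with a 30-min exponential
  after a pulse ends (the measurements show reversibility but no rate;
  30 min is a package choice). Raw units are arbitrary: all downstream
  use is after joint 0-1 scaling.
* **Cluster expression**: forward simulations of the bundled reference
  parameter sets (`dusk_model_presets()`), plus clipped Gaussian
  measurement noise. The feedback variants need another cluster's
  trajectory as input, and the three best feedback models form a cycle
  (Early <- Late, Middle <- Late, Late <- Middle); since feedback
  inputs are *measured*, not co-simulated, the generator first
  simulates all clusters under their joint-activation parameter rows
  and feeds those 0-1 scaled trajectories to the feedback models.
  Sampling every 0.5 h over the 12-h light period (25 points per
  condition, 50 fitted residuals) is the package's default design.
* **Counts**: Poisson draws around per-sample-scaled cosinor means on
  the log2 scale (planted mesor 1.5 log2 reads/nt, amplitude 0.4,
  extra Gaussian noise sd 0.02), with per-sample scale factors drawn
  from [0.5, 2] to exercise the median normalization, on a circular
  chromosome of 2.7 Mb — the scale of the *S. elongatus* genome.
* **ChIP tracks**: mock = Poisson noise around a flat background; ip =
  the same law times a Gaussian fold-profile (enrichment `fold` at the
  summit, sd = width/4). Smoothing attenuates a planted summit ratio
  by $\sigma_b/\sqrt{\sigma_b^2 + \sigma_s^2}$ and library-size
  scaling pulls it down further, so test fixtures plant 600-bp-wide
  bumps on a 200-kb genome at deep coverage (background 5000), where
  fold-4 bumps stay safely above the 3.5 threshold and fold-3.4 bumps
  safely below, and summits are localized to +/-1 bp.

What passing on these fixtures does *not* show: robustness to
overdispersed counts, growth-rate-coupled global expression changes,
unmodeled promoters (the ~20 light-insensitive dusk genes around
*kaiBC* are explicitly outside the model's scope), fragment-length
artifacts in ChIP, or the behavior of the peak caller on the original
study's read data — whose genome-wide tallies (450 circadian genes,
281 dusk genes, 114/218/451 peaks) depend on inputs this package does
not ship.

## Worked model comparison

```{r fit, eval = FALSE}
ds <- simulate_cluster_dataset(noise_sd = 0.05, seed = 1001)
early <- ds$data[ds$data$cluster == "Early",
                 c("condition", "time_h", "value")]
fits <- lapply(list(feedback = ds$models$Early$spec,
                    joint = dusk_model_spec("Early", c("RpaA", "RpaB")),
                    rpaA = dusk_model_spec("Early", "RpaA"),
                    rpaB = dusk_model_spec("Early", "RpaB")),
               function(sp) fit_dusk_model(early, ds$regulators, sp,
                                           n_starts = 12, seed = 1))
compare_models(fits)
plot(fits$feedback)
```

On data generated from the Early feedback model (Late represses Early
downstream of joint RpaA~P/RpaB~P activation — an incoherent
feedforward loop) with realistic noise, the fitted misfits order
feedback < joint < single-regulator, reproducing the published
within-cluster pattern: single regulators cannot express circadian
gating, joint activation captures most dynamics but makes Shade and
Sunset responses too similar, and the feedback term differentiates
them.

## Problem sizes and runtimes

The test suite and the acceptance script run on scaled-down but
structurally faithful problems chosen as reasonable desk-scale
experiments: 25 sampling times per condition, two fitted conditions,
12-24 optimizer starts (64 is the package default for final
analyses), 10 seeded repeats for the model-ordering experiment, 60-90
genes for classification/clustering recovery, and a 200-kb ChIP
fixture genome. The model-ordering experiment is the largest single
computation (roughly three minutes on one core).

## Known limitations

* The Hill parameters are *effective* constants absorbing indirect
  regulation (e.g. via sigma factors); fitted values should not be
  read as binding constants, and are frequently non-identifiable.
* Feedback inputs are exogenous measured trajectories; the package
  never co-simulates coupled clusters, so the models cannot be used to
  predict knockout dynamics of the feedback source.
* The degenerate published RpaB-only/Middle parameter row (no decay
  rate) is carried in the reference table for completeness but cannot
  be simulated.
* `fit_dusk_model()` assumes the data and regulator series are on the
  joint 0-1 scale; feeding unscaled data technically works but makes
  the bounded parameter box inappropriate.
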