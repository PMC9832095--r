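---
title: "Bayesian history matching with Gaussian process emulators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian history matching with Gaussian process emulators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`cardiohm` calibrates biophysical models — the motivating application is
cohorts of cardiac electrophysiology (EP) models — by Bayesian history
matching (BHM): instead of seeking a single best-fitting parameter vector,
it iteratively *rules out* the parts of a bounded parameter space that are
implausible given observed biomarkers and their uncertainties. What remains
is the not-ruled-out-yet (NROY) region, a set-valued answer that carries
the calibration uncertainty with it. This vignette describes the model,
the algorithmic choices, and what the synthetic test bed does and does not
demonstrate.

## The parameter space

The default space has 14 dimensions: nine statistical-shape-model (SSM)
mode weights that encode anatomy as scalars, and five functional EP
parameters — fibre angle $\alpha \in [40, 90]^\circ$, fast endocardial
conduction (FEC) layer height $\in [33, 100]$ % of the apico-basal
extension, fibre conduction velocity $CV \in [0.64, 0.92]$ m/s, the
cross-fibre velocity ratio $k_{xf} \in [0.11, 0.35]$ and the FEC velocity
ratio $k_{FEC} \in [1.1, 8.75]$. Representing anatomy by mode weights is
what lets a single emulator serve every subject: all models for all
patients live in one common space.

Mode-weight bounds default to $[-3, 3]$, read as standard deviations of a
PCA mode weight; they are a configuration field because the tight interval
depends on the cohort behind the shape model. Internally *everything* —
sampling, emulation, implausibility — operates on the unit hypercube
$[0,1]^{14}$; natural units appear only at the simulator boundary and in
reports. This makes GP length-scales comparable across dimensions and
uniform sampling genuinely uniform.

## Gaussian process emulators

One univariate emulator per biomarker:
$$f(\mathbf{x}) = \beta_0 + \textstyle\sum_i \beta_i x_i +
  \mathcal{G}(\mathbf{x}) + \varepsilon,$$
with $\mathcal{G}$ a zero-mean GP with automatic-relevance-determination
squared-exponential kernel
$$k(\mathbf{x}, \mathbf{x}') = \sigma_f^2 \exp\!\Big(
  -\tfrac12 \sum_i (x_i - x_i')^2 / \delta_i^2\Big)$$
and $\varepsilon \sim N(0, \sigma_n)$. Hyperparameters maximize the
log-marginal likelihood via multi-restart L-BFGS in log space with analytic
gradients; the mean coefficients $(\beta_0, \boldsymbol\beta)$ are profiled
out by generalized least squares at every step (by the envelope theorem the
profiled gradient is exact). Numerical choices worth knowing:

* **Output standardization.** Responses are centred and scaled to unit
  variance during fitting (optimizer conditioning) and all hyperparameters
  are mapped back to natural response units afterwards, so stored emulators
  are standardization-free.
* **Restarts.** Default 10 for one-off fits (`fit_gpe`), 5 inside
  `fit_bank`; initial log-hyperparameters are Latin-hypercube spread over
  $\delta \in [0.1, 3]$, $\sigma_f \in [0.3, 2]$,
  $\sigma_n \in [10^{-6}, 0.1]$, plus one conventional start. Pipeline
  configurations in the tests use 2 restarts, which is adequate for the
  smooth synthetic responses.
* **Noise-free mode** pins $\sigma_n$ to a $10^{-10}$ floor (standardized
  scale), giving interpolation with predictive variance $\le 10^{-8}$ at
  training points; Cholesky failures escalate jitter
  ($10^{-10} \to 10^{-6}$, relative) only as far as needed.
* **Predictive variance** is latent-plus-noise: $\sigma_n$ is part of the
  emulator's uncertainty as seen by the implausibility measure.

Emulator quality is tracked by $R^2$ and by the *independent standard
error* (ISE): the percentage of held-out points whose true value falls
strictly within 2 predictive SD of the predicted mean — about 95.45 % when
the emulator's uncertainty is calibrated. The inequality is strict, so a
degenerate zero-SD prediction counts as a failure even with an exact mean.

## Implausibility and waves

Given targets $\mu_i \pm \sigma_i$, a candidate $\mathbf{x}$ scores
$$I(\mathbf{x}) = \max_i
  \frac{|\mathbb{E}[f_i(\mathbf{x})] - \mu_i]|}
       {\sqrt{\mathbb{V}ar[f_i(\mathbf{x})] + \sigma_i^2}},$$
(the square-root form of the squared measure; monotone-equivalent under the
max and numerically safer). A run proceeds in waves:

1. an initial Latin hypercube design is simulated and split
   train/validation/test (defaults 280/70/88);
2. the "reference" emulator bank is fitted to the training set;
3. **wave 1** emulates a Sobol' candidate set (default 10,000 points) and
   keeps points with $I < 3.2$ — no new simulations;
4. **each later wave** selects a batch (default 140) from the surviving
   candidates by greedy maximin, simulates it, refits the bank on all
   accumulated simulations, repopulates the candidate set inside the
   current NROY region with the cloud technique, and applies its threshold
   cumulatively: a point is NROY only if it passes *every* wave's bank and
   threshold. Thresholds default to 3.2, 3.2, 3.0, the final cut at 3
   following the three-sigma rule.

Design choices the method description leaves open, fixed here:

* **Cumulative membership.** Later emulators never re-admit points ruled
  out earlier; this guarantees monotone NROY shrinkage and is standard
  history-matching practice.
* **NROY size estimation.** Monte-Carlo fraction over a fixed Sobol'
  reference set (default 10,000 points) drawn once at run start; fixing
  the set makes overlap statistics between runs well defined. Wave-1
  candidates skip past the reference points so the two sets are disjoint.
* **Strict inequality** $I(\mathbf{x}) < T$ keeps membership
  bit-reproducible; the boundary has measure zero.
* **Batch selection.** How the per-wave batch is chosen from NROY is
  unstated in the method; greedy maximin (farthest-point) keeps the batch
  space-filling inside the surviving region.
* **Cloud technique.** New candidates are parents plus
  $s\,r \cdot \mathbf{z}$, $\mathbf{z}$ standard normal, rejected if they
  leave the cube or fail the previous waves' cuts; the scale
  ($s = 0.05$ in unit-cube units by default) is multiplied by the round
  index $r$, expanding the search towards the NROY boundary. The cap
  (50 rounds) returns fewer points with a warning rather than looping
  forever. Scale, offspring count (5) and cap are configurable; the
  original description fixes none of them.
* **Target uncertainty from deterministic simulations** uses
  $\sigma_i = c\,|\mu_i|$ with $c = 0.10$ by default and $c = 0.05$ as the
  low-uncertainty variant for sensitivity analyses.

Diagnostics mirror the usual reporting: NROY size as % of the original
space, the variance quotient
$VQ(\mathbf{x}) = \max_i \mathbb{V}ar[f_i(\mathbf{x})]/\sigma_i^2$
(max/median over NROY), per-parameter frequency maps, and agreement
between two NROY classifications (whole-space % and the % of one region
contained in the other; an empty region reports `NA` rather than 0/0).

## Reusing emulators across subjects

Because every subject lives in the same space, a bank trained for one
subject can score a new subject's targets directly: `reuse_calibrate()`
applies a donor bank to recipient targets in a single cut at the final
threshold, running **zero** new simulations. This is the package's
headline economy — a clinic holding one subject's simulation bank can
constrain a new patient's parameter space immediately. `l1_farthest()`
supports the stress test of reusing across maximally dissimilar subjects
(by inputs, or by z-scored biomarkers).

## The synthetic test bed

`simulate_biomarkers()` is a deterministic closed-form map from the unit
cube to four biomarkers (TAT and TAT-LV-endo in ms, LV mass in g, an LV
dimension in mm). It is *structurally* motivated — activation time scales
with heart size over conduction velocity, modulated by $k_{xf}$ and
$k_{FEC}$; endocardial activation is a bounded fraction of total
activation shortened by the FEC layer; anatomy weights decay with mode
number — and its TAT range (≈54–122 ms over the cube) brackets the
literature target 76.4 ± 8.2 ms. Synthetic patients draw ground truths
uniformly from $[0.15, 0.85]^{14}$, away from the cube boundary where GP
extrapolation degrades, mirroring interior cohort members.

What passing tests on this bed *show*: the machinery is correct — the GP
matches a dense oracle, implausibility matches a scalar oracle, NROY
shrinks monotonically, known ground truths are retained, reuse
out-performs a size-matched random baseline, and everything is
deterministic under a fixed seed. What they *do not* show: performance on
finite-element EP simulations. The synthetic map is far smoother and lower
in effective dimension than a real simulator, so emulator accuracy here is
optimistic and the NROY percentages are not comparable to those of any
real cohort (with four tightly coupled, low-noise biomarkers and
$c = 0.10$, the synthetic NROY stabilizes around 65–85 % of the cube).
Plug in a real simulator via the callback (or `csv_simulator()` for
precomputed runs) to learn anything about real hearts.

## Problem sizes and budgets

The shipped defaults reproduce the reference protocol (280/70/88 initial
split, 140 per wave, 10,000 candidates and reference points). Tests and
the acceptance script run the same code at reduced scale — typically 80
initial training points, 40 per wave, 2,000 candidates/reference points,
2 optimizer restarts — chosen so a full 3-wave run takes seconds while
leaving every qualitative property (shrinkage, truth retention, reuse
gains) intact.

## Known limitations

* Independent univariate GPs per biomarker; no correlated multi-output
  emulation, no sparse approximations (fits are exact, $O(n^3)$).
* No MCMC posterior sampling inside NROY and no emulator-discrepancy
  inflation beyond the fitted noise term.
* Sobol' direction numbers are provided for up to 19 dimensions; larger
  spaces need an extended table.
* The wave schedule is fixed in advance; a convergence-based stopping rule
  (only lowering the threshold once NROY size stabilizes) is a natural
  extension.
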