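---
title: "Multisensory integration as latent-variable density estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multisensory integration as latent-variable density estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ppcharm)
```

## The problem

When a reach is guided by both vision and proprioception, the brain receives
two noisy reports of the same hand location, expressed in different
coordinate systems (retinal/Cartesian versus joint angles). Statistically
optimal use of the two cues requires more than averaging point estimates: a
downstream population must carry the full posterior distribution over the
stimulus — mean *and* uncertainty — because the uncertainty sets the weight
the estimate should receive in any later computation.

`ppcharm` implements a model in which this ability is *learned* without
supervision, as a by-product of density estimation: a two-layer
energy-based network (an exponential-family harmonium) is trained to model
the joint distribution of its two input populations' spike counts. Because
the only compact explanation of the correlated activity is the underlying
hand location (and the per-trial reliabilities), a hidden layer half the
size of the input layer is forced to encode exactly those quantities — the
posterior mean and the information needed for the posterior covariance.

## The world model

**Population codes.** A stimulus $s$ is encoded by a population of neurons
with isotropic Gaussian tuning curves on a regular grid and independent
Poisson spike counts:
$$ r_i \sim \mathrm{Poisson}\!\big(g\, e^{-\|s-\tilde s_i\|^2 / 2\sigma_{tc}^2}\big), $$
where $\tilde s_i$ is the preferred stimulus and the gain $g$ (the maximum
mean spike count) is redrawn on every trial, uniformly on $[12, 18]$ spikes.
The gain plays the role of cue reliability: the single-population posterior
over $s$ is approximately Gaussian with covariance
$\sigma_{tc}^2 / n \cdot I$, where $n$ is the total spike count, itself
proportional to the gain.

Two layout rules fix the geometry. The preferred stimuli cover a *response
area* plus a margin of 4 tuning-curve standard deviations on every side, so
that edge stimuli are still represented without clipping; and the tuning
width is set so that the full width at half maximum of a curve covers 1/6
of the response-area extent (geometric mean across dimensions). A useful
identity following from these rules is that the single-population posterior
variance equals $\Delta_1 \Delta_2 / (2\pi g)$ in the population's own
space, with $\Delta_k$ the grid spacings — independent of the tuning width.

**Arm geometry.** The planar two-link arm has limb lengths 12 cm (upper
arm) and 20 cm (forearm); the fingertip position is
$x = (L_1 \cos\theta_1 + L_2\cos(\theta_1{+}\theta_2),\;
L_1 \sin\theta_1 + L_2\sin(\theta_1{+}\theta_2))$.
The default joint limits are shoulder $[\pi/4,\, 3\pi/4]$ and elbow
$[\pi/3,\, 5\pi/6]$. We chose these ranges (they are configurable) under
three constraints: (i) $\sin\theta_2 > 0$ over the whole elbow range, so
the Jacobian determinant $L_1 L_2 \sin\theta_2$ never vanishes and the
forward map restricted to the limits is injective; (ii) the workspace is
genuinely curved (the induced single-cue covariances are anisotropic and
misaligned between modalities, which is what makes integration
non-trivial); and (iii) with 30×30-unit populations the single-population
posterior variances fall in the low-millimetre-squared range (roughly 2–9
mm²) across the gain range — the regime in which the local linearization
of the kinematics underlying the Gaussian posterior is accurate, and which
matches psychophysical localization variances. Constraint (iii) follows
directly from the $\Delta_1\Delta_2/(2\pi g)$ identity above, so it pinned
the admissible workspace size before any network was trained.

**The optimal posterior.** With a flat (or Gaussian) prior in joint space,
the posterior over joint angles given both populations is approximately
Gaussian. Its precision is a sum of three terms — prior precision, the
proprioceptive tuning precision weighted by the prop total count
$n_p/\sigma_{tc,p}^2\, I$, and the visual precision warped into joint space
by the Jacobian, $n_v/\sigma_{tc,v}^2\, J^\top J$ — and its mean is the
precision-weighted combination of the prior mean, the prop center of mass,
and the inverse-kinematics image of the vis center of mass. $J$ is
evaluated at the prop center of mass (falling back to the vis-derived
estimate when prop is silent). `integration_posterior()` implements this;
the test suite verifies it against a brute-force numerical posterior (fine
local grid, exact Poisson likelihood, gains marginalized by quadrature) to
within 2% covariance error.

## The network

The harmonium has Poisson visible units (exponential inverse link, rates
capped at `rate_cap`) and Bernoulli hidden units (logistic inverse link),
connected by a single weight matrix with no intralayer connections:
$$ p(v_j = 1 \mid r) = \sigma(b_{h,j} + W_{\cdot j}^\top r), \qquad
   E[r_i \mid v] = \min\!\big(e^{b_{v,i} + W_{i\cdot} v},\ \text{cap}\big). $$
Training is one-step contrastive divergence: propagate data up, sample the
hidden layer, reconstruct the visible layer by a Poisson draw, propagate
back up, and update each weight by the difference between the data-phase
and reconstruction-phase correlations. The negative-phase hidden statistics
use conditional means rather than samples (the standard variance-reduction
choice; `sample_negative = TRUE` restores full sampling).

**Schedule.** Six stages of 15 epochs each (90 epochs total), minibatches
of 40, learning rates annealed by 0.8 after each stage. A fresh 40,000-
vector batch is generated for each stage, so the network never sees the
same noise twice. The stated stage structure admits two readings ("seven
times" versus 90 epochs); we use 6 × 15 = 90, which is self-consistent.

**Numerical choices.**

* Initial learning rate 1e-2 for weights and biases. No value is given in
  the source protocol (the schedule was "determined empirically"); we tuned
  this on reconstruction deviance and decoding quality of the small
  (12×12-input) configuration. At 5e-4, CD-1 is still far from convergence
  after 90 epochs at these problem sizes. The stable rate scales inversely
  with total visible activity: the coordinate-transformation network, whose
  proprioceptive gain is ~3× higher, defaults to 1e-3.
* Visible biases are initialized to `log(mean count + 0.01)` so the initial
  generative model matches the data marginals; weights start at
  $N(0, 0.01^2)$, hidden biases at zero.
* `rate_cap` (default 54 = 3× the top gain) guards the exponential link
  against early-training blow-ups. It does not bind after the first stage
  on default configurations; it is a numerical guard, not part of the
  model being studied.
* Non-finite parameters abort training with a diagnostic rather than
  propagating.

**Decoding.** At test time the hidden code is the average of 15 Bernoulli
samples (`n_samples = Inf` uses the conditional means — the
infinite-sample limit). The generative weights map the hidden code back to
expected input counts; the center of mass of the decoded prop population
is the joint-space estimate, and the same precision-weighted combination
used for the optimal posterior — fed with decoded centers of mass and
decoded total counts — is the model posterior. The posterior path uses no
trained decoder. Only the total-spike-count *reporting* metric uses a
calibration regressor (a one-hidden-layer network, 32 logistic units,
linear output, fit by `nnet` with a validation split selecting the
iteration budget), trained on trials disjoint from those evaluated.

## Evaluation

* **Error statistics.** Marginal (and per-stimulus-bin conditional) bias
  and covariance of four estimators: vis-only, prop-only, optimal, model.
* **Covariance transmission.** The covariance-only KL divergence from the
  optimal posterior, compared against a *fixed average-count* posterior
  that knows the mean totals but no trial-by-trial reliability — the floor
  for a network that had learned only the count prior.
* **Fractional information loss.** The normalized KL divergence
  $KL(\text{opt}\,\|\,\text{model}) / KL(\text{opt}\,\|\,\text{prior})$,
  0 when the decoded posterior equals the optimal posterior and 1 when it
  has degraded to the prior. The exact printed normalization is not
  recoverable from the source text; this ratio is the simple form
  consistent with the stated 0/1 endpoints. For flat priors the
  denominator uses a moment-matched Gaussian over the joint box (a flat
  prior has no finite KL). Within a gain bin we report the ratio of
  bin-summed numerators to bin-summed denominators, which is the
  trial-averaged loss fraction robust to individual near-zero denominators.

## Variant experiments

* **Prior learning** (`run_prior_experiment`): stimuli drawn from a tight
  Gaussian in joint space (extreme angles 150 prior SDs apart, per
  dimension). The decoder is unchanged, so the centering bias and the
  shrunken error covariance of the decoded estimates can only come from
  the trained weights.
* **Sometimes-decoupled inputs** (`run_decoupled`): the visual population
  reports the same hand only with probability `p_couple` (default 0.5; the
  source value is not recoverable), with one dedicated, observed toggle
  unit firing at the visual gain on decoupled trials. The benchmark is the
  condition-aware optimal estimator, whose marginal error covariance is
  the probability-weighted mixture of the two conditional covariances.
* **Hierarchical integration** (`run_hierarchical`): a second harmonium is
  trained on the first one's hidden activity concatenated with a third
  population (PROP 2, same joint-space code with its own gain). Whether
  the stage-1 activity fed forward is the 15-sample count, the average,
  or single samples is genuinely open; we feed stage 2 single Bernoulli
  sample vectors during training — the spikes as they occur trial by
  trial, which is also what a downstream circuit would see — and the
  15-sample average at test, modelling the channel as low-rate Poisson.
  We also evaluated the summed-count variant (integer counts in 0..15,
  Poisson with cap 15): it transmits markedly less information at our
  problem sizes, because the Poisson reconstruction noise of CD-1 is far
  larger than the underdispersed count channel's own variability.
* **Coordinate transformation** (`run_coordtrans`): the 1D arm
  ($H_b = 32\cos\theta$ cm) with gaze angle $E$. Following the generative
  story that vision reports the *retinal* position, the retinal position
  $X_r$ and gaze $E$ are the independent uniform draws (default
  $[-14, 14]$ cm each) and $H_b = X_r + E$; the 1D joint limits
  $[0.4, \pi - 0.4]$ keep every $H_b$ reachable. Proprioception therefore
  covers a larger space than the other populations, and its gain is raised
  (U[36, 54] against U[12, 18]) so its cue still contributes; the source
  states the raise but not the values. 60 units per population (180
  visible), 160 hidden.

## Hidden-unit analyses

`tuning_curves()` computes noiseless response maps (means in both layers,
fixed gain 15). A unit is *tuned* when its firing probability ranges over
more than 0.1 on the analysis domain — computed per domain (full planar
workspace or the constant-elbow arc of reach endpoints), never inherited
across domains. `active_fraction()` quantifies sharpening: the fraction of
hidden units firing within 15 samples falls as gain rises, while the input
layer's active fraction rises.

`reference_frame_analysis()` builds each tuned unit's response over a
rectangle of (body-centered position, gaze); separability is the squared
first-singular-value energy fraction of the mean-centered response matrix
(threshold 0.95), and the reference frame is the gradient-magnitude-
weighted axial circular mean of the response-gradient direction, binned at
15°. The analysis rectangle must sit inside the parallelogram of sampled
$(H_b, E)$ pairs; the default is the largest centered axis-aligned
rectangle ($|H_b|, |E| \le 7$ cm), and the choice is a configuration knob
recorded in the output, because the resulting histogram is known to depend
on it. The separability statistic in the cited electrophysiology analysis
is not reproduced verbatim; the SVD energy ratio is our explicit stand-in.

## Problem sizes

Three presets (`integration_config()`): `"standard"` is the full-size
model (two 30×30 inputs, 900 hidden, 40k vectors per stage, 40k test
trials). The package's own reported numbers (and `scripts/acceptance.R`)
use `"reduced"` — two 20×20 inputs, 400 hidden, 20k vectors per stage,
4000 test trials — which preserves every structural property of the
standard network (same tuning rules, same gain range, same 90-epoch
schedule) at roughly a tenth of the compute; a full run of the standard
network takes a few hours on one CPU and is unchanged code, just
`integration_config("standard")`. Property-style tests use `"scaled"`
(two 12×12 inputs, 144 hidden). Determinant-ratio assertions use a 1.5×
tolerance factor encoding "nearly optimal"; the source gives no numeric
tolerance, and the factor is reported, not hidden.

## What the generator does and does not emulate

The synthetic world isolates the computational problem: uniform tiling,
identical isotropic tuning curves, independent Poisson noise, trial-wise
constant gains, and an invertible kinematics. Real sensory populations
violate all of these (heterogeneous tuning, correlated noise, temporal
dynamics, redundant kinematics). Passing tests therefore demonstrate that
the learning rule extracts and preserves posterior information under the
stated encoding model — not that it would do so for arbitrary neural data.
Comparisons with recorded cortical data are limited to qualitative
signatures (multimodal planar tuning, gain-dependent sharpening, the
spread of reference frames between eye- and body-centered).

## Known limitations

* The Gaussian optimal posterior is itself an approximation, valid because
  the workspace keeps single-cue errors in the kinematics' linear regime;
  at the extreme edges of joint space the decoded and optimal estimates
  both degrade (edge effects of the finite grid).
* The unsignalled decoupled case (posterior a mixture of Gaussians with no
  observable toggle) is out of scope, as is any fully unsupervised
  mixture decoding.
* All-zero-count trials are undecodable and are dropped (and counted); at
  gains ≥ 12 they essentially never occur.
* CD-1 is a biased approximation to the density-estimation gradient; we
  monitor only reconstruction deviance and decoding quality, not the true
  likelihood.
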