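# ppcharm

Multisensory integration, prior learning, hierarchical cue combination and
coordinate transformation, learned from scratch by latent-variable density
estimation — an R implementation of a probabilistic-population-code world
model coupled to an exponential-family harmonium (Poisson visible units,
Bernoulli hidden units) trained with one-step contrastive divergence.

## The scientific problem

Vision and proprioception both report hand position, in different spaces
(Cartesian vs joint angles), with trial-varying reliability. Optimal use of
the two cues means preserving the full posterior over the stimulus, not
just a point estimate. For Gaussian-tuned, independent-Poisson population
codes with per-trial gains g drawn uniformly on [12, 18] spikes,

    r_i ~ Poisson( g * exp(-||s - s_i||^2 / (2 sigma_tc^2)) ),

the posterior over joint angles given both populations is approximately
Gaussian, with precision

    Sigma^-1 = Sigma_prior^-1 + (n_p / sigma_p^2) I + (n_v / sigma_v^2) J'J

(n_p, n_v the per-population total spike counts; J the arm Jacobian at the
proprioceptive center of mass) and mean the precision-weighted combination
of the prior mean, the prop center of mass and the back-transformed vis
center of mass.

The package asks whether a generic density estimator — a harmonium with a
hidden layer *half* the size of its input layer, trained only to model the
distribution of input spike counts by CD-1 — ends up carrying this
posterior in its hidden units. Decoding goes through the generative
weights: hidden activity (the average of 15 Bernoulli samples) is mapped
back to expected input counts, and the same closed-form combination above
is applied to the decoded populations. Evaluation compares the decoded
posterior against the optimal one by error covariances, covariance-only KL
divergence, and the fractional information loss
KL(opt || model) / KL(opt || prior).

## A worked example

Train the scaled two-cue network (two 12x12 Poisson populations encoding a
planar two-link arm, 144 hidden units) and evaluate it on fresh trials:

```r
library(ppcharm)
cfg <- integration_config("scaled", n_stages = 4)
rep <- run_integration(cfg, seed = 11)
print(rep)
#> evaluation_report (integration), 2000 test trials (0 dropped)
#>   model    bias (6.3e-05, 0.000229) det(cov) 1.61e-07
#>   optimal  bias (0.000638, -0.000609) det(cov) 1.32e-07
#>   prop     bias (0.000581, -0.000327) det(cov) 3.45e-07
#>   vis      bias (0.00141, -0.000954) det(cov) 2.81e-06
#>   info loss: mean 3.028%, max gain bin 3.415%
#>   totals R^2 (calibrated): 0.645, 0.597
```

Reading the output: the decoded ("model") estimator is unbiased (bias in
radians, ~1e-4 against joint ranges of ~1.6) and its marginal error
covariance is close to the optimal estimator's (det ratio ~1.2) and far
below either single-cue estimator — near-optimal integration. The decoded
posterior loses only ~3% of the information the inputs carried about the
stimulus (0 = perfect transmission, 100% = posterior collapsed to the
prior), and the per-trial total spike counts — the quantities that set
each cue's weight — are recoverable from the hidden layer (R^2 per
population on held-out trials; at this small 144-hidden-unit scale the
count readout is noisy, rising above 0.8 for the reduced 400-hidden-unit
network used by the acceptance script).

The other protocols are one call each: `run_prior_experiment()` (Gaussian
stimulus prior learned into the weights), `run_decoupled()` (an observed
toggle signals when vision reports the other hand), `run_hierarchical()`
(a second harmonium integrates a third population with the first hidden
layer), `run_coordtrans()` (1D arm plus gaze: body-centered position from
retinal position and eye position), and the hidden-unit analyses
`tuning_curves()`, `active_fraction()`, `reference_frame_analysis()`.
A thin command-line wrapper is in `inst/cli/ppcharm-run.R`.

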