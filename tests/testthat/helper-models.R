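# Trained models are expensive, so the suite trains each configuration once
# per session and reuses it across test files (training is deterministic
# given the seed, so caching does not change any result).

.model_cache <- new.env(parent = emptyenv())

cached <- function(key, fn) {
  if (!exists(key, envir = .model_cache)) {
    assign(key, fn(), envir = .model_cache)
  }
  get(key, envir = .model_cache)
}

# scaled two-cue network used by most property checks (12x12 inputs,
# 144 hidden, 60 epochs on fresh 10k batches)
scaled_cfg <- function(...) integration_config("scaled", n_stages = 4, ...)

scaled_trained <- function() cached("scaled_trained", function()
  train_integration(scaled_cfg(), seed = 11))

scaled_report <- function() cached("scaled_report", function()
  run_integration(scaled_cfg(), seed = 11, trained = scaled_trained()))

prior_report <- function() cached("prior_report", function()
  run_prior_experiment(scaled_cfg(prior = "gaussian-joint"), seed = 11))

decoupled_report <- function() cached("decoupled_report", function()
  run_decoupled(scaled_cfg(), seed = 11))

hierarchical_report <- function() cached("hierarchical_report", function()
  run_hierarchical(scaled_cfg(), seed = 11, trained = scaled_trained()))

coordtrans_report <- function() cached("coordtrans_report", function()
  run_coordtrans(coordtrans_config("standard"), seed = 11))

# reduced-scale network (20x20 inputs, 400 hidden, full 90-epoch schedule)
# for the headline information-loss and count-recovery checks
reduced_report <- function() cached("reduced_report", function()
  run_integration(integration_config("reduced"), seed = 11))

# A hand-built 1D coordinate-transformation harmonium with three planted
# hidden units: one reading only the prop population (body-centered), one
# only the eye population (gaze), one only the vis population (retinal).
planted_model <- function(arm, pops, gain = 15, hb_range = c(-7, 7),
                          e_range = c(-7, 7)) {
  V <- sum(sapply(pops, function(p) p$n_units))
  m <- harmonium(V, 3, rate_cap = 200, w_sd = 0)
  bump <- function(pop, center)
    exp(-(pop$preferred[, 1] - center)^2 / (2 * pop$sigma_tc^2))
  lay <- list(prop = 1:60, vis = 61:120, eye = 121:180)
  m$W[lay$prop, 1] <- bump(pops$prop, pi / 2)   # body-centered (H_b ~ 0)
  m$W[lay$eye, 2] <- bump(pops$eye, 0)          # pure gaze
  m$W[lay$vis, 3] <- bump(pops$vis, 0)          # pure retinal
  # rescale each unit so its net input swings +/- 3 over the analysis
  # rectangle, putting the logistic response through its full range
  hb <- seq(hb_range[1], hb_range[2], length.out = 21)
  ee <- seq(e_range[1], e_range[2], length.out = 21)
  grid <- expand.grid(hb = hb, e = ee)
  R <- matrix(0, nrow(grid), V)
  R[, lay$prop] <- mean_rates(pops$prop,
                              matrix(inverse_1d(grid$hb, arm), ncol = 1), gain)
  R[, lay$vis] <- mean_rates(pops$vis, matrix(grid$hb - grid$e, ncol = 1), gain)
  R[, lay$eye] <- mean_rates(pops$eye, matrix(grid$e, ncol = 1), gain)
  act <- R %*% m$W
  for (u in 1:3) {
    span <- range(act[, u])
    scale <- 6 / diff(span)
    m$W[, u] <- m$W[, u] * scale
    m$b_hid[u] <- -mean(span) * scale
  }
  list(model = m, layout = lay)
}
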