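# Reproducible experiment protocols. Every experiment is a pure function of
# (config, seed): data generation, training and evaluation each draw from a
# purpose-keyed seed stream so re-running reproduces the report exactly.

#' Configuration for the two-cue integration experiments
#'
#' Three presets are provided. \code{"standard"} is the full-size model (two
#' 30x30 input populations, 900 hidden units, six 15-epoch stages on fresh
#' 40000-vector batches); \code{"reduced"} (two 20x20 inputs, 400 hidden,
#' 20000 vectors) trains in minutes on one CPU and is the scale at which the
#' headline numbers are recomputed; \code{"scaled"} (two 12x12 inputs, 144
#' hidden, 10000 vectors, 30 epochs) is the fast scale used for
#' property-style checks.
#'
#' @param scale preset name.
#' @param ... named overrides of any config entry.
#' @return a config list.
#' @export
integration_config <- function(scale = c("scaled", "reduced", "standard"), ...) {
  scale <- match.arg(scale)
  base <- switch(scale,
    standard = list(units_per_dim = 30, n_hidden = 900,
                    n_vectors = 40000, n_stages = 6, n_test = 40000),
    reduced  = list(units_per_dim = 20, n_hidden = 400,
                    n_vectors = 20000, n_stages = 6, n_test = 4000),
    scaled   = list(units_per_dim = 12, n_hidden = 144,
                    n_vectors = 10000, n_stages = 2, n_test = 2000))
  cfg <- c(base, list(
    scale = scale,
    epochs_per_stage = 15, minibatch = 40,
    lr_w = 1e-2, lr_bias = 1e-2, anneal = 0.8,
    gain_lo = 12, gain_hi = 18,
    prior = "uniform-joint", sd_span = 150,
    p_couple = 0.5,
    n_samples = 15, rate_cap = 54,
    gain_bins = 3,
    arm = list()))
  override <- list(...)
  for (nm in names(override)) {
    if (!nm %in% names(cfg)) stop("unknown config entry: ", nm)
    cfg[[nm]] <- override[[nm]]
  }
  cfg
}

.cfg_arm <- function(config) do.call(arm_model, config$arm)

.cfg_gains <- function(config)
  list(prop = gain_prior(config$gain_lo, config$gain_hi),
       vis = gain_prior(config$gain_lo, config$gain_hi))

.cfg_prior <- function(config, arm) {
  if (identical(config$prior, "gaussian-joint"))
    tight_gaussian_prior(arm, config$sd_span)
  else stimulus_prior("uniform-joint")
}

.cfg_schedule <- function(config)
  training_schedule(n_vectors = config$n_vectors, minibatch = config$minibatch,
                    epochs_per_stage = config$epochs_per_stage,
                    n_stages = config$n_stages, lr_w = config$lr_w,
                    lr_bias = config$lr_bias, anneal = config$anneal)

# train an integration-style harmonium on batches from batch_fn(stage)
.train_on <- function(config, seed, n_visible, batch_fn) {
  set.seed(seed_stream(seed, "init"))
  model <- harmonium(n_visible, config$n_hidden, rate_cap = config$rate_cap)
  gen <- function(stage) {
    set.seed(seed_stream(seed, paste0("train-data-", stage)))
    batch_fn(stage)
  }
  set.seed(seed_stream(seed, "gibbs"))
  train_harmonium(model, gen, .cfg_schedule(config))
}

#' Train the standard integration network
#'
#' @param config from \code{\link{integration_config}}.
#' @param seed master seed.
#' @param stim_prior stimulus prior used for the training data.
#' @return list with \code{model}, \code{arm}, \code{pops}.
#' @export
train_integration <- function(config, seed,
                              stim_prior = NULL) {
  arm <- .cfg_arm(config)
  pops <- integration_populations(arm, config$units_per_dim)
  if (is.null(stim_prior)) stim_prior <- .cfg_prior(config, arm)
  gp <- .cfg_gains(config)
  n_vis <- pops$prop$n_units + pops$vis$n_units
  model <- .train_on(config, seed, n_vis, function(stage)
    sample_integration_batch(config$n_vectors, arm, pops, gp, stim_prior)$counts)
  list(model = model, arm = arm, pops = pops, stim_prior = stim_prior)
}

# Per-trial evaluation shared by the integration-style experiments.
# Returns estimator errors in joint space, per-trial KL divergences and
# recovered/true totals. Undecodable trials (no spikes in a needed
# population) are dropped and counted.
.evaluate_trials <- function(model, test, pops, arm, config, vbar,
                             prior = NULL, theta_true = NULL) {
  n <- test$n
  if (is.null(theta_true)) theta_true <- test$stimuli$theta
  layout <- test$layout[setdiff(names(test$layout), "toggle")]
  prior_proxy <- flat_prior_proxy(arm$joint_limits)
  cp <- test$counts[, layout$prop, drop = FALSE]
  cv <- test$counts[, layout$vis, drop = FALSE]
  com_p <- center_of_mass(cp, pops$prop)
  com_v <- center_of_mass(cv, pops$vis)
  out <- list(
    opt_mean = matrix(NA_real_, n, 2), model_mean = matrix(NA_real_, n, 2),
    prop_mean = com_p, vis_mean_joint = matrix(NA_real_, n, 2),
    opt_cov = matrix(NA_real_, n, 4), model_cov = matrix(NA_real_, n, 4),
    kl_full = rep(NA_real_, n), kl_cov = rep(NA_real_, n),
    kl_prior = rep(NA_real_, n), kl_cov_fixed = rep(NA_real_, n),
    totals_true = cbind(prop = rowSums(cp), vis = rowSums(cv)),
    totals_raw = matrix(NA_real_, n, 2, dimnames = list(NULL, c("prop", "vis"))))
  dropped <- 0L
  for (i in seq_len(n)) {
    opt <- integration_posterior(cp[i, ], cv[i, ], pops, arm, prior)
    mod <- decode_posterior(model, vbar[i, ], pops, test$layout, arm, prior)
    if (is.null(opt) || is.null(mod)) {
      dropped <- dropped + 1L
      next
    }
    out$opt_mean[i, ] <- opt$mean
    out$opt_cov[i, ] <- as.numeric(opt$covariance)
    out$model_mean[i, ] <- mod$mean
    out$model_cov[i, ] <- as.numeric(mod$covariance)
    out$kl_full[i] <- gaussian_kl(opt, mod)
    out$kl_cov[i] <- gaussian_kl(opt, mod, cov_only = TRUE)
    out$kl_prior[i] <- gaussian_kl(opt, prior_proxy)
    dec <- decode_expected_inputs(model, vbar[i, ], test$layout)
    out$totals_raw[i, ] <- c(sum(dec$prop), sum(dec$vis))
    out$vis_mean_joint[i, ] <- tryCatch(inverse_kinematics(com_v[i, ], arm),
                                        error = function(e) c(NA_real_, NA_real_))
  }
  # fixed-average-count posterior: Eq-3 covariance with across-trial mean
  # totals (and the trial's optimal mean), the floor any code that has only
  # learned the count prior could reach
  ok <- !is.na(out$kl_full)
  nbar <- colMeans(out$totals_true[ok, , drop = FALSE])
  for (i in which(ok)) {
    J <- jacobian(.clamp_theta(out$opt_mean[i, ], arm), arm)
    P <- nbar[1] / pops$prop$sigma_tc^2 * diag(2) +
      nbar[2] / pops$vis$sigma_tc^2 * crossprod(J)
    if (!is.null(prior)) P <- P + solve(prior$covariance)
    fixed <- gaussian_posterior(out$opt_mean[i, ], solve(P))
    opt_i <- gaussian_posterior(out$opt_mean[i, ],
                                matrix(out$opt_cov[i, ], 2, 2))
    out$kl_cov_fixed[i] <- gaussian_kl(opt_i, fixed, cov_only = TRUE)
  }
  out$theta_true <- theta_true
  out$dropped <- dropped
  out$ok <- ok
  out
}

.marginal_stats <- function(err) {
  ok <- stats::complete.cases(err)
  list(bias = colMeans(err[ok, , drop = FALSE]),
       cov = stats::cov(err[ok, , drop = FALSE]),
       n = sum(ok))
}

.bin_info_loss <- function(ev, gains, config) {
  brk <- seq(config$gain_lo, config$gain_hi, length.out = config$gain_bins + 1)
  bp <- cut(pmin(pmax(gains$prop, config$gain_lo), config$gain_hi),
            brk, include.lowest = TRUE, labels = FALSE)
  bv <- cut(pmin(pmax(gains$vis, config$gain_lo), config$gain_hi),
            brk, include.lowest = TRUE, labels = FALSE)
  ok <- ev$ok
  agg <- tapply(seq_along(bp)[ok], list(bp[ok], bv[ok]), function(ix)
    sum(ev$kl_full[ix]) / sum(ev$kl_prior[ix]))
  agg
}

#' Run the standard two-cue integration experiment
#'
#' Trains the integration harmonium, evaluates it on a fresh test batch and
#' reports marginal error statistics for the four estimators (vis-only,
#' prop-only, optimal, model), covariance-only KL divergences against the
#' optimal posterior (model vs the fixed average-count computation),
#' fractional information loss per gain bin, and total-spike-count recovery
#' with and without the calibration regressor (fit on a disjoint first half
#' of the test trials, evaluated on the second half).
#'
#' @param config from \code{\link{integration_config}}.
#' @param seed master seed.
#' @param trained optional result of \code{\link{train_integration}} to
#'   reuse a trained network.
#' @return an \code{evaluation_report} list.
#' @export
run_integration <- function(config = integration_config(), seed = 1,
                            trained = NULL) {
  if (is.null(trained)) trained <- train_integration(config, seed)
  model <- trained$model; arm <- trained$arm; pops <- trained$pops
  prior <- if (identical(config$prior, "gaussian-joint"))
    trained$stim_prior else NULL
  set.seed(seed_stream(seed, "test-data"))
  test <- sample_integration_batch(config$n_test, arm, pops,
                                   .cfg_gains(config), trained$stim_prior)
  set.seed(seed_stream(seed, "decode"))
  vbar <- hidden_code(model, test$counts, config$n_samples)
  ev <- .evaluate_trials(model, test, pops, arm, config, vbar, prior)
  err <- function(est) est - ev$theta_true
  marg <- list(model = .marginal_stats(err(ev$model_mean)),
               optimal = .marginal_stats(err(ev$opt_mean)),
               prop = .marginal_stats(err(ev$prop_mean)),
               vis = .marginal_stats(err(ev$vis_mean_joint)))
  loss_bins <- .bin_info_loss(ev, test$gains, config)
  # count recovery: calibrator on the first half, R^2 on the second
  ok <- which(ev$ok)
  half <- ok[seq_len(floor(length(ok) / 2))]
  rest <- setdiff(ok, half)
  set.seed(seed_stream(seed, "calibrator"))
  cal <- fit_count_calibrator(ev$totals_raw[half, ], ev$totals_true[half, ],
                              vbar = vbar[half, , drop = FALSE])
  pred <- stats::predict(cal, ev$totals_raw[rest, ],
                         vbar = vbar[rest, , drop = FALSE])
  r2 <- function(truth, est)
    1 - colSums((truth - est)^2) / colSums(sweep(truth, 2, colMeans(truth))^2)
  r2_cal <- r2(ev$totals_true[rest, ], pred)
  r2_raw <- r2(ev$totals_true[rest, ], ev$totals_raw[rest, ])
  structure(list(
    kind = "integration", config = config, seed = seed,
    marginal = marg,
    info_loss = list(by_gain_bin = loss_bins,
                     max_bin = max(loss_bins, na.rm = TRUE),
                     mean = sum(ev$kl_full[ev$ok]) / sum(ev$kl_prior[ev$ok])),
    kl_cov = list(model = mean(ev$kl_cov[ev$ok]),
                  fixed_average_counts = mean(ev$kl_cov_fixed[ev$ok])),
    totals_r2 = list(calibrated = r2_cal, raw = r2_raw,
                     min_calibrated = min(r2_cal)),
    calibrator = cal,
    n_test = test$n, dropped = ev$dropped,
    trained = trained, eval = ev),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation_report (%s), %d test trials (%d dropped)\n",
              x$kind, x$n_test, x$dropped))
  if (!is.null(x$marginal)) {
    for (nm in names(x$marginal)) {
      m <- x$marginal[[nm]]
      cat(sprintf("  %-8s bias (%s) det(cov) %.3g\n", nm,
                  paste(signif(m$bias, 3), collapse = ", "), det(m$cov)))
    }
  }
  if (!is.null(x$info_loss))
    cat(sprintf("  info loss: mean %.3f%%, max gain bin %.3f%%\n",
                100 * x$info_loss$mean, 100 * x$info_loss$max_bin))
  if (!is.null(x$totals_r2))
    cat(sprintf("  totals R^2 (calibrated): %s\n",
                paste(signif(x$totals_r2$calibrated, 3), collapse = ", ")))
  invisible(x)
}

#' Capacity and hidden-noise sweep
#'
#' Trains one network per hidden-layer size and decodes the posterior mean
#' with each number of hidden samples, reporting the determinant of the
#' marginal error covariance (plus the infinite-sample, hidden-means decode
#' for each size).
#'
#' @param hidden_sizes integer vector of hidden-layer sizes.
#' @param sample_counts integer vector of hidden sample counts (\code{Inf}
#'   allowed).
#' @param config,seed as in \code{\link{run_integration}}.
#' @return data frame with columns \code{n_hidden}, \code{n_samples},
#'   \code{det_error_cov}, plus the optimal and prop-only reference dets as
#'   attributes.
#' @export
run_capacity_sweep <- function(hidden_sizes, sample_counts,
                               config = integration_config(), seed = 1) {
  arm <- .cfg_arm(config)
  pops <- integration_populations(arm, config$units_per_dim)
  sp <- .cfg_prior(config, arm)
  set.seed(seed_stream(seed, "test-data"))
  test <- sample_integration_batch(config$n_test, arm, pops,
                                   .cfg_gains(config), sp)
  rows <- list()
  ref <- NULL
  for (h in hidden_sizes) {
    cfg_h <- config
    cfg_h$n_hidden <- h
    tr <- train_integration(cfg_h, seed)
    for (s in sample_counts) {
      set.seed(seed_stream(seed, paste0("decode-", h, "-", s)))
      vbar <- hidden_code(tr$model, test$counts, s)
      est <- t(vapply(seq_len(test$n), function(i)
        decode_posterior_mean(tr$model, vbar[i, ], pops, test$layout),
        numeric(2)))
      m <- .marginal_stats(est - test$stimuli$theta)
      rows[[length(rows) + 1L]] <-
        data.frame(n_hidden = h, n_samples = s, det_error_cov = det(m$cov))
    }
  }
  out <- do.call(rbind, rows)
  # reference estimators on the same test data
  cp <- test$counts[, test$layout$prop, drop = FALSE]
  cv <- test$counts[, test$layout$vis, drop = FALSE]
  opt <- t(vapply(seq_len(test$n), function(i) {
    p <- integration_posterior(cp[i, ], cv[i, ], pops, arm)
    if (is.null(p)) c(NA_real_, NA_real_) else p$mean
  }, numeric(2)))
  attr(out, "det_optimal") <-
    det(.marginal_stats(opt - test$stimuli$theta)$cov)
  attr(out, "det_prop") <-
    det(.marginal_stats(center_of_mass(cp, pops$prop) - test$stimuli$theta)$cov)
  out
}

#' Generalization to discrepant and gain-modulated inputs
#'
#' A single trained network is evaluated on test batches whose
#' proprioceptive input is shifted by \code{k_sd} standard deviations of the
#' summed input covariance and/or whose gains are drawn from ranges outside
#' the training regime.
#'
#' @param k_sds numeric vector of discrepancy magnitudes (0 = none).
#' @param gain_ranges list of named lists with \code{prop} and \code{vis}
#'   \code{\link{gain_prior}}s; \code{NULL} for the training gains only.
#' @param config,seed as in \code{\link{run_integration}}.
#' @param trained optional pre-trained network.
#' @return data frame with one row per (k_sd, gain range) condition,
#'   recording model and optimal error means and covariance determinants and
#'   the cosine similarity between the model and optimal mean displacements.
#' @export
run_generalization <- function(k_sds = c(0, 2.5, 5, 7.5), gain_ranges = NULL,
                               config = integration_config(), seed = 1,
                               trained = NULL) {
  if (is.null(trained)) trained <- train_integration(config, seed)
  model <- trained$model; arm <- trained$arm; pops <- trained$pops
  if (is.null(gain_ranges)) gain_ranges <- list(train = .cfg_gains(config))
  if (is.null(names(gain_ranges)))
    names(gain_ranges) <- paste0("g", seq_along(gain_ranges))
  rows <- list()
  for (gnm in names(gain_ranges)) {
    for (k in k_sds) {
      set.seed(seed_stream(seed, paste0("gen-", gnm, "-", k)))
      test <- if (k > 0)
        sample_discrepant_batch(config$n_test, arm, pops, k_sd = k,
                                gain_priors = gain_ranges[[gnm]])
      else sample_integration_batch(config$n_test, arm, pops,
                                    gain_ranges[[gnm]])
      vbar <- hidden_code(model, test$counts, config$n_samples)
      ev <- .evaluate_trials(model, test, pops, arm, config, vbar)
      e_mod <- .marginal_stats(ev$model_mean - ev$theta_true)
      e_opt <- .marginal_stats(ev$opt_mean - ev$theta_true)
      cossim <- if (sqrt(sum(e_mod$bias^2)) * sqrt(sum(e_opt$bias^2)) > 0)
        sum(e_mod$bias * e_opt$bias) /
          (sqrt(sum(e_mod$bias^2)) * sqrt(sum(e_opt$bias^2)))
      else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        gains = gnm, k_sd = k,
        model_bias_1 = e_mod$bias[1], model_bias_2 = e_mod$bias[2],
        opt_bias_1 = e_opt$bias[1], opt_bias_2 = e_opt$bias[2],
        det_model = det(e_mod$cov), det_opt = det(e_opt$cov),
        bias_cosine = cossim,
        mean_gap = sqrt(mean(rowSums((ev$model_mean - ev$opt_mean)^2),
                             na.rm = TRUE)))
    }
  }
  do.call(rbind, rows)
}

#' Prior-learning experiment
#'
#' Trains with a tight Gaussian joint-space prior over the stimulus (extreme
#' angles \code{sd_span} prior SDs apart); the decoder is unchanged, so any
#' bias toward the prior mean must have been learned into the weights. The
#' optimal benchmark includes the prior-precision term.
#'
#' @param config,seed as in \code{\link{run_integration}} (the config's
#'   \code{prior} entry is forced to \code{"gaussian-joint"}).
#' @return an \code{evaluation_report}.
#' @export
run_prior_experiment <- function(config = integration_config(), seed = 1) {
  config$prior <- "gaussian-joint"
  run_integration(config, seed)
}

#' Sometimes-decoupled-inputs experiment
#'
#' Trains on data in which the visual population reports the same hand as
#' proprioception only with probability \code{p_couple}, with an observed
#' toggle unit signalling decoupled trials. The decoded posterior over the
#' "right hand" is compared against the condition-aware optimal estimator,
#' whose marginal error covariance is the probability-weighted average of
#' the coupled (integrated) and uncoupled (prop-only) covariances.
#'
#' @param config,seed as in \code{\link{run_integration}}.
#' @return an \code{evaluation_report} with per-condition statistics.
#' @export
run_decoupled <- function(config = integration_config(), seed = 1) {
  arm <- .cfg_arm(config)
  pops <- integration_populations(arm, config$units_per_dim)
  gp <- .cfg_gains(config)
  sp <- stimulus_prior("uniform-joint")
  n_vis <- pops$prop$n_units + pops$vis$n_units + 1L
  model <- .train_on(config, seed, n_vis, function(stage)
    sample_decoupled_batch(config$n_vectors, arm, pops, config$p_couple,
                           gp, sp)$counts)
  set.seed(seed_stream(seed, "test-data"))
  test <- sample_decoupled_batch(config$n_test, arm, pops, config$p_couple,
                                 gp, sp)
  set.seed(seed_stream(seed, "decode"))
  vbar <- hidden_code(model, test$counts, config$n_samples)
  coupled <- test$meta$coupled
  n <- test$n
  cp <- test$counts[, test$layout$prop, drop = FALSE]
  cv <- test$counts[, test$layout$vis, drop = FALSE]
  model_mean <- matrix(NA_real_, n, 2)
  opt_mean <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    mod <- decode_posterior(model, vbar[i, ], pops, test$layout, arm)
    if (!is.null(mod)) model_mean[i, ] <- mod$mean
    opt <- if (coupled[i])
      integration_posterior(cp[i, ], cv[i, ], pops, arm)
    else single_population_posterior(cp[i, ], pops$prop)
    if (!is.null(opt)) opt_mean[i, ] <- opt$mean
  }
  theta <- test$stimuli$theta
  m_all <- .marginal_stats(model_mean - theta)
  o_all <- .marginal_stats(opt_mean - theta)
  o_c <- .marginal_stats((opt_mean - theta)[coupled, , drop = FALSE])
  o_u <- .marginal_stats((opt_mean - theta)[!coupled, , drop = FALSE])
  m_c <- .marginal_stats((model_mean - theta)[coupled, , drop = FALSE])
  mix_cov <- decoupled_optimal_covariance(o_c$cov, o_u$cov,
                                          mean(coupled))
  structure(list(kind = "decoupled", config = config, seed = seed,
                 marginal = list(model = m_all, optimal = o_all),
                 coupled_only = list(model = m_c, optimal = o_c),
                 uncoupled_optimal = o_u,
                 mixture_cov = mix_cov,
                 p_couple_empirical = mean(coupled),
                 n_test = n, dropped = sum(is.na(model_mean[, 1])),
                 model = model, arm = arm, pops = pops, layout = test$layout),
            class = "evaluation_report")
}

#' Hierarchical (two-stage) integration experiment
#'
#' Stage 1 is the standard integration network. Stage 2 is trained on a
#' visible layer made of the stage-1 hidden activity concatenated with a
#' third population, PROP 2, that encodes the same joint angles with its
#' own gain. During training the stage-1 channel carries single Bernoulli
#' sample vectors — the hidden spikes as they occur trial by trial — and at
#' test time the usual 15-sample average is fed in their place; the channel
#' is modeled as low-rate Poisson. Decoding goes back through both
#' generative maps, and the three decoded populations are combined by the
#' usual precision weighting.
#'
#' @param config,seed as in \code{\link{run_integration}}.
#' @param trained optional pre-trained stage-1 network.
#' @return an \code{evaluation_report} comparing stage-1, stage-2, two-cue
#'   optimal and three-cue optimal error statistics.
#' @export
run_hierarchical <- function(config = integration_config(), seed = 1,
                             trained = NULL) {
  if (is.null(trained)) trained <- train_integration(config, seed)
  model1 <- trained$model; arm <- trained$arm; pops <- trained$pops
  gp <- .cfg_gains(config)
  sp <- trained$stim_prior
  pop2 <- population_code("prop2", arm$joint_limits, config$units_per_dim)
  ns <- config$n_samples
  stage2_batch <- function(n, hidden_samples = 1) {
    b <- sample_integration_batch(n, arm, pops, gp, sp)
    v1 <- hidden_code(model1, b$counts, hidden_samples)
    if (hidden_samples == 1) v1 <- round(v1)    # binary spike vectors
    g2 <- sample_gains(gp$prop, n)
    c2 <- encode(pop2, b$stimuli$theta, g2)
    list(counts = cbind(v1, c2), theta = b$stimuli$theta, batch1 = b)
  }
  cap2 <- rep(c(3, config$rate_cap),     # stage-1 channel is 0/1 spikes
              c(model1$n_hidden, pop2$n_units))
  cfg2 <- config
  set.seed(seed_stream(seed, "init-2"))
  model2 <- harmonium(model1$n_hidden + pop2$n_units, model1$n_hidden,
                      rate_cap = cap2)
  gen <- function(stage) {
    set.seed(seed_stream(seed, paste0("train2-data-", stage)))
    stage2_batch(cfg2$n_vectors)$counts
  }
  set.seed(seed_stream(seed, "gibbs-2"))
  model2 <- train_harmonium(model2, gen, .cfg_schedule(cfg2))
  # evaluation: the stage-1 channel now carries the 15-sample average
  set.seed(seed_stream(seed, "test-data-2"))
  tb <- stage2_batch(config$n_test, hidden_samples = ns)
  set.seed(seed_stream(seed, "decode-2"))
  vbar2 <- hidden_code(model2, tb$counts, ns)
  vbar1 <- hidden_code(model1, tb$batch1$counts, ns)
  layout1 <- tb$batch1$layout
  lay2 <- list(hidden1 = seq_len(model1$n_hidden),
               prop2 = model1$n_hidden + seq_len(pop2$n_units))
  cp1 <- tb$batch1$counts[, layout1$prop, drop = FALSE]
  cv1 <- tb$batch1$counts[, layout1$vis, drop = FALSE]
  c2 <- tb$counts[, lay2$prop2, drop = FALSE]
  n <- config$n_test
  est1 <- matrix(NA_real_, n, 2)   # stage-1 model
  est2 <- matrix(NA_real_, n, 2)   # stage-2 model
  opt2cue <- matrix(NA_real_, n, 2)
  opt3cue <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    est1[i, ] <- decode_posterior_mean(model1, vbar1[i, ], pops, layout1)
    dec2 <- decode_expected_inputs(model2, vbar2[i, ], lay2)
    vbar1_hat <- pmin(pmax(dec2$hidden1, 0), 1)
    dec1 <- decode_expected_inputs(model1, vbar1_hat, layout1)
    p <- cue_posterior(list(
      list(counts = dec1$prop, pop = pops$prop, frame = "joint"),
      list(counts = dec1$vis, pop = pops$vis, frame = "cartesian"),
      list(counts = dec2$prop2, pop = pop2, frame = "joint")), arm)
    if (!is.null(p)) est2[i, ] <- p$mean
    o2 <- integration_posterior(cp1[i, ], cv1[i, ], pops, arm)
    if (!is.null(o2)) opt2cue[i, ] <- o2$mean
    o3 <- cue_posterior(list(
      list(counts = cp1[i, ], pop = pops$prop, frame = "joint"),
      list(counts = cv1[i, ], pop = pops$vis, frame = "cartesian"),
      list(counts = c2[i, ], pop = pop2, frame = "joint")), arm)
    if (!is.null(o3)) opt3cue[i, ] <- o3$mean
  }
  theta <- tb$theta
  structure(list(kind = "hierarchical", config = config, seed = seed,
                 marginal = list(stage1 = .marginal_stats(est1 - theta),
                                 stage2 = .marginal_stats(est2 - theta),
                                 optimal_2cue = .marginal_stats(opt2cue - theta),
                                 optimal_3cue = .marginal_stats(opt3cue - theta)),
                 n_test = n, dropped = sum(is.na(est2[, 1])),
                 model2 = model2),
            class = "evaluation_report")
}

#' Configuration for the coordinate-transformation experiment
#'
#' The full-size model from the 1D arm-plus-gaze setting: 60 units per input
#' population (180 visible), 160 hidden units.
#'
#' @param scale \code{"standard"} (60 units/population, 160 hidden) or
#'   \code{"scaled"} (reduced training set for fast checks).
#' @param ... named overrides.
#' @return a config list.
#' @export
coordtrans_config <- function(scale = c("standard", "scaled"), ...) {
  scale <- match.arg(scale)
  base <- switch(scale,
    standard = list(n_vectors = 40000, n_stages = 6, n_test = 4000),
    scaled   = list(n_vectors = 10000, n_stages = 2, n_test = 2000))
  cfg <- c(base, list(
    scale = scale,
    units_per_pop = 60, n_hidden = 160,
    epochs_per_stage = 15, minibatch = 40,
    # the raised proprioceptive gain makes total visible activity ~2-3x the
    # integration network's, so the stable CD-1 rate is lower here
    lr_w = 1e-3, lr_bias = 1e-3, anneal = 0.8,
    range_x = c(-14, 14), range_e = c(-14, 14),
    gain_prop = c(36, 54), gain_vis = c(12, 18), gain_eye = c(12, 18),
    n_samples = 15, rate_cap = 162,    # 3x the top proprioceptive gain
    arm = list()))
  override <- list(...)
  for (nm in names(override)) {
    if (!nm %in% names(cfg)) stop("unknown config entry: ", nm)
    cfg[[nm]] <- override[[nm]]
  }
  cfg
}

#' Coordinate-transformation experiment (1D arm plus gaze)
#'
#' Trains the 180-visible / 160-hidden network on the three 1D populations
#' (joint angle, retinal hand position, gaze angle) and reports mean square
#' errors of the decoded body-centered hand position for the model, the
#' three-cue optimal posterior mean, and the two single-route estimators
#' (proprioception through the cosine map; vision plus eye position).
#'
#' @param config from \code{\link{coordtrans_config}}.
#' @param seed master seed.
#' @return an \code{evaluation_report} with the MSE table (cm^2).
#' @export
run_coordtrans <- function(config = coordtrans_config("scaled"), seed = 1) {
  arm <- .cfg_arm(config)
  pops <- coordtrans_populations(arm, config$range_x, config$range_e,
                                 config$units_per_pop)
  gp <- list(prop = gain_prior(config$gain_prop[1], config$gain_prop[2]),
             vis = gain_prior(config$gain_vis[1], config$gain_vis[2]),
             eye = gain_prior(config$gain_eye[1], config$gain_eye[2]))
  n_vis <- sum(vapply(pops, function(p) p$n_units, 1L))
  model <- .train_on(config, seed, n_vis, function(stage)
    sample_coordtrans_batch(config$n_vectors, arm, pops, config$range_x,
                            config$range_e, gp)$counts)
  set.seed(seed_stream(seed, "test-data"))
  test <- sample_coordtrans_batch(config$n_test, arm, pops, config$range_x,
                                  config$range_e, gp)
  set.seed(seed_stream(seed, "decode"))
  vbar <- hidden_code(model, test$counts, config$n_samples)
  lay <- test$layout
  n <- test$n
  est <- rep(NA_real_, n)
  opt <- rep(NA_real_, n)
  prop_route <- rep(NA_real_, n)
  viseye_route <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    dec <- decode_expected_inputs(model, vbar[i, ], lay)
    p <- coordtrans_posterior(dec$prop, dec$vis, dec$eye, pops, arm)
    if (!is.null(p)) est[i] <- p$mean
    cp <- test$counts[i, lay$prop]
    cv <- test$counts[i, lay$vis]
    ce <- test$counts[i, lay$eye]
    o <- coordtrans_posterior(cp, cv, ce, pops, arm)
    if (!is.null(o)) opt[i] <- o$mean
    if (sum(cp) > 0)
      prop_route[i] <- arm$link_1d *
        cos(drop(center_of_mass(cp, pops$prop)))
    if (sum(cv) > 0 && sum(ce) > 0)
      viseye_route[i] <- drop(center_of_mass(cv, pops$vis)) +
        drop(center_of_mass(ce, pops$eye))
  }
  hb <- test$stimuli$body
  mse <- function(e) mean((e - hb)^2, na.rm = TRUE)
  structure(list(kind = "coordtrans", config = config, seed = seed,
                 mse = c(model = mse(est), optimal = mse(opt),
                         prop_route = mse(prop_route),
                         viseye_route = mse(viseye_route)),
                 n_test = n, dropped = sum(is.na(est)),
                 model = model, arm = arm, pops = pops, layout = lay),
            class = "evaluation_report")
}
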