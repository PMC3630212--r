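# Trial-batch generators: the world model that produces all training and
# testing data. A trial_batch records the true stimuli, per-trial gains, the
# concatenated spike-count matrix and the column layout of its populations.

new_trial_batch <- function(n, stimuli, gains, counts, layout, meta = list()) {
  structure(list(n = n, stimuli = stimuli, gains = gains, counts = counts,
                 layout = layout, meta = meta),
            class = "trial_batch")
}

#' @export
print.trial_batch <- function(x, ...) {
  cat(sprintf("trial_batch: %d trials, %d visible units (%s)\n",
              x$n, ncol(x$counts),
              paste(sprintf("%s:%d", names(x$layout),
                            vapply(x$layout, length, 1L)), collapse = ", ")))
  invisible(x)
}

.layout_from_pops <- function(pops, extra = 0L) {
  sizes <- vapply(pops, function(p) p$n_units, 1L)
  if (extra > 0L) sizes <- c(sizes, extra)
  ends <- cumsum(sizes)
  starts <- c(1L, ends[-length(ends)] + 1L)
  layout <- mapply(function(s, e) seq.int(s, e), starts, ends, SIMPLIFY = FALSE)
  names(layout) <- c(names(pops), if (extra > 0L) "toggle" else NULL)
  layout
}

#' Sample a two-cue integration batch
#'
#' On each trial a hand location is drawn from the stimulus prior in joint
#' space and a gain for each modality from its gain prior; the proprioceptive
#' population encodes the joint angles and the visual population encodes the
#' fingertip position given by the forward kinematics. Spike counts are
#' independent Poisson draws.
#'
#' @param n number of trials.
#' @param arm an \code{\link{arm_model}}.
#' @param pops list with \code{prop} and \code{vis}
#'   \code{\link{population_code}}s (see
#'   \code{\link{integration_populations}}).
#' @param gain_priors list of \code{\link{gain_prior}}s named as \code{pops}.
#' @param stim_prior a \code{\link{stimulus_prior}} over joint space.
#' @return a \code{trial_batch}.
#' @export
sample_integration_batch <- function(n, arm, pops,
                                     gain_priors = list(prop = gain_prior(),
                                                        vis = gain_prior()),
                                     stim_prior = stimulus_prior("uniform-joint")) {
  theta <- sample_stimuli(stim_prior, n, arm)
  x <- if (n > 0) forward_kinematics(theta, arm) else matrix(0, 0, 2)
  g_p <- sample_gains(gain_priors$prop, n)
  g_v <- sample_gains(gain_priors$vis, n)
  counts <- cbind(encode(pops$prop, theta, g_p),
                  encode(pops$vis, x, g_v))
  if (n == 0) counts <- matrix(0L, 0, pops$prop$n_units + pops$vis$n_units)
  new_trial_batch(n, list(theta = theta, x = x),
                  list(prop = g_p, vis = g_v), counts,
                  .layout_from_pops(pops))
}

# single-population posterior covariances (joint space) at the workspace
# center with median gains; their sum sets the natural discrepancy scale
.input_cov_scale <- function(arm, pops, gain_priors) {
  th0 <- rowMeans(arm$joint_limits)
  g0p <- mean(c(gain_priors$prop$lo, gain_priors$prop$hi))
  g0v <- mean(c(gain_priors$vis$lo, gain_priors$vis$hi))
  n_p <- sum(mean_rates(pops$prop, th0, g0p))
  n_v <- sum(mean_rates(pops$vis, forward_kinematics(th0, arm), g0v))
  J <- jacobian(th0, arm)
  Sp <- diag(2) * pops$prop$sigma_tc^2 / n_p
  Jin <- solve(J)
  Sv <- Jin %*% (diag(2) * pops$vis$sigma_tc^2 / n_v) %*% t(Jin)
  Sp + Sv
}

#' Sample a batch with a fixed proprioceptive-visual discrepancy
#'
#' Replicates the prism-goggle style manipulation: before encoding, the joint
#' angles seen by the proprioceptive population are displaced by a fixed
#' vector \code{delta = k_sd * sd * direction}, where \code{sd} is the
#' standard deviation of the summed single-population posterior covariances
#' along \code{direction} (evaluated at the workspace center with median
#' gains). The visual population still encodes the unshifted hand position.
#' Trials whose shifted angles leave the joint limits are resampled (the
#' number of resamples is recorded), so the prior over the true stimulus is
#' unchanged.
#'
#' @inheritParams sample_integration_batch
#' @param k_sd discrepancy magnitude in units of that standard deviation
#'   (e.g. 2.5, 5, 7.5).
#' @param direction unit vector in joint space (default along the shoulder
#'   angle).
#' @return a \code{trial_batch}; \code{meta$delta} holds the applied shift.
#' @export
sample_discrepant_batch <- function(n, arm, pops, k_sd,
                                    direction = c(1, 0),
                                    gain_priors = list(prop = gain_prior(),
                                                       vis = gain_prior()),
                                    stim_prior = stimulus_prior("uniform-joint")) {
  if (k_sd < 0) stop("k_sd must be nonnegative")
  direction <- direction / sqrt(sum(direction^2))
  S <- .input_cov_scale(arm, pops, gain_priors)
  sd_dir <- sqrt(drop(direction %*% S %*% direction))
  delta <- k_sd * sd_dir * direction
  lim <- arm$joint_limits
  theta <- matrix(0, n, 2)
  filled <- 0L
  resampled <- 0L
  while (filled < n) {
    m <- n - filled
    cand <- sample_stimuli(stim_prior, m, arm)
    shifted <- sweep(cand, 2, delta, "+")
    ok <- shifted[, 1] >= lim[1, 1] & shifted[, 1] <= lim[1, 2] &
          shifted[, 2] >= lim[2, 1] & shifted[, 2] <= lim[2, 2]
    k <- sum(ok)
    if (k > 0) theta[filled + seq_len(k), ] <- cand[ok, , drop = FALSE]
    filled <- filled + k
    resampled <- resampled + (m - k)
  }
  x <- forward_kinematics(theta, arm)
  theta_prop <- sweep(theta, 2, delta, "+")
  g_p <- sample_gains(gain_priors$prop, n)
  g_v <- sample_gains(gain_priors$vis, n)
  counts <- cbind(encode(pops$prop, theta_prop, g_p),
                  encode(pops$vis, x, g_v))
  new_trial_batch(n, list(theta = theta, x = x, theta_prop = theta_prop),
                  list(prop = g_p, vis = g_v), counts,
                  .layout_from_pops(pops),
                  meta = list(k_sd = k_sd, delta = delta,
                              direction = direction, resampled = resampled))
}

#' Sample a batch with sometimes-decoupled inputs
#'
#' With probability \code{p_couple} the visual population reports the same
#' hand as proprioception; otherwise it encodes an independently drawn "left
#' hand" and a dedicated toggle unit (appended as the last visible unit)
#' fires at the trial's visual gain (Poisson), signalling the decoupling.
#'
#' @inheritParams sample_integration_batch
#' @param p_couple probability that the two populations report the same hand.
#' @return a \code{trial_batch}; \code{meta$coupled} is the per-trial flag and
#'   \code{layout$toggle} the toggle column.
#' @export
sample_decoupled_batch <- function(n, arm, pops, p_couple = 0.5,
                                   gain_priors = list(prop = gain_prior(),
                                                      vis = gain_prior()),
                                   stim_prior = stimulus_prior("uniform-joint")) {
  if (p_couple < 0 || p_couple > 1) stop("p_couple must be in [0, 1]")
  theta <- sample_stimuli(stim_prior, n, arm)         # right hand
  theta_left <- sample_stimuli(stim_prior, n, arm)    # independent left hand
  coupled <- stats::runif(n) < p_couple
  theta_vis <- theta
  theta_vis[!coupled, ] <- theta_left[!coupled, , drop = FALSE]
  x_vis <- forward_kinematics(theta_vis, arm)
  g_p <- sample_gains(gain_priors$prop, n)
  g_v <- sample_gains(gain_priors$vis, n)
  toggle_mean <- ifelse(coupled, 0, g_v)
  counts <- cbind(encode(pops$prop, theta, g_p),
                  encode(pops$vis, x_vis, g_v),
                  stats::rpois(n, toggle_mean))
  new_trial_batch(n, list(theta = theta, x = forward_kinematics(theta, arm),
                          theta_vis = theta_vis, x_vis = x_vis),
                  list(prop = g_p, vis = g_v), counts,
                  .layout_from_pops(pops, extra = 1L),
                  meta = list(p_couple = p_couple, coupled = coupled))
}

#' Default 1D populations for the coordinate-transformation model
#'
#' Sixty units each for the joint angle (prop), the retinal hand position
#' (vis) and the gaze angle (eye).
#'
#' @param arm an \code{\link{arm_model}}.
#' @param range_x,range_e sampling intervals (cm) of the retinal position and
#'   gaze angle; these are also the response areas of the vis and eye
#'   populations.
#' @param units_per_pop neurons per population (default 60).
#' @return list with \code{prop}, \code{vis}, \code{eye}.
#' @export
coordtrans_populations <- function(arm, range_x = c(-14, 14),
                                   range_e = c(-14, 14), units_per_pop = 60) {
  list(prop = population_code("prop", arm$joint_limits_1d, units_per_pop),
       vis = population_code("vis", range_x, units_per_pop),
       eye = population_code("eye", range_e, units_per_pop))
}

#' Sample a coordinate-transformation batch (1D arm plus gaze)
#'
#' The retinal hand position \code{X_r} and the gaze angle \code{E} are drawn
#' independently and uniformly on their ranges; the body-centered position is
#' \code{X_b = X_r + E} and the joint angle is its inverse cosine map. The
#' configured ranges must keep \code{X_b} inside the 1D joint workspace.
#' Proprioception encodes the joint angle, vision the retinal position, and
#' the eye population the gaze angle. The proprioceptive gain is typically
#' raised relative to the others so that its cue still matters over its
#' larger response range.
#'
#' @param n number of trials.
#' @param arm an \code{\link{arm_model}} (1D fields are used).
#' @param pops list from \code{\link{coordtrans_populations}}.
#' @param range_x,range_e sampling intervals (cm).
#' @param gain_priors list of \code{\link{gain_prior}}s for \code{prop},
#'   \code{vis} and \code{eye} (defaults: prop U[36,54], others U[12,18]).
#' @return a \code{trial_batch}; \code{stimuli} records \code{theta},
#'   \code{eye}, \code{body} and \code{retinal}.
#' @export
sample_coordtrans_batch <- function(n, arm, pops,
                                    range_x = c(-14, 14), range_e = c(-14, 14),
                                    gain_priors = list(prop = gain_prior(36, 54),
                                                       vis = gain_prior(),
                                                       eye = gain_prior())) {
  lim <- arm$joint_limits_1d
  hb_max <- arm$link_1d * cos(lim[1])
  hb_min <- arm$link_1d * cos(lim[2])
  if (range_x[1] + range_e[1] < hb_min || range_x[2] + range_e[2] > hb_max)
    stop("sampling ranges allow body positions outside the 1D joint limits")
  xr <- stats::runif(n, range_x[1], range_x[2])
  ey <- stats::runif(n, range_e[1], range_e[2])
  hb <- xr + ey
  theta <- inverse_1d(hb, arm)
  g <- lapply(gain_priors, sample_gains, n = n)
  counts <- cbind(encode(pops$prop, matrix(theta, ncol = 1), g$prop),
                  encode(pops$vis, matrix(xr, ncol = 1), g$vis),
                  encode(pops$eye, matrix(ey, ncol = 1), g$eye))
  new_trial_batch(n, list(theta = theta, eye = ey, body = hb, retinal = xr),
                  g, counts, .layout_from_pops(pops),
                  meta = list(range_x = range_x, range_e = range_e))
}
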