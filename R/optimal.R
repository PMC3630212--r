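# Closed-form optimal posteriors over the stimulus given population spike
# counts, and the divergence metrics used to score decoded posteriors.

#' Gaussian posterior over the stimulus
#'
#' @param mean stimulus-space mean vector.
#' @param covariance symmetric positive-definite covariance (stimulus
#'   units^2).
#' @param space label of the coordinate space (e.g. \code{"joint"},
#'   \code{"cartesian"}, \code{"body"}).
#' @return an object of class \code{gaussian_posterior}.
#' @export
gaussian_posterior <- function(mean, covariance, space = "joint") {
  covariance <- as.matrix(covariance)
  covariance <- (covariance + t(covariance)) / 2
  if (any(!is.finite(mean)) || any(!is.finite(covariance)))
    stop("non-finite posterior moments")
  if (any(eigen(covariance, symmetric = TRUE, only.values = TRUE)$values <= 0))
    stop("posterior covariance must be positive definite")
  structure(list(mean = as.numeric(mean), covariance = covariance,
                 space = space), class = "gaussian_posterior")
}

#' @export
print.gaussian_posterior <- function(x, ...) {
  cat(sprintf("gaussian_posterior (%s): mean = (%s)\n", x$space,
              paste(signif(x$mean, 4), collapse = ", ")))
  print(signif(x$covariance, 4))
  invisible(x)
}

#' Center of mass of a population's spike counts
#'
#' The spike-count-weighted average of preferred stimuli, which is the
#' maximum-likelihood stimulus estimate for a single Gaussian-tuned Poisson
#' population.
#'
#' @param counts length-N count vector (or n x N matrix for many trials).
#' @param pop the \code{\link{population_code}} that produced the counts.
#' @return stimulus estimate(s); rows of all-zero counts give \code{NA}
#'   (undecodable trial, caller decides whether to drop).
#' @export
center_of_mass <- function(counts, pop) {
  if (is.null(dim(counts))) {
    tot <- sum(counts)
    if (tot <= 0) return(rep(NA_real_, ncol(pop$preferred)))
    drop(counts %*% pop$preferred) / tot
  } else {
    tot <- rowSums(counts)
    out <- (counts %*% pop$preferred) / tot
    out[tot <= 0, ] <- NA_real_
    out
  }
}

# clamp a joint-space point into the configured joint box (used as the
# Jacobian evaluation point when an estimate falls epsilon outside)
.clamp_theta <- function(theta, arm) {
  lim <- arm$joint_limits
  c(min(max(theta[1], lim[1, 1]), lim[1, 2]),
    min(max(theta[2], lim[2, 1]), lim[2, 2]))
}

#' Single-population Gaussian posterior (flat prior)
#'
#' Mean is the center of mass; the covariance is
#' \code{sigma_tc^2 / n} times the identity, with \code{n} the total spike
#' count, in the population's own space.
#'
#' @inheritParams center_of_mass
#' @return a \code{\link{gaussian_posterior}} in the population's space, or
#'   \code{NULL} for an undecodable (all-zero) trial.
#' @export
single_population_posterior <- function(counts, pop) {
  tot <- sum(counts)
  if (tot <= 0) return(NULL)
  d <- ncol(pop$preferred)
  gaussian_posterior(center_of_mass(counts, pop),
                     diag(d) * pop$sigma_tc^2 / tot,
                     space = pop$space_id)
}

#' Optimal posterior over joint angles from population cues
#'
#' Combines any number of population cues (plus an optional Gaussian prior)
#' into the Gaussian posterior over the stimulus in joint space. The
#' posterior precision is the sum of the prior precision and each cue's
#' weighted tuning-curve precision, where a cue's weight is its total spike
#' count; Cartesian cues are warped into joint space by the Jacobian of the
#' forward kinematics, evaluated at the proprioceptive center of mass (or,
#' if no joint-space cue has spikes, at the inverse-kinematics image of the
#' visual center of mass). The posterior mean is the precision-weighted
#' combination of the prior mean, the joint-space centers of mass, and the
#' back-transformed (inverse-kinematics) Cartesian centers of mass.
#'
#' @param cues list of cues; each cue is a list with elements \code{counts}
#'   (length-N vector), \code{pop} (a \code{\link{population_code}}) and
#'   \code{frame} (\code{"joint"} or \code{"cartesian"}).
#' @param arm an \code{\link{arm_model}}.
#' @param prior \code{NULL} for a flat prior, or a
#'   \code{\link{stimulus_prior}} of kind \code{"gaussian-joint"}.
#' @return a \code{\link{gaussian_posterior}} in joint space, or \code{NULL}
#'   when the precision is singular (no spikes anywhere and flat prior).
#' @export
cue_posterior <- function(cues, arm, prior = NULL) {
  d <- 2L
  P <- matrix(0, d, d)
  b <- rep(0, d)
  # linearization point for Cartesian cues
  theta0 <- NULL
  for (cue in cues) {
    if (identical(cue$frame, "joint") && sum(cue$counts) > 0) {
      theta0 <- .clamp_theta(center_of_mass(cue$counts, cue$pop), arm)
      break
    }
  }
  if (is.null(theta0)) {
    for (cue in cues) {
      if (identical(cue$frame, "cartesian") && sum(cue$counts) > 0) {
        com <- center_of_mass(cue$counts, cue$pop)
        theta0 <- tryCatch(.clamp_theta(inverse_kinematics(com, arm), arm),
                           error = function(e) NULL)
        break
      }
    }
  }
  if (!is.null(prior)) {
    if (!inherits(prior, "stimulus_prior") || prior$kind != "gaussian-joint")
      stop("prior must be NULL (flat) or a gaussian-joint stimulus_prior")
    P0 <- solve(prior$covariance)
    P <- P + P0
    b <- b + drop(P0 %*% prior$mean)
  }
  for (cue in cues) {
    n_tot <- sum(cue$counts)
    if (n_tot <= 0) next
    com <- center_of_mass(cue$counts, cue$pop)
    w <- n_tot / cue$pop$sigma_tc^2
    if (identical(cue$frame, "joint")) {
      P <- P + w * diag(d)
      b <- b + w * com
    } else if (identical(cue$frame, "cartesian")) {
      if (is.null(theta0)) next
      J <- jacobian(theta0, arm)
      JtJ <- crossprod(J)
      theta_cue <- tryCatch(inverse_kinematics(com, arm), error = function(e) NULL)
      if (is.null(theta_cue)) {
        # center of mass outside the reachable workspace (rare, edge trials):
        # fall back to the linearized inverse about theta0
        theta_cue <- theta0 + drop(solve(J, com - forward_kinematics(theta0, arm)))
      }
      P <- P + w * JtJ
      b <- b + w * drop(JtJ %*% theta_cue)
    } else stop("cue frame must be 'joint' or 'cartesian'")
  }
  if (all(P == 0)) return(NULL)
  ev <- eigen(P, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12 * max(ev)) return(NULL)
  S <- solve(P)
  gaussian_posterior(drop(S %*% b), S, space = "joint")
}

#' Two-cue optimal integration posterior
#'
#' Convenience wrapper around \code{\link{cue_posterior}} for the standard
#' proprioceptive + visual integration model.
#'
#' @param counts_prop,counts_vis spike-count vectors of the two populations.
#' @param pops list with \code{prop} and \code{vis} population codes.
#' @param arm an \code{\link{arm_model}}.
#' @param prior flat (\code{NULL}) or Gaussian joint-space prior.
#' @return a \code{\link{gaussian_posterior}} in joint space.
#' @export
integration_posterior <- function(counts_prop, counts_vis, pops, arm,
                                  prior = NULL) {
  cue_posterior(list(list(counts = counts_prop, pop = pops$prop, frame = "joint"),
                     list(counts = counts_vis, pop = pops$vis, frame = "cartesian")),
                arm, prior)
}

#' Optimal posterior over body-centered position for the 1D
#' coordinate-transformation model
#'
#' Combines the proprioceptive cue about the joint angle (mapped through the
#' local derivative of the cosine link) with the visual-plus-eye chain
#' \code{X_b = X_r + E} into a Gaussian posterior over the body-centered hand
#' position.
#'
#' @param counts_prop,counts_vis,counts_eye count vectors for the three 1D
#'   populations.
#' @param pops list from \code{\link{coordtrans_populations}}.
#' @param arm an \code{\link{arm_model}} (1D fields used).
#' @return a \code{\link{gaussian_posterior}} in the \code{"body"} space, or
#'   \code{NULL} if no cue constrains \code{X_b}.
#' @export
coordtrans_posterior <- function(counts_prop, counts_vis, counts_eye,
                                 pops, arm) {
  prec <- 0
  b <- 0
  n_p <- sum(counts_prop)
  if (n_p > 0) {
    th <- drop(center_of_mass(counts_prop, pops$prop))
    slope <- -arm$link_1d * sin(th)     # dX_b/dtheta at the prop estimate
    var_b <- slope^2 * pops$prop$sigma_tc^2 / n_p
    if (var_b > 0) {
      prec <- prec + 1 / var_b
      b <- b + arm$link_1d * cos(th) / var_b
    }
  }
  n_v <- sum(counts_vis)
  n_e <- sum(counts_eye)
  if (n_v > 0 && n_e > 0) {
    mu_chain <- drop(center_of_mass(counts_vis, pops$vis)) +
      drop(center_of_mass(counts_eye, pops$eye))
    var_chain <- pops$vis$sigma_tc^2 / n_v + pops$eye$sigma_tc^2 / n_e
    prec <- prec + 1 / var_chain
    b <- b + mu_chain / var_chain
  }
  if (prec <= 0) return(NULL)
  gaussian_posterior(b / prec, matrix(1 / prec), space = "body")
}

#' Mixture-averaged optimal error covariance for sometimes-decoupled inputs
#'
#' When the visual cue reports the same hand only a fraction
#' \code{p_couple} of the time (and an observed toggle signals which), the
#' optimal estimator's marginal error covariance is the probability-weighted
#' average of the coupled (integrated) and uncoupled (proprioception-only)
#' error covariances.
#'
#' @param cov_coupled,cov_uncoupled SPD error covariances in the two
#'   conditions.
#' @param p_couple probability of the coupled condition.
#' @return the weighted-average covariance matrix.
#' @export
decoupled_optimal_covariance <- function(cov_coupled, cov_uncoupled, p_couple) {
  if (p_couple < 0 || p_couple > 1) stop("p_couple must be in [0, 1]")
  for (S in list(cov_coupled, cov_uncoupled))
    if (any(eigen(as.matrix(S), symmetric = TRUE, only.values = TRUE)$values <= 0))
      stop("covariances must be symmetric positive definite")
  p_couple * as.matrix(cov_coupled) + (1 - p_couple) * as.matrix(cov_uncoupled)
}

#' KL divergence between two Gaussian posteriors
#'
#' \code{KL(p || q) = (tr(Sq^-1 Sp) + (mq-mp)' Sq^-1 (mq-mp) - d +
#' log(det Sq / det Sp)) / 2} in nats. With \code{cov_only = TRUE} the
#' mean-difference term is dropped, leaving only the divergence contributed
#' by the covariances.
#'
#' @param p,q \code{\link{gaussian_posterior}} objects over the same space.
#' @param cov_only drop the mean term?
#' @return divergence in nats (nonnegative).
#' @export
gaussian_kl <- function(p, q, cov_only = FALSE) {
  if (length(p$mean) != length(q$mean))
    stop("posteriors must have the same dimension")
  d <- length(p$mean)
  Sq_inv <- solve(q$covariance)
  term <- sum(diag(Sq_inv %*% p$covariance)) - d +
    determinant(q$covariance)$modulus - determinant(p$covariance)$modulus
  if (!cov_only) {
    dm <- q$mean - p$mean
    term <- term + drop(dm %*% Sq_inv %*% dm)
  }
  max(as.numeric(term) / 2, 0)
}

#' Moment-matched Gaussian proxy for a flat prior
#'
#' A flat prior has no finite KL divergence from a Gaussian, so the
#' information-loss denominator uses a Gaussian with the moments of the
#' uniform distribution over the response area: the box center and variance
#' \code{range^2 / 12} per dimension.
#'
#' @param bounds d x 2 matrix of per-dimension intervals (e.g. the joint
#'   limits).
#' @param space space label.
#' @return a \code{\link{gaussian_posterior}}.
#' @export
flat_prior_proxy <- function(bounds, space = "joint") {
  bounds <- rbind(bounds)
  gaussian_posterior(rowMeans(bounds),
                     diag((bounds[, 2] - bounds[, 1])^2 / 12,
                          nrow = nrow(bounds)),
                     space = space)
}

#' Fractional information loss
#'
#' The normalized KL divergence \code{KL(opt || model) / KL(opt || prior)}:
#' 0 when the decoded model posterior equals the optimal posterior, 1 when it
#' has degraded to the prior.
#'
#' @param opt,model,prior \code{\link{gaussian_posterior}} objects over the
#'   same space (for a flat prior pass \code{\link{flat_prior_proxy}}).
#' @return the loss fraction (dimensionless).
#' @export
info_loss_fraction <- function(opt, model, prior) {
  denom <- gaussian_kl(opt, prior)
  if (denom <= 0) stop("zero KL between optimal posterior and prior")
  gaussian_kl(opt, model) / denom
}
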