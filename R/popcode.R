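#' Gaussian-tuned Poisson population code
#'
#' A population of neurons whose preferred stimuli form a regular grid over a
#' "response area" plus a surrounding margin, with isotropic, unnormalized
#' Gaussian tuning curves and independent Poisson spike counts. The margin is
#' \code{margin_sd} tuning-curve standard deviations wide on every side, so
#' that stimuli at the edge of the response area still fall well inside the
#' grid. The tuning width is set so that the full width at half maximum of a
#' tuning curve covers \code{fwhm_fraction} of the response-area extent
#' (geometric mean across dimensions for anisotropic areas).
#'
#' @param space_id label of the encoded space, e.g. \code{"prop"}, \code{"vis"},
#'   \code{"eye"}.
#' @param bounds d x 2 matrix (or length-2 vector for 1D): per-dimension
#'   response-area interval, in stimulus units.
#' @param units_per_dim number of neurons along each dimension (scalar or
#'   length-d).
#' @param margin_sd margin width in units of the tuning-curve SD (default 4).
#' @param fwhm_fraction fraction of the response-area extent covered by the
#'   tuning-curve FWHM (default 1/6).
#' @return an object of class \code{population_code} with fields
#'   \code{preferred} (N x d grid of preferred stimuli), \code{sigma_tc}
#'   (tuning SD, stimulus units), \code{spacing} (per-dimension grid spacing),
#'   \code{n_units}, \code{bounds}, \code{grid_shape}.
#' @examples
#' pop <- population_code("vis", rbind(c(-30, 30), c(-30, 30)), 30)
#' pop$n_units  # 900
#' @export
population_code <- function(space_id, bounds, units_per_dim,
                            margin_sd = 4, fwhm_fraction = 1 / 6) {
  if (is.null(dim(bounds))) bounds <- matrix(bounds, ncol = 2L)
  d <- nrow(bounds)
  if (any(!is.finite(bounds)) || any(bounds[, 2] <= bounds[, 1]))
    stop("degenerate response-area bounds")
  units <- rep_len(as.integer(units_per_dim), d)
  if (any(units < 2L)) stop("need at least 2 units per dimension")
  extent <- bounds[, 2] - bounds[, 1]
  gm_extent <- exp(mean(log(extent)))
  # FWHM = 2*sqrt(2*log(2)) * sigma
  sigma <- gm_extent * fwhm_fraction / (2 * sqrt(2 * log(2)))
  lo <- bounds[, 1] - margin_sd * sigma
  hi <- bounds[, 2] + margin_sd * sigma
  axes <- lapply(seq_len(d), function(j) seq(lo[j], hi[j], length.out = units[j]))
  preferred <- as.matrix(expand.grid(axes))
  dimnames(preferred) <- NULL
  spacing <- (hi - lo) / (units - 1)
  structure(list(space_id = as.character(space_id),
                 preferred = preferred,
                 sigma_tc = sigma,
                 spacing = spacing,
                 grid_shape = units,
                 bounds = unname(bounds),
                 margin_sd = margin_sd,
                 n_units = nrow(preferred)),
            class = "population_code")
}

#' @export
print.population_code <- function(x, ...) {
  cat(sprintf("population_code '%s': %s units, sigma_tc = %.4g, margin = %g sd\n",
              x$space_id, paste(x$grid_shape, collapse = "x"), x$sigma_tc,
              x$margin_sd))
  invisible(x)
}

#' Mean spike counts of a population for given stimuli
#'
#' \code{rate_i = gain * exp(-||s - s_i||^2 / (2 sigma_tc^2))} for preferred
#' stimulus \code{s_i}; isotropic and unnormalized, so \code{gain} is the
#' maximum mean spike count.
#'
#' @param pop a \code{\link{population_code}}.
#' @param stimulus length-d vector or n x d matrix of stimuli.
#' @param gain per-trial gain: scalar or length-n (max mean spike count).
#' @return n x N matrix of mean counts (or a length-N vector for one stimulus).
#' @export
mean_rates <- function(pop, stimulus, gain) {
  vec <- is.null(dim(stimulus))
  if (vec) stimulus <- matrix(stimulus, ncol = ncol(pop$preferred))
  if (any(gain < 0)) stop("gain must be nonnegative")
  # squared distances via the expanded quadratic form (vectorized)
  p2 <- rowSums(pop$preferred^2)
  s2 <- rowSums(stimulus^2)
  d2 <- outer(s2, p2, "+") - 2 * stimulus %*% t(pop$preferred)
  d2[d2 < 0] <- 0
  rates <- gain * exp(-d2 / (2 * pop$sigma_tc^2))
  if (vec) drop(rates) else rates
}

#' Draw Poisson spike counts from a population
#'
#' @inheritParams mean_rates
#' @return integer count matrix (n x N) or vector for a single stimulus.
#' @export
encode <- function(pop, stimulus, gain) {
  mu <- mean_rates(pop, stimulus, gain)
  if (is.null(dim(mu))) {
    stats::rpois(length(mu), mu)
  } else {
    matrix(stats::rpois(length(mu), mu), nrow = nrow(mu))
  }
}

#' Uniform prior over population gains
#'
#' The gain of each modality is drawn independently and uniformly on
#' \code{[lo, hi]} spikes on every trial; it sets that population's maximum
#' mean spike count and hence the reliability of the cue.
#'
#' @param lo,hi interval of maximum mean spike counts (default 12 to 18).
#' @return an object of class \code{gain_prior}.
#' @export
gain_prior <- function(lo = 12, hi = 18) {
  if (lo < 0 || hi < lo) stop("invalid gain interval")
  structure(list(lo = lo, hi = hi), class = "gain_prior")
}

#' Draw per-trial gains from a gain prior
#'
#' @param prior a \code{\link{gain_prior}}.
#' @param n number of trials.
#' @return numeric vector of gains (spikes).
#' @export
sample_gains <- function(prior, n) stats::runif(n, prior$lo, prior$hi)

#' Prior over the stimulus
#'
#' Either uniform over the joint-angle box, Gaussian in joint space, or
#' uniform on a 1D interval.
#'
#' @param kind \code{"uniform-joint"}, \code{"gaussian-joint"} or
#'   \code{"uniform-1d"}.
#' @param mean joint-angle mean (Gaussian kind).
#' @param covariance 2x2 SPD covariance in rad^2 (Gaussian kind).
#' @param bounds box (d x 2) for the uniform kinds; defaults to the arm's
#'   joint limits when used by the samplers.
#' @return an object of class \code{stimulus_prior}.
#' @export
stimulus_prior <- function(kind = c("uniform-joint", "gaussian-joint", "uniform-1d"),
                           mean = NULL, covariance = NULL, bounds = NULL) {
  kind <- match.arg(kind)
  if (kind == "gaussian-joint") {
    if (is.null(mean) || is.null(covariance))
      stop("gaussian-joint prior needs mean and covariance")
    covariance <- (covariance + t(covariance)) / 2
    if (any(eigen(covariance, symmetric = TRUE, only.values = TRUE)$values <= 0))
      stop("prior covariance must be symmetric positive definite")
  }
  structure(list(kind = kind, mean = mean, covariance = covariance,
                 bounds = bounds), class = "stimulus_prior")
}

#' Gaussian joint-space prior tied to the joint ranges
#'
#' Builds the tight Gaussian prior used in the prior-learning experiment:
#' centered in the middle of joint space, with a per-dimension standard
#' deviation such that the extreme angles of each joint are
#' \code{sd_span} standard deviations apart (default 150).
#'
#' @param arm an \code{\link{arm_model}}.
#' @param sd_span number of prior SDs between the extreme angles.
#' @return a \code{\link{stimulus_prior}} of kind \code{"gaussian-joint"}.
#' @export
tight_gaussian_prior <- function(arm, sd_span = 150) {
  lim <- arm$joint_limits
  mu <- rowMeans(lim)
  sd <- (lim[, 2] - lim[, 1]) / sd_span
  stimulus_prior("gaussian-joint", mean = mu, covariance = diag(sd^2),
                 bounds = lim)
}

#' Draw stimuli from a stimulus prior
#'
#' @param prior a \code{\link{stimulus_prior}}.
#' @param n number of trials.
#' @param arm an \code{\link{arm_model}} supplying default bounds.
#' @return an n x d matrix of stimuli.
#' @export
sample_stimuli <- function(prior, n, arm) {
  bounds <- prior$bounds
  if (is.null(bounds)) bounds <- arm$joint_limits
  switch(prior$kind,
    "uniform-joint" = cbind(stats::runif(n, bounds[1, 1], bounds[1, 2]),
                            stats::runif(n, bounds[2, 1], bounds[2, 2])),
    "gaussian-joint" = {
      th <- MASS::mvrnorm(n, prior$mean, prior$covariance)
      th <- matrix(th, ncol = 2L)
      # truncate to the joint box (negligible mass at the default 150-sd span)
      for (j in 1:2) th[, j] <- pmin(pmax(th[, j], bounds[j, 1]), bounds[j, 2])
      th
    },
    "uniform-1d" = matrix(stats::runif(n, bounds[1], bounds[2]), ncol = 1L),
    stop("unknown prior kind"))
}

#' Default populations for the two-cue integration model
#'
#' Builds the proprioceptive population over the joint box and the visual
#' population over the (axis-aligned bounding box of the) reachable Cartesian
#' workspace of the arm.
#'
#' @param arm an \code{\link{arm_model}}.
#' @param units_per_dim neurons per dimension for each population (default 30,
#'   i.e. 30x30 = 900 units each).
#' @param margin_sd,fwhm_fraction passed to \code{\link{population_code}}.
#' @return list with elements \code{prop} and \code{vis}.
#' @export
integration_populations <- function(arm, units_per_dim = 30,
                                    margin_sd = 4, fwhm_fraction = 1 / 6) {
  prop <- population_code("prop", arm$joint_limits, units_per_dim,
                          margin_sd, fwhm_fraction)
  ws <- workspace_bounds(arm)
  vis <- population_code("vis", ws, units_per_dim, margin_sd, fwhm_fraction)
  list(prop = prop, vis = vis)
}

#' Axis-aligned bounding box of the reachable workspace
#'
#' @param arm an \code{\link{arm_model}}.
#' @param n grid resolution per joint used for the numerical bound.
#' @return 2 x 2 matrix of (lo, hi) rows for x and y (cm).
#' @export
workspace_bounds <- function(arm, n = 60L) {
  g1 <- seq(arm$joint_limits[1, 1], arm$joint_limits[1, 2], length.out = n)
  g2 <- seq(arm$joint_limits[2, 1], arm$joint_limits[2, 2], length.out = n)
  x <- forward_kinematics(as.matrix(expand.grid(g1, g2)), arm)
  rbind(range(x[, 1]), range(x[, 2]))
}
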