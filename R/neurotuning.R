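# Hidden-unit characterization: tuning curves, gain sharpening, and the
# reference-frame gradient/separability analysis. All analyses consume only
# the model parameters and stimulus grids — never training internals.

#' Noiseless hidden-unit tuning curves over a stimulus grid
#'
#' For each grid stimulus the visible means (no Poisson draw) of every
#' population are propagated through the recognition weights, yielding each
#' hidden unit's firing probability — one response map per unit.
#'
#' @param model a \code{\link{harmonium}}.
#' @param pops named list of population codes matching \code{layout}.
#' @param layout named list of visible column indices.
#' @param stimuli list of per-population stimulus matrices (one row per grid
#'   point, aligned across populations).
#' @param gain fixed gain applied to every population (default 15).
#' @return an n_grid x n_hidden matrix of firing probabilities.
#' @export
tuning_curves <- function(model, pops, layout, stimuli, gain = 15) {
  nm <- setdiff(names(layout), "toggle")
  n <- nrow(rbind(stimuli[[nm[1]]]))
  R <- matrix(0, n, model$n_visible)
  for (p in nm)
    R[, layout[[p]]] <- mean_rates(pops[[p]], rbind(stimuli[[p]]), gain)
  up_mean(model, R)
}

#' Which units are tuned?
#'
#' A unit counts as tuned when its firing probability varies by more than
#' \code{threshold} over the stimulus domain on which the curves were
#' computed.
#'
#' @param curves n_grid x n_units response matrix from
#'   \code{\link{tuning_curves}}.
#' @param threshold minimum response range (default 0.1).
#' @return logical vector, one entry per unit.
#' @export
tuned_mask <- function(curves, threshold = 0.1) {
  apply(curves, 2, function(y) diff(range(y)) > threshold)
}

#' Fraction of active units under sampled activity
#'
#' Draws \code{n_samples} hidden sample vectors per trial and counts the
#' fraction of hidden units with at least one spike; also reports the
#' fraction of input units with at least one spike in the same trials.
#' Sharper hidden tuning at higher gain shows up as a *decreasing* hidden
#' fraction, opposite to the input layer.
#'
#' @param model a \code{\link{harmonium}}.
#' @param counts n x V matrix of input spike counts.
#' @param n_samples hidden samples per trial (default 15).
#' @return list with \code{hidden} and \code{input} mean active fractions.
#' @export
active_fraction <- function(model, counts, n_samples = 15) {
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1L)
  ph <- up_mean(model, counts)
  none <- matrix(1, nrow(ph), ncol(ph))
  for (s in seq_len(n_samples))
    none <- none * ((stats::runif(length(ph)) >= ph) + 0)
  list(hidden = mean(1 - none), input = mean(counts > 0))
}

#' Tuning along the arc of reach endpoints
#'
#' The 1D submanifold of joint space with the elbow fixed at its mid-range
#' value maps to a constant-radius arc of fingertip positions; hidden-unit
#' tuning is computed noiselessly along it for each requested gain.
#'
#' @param model,pops,layout as in \code{\link{tuning_curves}}.
#' @param arm an \code{\link{arm_model}}.
#' @param gains gains at which to compute the curves (default 9, 15, 21).
#' @param n_arc number of arc points.
#' @return list with \code{theta} (arc joint angles), \code{xy} (Cartesian
#'   arc) and \code{responses}, a list of response matrices, one per gain.
#' @export
arc_tuning <- function(model, pops, layout, arm, gains = c(9, 15, 21),
                       n_arc = 50L) {
  lim <- arm$joint_limits
  th1 <- seq(lim[1, 1], lim[1, 2], length.out = n_arc)
  theta <- cbind(th1, mean(lim[2, ]))
  xy <- forward_kinematics(theta, arm)
  responses <- lapply(gains, function(g)
    tuning_curves(model, pops, layout,
                  list(prop = theta, vis = xy), gain = g))
  names(responses) <- paste0("gain", gains)
  list(theta = theta, xy = xy, responses = responses)
}

#' Reference-frame gradient and separability analysis
#'
#' Builds each tuned hidden unit's noiseless response over a rectangular
#' grid of (body-centered position \code{H_b}, gaze angle \code{E}), then
#' summarizes (1) separability — the energy fraction of the first singular
#' value of the mean-centered response matrix, near 1 for multiplicatively
#' separable (pure gain-field) units — and (2) the reference frame, as the
#' gradient-magnitude-weighted axial circular mean of the response-gradient
#' direction in the \code{(H_b, E)} plane. Angles near 0 degrees indicate
#' body-centered tuning, near +/-90 gaze tuning, near -45 retinotopic tuning
#' (\code{H_r = H_b - E}), and near +45 tuning for \code{H_b + E}.
#'
#' By default the rectangle is the largest centered axis-aligned rectangle
#' inside the (H_b, E) parallelogram reachable when the retinal position and
#' gaze are sampled independently on \code{[-a, a]}: \code{|H_b|, |E| <= a/2}.
#'
#' @param model a trained 1D \code{\link{harmonium}}.
#' @param pops,layout from the coordinate-transformation batch.
#' @param arm an \code{\link{arm_model}}.
#' @param hb_range,e_range analysis rectangle (cm).
#' @param n_grid grid resolution per axis.
#' @param gain fixed gain for all populations (default 15).
#' @param threshold tuned-unit response-range threshold.
#' @param bin_width histogram bin width in degrees (default 15).
#' @return list with a per-unit data frame (\code{angle_deg},
#'   \code{separability}, \code{tuned}) and the angle histogram.
#' @export
reference_frame_analysis <- function(model, pops, layout, arm,
                                     hb_range = c(-7, 7), e_range = c(-7, 7),
                                     n_grid = 25L, gain = 15,
                                     threshold = 0.1, bin_width = 15) {
  hb <- seq(hb_range[1], hb_range[2], length.out = n_grid)
  ee <- seq(e_range[1], e_range[2], length.out = n_grid)
  grid <- expand.grid(hb = hb, e = ee)
  theta <- inverse_1d(grid$hb, arm)
  xr <- grid$hb - grid$e
  curves <- tuning_curves(model, pops, layout,
                          list(prop = matrix(theta, ncol = 1),
                               vis = matrix(xr, ncol = 1),
                               eye = matrix(grid$e, ncol = 1)), gain = gain)
  tuned <- tuned_mask(curves, threshold)
  dhb <- hb[2] - hb[1]
  de <- ee[2] - ee[1]
  n_units <- ncol(curves)
  angle <- rep(NA_real_, n_units)
  sep <- rep(NA_real_, n_units)
  for (u in which(tuned)) {
    Rm <- matrix(curves[, u], n_grid, n_grid)    # rows: H_b, cols: E
    Rc <- Rm - mean(Rm)
    sv <- svd(Rc, nu = 0, nv = 0)$d
    sep[u] <- sv[1]^2 / sum(sv^2)
    gx <- (Rm[c(2:n_grid, n_grid), ] - Rm[c(1, 1:(n_grid - 1)), ]) /
      (dhb * c(1, rep(2, n_grid - 2), 1))
    gy <- (Rm[, c(2:n_grid, n_grid)] - Rm[, c(1, 1:(n_grid - 1))]) /
      (de * c(1, rep(2, n_grid - 2), 1)[col(Rm)])
    w <- sqrt(gx^2 + gy^2)
    phi <- atan2(gy, gx)
    # axial statistics: gradient direction is defined modulo 180 degrees
    a2 <- atan2(sum(w * sin(2 * phi)), sum(w * cos(2 * phi))) / 2
    angle[u] <- a2 * 180 / pi
  }
  brk <- seq(-90, 90, by = bin_width)
  hist_counts <- table(cut(angle[tuned], brk, include.lowest = TRUE))
  classify <- function(a) {
    if (is.na(a)) return(NA_character_)
    targets <- c(body = 0, plus = 45, eye = 90, eye2 = -90, retinal = -45)
    nm <- names(targets)[which.min(pmin(abs(a - targets),
                                        180 - abs(a - targets)))]
    if (nm == "eye2") "eye" else nm
  }
  data <- data.frame(unit = seq_len(n_units), tuned = tuned,
                     angle_deg = angle, separability = sep,
                     class = vapply(angle, classify, character(1)))
  list(units = data, histogram = hist_counts,
       breaks = brk, hb_range = hb_range, e_range = e_range,
       n_tuned = sum(tuned))
}
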