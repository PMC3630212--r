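# Decoding the stimulus posterior from hidden-layer activity. All decoders
# consume only the model parameters, the averaged hidden vector and static
# configuration (populations, layout, arm) — never the true stimuli or gains.

#' Expected input spike counts implied by hidden activity
#'
#' Uses the generative (hidden-to-visible) weights to map an averaged hidden
#' vector back into expected input spike counts, split per population by the
#' recorded column layout.
#'
#' @param model a \code{\link{harmonium}}.
#' @param vbar averaged hidden vector in [0,1]^H (see
#'   \code{\link{hidden_code}}).
#' @param layout named list of visible column indices per population (from a
#'   \code{trial_batch}).
#' @return named list of expected count vectors, one per layout entry, plus
#'   the full vector as attribute \code{"full"}.
#' @export
decode_expected_inputs <- function(model, vbar, layout) {
  if (length(vbar) != model$n_hidden) stop("vbar length != hidden layer size")
  full <- down_mean(model, vbar)
  if (max(vapply(layout, max, 1L)) != model$n_visible)
    stop("column layout does not match the visible layer")
  out <- lapply(layout, function(ix) full[ix])
  attr(out, "full") <- full
  out
}

#' Posterior-mean estimate decoded from the hidden layer
#'
#' The center of mass of a single decoded population: the proprioceptive
#' population for joint-space estimates, the visual population for Cartesian
#' ones.
#'
#' @inheritParams decode_expected_inputs
#' @param pops list of population codes named as in \code{layout}.
#' @param target_space \code{"prop"} (joint angles) or \code{"vis"}
#'   (Cartesian).
#' @return the stimulus estimate, or \code{NA}s for an undecodable trial.
#' @export
decode_posterior_mean <- function(model, vbar, pops, layout,
                                  target_space = c("prop", "vis")) {
  target_space <- match.arg(target_space)
  dec <- decode_expected_inputs(model, vbar, layout)
  center_of_mass(dec[[target_space]], pops[[target_space]])
}

#' Recover per-population total spike counts from hidden activity
#'
#' Sums the decoded expected inputs per population; when a calibrator fitted
#' with \code{\link{fit_count_calibrator}} is supplied the raw sums are
#' mapped through it.
#'
#' @inheritParams decode_expected_inputs
#' @param calibrator optional \code{count_calibrator}.
#' @return named numeric vector of totals.
#' @export
recover_totals <- function(model, vbar, layout, calibrator = NULL) {
  dec <- decode_expected_inputs(model, vbar, layout)
  raw <- vapply(dec, sum, numeric(1))
  if (is.null(calibrator)) return(raw)
  out <- drop(stats::predict(calibrator, matrix(raw, nrow = 1L),
                             vbar = matrix(vbar, nrow = 1L)))
  names(out) <- names(raw)
  out
}

#' Fit the total-spike-count calibration regressor
#'
#' A one-hidden-layer network (32 logistic units, linear output) mapping
#' hidden-layer readouts to the true input totals. The regressor's inputs
#' are the raw decoded per-population sums, optionally augmented with the
#' leading principal components of the averaged hidden vector (the PCA is
#' fit on the same training trials, so no evaluation trial leaks in). The
#' fit uses a held-out validation split to select the stopping point
#' (number of optimizer iterations); inputs and targets are standardized
#' internally. Train and evaluation trials must be disjoint — the function
#' only ever sees its training pairs.
#'
#' @param raw n x P matrix of raw decoded totals (training trials).
#' @param true_totals n x P matrix of true input totals for the same trials.
#' @param vbar optional n x H matrix of averaged hidden vectors for the
#'   same trials; adds \code{n_pc} principal components as features.
#' @param n_pc number of hidden-activity principal components (default 16).
#' @param size hidden-layer width (default 32).
#' @param val_frac fraction of rows held out for stopping-point selection.
#' @param maxit_grid candidate iteration budgets.
#' @param decay weight decay passed to \code{nnet}.
#' @return an object of class \code{count_calibrator}.
#' @export
fit_count_calibrator <- function(raw, true_totals, vbar = NULL, n_pc = 16,
                                 size = 32, val_frac = 0.2,
                                 maxit_grid = c(100L, 300L, 600L),
                                 decay = 1e-4) {
  raw <- as.matrix(raw)
  true_totals <- as.matrix(true_totals)
  if (nrow(raw) != nrow(true_totals)) stop("mismatched training pairs")
  n <- nrow(raw)
  if (n < 20L) stop("too few training trials for the calibrator")
  pca <- NULL
  if (!is.null(vbar)) {
    if (nrow(vbar) != n) stop("mismatched training pairs")
    pca <- stats::prcomp(vbar, center = TRUE, rank. = min(n_pc, ncol(vbar)))
    pca$x <- NULL   # drop stored scores; only the rotation is needed
    raw <- cbind(raw, stats::predict(pca, vbar))
  }
  n_val <- max(2L, round(val_frac * n))
  val <- seq_len(n_val)                    # caller supplies shuffled trials
  tr <- setdiff(seq_len(n), val)
  mu_x <- colMeans(raw); sd_x <- pmax(apply(raw, 2, stats::sd), 1e-8)
  mu_y <- colMeans(true_totals); sd_y <- pmax(apply(true_totals, 2, stats::sd), 1e-8)
  X <- sweep(sweep(raw, 2, mu_x), 2, sd_x, "/")
  Y <- sweep(sweep(true_totals, 2, mu_y), 2, sd_y, "/")
  best <- NULL
  best_err <- Inf
  for (mi in maxit_grid) {
    fit <- nnet::nnet(X[tr, , drop = FALSE], Y[tr, , drop = FALSE],
                      size = size, linout = TRUE, decay = decay,
                      maxit = mi, trace = FALSE, MaxNWts = 100000)
    pred <- stats::predict(fit, X[val, , drop = FALSE])
    err <- mean((pred - Y[val, , drop = FALSE])^2)
    if (err < best_err) {
      best_err <- err
      best <- fit
    }
  }
  structure(list(net = best, pca = pca, mu_x = mu_x, sd_x = sd_x,
                 mu_y = mu_y, sd_y = sd_y, n_train = n,
                 val_mse = best_err),
            class = "count_calibrator")
}

#' @export
predict.count_calibrator <- function(object, newdata, vbar = NULL, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(object$pca)) {
    if (is.null(vbar))
      stop("this calibrator was fit with hidden-activity features; pass vbar")
    newdata <- cbind(newdata, stats::predict(object$pca, as.matrix(vbar)))
  }
  X <- sweep(sweep(newdata, 2, object$mu_x), 2, object$sd_x, "/")
  Y <- stats::predict(object$net, X)
  sweep(sweep(Y, 2, object$sd_y, "*"), 2, object$mu_y, "+")
}

#' Full Gaussian posterior decoded from the hidden layer
#'
#' The model-based ("RBM-based") posterior: the hidden vector is mapped back
#' to expected input counts through the generative weights, and the standard
#' precision-weighted combination is applied to the decoded populations —
#' exactly the computation used for the optimal posterior, but fed with
#' decoded rather than true counts. No trained calibrator is involved.
#'
#' @inheritParams decode_posterior_mean
#' @param arm an \code{\link{arm_model}}.
#' @param prior flat (\code{NULL}) or Gaussian joint-space prior.
#' @param frames named character vector giving each decoded population's
#'   frame (defaults: \code{prop}/\code{prop2} joint, \code{vis} Cartesian;
#'   a \code{toggle} column is ignored).
#' @return a \code{\link{gaussian_posterior}} in joint space, or \code{NULL}
#'   for an undecodable trial.
#' @export
decode_posterior <- function(model, vbar, pops, layout, arm, prior = NULL,
                             frames = NULL) {
  dec <- decode_expected_inputs(model, vbar, layout)
  nm <- setdiff(names(dec), "toggle")
  if (is.null(frames))
    frames <- stats::setNames(ifelse(grepl("vis", nm), "cartesian", "joint"), nm)
  cues <- lapply(nm, function(p)
    list(counts = dec[[p]], pop = pops[[p]], frame = frames[[p]]))
  cue_posterior(cues, arm, prior)
}
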