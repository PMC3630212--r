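# Exponential-family harmonium: Poisson visible units with exponential
# inverse-link, Bernoulli hidden units with logistic inverse-link, trained by
# one-step contrastive divergence. All sampling uses R's global RNG stream so
# that a single set.seed() makes a whole training run reproducible.

#' Construct a Poisson-Bernoulli harmonium
#'
#' A two-layer undirected generative model with full interlayer and no
#' intralayer connections. Visible units are Poisson spike counts whose
#' conditional means are \code{min(exp(b_vis + W v), rate_cap)}; hidden units
#' are Bernoulli with conditional means \code{logistic(b_hid + W' r)}. The
#' rate cap is a numerical guard on the exponential link, which can otherwise
#' run away early in training; with the default training settings it stops
#' binding after the first stage.
#'
#' @param n_visible,n_hidden layer sizes.
#' @param rate_cap maximum visible conditional mean (spikes); a scalar or
#'   one value per visible unit; default 54, i.e. three times the top of
#'   the default gain range.
#' @param w_sd standard deviation of the centered Gaussian weight
#'   initialization.
#' @return an object of class \code{harmonium} with fields \code{W}
#'   (visible x hidden), \code{b_vis}, \code{b_hid}, \code{rate_cap},
#'   \code{epochs_trained}.
#' @export
harmonium <- function(n_visible, n_hidden, rate_cap = 54, w_sd = 0.01) {
  if (n_visible < 1 || n_hidden < 1) stop("layer sizes must be positive")
  if (any(rate_cap <= 0)) stop("rate_cap must be positive")
  if (!length(rate_cap) %in% c(1L, n_visible))
    stop("rate_cap must be a scalar or one value per visible unit")
  structure(list(W = matrix(stats::rnorm(n_visible * n_hidden, 0, w_sd),
                            n_visible, n_hidden),
                 b_vis = rep(0, n_visible),
                 b_hid = rep(0, n_hidden),
                 rate_cap = rate_cap,
                 n_visible = as.integer(n_visible),
                 n_hidden = as.integer(n_hidden),
                 epochs_trained = 0L),
            class = "harmonium")
}

#' @export
print.harmonium <- function(x, ...) {
  cat(sprintf("harmonium: %d Poisson visible x %d Bernoulli hidden, %d epochs trained\n",
              x$n_visible, x$n_hidden, x$epochs_trained))
  invisible(x)
}

#' Hidden-layer conditional means given visible counts
#'
#' \code{logistic(b_hid + W' r)}, elementwise.
#'
#' @param model a \code{\link{harmonium}}.
#' @param r visible count vector, or an n x V matrix of trials.
#' @return Bernoulli means in (0, 1), same trial convention as \code{r}.
#' @export
up_mean <- function(model, r) {
  vec <- is.null(dim(r))
  if (vec) r <- matrix(r, nrow = 1L)
  a <- r %*% model$W
  a <- sweep(a, 2, model$b_hid, "+")
  out <- 1 / (1 + exp(-a))
  if (vec) drop(out) else out
}

#' Visible-layer conditional means given hidden activity
#'
#' \code{min(exp(b_vis + W v), rate_cap)}, elementwise; \code{v} may be a
#' binary sample or a vector of hidden means.
#'
#' @param model a \code{\link{harmonium}}.
#' @param v hidden vector in [0,1]^H, or an n x H matrix.
#' @return Poisson means, capped at \code{rate_cap}.
#' @export
down_mean <- function(model, v) {
  vec <- is.null(dim(v))
  if (vec) v <- matrix(v, nrow = 1L)
  a <- tcrossprod(v, model$W)
  a <- sweep(a, 2, model$b_vis, "+")
  cap <- model$rate_cap
  out <- if (length(cap) == 1L) pmin(exp(a), cap)
         else pmin(exp(a), rep(cap, each = nrow(a)))
  if (vec) drop(out) else out
}

#' Sample realized units from conditional means
#'
#' @param means matrix/vector of conditional means.
#' @param family \code{"bernoulli"} (0/1 draws) or \code{"poisson"}
#'   (count draws).
#' @return realized units with the shape of \code{means}.
#' @export
gibbs_sample <- function(means, family = c("bernoulli", "poisson")) {
  family <- match.arg(family)
  out <- switch(family,
    bernoulli = (stats::runif(length(means)) < means) + 0,
    poisson = stats::rpois(length(means), means))
  if (is.null(dim(means))) out else array(out, dim(means))
}

#' One contrastive-divergence (CD-1) parameter update
#'
#' Runs the up, down and back-up pass on a minibatch: hidden sample
#' \code{v ~ Bernoulli(up_mean(r))}, visible reconstruction
#' \code{rhat ~ Poisson(down_mean(v))}, negative-phase hidden means
#' \code{up_mean(rhat)}. The weight update is the difference of the
#' data-phase and reconstruction-phase correlations, averaged over the
#' minibatch; bias updates are the corresponding mean differences.
#'
#' @param model a \code{\link{harmonium}}.
#' @param r_batch minibatch of visible count vectors (m x V).
#' @param lr_w,lr_bias learning rates for weights and biases.
#' @param sample_negative use sampled (rather than mean) hidden units in the
#'   negative phase (default \code{FALSE}, the usual variance-reduction
#'   choice).
#' @return the updated \code{harmonium}.
#' @export
cd1_step <- function(model, r_batch, lr_w, lr_bias = lr_w,
                     sample_negative = FALSE) {
  if (is.null(dim(r_batch))) r_batch <- matrix(r_batch, nrow = 1L)
  m <- nrow(r_batch)
  ph <- up_mean(model, r_batch)
  v <- (stats::runif(length(ph)) < ph) + 0
  dim(v) <- dim(ph)
  rhat_mean <- down_mean(model, v)
  rhat <- stats::rpois(length(rhat_mean), rhat_mean)
  dim(rhat) <- dim(rhat_mean)
  phat <- up_mean(model, rhat)
  if (sample_negative) {
    phat <- (stats::runif(length(phat)) < phat) + 0
    dim(phat) <- dim(ph)
  }
  dW <- (crossprod(r_batch, ph) - crossprod(rhat, phat)) / m
  db_v <- colMeans(r_batch) - colMeans(rhat)
  db_h <- colMeans(ph) - colMeans(phat)
  model$W <- model$W + lr_w * dW
  model$b_vis <- model$b_vis + lr_bias * db_v
  model$b_hid <- model$b_hid + lr_bias * db_h
  if (any(!is.finite(model$W)) || any(!is.finite(model$b_vis)) ||
      any(!is.finite(model$b_hid)))
    stop(sprintf(paste0("non-finite parameter update (max |W| = %g); ",
                        "the learning rate is probably too high"),
                 max(abs(model$W[is.finite(model$W)]), 0)))
  model
}

#' Training schedule for contrastive divergence
#'
#' A run consists of \code{n_stages} stages of \code{epochs_per_stage} epochs
#' each (default 6 x 15 = 90 epochs); one epoch is a full pass over the
#' \code{n_vectors} training vectors in shuffled minibatches. After each
#' stage the learning rates are multiplied by \code{anneal}.
#'
#' @param n_vectors training vectors per stage (default 40000).
#' @param minibatch minibatch size (default 40).
#' @param epochs_per_stage,n_stages stage structure.
#' @param lr_w,lr_bias initial learning rates.
#' @param anneal learning-rate multiplier applied after each stage.
#' @return an object of class \code{training_schedule}.
#' @export
training_schedule <- function(n_vectors = 40000, minibatch = 40,
                              epochs_per_stage = 15, n_stages = 6,
                              lr_w = 1e-2, lr_bias = 1e-2, anneal = 0.8) {
  stopifnot(n_vectors > 0, minibatch > 0, epochs_per_stage > 0, n_stages > 0,
            lr_w > 0, lr_bias > 0, anneal > 0)
  structure(list(n_vectors = n_vectors, minibatch = minibatch,
                 epochs_per_stage = epochs_per_stage, n_stages = n_stages,
                 lr_w = lr_w, lr_bias = lr_bias, anneal = anneal,
                 total_epochs = epochs_per_stage * n_stages),
            class = "training_schedule")
}

# mean Poisson deviance between counts and reconstruction means
.poisson_deviance <- function(r, mu) {
  mu <- pmax(mu, 1e-12)
  ll <- ifelse(r > 0, r * log(r / mu), 0) - (r - mu)
  2 * mean(ll)
}

#' Initialize visible biases from data marginals
#'
#' Sets \code{b_vis = log(mean count per unit + eps)} so that the model's
#' initial reconstruction matches the data marginals.
#'
#' @param model a \code{\link{harmonium}}.
#' @param data visible count matrix (n x V).
#' @param eps small offset guarding against silent units.
#' @return the updated model.
#' @export
init_visible_bias <- function(model, data, eps = 0.01) {
  model$b_vis <- log(colMeans(data) + eps)
  model
}

#' Train a harmonium with one-step contrastive divergence
#'
#' Iterates \code{\link{cd1_step}} over shuffled minibatches according to the
#' schedule. \code{data} may be a fixed count matrix (reused every stage) or
#' a generator \code{function(stage)} returning a fresh
#' \code{n_vectors} x V matrix per stage, which matches the protocol of
#' drawing a new world-driven batch for each learning-rate stage. A per-epoch
#' reconstruction Poisson deviance is recorded on a fixed monitoring subset.
#'
#' @param model a \code{\link{harmonium}} (freshly constructed or to be
#'   trained further).
#' @param data count matrix or \code{function(stage)}.
#' @param schedule a \code{\link{training_schedule}}.
#' @param init_bias initialize visible biases from the first stage's data
#'   marginals (only when the model is untrained)?
#' @param monitor_rows number of rows of each stage's data used for the
#'   deviance trace.
#' @param verbose print per-epoch deviance?
#' @return the trained model, with the deviance trace in \code{$trace}.
#' @export
train_harmonium <- function(model, data, schedule = training_schedule(),
                            init_bias = TRUE, monitor_rows = 500L,
                            verbose = FALSE) {
  gen <- if (is.function(data)) data else function(stage) data
  lr_w <- schedule$lr_w
  lr_b <- schedule$lr_bias
  trace <- numeric(0)
  for (stage in seq_len(schedule$n_stages)) {
    R <- gen(stage)
    if (ncol(R) != model$n_visible)
      stop("training data width does not match the visible layer")
    if (stage == 1L && init_bias && model$epochs_trained == 0L)
      model <- init_visible_bias(model, R)
    n <- nrow(R)
    mb <- schedule$minibatch
    n_mb <- n %/% mb
    mon <- seq_len(min(monitor_rows, n))
    for (epoch in seq_len(schedule$epochs_per_stage)) {
      ord <- sample.int(n)
      for (k in seq_len(n_mb)) {
        idx <- ord[((k - 1L) * mb + 1L):(k * mb)]
        model <- cd1_step(model, R[idx, , drop = FALSE], lr_w, lr_b)
      }
      model$epochs_trained <- model$epochs_trained + 1L
      mu <- down_mean(model, up_mean(model, R[mon, , drop = FALSE]))
      dev <- .poisson_deviance(R[mon, , drop = FALSE], mu)
      trace <- c(trace, dev)
      if (verbose)
        message(sprintf("stage %d epoch %d: deviance %.4f", stage, epoch, dev))
    }
    lr_w <- lr_w * schedule$anneal
    lr_b <- lr_b * schedule$anneal
  }
  model$trace <- c(model$trace, trace)
  model
}

#' Averaged hidden-layer code for visible inputs
#'
#' Draws \code{n_samples} Bernoulli sample vectors from the hidden
#' conditional and averages them — the multisensory code read out by the
#' decoders. With \code{n_samples = Inf} the conditional means themselves
#' are returned (the infinite-sample limit).
#'
#' @param model a \code{\link{harmonium}}.
#' @param r visible counts (vector or n x V matrix).
#' @param n_samples number of hidden samples to average (default 15).
#' @return averaged hidden activity with entries in [0, 1].
#' @export
hidden_code <- function(model, r, n_samples = 15) {
  ph <- up_mean(model, r)
  if (is.infinite(n_samples)) return(ph)
  if (n_samples < 1) stop("n_samples must be >= 1 (or Inf for means)")
  acc <- 0
  for (s in seq_len(n_samples)) {
    v <- (stats::runif(length(ph)) < ph) + 0
    acc <- acc + v
  }
  out <- acc / n_samples
  if (!is.null(dim(ph))) dim(out) <- dim(ph)
  out
}
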