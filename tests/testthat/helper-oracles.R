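# Independent oracles used by the tests. These deliberately avoid the
# package's closed-form posterior code paths: posteriors are computed by
# brute-force numerical integration of the exact Poisson likelihood, and
# harmonium conditionals/updates by exhaustive enumeration.

# Brute-force posterior over joint angles on a fine local grid, with the
# per-population gains marginalized over their uniform prior by quadrature.
grid_posterior_2d <- function(cp, cv, pops, arm, prior = NULL,
                              gain_range = c(12, 18), half = 8, ngrid = 101) {
  com <- center_of_mass(cp, pops$prop)
  sd0 <- pops$prop$sigma_tc / sqrt(sum(cp))
  g1 <- seq(com[1] - half * sd0, com[1] + half * sd0, length.out = ngrid)
  g2 <- seq(com[2] - half * sd0, com[2] + half * sd0, length.out = ngrid)
  th <- as.matrix(expand.grid(g1, g2))
  lim <- arm$joint_limits
  inside <- th[, 1] >= lim[1, 1] & th[, 1] <= lim[1, 2] &
            th[, 2] >= lim[2, 1] & th[, 2] <= lim[2, 2]
  loglik_pop <- function(counts, pop, S) {
    f <- mean_rates(pop, S, 1)
    base <- drop(log(pmax(f, 1e-300)) %*% counts)
    Fs <- rowSums(f)
    gs <- seq(gain_range[1], gain_range[2], length.out = 13)
    M <- outer(Fs, gs, function(F, g) sum(counts) * log(g) - g * F)
    mx <- apply(M, 1, max)
    base + mx + log(rowSums(exp(M - mx)))
  }
  lp <- rep(-Inf, nrow(th))
  x <- forward_kinematics(th[inside, , drop = FALSE], arm)
  lp[inside] <- loglik_pop(cp, pops$prop, th[inside, , drop = FALSE]) +
    loglik_pop(cv, pops$vis, x)
  if (!is.null(prior)) {
    Pm <- solve(prior$covariance)
    d <- sweep(th, 2, prior$mean)
    lp <- lp - 0.5 * rowSums((d %*% Pm) * d)
  }
  lp <- lp - max(lp)
  w <- exp(lp)
  w <- w / sum(w)
  mu <- colSums(th * w)
  d <- sweep(th, 2, mu)
  S <- t(d) %*% (d * w)
  dimnames(S) <- NULL
  list(mean = unname(mu), cov = S)
}

# Brute-force posterior over (X_b, E) for the 1D coordinate-transformation
# model; returns the marginal moments of X_b.
grid_posterior_coordtrans <- function(cp, cv, ce, pops, arm,
                                      gain_ranges = list(prop = c(36, 54),
                                                         vis = c(12, 18),
                                                         eye = c(12, 18)),
                                      ngrid = 121) {
  hb0 <- arm$link_1d * cos(drop(center_of_mass(cp, pops$prop)))
  e0 <- drop(center_of_mass(ce, pops$eye))
  sd_h <- 4
  hb <- seq(hb0 - sd_h, hb0 + sd_h, length.out = ngrid)
  ee <- seq(e0 - sd_h, e0 + sd_h, length.out = ngrid)
  gr <- as.matrix(expand.grid(hb = hb, e = ee))
  ok <- abs(gr[, 1]) < arm$link_1d * 0.999
  loglik_pop <- function(counts, pop, S, grange) {
    f <- mean_rates(pop, matrix(S, ncol = 1), 1)
    base <- drop(log(pmax(f, 1e-300)) %*% counts)
    Fs <- rowSums(f)
    gs <- seq(grange[1], grange[2], length.out = 13)
    M <- outer(Fs, gs, function(F, g) sum(counts) * log(g) - g * F)
    mx <- apply(M, 1, max)
    base + mx + log(rowSums(exp(M - mx)))
  }
  lp <- rep(-Inf, nrow(gr))
  th <- acos(pmin(pmax(gr[ok, 1] / arm$link_1d, -1), 1))
  lp[ok] <- loglik_pop(cp, pops$prop, th, gain_ranges$prop) +
    loglik_pop(cv, pops$vis, gr[ok, 1] - gr[ok, 2], gain_ranges$vis) +
    loglik_pop(ce, pops$eye, gr[ok, 2], gain_ranges$eye)
  lp <- lp - max(lp)
  w <- exp(lp)
  w <- w / sum(w)
  mu <- sum(gr[, 1] * w)
  list(mean = mu, var = sum((gr[, 1] - mu)^2 * w))
}

# Enumerate p(v | r) for a small harmonium by summing the Boltzmann weights
# over all hidden states; returns the vector of P(v_j = 1 | r).
enum_hidden_conditional <- function(model, r) {
  H <- model$n_hidden
  states <- as.matrix(expand.grid(rep(list(0:1), H)))
  logw <- drop(states %*% (model$b_hid + drop(r %*% model$W)))
  w <- exp(logw - max(logw))
  w <- w / sum(w)
  unname(drop(w %*% states))
}

# Enumerate E[r_i | v] for Poisson visibles by summing over counts 0..kmax.
enum_visible_conditional_mean <- function(model, v, kmax = 60) {
  lam <- exp(model$b_vis + drop(model$W %*% v))
  vapply(lam, function(l) {
    k <- 0:kmax
    p <- stats::dpois(k, l)
    sum(k * p) / sum(p)
  }, numeric(1))
}

# Exact expected CD-1 weight update for a tiny model and one data vector:
# positive term exactly, negative term by enumerating the hidden sample and
# the Poisson reconstruction (truncated at kmax with negligible tail).
enum_expected_cd1_dW <- function(model, r, kmax = 30) {
  ph <- up_mean(model, r)
  pos <- outer(unname(r), unname(ph))
  H <- model$n_hidden
  V <- model$n_visible
  vstates <- as.matrix(expand.grid(rep(list(0:1), H)))
  pv <- apply(vstates, 1, function(v) prod(ifelse(v == 1, ph, 1 - ph)))
  rstates <- as.matrix(expand.grid(rep(list(0:kmax), V)))
  phat <- up_mean(model, rstates)
  neg <- matrix(0, V, H)
  for (s in seq_len(nrow(vstates))) {
    v <- vstates[s, ]
    lam <- drop(down_mean(model, v))
    pr <- apply(rstates, 1, function(rr) prod(stats::dpois(rr, lam)))
    pr <- pr / sum(pr)
    neg <- neg + pv[s] * crossprod(rstates * pr, phat)
  }
  pos - neg
}

expect_spd <- function(S) {
  ev <- eigen(as.matrix(S), symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > 0))
}
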