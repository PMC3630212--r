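test_that("center of mass is the single-population ML estimate", {
  pop <- population_code("prop", rbind(c(0, 1), c(0, 1)), 12)
  counts <- rep(0, pop$n_units)
  counts[40] <- 1
  expect_equal(center_of_mass(counts, pop), pop$preferred[40, ])
  counts[80] <- 1
  expect_equal(center_of_mass(counts, pop),
               colMeans(pop$preferred[c(40, 80), ]))
  expect_true(all(is.na(center_of_mass(rep(0, pop$n_units), pop))))
  # matches the grid argmax of the exact Poisson log-likelihood
  arm <- arm_model()
  pops <- integration_populations(arm, 20)
  set.seed(10)
  th <- c(1.2, 1.9)
  cp <- drop(encode(pops$prop, th, 15))
  g1 <- seq(th[1] - 0.15, th[1] + 0.15, length.out = 301)
  g2 <- seq(th[2] - 0.15, th[2] + 0.15, length.out = 301)
  grid <- as.matrix(expand.grid(g1, g2))
  f <- mean_rates(pops$prop, grid, 1)
  ll <- drop(log(pmax(f, 1e-300)) %*% cp) - 15 * rowSums(f)
  peak <- unname(grid[which.max(ll), ])
  expect_equal(center_of_mass(cp, pops$prop), peak, tolerance = 0.002)
})

test_that("integration posterior matches the brute-force grid posterior", {
  arm <- arm_model()
  pops <- integration_populations(arm, 20)
  lim <- arm$joint_limits
  interior <- lim + cbind(c(0.12, 0.12), c(-0.12, -0.12))
  sp <- stimulus_prior("uniform-joint", bounds = interior)
  set.seed(11)
  n_rep <- 40
  mean_err <- cov_err <- numeric(n_rep)
  for (k in seq_len(n_rep)) {
    th <- sample_stimuli(sp, 1, arm)
    g <- runif(2, 12, 18)
    cp <- drop(encode(pops$prop, th, g[1]))
    cv <- drop(encode(pops$vis, forward_kinematics(th, arm), g[2]))
    p <- integration_posterior(cp, cv, pops, arm)
    o <- grid_posterior_2d(cp, cv, pops, arm)
    mean_err[k] <- sqrt(sum((p$mean - o$mean)^2))
    cov_err[k] <- norm(p$covariance - o$cov, "F") / norm(o$cov, "F")
  }
  expect_lt(max(mean_err), 0.1 * pops$prop$spacing[1])
  expect_lt(max(cov_err), 0.02)
})

test_that("posterior limiting cases: missing cues and flat prior", {
  arm <- arm_model()
  pops <- integration_populations(arm, 12)
  set.seed(12)
  th <- c(1.3, 1.8)
  cp <- drop(encode(pops$prop, th, 15))
  zero_v <- rep(0, pops$vis$n_units)
  p <- integration_posterior(cp, zero_v, pops, arm)
  # reduces to the prop-only posterior: isotropic with precision n/sigma^2
  expect_equal(p$mean, center_of_mass(cp, pops$prop))
  expect_equal(p$covariance,
               diag(2) * pops$prop$sigma_tc^2 / sum(cp), tolerance = 1e-10)
  # all-zero counts with flat prior: singular, flagged as NULL
  expect_null(integration_posterior(rep(0, pops$prop$n_units), zero_v,
                                    pops, arm))
  # with a Gaussian prior the posterior exists and equals the prior
  pr <- tight_gaussian_prior(arm)
  p0 <- integration_posterior(rep(0, pops$prop$n_units), zero_v, pops, arm, pr)
  expect_equal(p0$mean, pr$mean)
  expect_equal(p0$covariance, pr$covariance)
})

test_that("adding a cue never decreases the posterior precision", {
  arm <- arm_model()
  pops <- integration_populations(arm, 12)
  set.seed(13)
  for (k in 1:20) {
    th <- sample_stimuli(stimulus_prior("uniform-joint"), 1, arm)
    cp <- drop(encode(pops$prop, th, 15))
    cv <- drop(encode(pops$vis, forward_kinematics(th, arm), 15))
    p1 <- integration_posterior(cp, rep(0, pops$vis$n_units), pops, arm)
    p12 <- integration_posterior(cp, cv, pops, arm)
    dP <- solve(p12$covariance) - solve(p1$covariance)
    ev <- eigen((dP + t(dP)) / 2, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev > -1e-8))
  }
})

test_that("cue order does not change the posterior", {
  arm <- arm_model()
  pops <- integration_populations(arm, 12)
  set.seed(14)
  th <- c(1.4, 1.7)
  cp <- drop(encode(pops$prop, th, 15))
  cv <- drop(encode(pops$vis, forward_kinematics(th, arm), 15))
  a <- cue_posterior(list(list(counts = cp, pop = pops$prop, frame = "joint"),
                          list(counts = cv, pop = pops$vis, frame = "cartesian")),
                     arm)
  b <- cue_posterior(list(list(counts = cv, pop = pops$vis, frame = "cartesian"),
                          list(counts = cp, pop = pops$prop, frame = "joint")),
                     arm)
  expect_equal(a$mean, b$mean)
  expect_equal(a$covariance, b$covariance)
})

test_that("coordinate-transformation posterior matches its grid oracle", {
  arm <- arm_model()
  pops <- coordtrans_populations(arm)
  set.seed(15)
  for (k in 1:10) {
    b <- sample_coordtrans_batch(1, arm, pops)
    cp <- drop(b$counts[, b$layout$prop])
    cv <- drop(b$counts[, b$layout$vis])
    ce <- drop(b$counts[, b$layout$eye])
    p <- coordtrans_posterior(cp, cv, ce, pops, arm)
    o <- grid_posterior_coordtrans(cp, cv, ce, pops, arm)
    expect_equal(p$mean, o$mean, tolerance = 0.08)
    expect_equal(drop(p$covariance), o$var, tolerance = 0.15)
  }
  # no prop spikes: the vis + eye chain alone, with added variances
  b <- sample_coordtrans_batch(1, arm, pops)
  cv <- drop(b$counts[, b$layout$vis]); ce <- drop(b$counts[, b$layout$eye])
  p <- coordtrans_posterior(rep(0, 60), cv, ce, pops, arm)
  expect_equal(p$mean, drop(center_of_mass(cv, pops$vis)) +
                 drop(center_of_mass(ce, pops$eye)))
  expect_equal(drop(p$covariance),
               pops$vis$sigma_tc^2 / sum(cv) + pops$eye$sigma_tc^2 / sum(ce))
  # removing the eye cue removes the chain: only prop remains, variance grows
  cp <- drop(b$counts[, b$layout$prop])
  full <- coordtrans_posterior(cp, cv, ce, pops, arm)
  noeye <- coordtrans_posterior(cp, cv, rep(0, 60), pops, arm)
  expect_gt(drop(noeye$covariance), drop(full$covariance))
})

test_that("mixture covariance for decoupled inputs interpolates its endpoints", {
  A <- matrix(c(2, 0.3, 0.3, 1), 2)
  B <- matrix(c(5, -0.2, -0.2, 4), 2)
  expect_equal(decoupled_optimal_covariance(A, B, 1), A)
  expect_equal(decoupled_optimal_covariance(A, B, 0), B)
  expect_equal(decoupled_optimal_covariance(A, B, 0.3), 0.3 * A + 0.7 * B)
  expect_error(decoupled_optimal_covariance(A, B, 1.5), "p_couple")
  expect_error(decoupled_optimal_covariance(matrix(c(-1, 0, 0, 1), 2), B, 0.5),
               "positive definite")
  # matches the empirical error covariance of the condition-aware estimator
  arm <- arm_model()
  pops <- integration_populations(arm, 10)
  set.seed(16)
  b <- sample_decoupled_batch(4000, arm, pops, p_couple = 0.5)
  est <- matrix(NA_real_, b$n, 2)
  for (i in seq_len(b$n)) {
    p <- if (b$meta$coupled[i])
      integration_posterior(b$counts[i, b$layout$prop],
                            b$counts[i, b$layout$vis], pops, arm)
    else single_population_posterior(b$counts[i, b$layout$prop], pops$prop)
    if (!is.null(p)) est[i, ] <- p$mean
  }
  err <- est - b$stimuli$theta
  emp <- cov(err[complete.cases(err), ])
  cond_cov <- function(sel) cov(err[sel & complete.cases(err), ])
  pred <- decoupled_optimal_covariance(cond_cov(b$meta$coupled),
                                       cond_cov(!b$meta$coupled),
                                       mean(b$meta$coupled))
  expect_equal(emp, pred, tolerance = 0.1)
})

test_that("gaussian KL divergence has its closed-form values and properties", {
  p <- gaussian_posterior(c(0, 0), diag(2))
  expect_equal(gaussian_kl(p, p), 0)
  # 1D covariance-only value: (1/2)(1/2 - 1 + log 2)
  p1 <- gaussian_posterior(0, matrix(1), space = "s")
  q1 <- gaussian_posterior(0, matrix(2), space = "s")
  expect_equal(gaussian_kl(p1, q1, cov_only = TRUE),
               0.5 * (1 / 2 - 1 + log(2)), tolerance = 1e-12)
  expect_equal(gaussian_kl(p1, q1, cov_only = TRUE), 0.0966, tolerance = 1e-3)
  # nonnegative on random SPD pairs, zero only at equality
  set.seed(17)
  for (k in 1:20) {
    A <- crossprod(matrix(rnorm(4), 2)) + diag(2) * 0.1
    B <- crossprod(matrix(rnorm(4), 2)) + diag(2) * 0.1
    pk <- gaussian_posterior(rnorm(2), A)
    qk <- gaussian_posterior(rnorm(2), B)
    expect_gte(gaussian_kl(pk, qk), 0)
  }
  expect_error(gaussian_posterior(c(0, 0), matrix(c(1, 2, 2, 1), 2)),
               "positive definite")
})

test_that("information-loss fraction is anchored at 0 and 1 and monotone", {
  arm <- arm_model()
  prior <- flat_prior_proxy(arm$joint_limits)
  opt <- gaussian_posterior(c(1.5, 1.9), diag(2) * 1e-4)
  expect_equal(info_loss_fraction(opt, opt, prior), 0)
  expect_equal(info_loss_fraction(opt, prior, prior), 1)
  mid <- gaussian_posterior(c(1.5, 1.9), diag(2) * 4e-4)
  expect_gt(info_loss_fraction(opt, mid, prior), 0)
  expect_lt(info_loss_fraction(opt, mid, prior), 1)
  worse <- gaussian_posterior(c(1.5, 1.9), diag(2) * 16e-4)
  expect_gt(info_loss_fraction(opt, worse, prior),
            info_loss_fraction(opt, mid, prior))
  expect_error(info_loss_fraction(opt, mid, opt), "zero KL")
})
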