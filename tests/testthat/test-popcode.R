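test_that("population grids obey the margin and FWHM conventions", {
  pop <- population_code("vis", rbind(c(-30, 30), c(-30, 30)), 30)
  expect_equal(pop$n_units, 900L)
  # FWHM covers one sixth of the extent: sigma = extent / (6 * 2.3548...)
  expect_equal(pop$sigma_tc, 60 / (6 * 2 * sqrt(2 * log(2))), tolerance = 1e-12)
  expect_equal(pop$sigma_tc, 4.246, tolerance = 1e-3)
  # preferred grid spans the response area plus a 4-sigma margin per side
  expect_equal(min(pop$preferred[, 1]), -30 - 4 * pop$sigma_tc)
  expect_equal(max(pop$preferred[, 2]), 30 + 4 * pop$sigma_tc)
  # spacing constant per dimension
  u1 <- sort(unique(pop$preferred[, 1]))
  expect_equal(diff(u1), rep(pop$spacing[1], 29))
  # no margin: grid spans exactly the response area
  pop0 <- population_code("vis", rbind(c(-30, 30), c(-30, 30)), 10, margin_sd = 0)
  expect_equal(range(pop0$preferred[, 1]), c(-30, 30))
  expect_error(population_code("x", rbind(c(1, 1), c(0, 1)), 10), "degenerate")
  expect_error(population_code("x", rbind(c(0, 1), c(0, 1)), 1), "at least 2")
})

test_that("mean rates are unnormalized Gaussians with gain = peak count", {
  pop <- population_code("prop", rbind(c(0, 1), c(0, 1)), 10)
  i <- 37
  r <- mean_rates(pop, pop$preferred[i, ], 15)
  expect_equal(r[i], 15)                # stimulus at a preferred location
  expect_equal(max(r), 15)
  expect_equal(mean_rates(pop, c(0.5, 0.5), 0), rep(0, 100))
  # grid-sum oracle: total expected count ~ gain * 2*pi*sigma^2 / (dx*dy)
  # (on a grid dense relative to the tuning width)
  popd <- population_code("prop", rbind(c(0, 1), c(0, 1)), 30)
  tot <- sum(mean_rates(popd, c(0.5, 0.5), 15))
  expect_equal(tot, 15 * 2 * pi * popd$sigma_tc^2 / prod(popd$spacing),
               tolerance = 0.01)
})

test_that("encoding is translation-covariant in the grid interior", {
  pop <- population_code("prop", rbind(c(0, 1), c(0, 1)), 15)
  s <- c(0.5, 0.5)
  r0 <- mean_rates(pop, s, 15)
  r1 <- mean_rates(pop, s + c(pop$spacing[1], 0), 15)
  m0 <- matrix(r0, 15, 15)
  m1 <- matrix(r1, 15, 15)
  expect_equal(m1[2:15, ], m0[1:14, ], tolerance = 1e-10)
})

test_that("the 4-sigma margin keeps off-grid units silent", {
  pop <- population_code("prop", rbind(c(0, 1), c(0, 1)), 20)
  # a hypothetical unit one spacing beyond the grid edge, stimulus at the
  # response-area boundary (worst interior-adjacent case)
  dist <- 4 * pop$sigma_tc + pop$spacing[1]
  expect_lt(exp(-dist^2 / (2 * pop$sigma_tc^2)), 1e-4)
})

test_that("Poisson encoding has matching empirical mean and variance", {
  pop <- population_code("prop", rbind(c(0, 1), c(0, 1)), 8)
  mu <- mean_rates(pop, c(0.5, 0.5), 15)
  set.seed(4)
  draws <- encode(pop, matrix(rep(0.5, 2 * 4000), ncol = 2), rep(15, 4000))
  emp_mean <- colMeans(draws)
  se <- sqrt(mu / 4000)
  active <- mu > 0.5
  expect_true(all(abs(emp_mean - mu)[active] < 3.5 * se[active]))
  emp_var <- apply(draws, 2, var)
  expect_equal(emp_var[active], emp_mean[active], tolerance = 0.15)
  expect_equal(encode(pop, c(0.5, 0.5), 0), rep(0L, 64))
})

test_that("integration batches are internally consistent and reproducible", {
  arm <- arm_model()
  pops <- integration_populations(arm, 8)
  set.seed(5)
  b <- sample_integration_batch(200, arm, pops)
  expect_equal(b$stimuli$x, forward_kinematics(b$stimuli$theta, arm))
  expect_equal(ncol(b$counts), 128L)
  expect_true(all(b$counts >= 0) && all(b$counts == round(b$counts)))
  expect_true(all(b$gains$prop >= 12 & b$gains$prop <= 18))
  # empty batch
  b0 <- sample_integration_batch(0, arm, pops)
  expect_equal(b0$n, 0)
  expect_equal(nrow(b0$counts), 0L)
  # reproducibility from the seed
  set.seed(5)
  b2 <- sample_integration_batch(200, arm, pops)
  expect_identical(b$counts, b2$counts)
  # fixed gains: mean total count per population matches the grid sum
  gp <- list(prop = gain_prior(15, 15), vis = gain_prior(15, 15))
  set.seed(6)
  b3 <- sample_integration_batch(1000, arm, pops, gp)
  tot_p <- mean(rowSums(b3$counts[, b3$layout$prop]))
  pred <- mean(sapply(1:50, function(i)
    sum(mean_rates(pops$prop, b3$stimuli$theta[i, ], 15))))
  expect_equal(tot_p, pred, tolerance = 0.05)
})

test_that("discrepant batches shift prop by the requested covariance multiple", {
  arm <- arm_model()
  pops <- integration_populations(arm, 12)
  set.seed(7)
  b0 <- sample_discrepant_batch(300, arm, pops, k_sd = 0)
  expect_equal(b0$meta$delta, c(0, 0))
  expect_equal(b0$stimuli$theta_prop, b0$stimuli$theta)
  set.seed(7)
  b <- sample_discrepant_batch(3000, arm, pops, k_sd = 5)
  expect_true(all(abs(b$stimuli$theta_prop - b$stimuli$theta -
                        rep(b$meta$delta, each = 3000)) < 1e-12))
  # decoded prop center of mass minus vis-based joint estimate ~ delta
  com_p <- center_of_mass(b$counts[, b$layout$prop], pops$prop)
  com_v <- center_of_mass(b$counts[, b$layout$vis], pops$vis)
  th_v <- t(apply(com_v, 1, function(x)
    tryCatch(inverse_kinematics(x, arm), error = function(e) c(NA, NA))))
  gap <- colMeans(com_p - th_v, na.rm = TRUE)
  expect_equal(gap, b$meta$delta, tolerance = 0.15)
  # shifted angles stay within limits (resampling, not clipping)
  lim <- arm$joint_limits
  expect_true(all(b$stimuli$theta_prop[, 1] >= lim[1, 1] - 1e-9 &
                    b$stimuli$theta_prop[, 1] <= lim[1, 2] + 1e-9))
})

test_that("decoupled batches wire the toggle unit to the decoupled trials", {
  arm <- arm_model()
  pops <- integration_populations(arm, 8)
  set.seed(8)
  b1 <- sample_decoupled_batch(300, arm, pops, p_couple = 1)
  expect_true(all(b1$counts[, b1$layout$toggle] == 0))
  set.seed(8)
  b <- sample_decoupled_batch(4000, arm, pops, p_couple = 0.5)
  expect_equal(mean(b$meta$coupled), 0.5, tolerance = 0.03)
  # toggle fires only on decoupled trials
  expect_true(all(b$counts[b$meta$coupled, b$layout$toggle] == 0))
  expect_gt(mean(b$counts[!b$meta$coupled, b$layout$toggle]), 10)
  # on decoupled trials the vis stimulus is independent of the true hand
  dec <- !b$meta$coupled
  expect_lt(abs(cor(b$stimuli$theta[dec, 1], b$stimuli$theta_vis[dec, 1])), 0.06)
  expect_equal(b$stimuli$theta_vis[b$meta$coupled, ],
               b$stimuli$theta[b$meta$coupled, ])
})

test_that("coordinate-transformation batches respect the 1D geometry", {
  arm <- arm_model()
  pops <- coordtrans_populations(arm)
  expect_equal(sum(sapply(pops, function(p) p$n_units)), 180L)
  set.seed(9)
  b <- sample_coordtrans_batch(500, arm, pops)
  expect_equal(b$stimuli$body, b$stimuli$retinal + b$stimuli$eye)
  expect_equal(32 * cos(b$stimuli$theta), b$stimuli$body, tolerance = 1e-9)
  expect_equal(ncol(b$counts), 180L)
  # raised proprioceptive gain
  expect_true(all(b$gains$prop >= 36 & b$gains$prop <= 54))
  expect_error(
    sample_coordtrans_batch(10, arm, pops, range_x = c(-30, 30)),
    "joint limits")
})
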