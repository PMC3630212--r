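make_toy <- function(V = 3, H = 2, seed = 21, w_scale = 0.3) {
  set.seed(seed)
  m <- harmonium(V, H, rate_cap = 1000, w_sd = 0.01)
  m$W <- matrix(runif(V * H, -w_scale, w_scale), V, H)
  m$b_vis <- runif(V, -0.5, 0.5)
  m$b_hid <- runif(H, -0.5, 0.5)
  m
}

test_that("conditional means equal the enumerated Boltzmann conditionals", {
  m <- make_toy()
  for (r in list(c(0, 0, 0), c(1, 0, 2), c(3, 1, 0), c(5, 2, 4))) {
    expect_equal(up_mean(m, r), enum_hidden_conditional(m, r),
                 tolerance = 1e-12)
  }
  for (v in list(c(0, 0), c(1, 0), c(1, 1))) {
    expect_equal(down_mean(m, v), enum_visible_conditional_mean(m, v),
                 tolerance = 1e-8)
  }
  # degenerate parameters: zero weights give 0.5 hidden means and
  # bias-driven visible rates
  m0 <- harmonium(4, 3, w_sd = 0)
  expect_equal(up_mean(m0, c(5, 0, 2, 1)), rep(0.5, 3))
  expect_equal(down_mean(m0, c(1, 0, 1)), rep(1, 4))  # exp(0)
  # the rate cap binds
  mc <- make_toy()
  mc$rate_cap <- 0.5
  expect_true(all(down_mean(mc, c(1, 1)) <= 0.5))
})

test_that("hidden means are monotone in inputs under positive weights", {
  m <- make_toy()
  m$W <- abs(m$W)
  r <- c(1, 2, 0)
  base <- up_mean(m, r)
  for (j in 1:3) {
    r2 <- r
    r2[j] <- r2[j] + 1
    expect_true(all(up_mean(m, r2) >= base))
  }
})

test_that("gibbs_sample reproduces its means and respects degenerate cases", {
  set.seed(22)
  p <- c(0, 0.25, 0.75, 1)
  draws <- matrix(gibbs_sample(matrix(rep(p, 4000), ncol = 4, byrow = TRUE),
                               "bernoulli"), ncol = 4)
  expect_equal(colMeans(draws), p, tolerance = 0.03)
  expect_true(all(draws[, 1] == 0) && all(draws[, 4] == 1))
  lam <- c(0, 3, 10)
  pd <- matrix(gibbs_sample(matrix(rep(lam, 3000), ncol = 3, byrow = TRUE),
                            "poisson"), ncol = 3)
  expect_equal(colMeans(pd), lam, tolerance = 0.05)
  expect_equal(apply(pd, 2, var)[2:3], lam[2:3], tolerance = 0.1)
})

test_that("expected CD-1 update matches the enumerated correlation difference", {
  m <- make_toy(V = 2, H = 1, seed = 23, w_scale = 0.2)
  m$b_vis <- c(0.2, -0.1)   # modest rates keep the enumeration tight
  r <- c(2, 1)
  exact <- enum_expected_cd1_dW(m, r)
  set.seed(24)
  n_rep <- 4000
  acc <- matrix(0, 2, 1)
  for (k in seq_len(n_rep)) {
    m2 <- cd1_step(m, r, lr_w = 1, lr_bias = 1)
    acc <- acc + (m2$W - m$W)
  }
  est <- acc / n_rep
  expect_equal(unname(est), unname(exact), tolerance = 0.02)
  # Hebbian sign: co-active pair with silent reconstruction strengthens W.
  # With a strongly negative visible bias the reconstruction is ~0, so the
  # negative phase vanishes and the data correlation dominates.
  mh <- make_toy(V = 2, H = 1, seed = 25, w_scale = 0)
  mh$b_vis <- c(-8, -8)
  mh$b_hid <- 5       # hidden unit reliably on
  set.seed(26)
  m3 <- cd1_step(mh, c(4, 0), lr_w = 1)
  expect_gt(m3$W[1, 1] - mh$W[1, 1], 0)
})

test_that("cd1_step fixed points and divergence guard", {
  m <- make_toy()
  # zero learning rate leaves parameters unchanged through train()
  sched <- training_schedule(n_vectors = 80, minibatch = 40,
                             epochs_per_stage = 1, n_stages = 1, lr_w = 1e-12,
                             lr_bias = 1e-12)
  set.seed(27)
  data <- matrix(rpois(80 * 3, 2), 80, 3)
  set.seed(28)
  m_t <- train_harmonium(m, data, sched, init_bias = FALSE)
  expect_equal(m_t$W, m$W, tolerance = 1e-9)
  # exploding parameters abort with a diagnostic
  mb <- make_toy()
  mb$W[] <- 700        # exp overflow in the down pass
  mb$rate_cap <- Inf
  expect_error(suppressWarnings(cd1_step(mb, c(3, 3, 3), lr_w = 1)),
               "learning rate")
})

test_that("CD-1 training improves the enumerated visible marginal (KL to data)", {
  # tiny 2-visible/2-hidden model; target data concentrated on two modes
  set.seed(29)
  target <- rbind(matrix(rep(c(0L, 4L), 150), ncol = 2, byrow = TRUE),
                  matrix(rep(c(4L, 0L), 150), ncol = 2, byrow = TRUE))
  target <- target[sample.int(300), ]
  kmax <- 12
  states <- as.matrix(expand.grid(0:kmax, 0:kmax))
  enum_marginal <- function(m) {
    vstates <- as.matrix(expand.grid(0:1, 0:1))
    lw <- matrix(-Inf, nrow(states), 1)
    # log p(r) ~ log sum_v exp(b_v.r + b_h.v + r' W v) - log prod r!
    lr_fact <- rowSums(lgamma(states + 1))
    A <- states %*% m$W          # n_states x H terms r'W
    lse <- sapply(seq_len(nrow(vstates)), function(s) {
      v <- vstates[s, ]
      drop(states %*% m$b_vis) + sum(m$b_hid * v) + drop(A %*% v)
    })
    mx <- apply(lse, 1, max)
    lp <- mx + log(rowSums(exp(lse - mx))) - lr_fact
    p <- exp(lp - max(lp))
    p / sum(p)
  }
  kl_to_data <- function(m) {
    p_model <- enum_marginal(m)
    key <- paste(states[, 1], states[, 2])
    emp <- table(factor(paste(target[, 1], target[, 2]), levels = key))
    emp <- as.numeric(emp) / sum(emp)
    keep <- emp > 0
    sum(emp[keep] * log(emp[keep] / pmax(p_model[keep], 1e-300)))
  }
  set.seed(30)
  m <- harmonium(2, 2, rate_cap = 20)
  kl0 <- kl_to_data(m)
  sched <- training_schedule(n_vectors = 300, minibatch = 30,
                             epochs_per_stage = 100, n_stages = 2,
                             lr_w = 0.02, lr_bias = 0.02)
  m_t <- train_harmonium(m, target, sched)
  kl1 <- kl_to_data(m_t)
  expect_lt(kl1, 0.5 * kl0)
})

test_that("training is reproducible and lowers reconstruction deviance", {
  arm <- arm_model()
  pops <- integration_populations(arm, 6)
  set.seed(31)
  data <- sample_integration_batch(2000, arm, pops)$counts
  sched <- training_schedule(n_vectors = 2000, minibatch = 40,
                             epochs_per_stage = 5, n_stages = 2)
  run <- function() {
    set.seed(32)
    m <- harmonium(ncol(data), 36)
    set.seed(33)
    train_harmonium(m, data, sched)
  }
  m1 <- run()
  m2 <- run()
  expect_identical(m1$W, m2$W)
  expect_identical(m1$trace, m2$trace)
  expect_lt(tail(m1$trace, 1), 0.5 * m1$trace[1])
  expect_equal(m1$epochs_trained, 10L)
})

test_that("hidden_code averages Bernoulli samples with the right statistics", {
  m <- make_toy()
  r <- c(2, 1, 3)
  expect_equal(hidden_code(m, r, Inf), up_mean(m, r))
  set.seed(34)
  v15 <- hidden_code(m, r, 15)
  expect_true(all(v15 %in% ((0:15) / 15)))
  # variance of the average ~ p(1-p)/15
  set.seed(35)
  reps <- replicate(3000, hidden_code(m, r, 15))
  p <- up_mean(m, r)
  expect_equal(apply(reps, 1, var), p * (1 - p) / 15, tolerance = 0.1)
  expect_error(hidden_code(m, r, 0), "n_samples")
})
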