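test_that("Rescorla-Wagner update follows the delta rule", {
  p <- model_params(alpha = 0.3)
  st <- agent_state(1L, p, bayesian = FALSE)
  u <- rw_update(st, x = 1, r = 1, p)
  expect_equal(u$delta, 1)
  expect_equal(unname(u$state$w), 0.3)

  # overexpectation: two trained cues in compound produce a negative error
  st2 <- agent_state(2L, p, bayesian = FALSE)
  st2$w <- c(1, 1)
  u2 <- rw_update(st2, x = c(1, 1), r = 1, p)
  expect_equal(u2$delta, -1)
  expect_equal(unname(u2$state$w), c(0.7, 0.7))

  # zero error is a fixed point
  st3 <- agent_state(2L, p, bayesian = FALSE)
  st3$w <- c(0.4, 0.6)
  u3 <- rw_update(st3, x = c(1, 1), r = 1, p)
  expect_identical(u3$state$w, st3$w)

  # decaying schedule divides alpha by the step count
  p1n <- model_params(alpha = 1, lr_schedule = "one_over_n")
  st4 <- agent_state(1L, p1n, bayesian = FALSE)
  u4 <- rw_update(st4, 1, 1, p1n)          # n = 1, full step
  expect_equal(unname(u4$state$w), 1)
  u5 <- rw_update(u4$state, 1, 3, p1n)     # n = 2, half step toward delta
  expect_equal(unname(u5$state$w), 1 + (3 - 1) / 2)
})

test_that("Kalman filter gain, mean and covariance follow the LDS update", {
  p <- model_params()  # sigma_w2 = 1, sigma_r2 = 1, tau2 = 0.01
  st <- agent_state(1L, p)
  u <- kalman_step(st, x = 1, r = 1, p)
  expect_equal(unname(u$gain), 1.01 / 2.01, tolerance = 1e-12)
  expect_equal(unname(u$state$w), 1.01 / 2.01, tolerance = 1e-12)
  expect_equal(unname(u$state$Sigma[1, 1]), 1.01 - 1.01^2 / 2.01,
               tolerance = 1e-12)

  # huge observation noise: gain ~ 0, covariance just diffuses
  pn <- model_params(sigma_r2 = 1e12)
  st2 <- agent_state(2L, pn)
  u2 <- kalman_step(st2, c(1, 0), 1, pn)
  expect_lt(max(abs(u2$gain)), 1e-10)
  expect_equal(u2$state$w, st2$w, tolerance = 1e-9)
  expect_equal(u2$state$Sigma, st2$Sigma + diag(0.01, 2), tolerance = 1e-6)

  # Joseph form agrees with the standard form
  st3 <- agent_state(3L, p)
  x <- c(1, 1, 0)
  ua <- kalman_step(st3, x, 1, p, form = "standard")
  ub <- kalman_step(st3, x, 1, p, form = "joseph")
  expect_equal(ua$state$Sigma, ub$state$Sigma, tolerance = 1e-12)
  expect_equal(ua$state$w, ub$state$w)

  expect_error(kalman_step(st3, c(1, NA, 0), 1, p), "non-finite")
})

test_that("compound training stores cue competition as negative covariance", {
  p <- model_params()
  run <- run_model("AB→+", "KF", p)
  expect_lt(run$state$Sigma["A", "B"], 0)

  # magnitude agrees with the static conjugate posterior when tau2 = 0
  p0 <- model_params(tau2 = 0)
  run0 <- run_model("AB→+", "KF", p0)
  X <- matrix(1, 10, 2)
  post <- batch_posterior_oracle(X, rep(1, 10), 1, 1)
  expect_equal(unname(run0$state$Sigma), unname(post$cov), tolerance = 1e-10)
  expect_equal(unname(run0$state$w), unname(post$mean), tolerance = 1e-10)
})

test_that("TD update implements the temporal-difference error", {
  p <- model_params(alpha = 0.3, gamma = 0.98)
  st <- agent_state(2L, p, bayesian = FALSE)
  st$w <- c(0, 1)
  u <- td_step(st, x = c(1, 0), x_next = c(0, 1), r = 0, p)
  expect_equal(u$delta, 0.98)
  expect_equal(unname(u$state$w), c(0.294, 1))

  # gamma = 0 reduces exactly to Rescorla-Wagner
  p0 <- model_params(alpha = 0.3, gamma = 0)
  set.seed(1)
  st_td <- st_rw <- agent_state(3L, p0, bayesian = FALSE)
  for (i in 1:25) {
    x <- rbinom(3, 1, 0.5)
    r <- rbinom(1, 1, 0.5)
    st_td <- td_step(st_td, x, x_next = rbinom(3, 1, 0.5), r, p0)$state
    st_rw <- rw_update(st_rw, x, r, p0)$state
    expect_identical(st_td$w, st_rw$w)
  }

  # second-order step: no reward, but a valued successor drives learning
  st2 <- agent_state(2L, p, bayesian = FALSE)
  st2$w <- c(0, 0.8)
  u2 <- td_step(st2, c(1, 0), c(0, 1), r = 0, p)
  expect_gt(u2$delta, 0)
  expect_gt(u2$state$w[1], 0)
})

test_that("Kalman TD with gamma = 0 on one-step trials equals the Kalman filter", {
  p <- model_params(gamma = 0, bins_per_stimulus = 1L)
  d <- parse_design("A→+ / AB→-; B→+")
  ktd <- run_model(d, "KTD", p)
  kf <- run_model(d, "KF", p)
  expect_equal(unname(ktd$trace$w), unname(kf$trace$w))
  expect_equal(unname(ktd$state$Sigma), unname(kf$state$Sigma))
})

test_that("sequential filtering with tau2 = 0 matches the batch posterior", {
  p0 <- model_params(tau2 = 0)
  for (seed in 1:8) {
    prob <- rand_problem(seed, max_features = 8L, max_obs = 40L)
    st <- kalman_run_sequence(prob$X, prob$r, p0)
    post <- batch_posterior_oracle(prob$X, prob$r, 1, 1)
    expect_equal(unname(st$w), unname(post$mean), tolerance = 1e-10)
    expect_equal(unname(st$Sigma), unname(post$cov), tolerance = 1e-10)
  }
  # closed-form single observation and the empty-data prior
  one <- batch_posterior_oracle(matrix(1, 1, 1), 1, 1, 1)
  expect_equal(unname(one$mean), 0.5)
  expect_equal(unname(one$cov[1, 1]), 0.5)
  none <- batch_posterior_oracle(matrix(numeric(0), 0, 3), numeric(0), 2, 1)
  expect_equal(unname(none$mean), rep(0, 3))
  expect_equal(unname(none$cov), diag(2, 3))
})

test_that("posterior covariance stays symmetric positive semidefinite", {
  p <- model_params()
  set.seed(7)
  for (rep in 1:5) {
    D <- sample(2:6, 1)
    st <- agent_state(D, p)
    for (i in 1:60) {
      x <- rbinom(D, 1, 0.5)
      st <- kalman_step(st, x, rnorm(1), p)$state
      expect_equal(st$Sigma, t(st$Sigma))
      expect_gte(min_eigen(st$Sigma), -1e-8)
    }
  }
})

test_that("repeated exposure shrinks the gain; diffusion alone restores it", {
  p <- model_params()
  st <- agent_state(1L, p)
  gains <- numeric(10)
  for (i in 1:10) {
    u <- kalman_step(st, 1, 0, p)
    gains[i] <- u$gain
    st <- u$state
  }
  expect_true(all(diff(gains) < 0))
  # an interval of pure diffusion re-inflates the posterior and the gain
  st_wait <- kalman_predict(st, p, n = 200L)
  g_after <- kalman_step(st_wait, 1, 0, p)$gain
  expect_gt(g_after, gains[10])
})

test_that("parameter bounds are enforced", {
  expect_error(model_params(alpha = 2), "alpha")
  expect_error(model_params(gamma = -0.1), "gamma")
  expect_error(model_params(sigma_r2 = 0), "sigma_r2")
  expect_error(model_params(tau2 = -1), "tau2")
  expect_error(model_params(bins_per_stimulus = 2, serial_overlap = 2))
})
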