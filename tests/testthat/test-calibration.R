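test_that("objective is an exact weighted sum of scaled squared residuals", {
  p <- eh_params()
  cond <- reference_condition(duration = 30)
  # three-point toy dataset with known values; compute the model curve once
  times <- c(4, 8, 24)
  traj <- simulate_batch(cond, p, times = c(0, times))
  mod_g <- traj$c_g_g_per_L[-1]
  obs <- tibble::tibble(
    condition_id = "toy", time_h = times, observable = "glucose",
    value = mod_g + c(1, -2, 0.5), weight = c(1, 2, 1)
  )
  o <- eh_objective(p, obs, conditions = list(toy = cond), rtol = 1e-8,
                    atol = 1e-12)
  scale <- max(obs$value)
  by_hand <- sum(obs$weight * ((mod_g - obs$value) / scale)^2)
  expect_equal(o, by_hand, tolerance = 1e-8)
  expect_error(eh_objective(p, obs[0, ], conditions = list(toy = cond)),
               "empty")
})

test_that("objective is zero at the generating parameters and rises away", {
  truth <- eh_params()
  data <- generate_batch_set(truth, design = batch_design()[c(1, 4), ],
                             noise = noise_model(0, 0))
  expect_lt(eh_objective(truth, data), 1e-10)
  worse <- eh_objective(update_params(truth, k_R = 14713 * 1.4), data)
  expect_gt(worse, eh_objective(truth, data))
  expect_gt(worse, 1e-3)
})

test_that("objective is invariant to dataset row order", {
  truth <- eh_params()
  data <- generate_batch_set(truth, design = batch_design()[c(1, 7), ],
                             noise = noise_model(0.05, 0.05, seed = 3))
  p <- update_params(truth, k_R = 1.2e4)
  o1 <- eh_objective(p, data)
  shuffled <- data[sample(nrow(data)), ]
  attr(shuffled, "conditions") <- attr(data, "conditions")
  expect_equal(eh_objective(p, shuffled), o1, tolerance = 1e-12)
})

test_that("bound transforms are inverse bijections and respect the box", {
  b <- default_bounds()
  set.seed(41)
  for (i in 1:20) {
    theta <- c(k_R = 10^runif(1, 0.1, 5.9), k_X = 10^runif(1, 0.1, 3.9),
               k_L = runif(1, 1, 9999), K_dR = 10^runif(1, -3.9, 0.9),
               kappa_RF = runif(1, 0.2, 49), kappa_RX = runif(1, 0.2, 49),
               kappa_RL = runif(1, 0.2, 49), kappa_Rs = runif(1, 0.2, 49),
               y_F0 = runif(1))
    z <- ehsim:::to_unconstrained(theta, b)
    back <- ehsim:::from_unconstrained(z, b)
    expect_equal(back, theta, tolerance = 1e-6)
    # arbitrary reals map inside the box
    z2 <- stats::setNames(rnorm(length(theta), sd = 20), names(theta))
    th2 <- ehsim:::from_unconstrained(z2, b)
    for (nm in names(th2)) {
      bb <- b[b$term == nm, ]
      expect_gte(th2[[nm]], bb$lower)
      expect_lte(th2[[nm]], bb$upper)
    }
  }
})

test_that("a fit started at the truth converges there with ~zero objective", {
  truth <- eh_params()
  data <- generate_batch_set(truth, design = batch_design()[c(1, 4, 7), ],
                             noise = noise_model(0, 0))
  fit <- fit_batch(data, init = truth, n_starts = 1, perturb = 0,
                   maxit = 300, seed = 7)
  expect_lt(fit$objective, 1e-8)
  est <- params_vector(fit$params)
  tv <- params_vector(truth)
  for (nm in c("k_R", "kappa_RF", "y_F0")) {
    expect_equal(est[[nm]], tv[[nm]], tolerance = 0.01)
  }
  # broom-style accessors
  td <- tidy(fit)
  expect_setequal(td$term, fit$free)
  expect_true(all(is.finite(td$estimate)))
  gl <- glance(fit)
  expect_equal(gl$n_obs, nrow(data))
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("parameters generated on a bound are flagged as bound-active", {
  truth <- eh_params() # kappa_RL = kappa_Rs = 50 sit on the default bound
  data <- generate_batch_set(truth, design = batch_design()[c(1, 7), ],
                             noise = noise_model(0, 0))
  fit <- fit_batch(data, init = truth, n_starts = 1, perturb = 0,
                   maxit = 300, seed = 7)
  expect_true(fit$at_bound[["kappa_Rs"]])
  expect_false(fit$at_bound[["kappa_RF"]])
})

test_that("fit result is invariant to dataset ordering", {
  truth <- eh_params()
  data <- generate_batch_set(truth, design = batch_design()[c(1, 4), ],
                             noise = noise_model(0.03, 0.05, seed = 9))
  f1 <- fit_batch(data, init = truth, n_starts = 1, perturb = 0, maxit = 40,
                  seed = 5)
  rev_data <- data[rev(seq_len(nrow(data))), ]
  attr(rev_data, "conditions") <- attr(data, "conditions")
  f2 <- fit_batch(rev_data, init = truth, n_starts = 1, perturb = 0,
                  maxit = 40, seed = 5)
  expect_equal(f1$objective, f2$objective, tolerance = 1e-10)
  expect_equal(params_vector(f1$params), params_vector(f2$params),
               tolerance = 1e-8)
})
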