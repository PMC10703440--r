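test_that("choice probability has the closed logistic form", {
  p0 <- model_params(gamma = 0, lambda = 0, delta0 = 0, alpha = 1, n_lags = 0)
  expect_equal(predict_choice_prob(p0, 0, numeric(0)), 0.5)
  expect_equal(predict_choice_prob(p0, 1, numeric(0)), 1 / (1 + exp(-1)))

  p1 <- model_params(gamma = 0.1, lambda = 0.2, delta0 = 0, alpha = 1,
                     n_lags = 0)
  expect_equal(predict_choice_prob(p1, 1e4, numeric(0)), 0.8) # 1 - lambda
  expect_equal(predict_choice_prob(p1, -1e4, numeric(0)), 0.1) # gamma
})

test_that("bias term is the kernel-weighted linear sum", {
  expect_equal(bias_term(model_params(delta0 = 0.3, n_lags = 0), numeric(0)),
               0.3)
  p <- model_params(delta0 = 0, omega = c(0.5, 0.2), n_lags = 1)
  expect_equal(bias_term(p, c(1, 1)), 0.7)
  # a zero-coherence previous stimulus contributes nothing via its z code
  expect_equal(bias_term(p, c(1, 0)), 0.5)
  expect_error(bias_term(p, c(1, 1, 1)), "2 \\* n_lags")
})

test_that("history vectors follow the (choices, stimuli) ordering with 0 padding", {
  tr <- hand_trials(category = c(1, 1, -1), coherence = c(0.09, 0.09, 0.09),
                    choice = c(1, -1, 1))
  expect_equal(history_vector(tr, 1, 2), rep(0, 4))
  # t = 3, n = 2: (c2, c1, z2, z1)
  expect_equal(history_vector(tr, 3, 2), c(-1, 1, 1, 1))

  # previous 0%-coherence trial: z entry 0, choice entry unchanged
  tr0 <- hand_trials(category = c(1, -1), coherence = c(0, 0.27),
                     choice = c(1, 1))
  expect_equal(history_vector(tr0, 2, 1), c(1, 0))

  # history never crosses block boundaries
  tr2 <- hand_trials(category = c(1, 1, 1, 1), coherence = rep(0.27, 4),
                     choice = c(1, 1, -1, -1), block = c(1L, 1L, 2L, 2L))
  expect_equal(history_vector(tr2, 3, 2), rep(0, 4))
})

test_that("log-likelihood equals brute-force per-trial summation", {
  p <- model_params(gamma = 0.05, lambda = 0.1, delta0 = 0.2, alpha = 2,
                    omega = c(0.3, -0.4), n_lags = 1)
  tr <- hand_trials(category = c(1, -1, -1, 1, 1),
                    coherence = c(0.03, 0, 0.27, 0.81, 0.09),
                    choice = c(1, 1, -1, 1, -1))
  # independent oracle: accumulate trial by trial with scalar arithmetic
  z <- ifelse(tr$coherence > 0, tr$category, 0)
  L <- 0
  for (t in seq_len(5)) {
    h <- c(if (t > 1) tr$choice[t - 1] else 0, if (t > 1) z[t - 1] else 0)
    x <- p$delta0 + sum(p$omega * h) + p$alpha * tr$signed_stim[t]
    p_up <- p$gamma + (1 - p$gamma - p$lambda) / (1 + exp(-x))
    L <- L + log(if (tr$choice[t] == 1) p_up else 1 - p_up)
  }
  expect_equal(log_likelihood(p, tr), L)

  # chance model: T * ln(0.5)
  p5 <- model_params(gamma = 0, lambda = 0, delta0 = 0, alpha = 0, n_lags = 0)
  expect_equal(log_likelihood(p5, tr), 5 * log(0.5))

  # no-response trials are excluded
  tr$choice[2] <- NA
  expect_equal(log_likelihood(p5, tr), 4 * log(0.5))
})

test_that("choice probability is monotone in stimulus and history", {
  p <- model_params(gamma = 0.05, lambda = 0.05, delta0 = 0, alpha = 2,
                    omega = c(0.5, 0.3), n_lags = 1)
  s <- seq(-1, 1, length.out = 21)
  probs <- predict_choice_prob(p, s, matrix(0, 21, 2))
  expect_true(all(diff(probs) > 0))
  for (k in 1:2) {
    h_lo <- h_hi <- rep(0, 2)
    h_lo[k] <- -1; h_hi[k] <- 1
    expect_lt(predict_choice_prob(p, 0.1, h_lo),
              predict_choice_prob(p, 0.1, h_hi))
  }
})

test_that("the optimizer's internal gradient matches finite differences", {
  tr <- make_trials(blocks = 1, seed = 10)
  d <- histbias:::ll_env(tr, 2, slope_by_session = FALSE)
  theta <- c(0.07, 0.12, 0.15, 3, 0.2, -0.1, 0.3, 0.05)
  an <- histbias:::ll_value_grad(theta, d)$grad
  num <- vapply(seq_along(theta), function(i) {
    e <- rep(0, length(theta)); e[i] <- 1e-6
    (histbias:::ll_value_grad(theta + e, d)$value -
       histbias:::ll_value_grad(theta - e, d)$value) / 2e-6
  }, numeric(1))
  expect_equal(an, num, tolerance = 1e-5)
})

test_that("fitting recovers generating parameters on a moderate sample", {
  true <- model_params(gamma = 0.05, lambda = 0.05, delta0 = 0, alpha = 2,
                       omega = c(0, 0.6), n_lags = 1)
  tr <- make_trials(blocks = 30, seed = 21, params = true) # ~3000 trials
  fit <- fit_history_model(tr, 1, restarts = 3, seed = 2,
                           slope_by_session = FALSE)
  expect_true(fit$converged)
  expect_lt(abs(fit$params$alpha - 2), 0.3)
  expect_lt(abs(omega_stim(fit$params)[1] - 0.6), 0.15)
  expect_lt(abs(omega_choice(fit$params)[1] - 0), 0.15)
  expect_lt(abs(fit$params$delta0), 0.15)

  # fitted likelihood dominates the truth on the training set
  expect_gte(fit$loglik, log_likelihood(true, tr) - 1e-6)
})

test_that("a memoryless agent yields small fitted kernels", {
  true <- model_params(gamma = 0.05, lambda = 0.05, alpha = 2,
                       omega = c(0, 0), n_lags = 1)
  tr <- make_trials(blocks = 20, seed = 31, params = true)
  fit <- fit_history_model(tr, 1, restarts = 3, slope_by_session = FALSE)
  expect_lt(max(abs(fit$params$omega)), 0.12)
})

test_that("an insensitive agent is fitted near chance", {
  true <- model_params(gamma = 0.02, lambda = 0.02, alpha = 0,
                       omega = numeric(0), n_lags = 0)
  tr <- make_trials(blocks = 10, seed = 41, params = true)
  fit <- fit_history_model(tr, 0, restarts = 3, slope_by_session = FALSE)
  H <- history_matrix(tr, 0)
  probs <- predict_choice_prob(fit$params, tr$signed_stim, H)
  expect_true(all(abs(probs - 0.5) < 0.1))
})

test_that("per-session slopes are fitted separately and averaged", {
  true <- model_params(gamma = 0.05, lambda = 0.05, alpha = 3,
                       omega = numeric(0), n_lags = 0)
  tr <- make_trials(blocks = 12, seed = 51, params = true)
  fit <- fit_history_model(tr, 0, restarts = 2, slope_by_session = TRUE)
  expect_length(fit$alpha_by_session, length(unique(tr$session)))
  expect_equal(fit$params$alpha, mean(fit$alpha_by_session))
})

test_that("lag-1 kernel estimates are unbiased at the per-environment trial count", {
  # 50 simulated subjects at 6 blocks x 99 trials under the default
  # (saturating) sensitivity; mean signed error of both lag-1 kernels small
  true <- model_params(gamma = 0.05, lambda = 0.05, delta0 = 0, alpha = 9,
                       omega = c(0.1, 0.6), n_lags = 1)
  err <- vapply(1:50, function(i) {
    tri <- make_trials(blocks = 6, seed = 600 + i, params = true)
    f <- fit_history_model(tri, 1, restarts = 2, seed = i,
                           slope_by_session = FALSE)
    f$params$omega - true$omega
  }, numeric(2))
  expect_lt(abs(mean(err[1, ])), 0.05)
  expect_lt(abs(mean(err[2, ])), 0.05)
})

test_that("tidy and glance expose the fit in broom shape", {
  tr <- make_trials(blocks = 2, seed = 61)
  fit <- fit_history_model(tr, 1, restarts = 2)
  td <- tidy(fit)
  expect_equal(td$term,
               c("gamma", "lambda", "delta0", "alpha",
                 "choice_lag1", "stim_lag1"))
  gl <- glance(fit)
  expect_equal(gl$nobs, nrow(tr))
  expect_lte(gl$logLik, 0)
})
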