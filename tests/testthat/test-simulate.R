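test_that("degenerate repetition probabilities give deterministic chains", {
  env1 <- environment_spec("repetitive", p_rep = 1, blocks = 2)
  st1 <- simulate_stimuli(env1, seed = 5)
  per_block <- split(st1$category, st1$block)
  expect_true(all(vapply(per_block, function(x) length(unique(x)) == 1,
                         logical(1))))

  env0 <- environment_spec("alternating", p_rep = 0, blocks = 2)
  st0 <- simulate_stimuli(env0, seed = 5)
  per_block <- split(st0$category, st0$block)
  expect_true(all(vapply(per_block, function(x) all(diff(x) != 0),
                         logical(1))))
})

test_that("empirical repetition frequency matches p_rep at large n", {
  for (nm in c("repetitive", "neutral", "alternating")) {
    env <- environment_spec(nm, blocks = 102) # ~10k trials
    st <- simulate_stimuli(env, seed = 7)
    reps <- unlist(lapply(split(st$category, st$block),
                          function(x) x[-1] == x[-length(x)]))
    p_hat <- mean(reps)
    # binomial 99.9% bounds around the nominal p_rep
    tol <- 3.3 * sqrt(env$p_rep * (1 - env$p_rep) / length(reps))
    expect_lt(abs(p_hat - env$p_rep), tol)
  }
})

test_that("long-run up-category frequency is one half in every environment", {
  for (nm in c("repetitive", "neutral", "alternating")) {
    env <- environment_spec(nm, blocks = 102)
    st <- simulate_stimuli(env, seed = 3)
    expect_lt(abs(mean(st$category == 1) - 0.5), 0.03)
  }
})

test_that("coherences are balanced per direction within blocks", {
  env <- environment_spec("neutral", blocks = 4)
  st <- simulate_stimuli(env, seed = 2)
  for (b in unique(st$block)) {
    tb <- st[st$block == b, ]
    expect_equal(sum(tb$coherence == 0), 11)
    expect_equal(sum(tb$signed_stim == 0), 11) # only 0% carries no direction
    # within each direction, nonzero coherence counts differ by at most 1
    for (d in c(-1, 1)) {
      counts <- table(tb$coherence[tb$category == d & tb$coherence > 0])
      expect_lte(diff(range(counts)), 1)
    }
    # zero-coherence trials still carry a Markov category
    expect_true(all(tb$category[tb$coherence == 0] %in% c(-1, 1)))
  }
})

test_that("generation is reproducible from the seed", {
  env <- environment_spec("repetitive", blocks = 2)
  a <- simulate_stimuli(env, seed = 42)
  b <- simulate_stimuli(env, seed = 42)
  expect_identical(a, b)
  expect_false(identical(a, simulate_stimuli(env, seed = 43)))

  p <- model_params(omega = c(0.1, 0.3), n_lags = 1)
  expect_identical(simulate_choices(a, p, seed = 9),
                   simulate_choices(a, p, seed = 9))

  sim1 <- simulate_experiment(1, environments = "neutral", blocks = 2, seed = 5)
  sim2 <- simulate_experiment(1, environments = "neutral", blocks = 2, seed = 5)
  expect_identical(sim1$trials, sim2$trials)
  expect_identical(sim1$epochs[[1]]$y, sim2$epochs[[1]]$y)
})

test_that("saturated sensitivity forces stimulus-following choices", {
  p <- model_params(gamma = 0, lambda = 0, alpha = 1e4,
                    omega = numeric(0), n_lags = 0)
  tr <- make_trials(params = p, seed = 3)
  sig <- tr[tr$coherence > 0, ]
  expect_true(all(sig$choice == sign(sig$signed_stim)))
})

test_that("with no sensitivity and huge bias, up-rate approaches 1 - lambda", {
  p <- model_params(gamma = 0.1, lambda = 0.2, delta0 = 50, alpha = 0,
                    omega = numeric(0), n_lags = 0)
  tr <- make_trials(params = p, blocks = 30, seed = 4)
  expect_lt(abs(mean(tr$choice == 1) - 0.8), 0.03)
})

test_that("agent choice probabilities use the agent's own history", {
  # strongly positive choice kernel induces strong choice repetition
  p <- model_params(gamma = 0, lambda = 0, alpha = 0,
                    omega = c(3, 0), n_lags = 1)
  tr <- make_trials(params = p, blocks = 10, seed = 6)
  reps <- unlist(lapply(split(tr$choice, tr$block),
                        function(x) x[-1] == x[-length(x)]))
  expect_gt(mean(reps), 0.9)
})

test_that("noise-free epochs are built exactly from their components", {
  env <- environment_spec("neutral", blocks = 1)
  tr <- simulate_choices(simulate_stimuli(env, 1), model_params(), 2)

  ep0 <- simulate_epochs(tr, bias = rep(0, nrow(tr)),
                         coefs = neural_coefs(a = 0, b = 0, q = 0, sigma = 0),
                         seed = 1)
  expect_true(all(ep0$y == 0))

  epq <- simulate_epochs(tr, bias = rep(0, nrow(tr)),
                         coefs = neural_coefs(a = 0, b = 0, q = 1, sigma = 0),
                         seed = 1)
  bl <- baseline_amplitude(epq)
  nonzero <- tr$prev_choice != 0
  expect_true(all(sign(bl[nonzero]) == sign(tr$prev_choice[nonzero])))
  # ramp: before evidence onset no coherence/bias signal
  epa <- simulate_epochs(tr, bias = rep(0, nrow(tr)),
                         coefs = neural_coefs(a = -1, b = 0, q = 0, sigma = 0),
                         seed = 1)
  pre <- epa$times < 0
  expect_true(all(epa$y[, pre] == 0))
  # at end of evidence the amplitude equals a * signed coherence
  at_end <- which.min(abs(epa$times - 0.75))
  expect_equal(epa$y[, at_end], -tr$signed_stim, tolerance = 1e-12)

  expect_error(simulate_epochs(tr, bias = c(0, 1), seed = 1),
               "one value per trial")
})

test_that("ground truth travels with simulated experiments", {
  sim <- simulate_experiment(1, environments = c("repetitive", "neutral"),
                             blocks = 2, seed = 8, coefs = neural_coefs())
  gt <- attr(sim, "ground_truth")
  expect_named(gt, c("behavior_params", "neural_coefs"))
  expect_s3_class(gt$behavior_params$repetitive, "model_params")
  expect_length(sim$true_bias, nrow(sim$trials))
  # true bias equals the generating bias term evaluated on realised history
  idx <- sim$trials$environment == "repetitive"
  H <- history_matrix(sim$trials[idx, ], 1)
  expect_equal(sim$true_bias[idx],
               as.numeric(bias_term(gt$behavior_params$repetitive, H)))
})
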