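# Shared fixture builders; everything is generated in code at test time.

make_trials <- function(environment = "neutral", blocks = 2, seed = 1,
                        params = model_params(omega = c(0.1, 0.4), n_lags = 1),
                        trials_per_block = 99) {
  env <- environment_spec(environment, blocks = blocks,
                          trials_per_block = trials_per_block)
  simulate_choices(simulate_stimuli(env, seed = seed), params,
                   seed = seed + 1000)
}

# tiny hand-rolled trial table for definitional checks
hand_trials <- function(category, coherence, choice,
                        block = rep(1L, length(category))) {
  tibble::tibble(
    subject = 1L, session = 1L, block = block,
    environment = "neutral", trial = stats::ave(category, block,
                                                FUN = seq_along),
    category = as.integer(category), coherence = coherence,
    signed_stim = coherence * category,
    choice = as.integer(choice),
    prev_choice = 0L, correct = NA_integer_, hand_map = 1L, seed = 0L
  )
}
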