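#' Simulate a Markov stimulus-category sequence with balanced coherences
#'
#' Generates the stimulus side of a trial table for one environment: within
#' each block the stimulus category follows a symmetric two-state Markov
#' chain with repetition probability `env$p_rep` (first trial of a block
#' drawn uniformly; blocks are independent chains), and motion coherences
#' are assigned so that the counts per coherence-by-direction cell are as
#' equal as integer counts allow.
#'
#' With 99 trials and coherence levels \{0, 0.03, 0.09, 0.27, 0.81\} there
#' are nine cells (four signed coherences times two directions plus the
#' direction-less 0 level), so 11 trials go to each cell. In general
#' `floor(trials_per_block / n_cells)` trials are reserved per cell and any
#' remainder is assigned to the 0 level; within each direction the nonzero
#' coherences are dealt as evenly as the realised Markov direction counts
#' allow (any leftover slots receive coherences drawn without replacement
#' from the level set), then shuffled onto that direction's trials.
#'
#' Zero-coherence trials keep their Markov category (the chain runs through
#' them) but their signed stimulus, and hence their stimulus-history code,
#' is 0.
#'
#' @param env An [environment_spec].
#' @param seed Integer seed; the same seed reproduces the same sequence.
#' @param subject,session_blocks Metadata written into the table: subject id,
#'   and number of consecutive blocks grouped into one session (default 2,
#'   mirroring two blocks per environment per session).
#' @return A tibble with one row per trial: `subject`, `session`, `block`,
#'   `environment`, `trial`, `category` (+1/-1), `coherence`, `signed_stim`,
#'   `hand_map` (+1 if the right hand codes up in that block, -1 otherwise)
#'   and `seed`. Choice columns are filled by [simulate_choices()].
#' @examples
#' env <- environment_spec("repetitive", blocks = 1)
#' head(simulate_stimuli(env, seed = 1))
#' @export
simulate_stimuli <- function(env, seed, subject = 1L, session_blocks = 2L) {
  stopifnot(inherits(env, "environment_spec"))
  session_blocks <- assert_count(session_blocks, "session_blocks")
  with_seed(seed, {
    blocks <- purrr::map(seq_len(env$blocks), function(b) {
      tb <- simulate_block(env)
      tb$block <- b
      tb
    })
    out <- dplyr::bind_rows(blocks)
  })
  out$subject <- subject
  out$session <- ((out$block - 1L) %/% session_blocks) + 1L
  out$environment <- env$name
  out$seed <- as.integer(seed)
  dplyr::select(
    out, "subject", "session", "block", "environment", "trial",
    "category", "coherence", "signed_stim", "hand_map", "seed"
  )
}

# One block: Markov categories + balanced coherence allocation.
simulate_block <- function(env) {
  n <- env$trials_per_block
  p <- env$p_rep
  category <- integer(n)
  category[1] <- sample(c(-1L, 1L), 1L)
  if (n > 1) {
    rep_draw <- stats::runif(n - 1) < p
    for (t in 2:n) {
      category[t] <- if (rep_draw[t - 1]) category[t - 1] else -category[t - 1]
    }
  }

  lv <- env$coherence_levels
  nonzero <- lv[lv > 0]
  has_zero <- any(lv == 0)
  n_cells <- 2L * length(nonzero) + as.integer(has_zero)
  base <- n %/% n_cells
  n_zero <- if (has_zero) base + (n - base * n_cells) else 0L

  coherence <- numeric(n)
  idx_all <- seq_len(n)
  idx_zero <- if (n_zero > 0) sample(idx_all, n_zero) else integer(0)
  coherence[idx_zero] <- 0
  idx_signal <- setdiff(idx_all, idx_zero)
  for (d in c(-1L, 1L)) {
    idx_d <- idx_signal[category[idx_signal] == d]
    n_d <- length(idx_d)
    if (n_d == 0) next
    pool <- rep(nonzero, each = n_d %/% length(nonzero))
    extra <- n_d - length(pool)
    if (extra > 0) pool <- c(pool, sample(nonzero, extra))
    coherence[idx_d] <- sample(pool)
  }

  tibble::tibble(
    trial = seq_len(n),
    category = category,
    coherence = coherence,
    signed_stim = coherence * category,
    hand_map = sample(c(-1L, 1L), 1L)
  )
}

#' Simulate choices of a history-biased observer
#'
#' Completes a stimulus table (from [simulate_stimuli()]) with choices drawn
#' from the history-kernel psychometric model: on every trial the up-choice
#' probability is evaluated from the agent's own previous choices and the
#' previous stimulus categories (see [model_params]), and the choice is
#' drawn from a Bernoulli. History never crosses block boundaries; lags
#' reaching before the first trial of a block are coded 0.
#'
#' @param stimuli Trial tibble with `category`, `coherence`, `signed_stim`,
#'   grouped into blocks by `subject`, `environment`, `block`.
#' @param params A [model_params] object governing the agent.
#' @param seed Integer seed.
#' @return The input tibble with columns `choice` (+1/-1), `prev_choice`
#'   (previous choice within block, 0 on first trials) and `correct`
#'   (1/0, `NA` on zero-coherence trials where accuracy is undefined).
#' @examples
#' env <- environment_spec("neutral", blocks = 1)
#' stim <- simulate_stimuli(env, seed = 1)
#' trials <- simulate_choices(stim, model_params(omega = c(0.1, 0.6)), seed = 2)
#' table(trials$choice)
#' @export
simulate_choices <- function(stimuli, params, seed) {
  stopifnot(inherits(params, "model_params"))
  n_lag <- params$n_lags
  out <- with_seed(seed, {
    stimuli |>
      dplyr::group_by(.data$subject, .data$environment, .data$block) |>
      dplyr::group_modify(function(tb, key) {
        n <- nrow(tb)
        z <- ifelse(tb$coherence > 0, tb$category, 0)
        choice <- integer(n)
        u <- stats::runif(n)
        for (t in seq_len(n)) {
          h <- history_lags(choice, z, t, n_lag)
          p_up <- params$gamma + (1 - params$gamma - params$lambda) *
            stats::plogis(params$delta0 + sum(params$omega * h) +
                            params$alpha * tb$signed_stim[t])
          choice[t] <- if (u[t] < p_up) 1L else -1L
        }
        tb$choice <- choice
        tb$prev_choice <- c(0L, choice[-n])
        tb$correct <- ifelse(tb$coherence == 0, NA_integer_,
                             as.integer(choice == tb$category))
        tb
      }) |>
      dplyr::ungroup()
  })
  # restore original column-major trial order
  dplyr::arrange(out, .data$subject, .data$environment, .data$block, .data$trial)
}

# history vector (c_{t-1..t-n}, z_{t-1..t-n}) for one trial, 0-padded
history_lags <- function(choice, z, t, n_lag) {
  if (n_lag == 0) return(numeric(0))
  idx <- t - seq_len(n_lag)
  c(ifelse(idx >= 1, choice[pmax(idx, 1)], 0),
    ifelse(idx >= 1, z[pmax(idx, 1)], 0))
}

#' Simulate beta-lateralization epochs with known injected effects
#'
#' Generates one synthetic lateralization time course per trial, coded
#' relative to the hand that maps to up-choices (more negative = toward up):
#' \deqn{y_i(t) = q\, c^{prev}_i\, k(t) + r(t)\,(a\,\tilde{s}_i + b\,\delta_i) + \epsilon}
#' where \eqn{k(t)} is a previous-choice rebound kernel (a positive bump
#' covering the pre-evidence baseline, decaying linearly to zero by
#' `rebound_end` seconds after evidence onset), \eqn{r(t)} is a ramp that is
#' zero before evidence onset and grows linearly to 1 across the evidence
#' interval (then holds), and \eqn{\epsilon \sim N(0, \sigma^2)} i.i.d. over
#' timepoints.
#'
#' @param trials Completed trial tibble (needs `signed_stim`, `prev_choice`).
#' @param bias Per-trial bias values \eqn{\delta_t}, one per trial row
#'   (either ground truth from the generator or estimates from
#'   [single_trial_bias()]).
#' @param coefs A [neural_coefs] object.
#' @param seed Integer seed.
#' @param times Epoch time axis in seconds relative to evidence onset
#'   (default -0.55 to 1.5 s in 25-ms steps).
#' @param evidence_interval Onset and offset of the evidence ramp (default
#'   `c(0, 0.75)` s).
#' @param rebound_end Time by which the rebound kernel has decayed to zero
#'   (default 0.3 s).
#' @return A [neural_epochs] object (trials x timepoints).
#' @examples
#' env <- environment_spec("neutral", blocks = 1)
#' trials <- simulate_choices(simulate_stimuli(env, 1), model_params(), 2)
#' ep <- simulate_epochs(trials, bias = rep(0, nrow(trials)),
#'                       coefs = neural_coefs(sigma = 0), seed = 3)
#' dim(ep$y)
#' @export
simulate_epochs <- function(trials, bias, coefs = neural_coefs(), seed,
                            times = seq(-0.55, 1.5, by = 0.025),
                            evidence_interval = c(0, 0.75),
                            rebound_end = 0.3) {
  stopifnot(inherits(coefs, "neural_coefs"))
  n <- nrow(trials)
  if (length(bias) != n) {
    stop("`bias` must supply one value per trial row", call. = FALSE)
  }
  ramp <- ramp_profile(times, evidence_interval)
  keb <- rebound_profile(times, rebound_end)
  amp <- coefs$a * trials$signed_stim + coefs$b * bias
  y <- outer(rep(coefs$q, n) * trials$prev_choice, keb) + outer(amp, ramp)
  if (coefs$sigma > 0) {
    y <- y + with_seed(seed, matrix(stats::rnorm(n * length(times),
                                                 sd = coefs$sigma), n))
  }
  neural_epochs(y, times,
                coding = "vs_up_hand",
                trial_info = trials[, intersect(
                  c("subject", "session", "block", "environment", "trial",
                    "signed_stim", "coherence", "choice", "prev_choice"),
                  names(trials)
                )])
}

ramp_profile <- function(times, evidence_interval = c(0, 0.75)) {
  on <- evidence_interval[1]
  off <- evidence_interval[2]
  pmin(pmax((times - on) / (off - on), 0), 1)
}

rebound_profile <- function(times, rebound_end = 0.3) {
  t0 <- times[1]
  pmax((rebound_end - times) / (rebound_end - t0), 0)
}

#' Simulate a full multi-environment experiment with ground truth
#'
#' Chains [simulate_stimuli()], [simulate_choices()] and (optionally)
#' [simulate_epochs()] for one or more simulated subjects across the three
#' sensory environments, storing the generating parameters as a
#' `ground_truth` attribute. The ground truth travels with the dataset for
#' recovery checks but is never consumed by any fitting stage.
#'
#' The per-trial true bias \eqn{\delta_t} used to couple the epochs is the
#' generating model's own bias term, evaluated on each trial's realised
#' history.
#'
#' @param n_subjects Number of simulated subjects.
#' @param environments Character vector of environment names to include.
#' @param params Either one [model_params] for all environments or a named
#'   list of [model_params] keyed by environment name. The default agent
#'   repeats the previous stimulus category in `repetitive`
#'   (lag-1 stimulus weight +0.6), alternates it in `alternating` (-0.4),
#'   carries a small repetition tendency in `neutral` (+0.15), and a weak
#'   idiosyncratic choice kernel (+0.1) throughout.
#' @param coefs A [neural_coefs] object, or `NULL` to skip epoch generation.
#' @param seed Root seed; per-subject/stage seeds are derived from it.
#' @param blocks Blocks per environment (default 6).
#' @return A list of class `histbias_sim` with elements `trials` (tibble,
#'   all subjects), `epochs` (named list of [neural_epochs] per subject, or
#'   `NULL`), `true_bias` (numeric vector aligned with `trials`), and a
#'   `ground_truth` attribute (list with `behavior_params`, `neural_coefs`).
#' @examples
#' sim <- simulate_experiment(n_subjects = 1, blocks = 2, seed = 1,
#'                            coefs = NULL)
#' dplyr::count(sim$trials, environment)
#' @export
simulate_experiment <- function(n_subjects = 1,
                                environments = c("repetitive", "neutral",
                                                 "alternating"),
                                params = default_agent_params(),
                                coefs = neural_coefs(),
                                seed = 1,
                                blocks = 6) {
  if (inherits(params, "model_params")) {
    params <- stats::setNames(rep(list(params), length(environments)),
                              environments)
  }
  stopifnot(all(environments %in% names(params)))

  per_subject <- purrr::map(seq_len(n_subjects), function(s) {
    tl <- purrr::imap(stats::setNames(environments, environments), function(e, nm) {
      env <- environment_spec(e, blocks = blocks)
      st <- simulate_stimuli(env, seed = derive_seed(seed, s * 1000 + match(e, environments)),
                             subject = s)
      simulate_choices(st, params[[e]],
                       seed = derive_seed(seed, s * 1000 + 100 + match(e, environments)))
    })
    trials <- dplyr::bind_rows(tl)
    true_bias <- true_bias_series(trials, params)
    epochs <- NULL
    if (!is.null(coefs)) {
      epochs <- simulate_epochs(trials, true_bias, coefs,
                                seed = derive_seed(seed, s * 1000 + 500))
    }
    list(trials = trials, true_bias = true_bias, epochs = epochs)
  })

  trials <- dplyr::bind_rows(purrr::map(per_subject, "trials"))
  out <- structure(
    list(
      trials = trials,
      true_bias = unlist(purrr::map(per_subject, "true_bias"), use.names = FALSE),
      epochs = if (!is.null(coefs)) {
        stats::setNames(purrr::map(per_subject, "epochs"),
                        paste0("subject_", seq_len(n_subjects)))
      }
    ),
    class = "histbias_sim"
  )
  attr(out, "ground_truth") <- list(behavior_params = params,
                                    neural_coefs = coefs)
  out
}

#' Default generating parameters per environment
#'
#' The synthetic observer adapts its lag-1 stimulus kernel to the
#' environment (repeat in `repetitive`, alternate in `alternating`, a small
#' repetition tendency in `neutral`) while keeping a weak, environment-
#' independent choice kernel, matching the qualitative pattern of adaptive
#' history biases this package is built to recover.
#'
#' @return Named list of [model_params], keyed by environment name.
#' @export
default_agent_params <- function() {
  list(
    repetitive  = model_params(omega = c(0.1, 0.6),  n_lags = 1),
    neutral     = model_params(omega = c(0.1, 0.15), n_lags = 1),
    alternating = model_params(omega = c(0.1, -0.4), n_lags = 1)
  )
}

# True per-trial bias delta(h_t) under the generating parameters.
true_bias_series <- function(trials, params) {
  out <- numeric(nrow(trials))
  for (e in unique(trials$environment)) {
    idx <- which(trials$environment == e)
    pe <- params[[e]]
    h <- history_matrix(trials[idx, ], pe$n_lags)
    out[idx] <- bias_term(pe, h)
  }
  out
}
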