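#' Bias term of the psychometric function
#'
#' Evaluates \eqn{\delta(h) = \delta' + \sum_k \omega_k h_k}: the
#' trial-specific offset of the psychometric function, combining the overall
#' bias with the kernel-weighted history. Positive values are a bias toward
#' the up choice.
#'
#' @param params A [model_params] object.
#' @param h History vector of length `2 * n_lags`, or a matrix with one such
#'   row per trial (see [history_matrix()]).
#' @return Numeric scalar or vector of bias values.
#' @examples
#' p <- model_params(delta0 = 0, omega = c(0.5, 0.2), n_lags = 1)
#' bias_term(p, c(1, 1)) # 0.7
#' @export
bias_term <- function(params, h) {
  stopifnot(inherits(params, "model_params"))
  if (is.null(dim(h))) h <- matrix(h, nrow = 1)
  if (ncol(h) != 2 * params$n_lags) {
    stop("history length must equal 2 * n_lags", call. = FALSE)
  }
  drop(params$delta0 + if (ncol(h) > 0) h %*% params$omega else
    rep(0, nrow(h)))
}

#' Probability of an up-choice
#'
#' Evaluates the lapse-rate logistic psychometric model
#' \eqn{P(c = +1) = \gamma + (1 - \gamma - \lambda) g(\delta(h) + \alpha \tilde{s})}
#' for given parameters, signed stimulus and history. The probability is
#' bounded in \eqn{(\gamma, 1 - \lambda)}.
#'
#' @inheritParams bias_term
#' @param signed_stim Signed stimulus strength \eqn{\tilde{s}} (coherence
#'   times category), scalar or vector.
#' @return Probability of choosing up, same length as `signed_stim`.
#' @examples
#' p <- model_params(gamma = 0, lambda = 0, alpha = 1, n_lags = 0)
#' predict_choice_prob(p, 1, numeric(0)) # plogis(1)
#' @export
predict_choice_prob <- function(params, signed_stim, h) {
  d <- bias_term(params, h)
  params$gamma + (1 - params$gamma - params$lambda) *
    stats::plogis(d + params$alpha * signed_stim)
}

#' Log-likelihood of observed choices
#'
#' Summed log-probability \eqn{L = \sum_t \log P(c_t \mid \tilde{s}_t, h_t)}
#' of the observed choices under the history-kernel model. Trials without a
#' recorded choice (`NA`) are excluded. Probabilities are clipped at
#' `1e-10` before taking logs so a single mispredicted trial cannot produce
#' `-Inf`.
#'
#' @inheritParams bias_term
#' @param trials Trial tibble with recorded `choice` values.
#' @return The summed log-likelihood (a non-positive number).
#' @examples
#' env <- environment_spec("neutral", blocks = 1)
#' tr <- simulate_choices(simulate_stimuli(env, 1), model_params(), 2)
#' log_likelihood(model_params(), tr)
#' @export
log_likelihood <- function(params, trials) {
  keep <- !is.na(trials$choice) & trials$choice != 0
  trials <- trials[keep, , drop = FALSE]
  H <- history_matrix(trials, params$n_lags)
  p_up <- predict_choice_prob(params, trials$signed_stim, H)
  p_obs <- ifelse(trials$choice == 1, p_up, 1 - p_up)
  sum(log(pmax(p_obs, 1e-10)))
}

# --- internal likelihood machinery used by the optimizer --------------------
# theta = (gamma, lambda, delta0, alpha_1..S, omega_1..2n)

ll_env <- function(trials, n_lags, slope_by_session = TRUE) {
  keep <- !is.na(trials$choice) & trials$choice != 0
  trials <- trials[keep, , drop = FALSE]
  sess <- if (slope_by_session && "session" %in% names(trials)) {
    match(trials$session, sort(unique(trials$session)))
  } else rep(1L, nrow(trials))
  list(
    H = history_matrix(trials, n_lags),
    s = trials$signed_stim,
    up = trials$choice == 1,
    sess = sess,
    n_sess = max(sess),
    n_lags = as.integer(n_lags),
    n_trials = nrow(trials)
  )
}

ll_value_grad <- function(theta, d) {
  S <- d$n_sess
  gamma <- theta[1]; lambda <- theta[2]; delta0 <- theta[3]
  alpha <- theta[3 + seq_len(S)]
  omega <- theta[(3 + S) + seq_len(2 * d$n_lags)]
  x <- delta0 + alpha[d$sess] * d$s +
    if (d$n_lags > 0) drop(d$H %*% omega) else 0
  g <- stats::plogis(x)
  w <- 1 - gamma - lambda
  p <- gamma + w * g
  p_obs <- ifelse(d$up, p, 1 - p)
  p_clip <- pmax(p_obs, 1e-10)
  sgn <- ifelse(d$up, 1, -1)
  inv <- sgn / p_clip
  gp <- g * (1 - g)
  com <- inv * w * gp
  grad <- c(
    sum(inv * (1 - g)),
    sum(-inv * g),
    sum(com),
    vapply(seq_len(S), function(s) sum(com[d$sess == s] * d$s[d$sess == s]),
           numeric(1)),
    if (d$n_lags > 0) drop(crossprod(d$H, com)) else numeric(0)
  )
  list(value = sum(log(p_clip)), grad = unname(grad))
}
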