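#' Parameters of the history-kernel psychometric model
#'
#' The choice model is a lapse-rate logistic psychometric function whose
#' offset is shifted on every trial by a linear kernel over the recent
#' history of choices and stimulus categories:
#' \deqn{P(c_t = +1) = \gamma + (1 - \gamma - \lambda)\, g(\delta(h_t) + \alpha \tilde{s}_t)}
#' with \eqn{g(x) = 1 / (1 + e^{-x})},
#' \eqn{\delta(h_t) = \delta' + \sum_k \omega_k h_{k,t}}, and
#' \eqn{h_t = (c_{t-1}, \ldots, c_{t-n}, z_{t-1}, \ldots, z_{t-n})} the signed
#' codes of the previous `n` choices and stimulus categories (up = +1,
#' down = -1, zero-coherence stimulus = 0).
#'
#' @param gamma,lambda Lapse rates for up- and down-choices; both
#'   non-negative with `gamma + lambda < 1`. They bound the choice
#'   probability in `(gamma, 1 - lambda)`.
#' @param delta0 Overall (history-independent) bias \eqn{\delta'} toward the
#'   up choice.
#' @param alpha Psychometric slope (perceptual sensitivity), applied to the
#'   signed stimulus \eqn{\tilde{s} = } coherence \eqn{\times} category.
#' @param omega Kernel weights, length `2 * n_lags`: first the `n_lags`
#'   previous-choice weights (lag 1 first), then the `n_lags`
#'   previous-stimulus weights. Positive weights favour repeating.
#' @param n_lags Model order `n >= 0`; `n_lags = 0` is the history-free model.
#'
#' @return An object of class `model_params`.
#' @examples
#' model_params(alpha = 9, omega = c(0.1, 0.6), n_lags = 1)
#' @export
model_params <- function(gamma = 0.05, lambda = 0.05, delta0 = 0,
                         alpha = 9, omega = numeric(0), n_lags = NULL) {
  if (is.null(n_lags)) n_lags <- length(omega) / 2
  n_lags <- if (n_lags == 0) 0L else assert_count(n_lags, "n_lags")
  if (!is.numeric(gamma) || !is.numeric(lambda) || gamma < 0 || lambda < 0 ||
      gamma + lambda >= 1) {
    stop("lapse rates must satisfy gamma, lambda >= 0 and gamma + lambda < 1",
         call. = FALSE)
  }
  if (length(omega) != 2 * n_lags) {
    stop(sprintf("`omega` must have length 2 * n_lags = %d", 2 * n_lags),
         call. = FALSE)
  }
  structure(
    list(gamma = gamma, lambda = lambda, delta0 = delta0,
         alpha = alpha, omega = as.numeric(omega), n_lags = as.integer(n_lags)),
    class = "model_params"
  )
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf(
    "<model_params> n = %d | gamma = %.3f, lambda = %.3f, delta' = %.3f, alpha = %.3f\n",
    x$n_lags, x$gamma, x$lambda, x$delta0, mean(x$alpha)
  ))
  if (x$n_lags > 0) {
    cat("  omega (choice):   ", paste(signif(omega_choice(x), 3), collapse = ", "), "\n")
    cat("  omega (stimulus): ", paste(signif(omega_stim(x), 3), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Extract choice- and stimulus-kernel weights
#'
#' Convenience accessors for the two halves of the `omega` vector of a
#' [model_params] object: lag 1 to `n` previous-choice weights and lag 1 to
#' `n` previous-stimulus weights.
#'
#' @param params A [model_params] object (or fitted parameters from
#'   [fit_history_model()]).
#' @return Numeric vector of length `n_lags`.
#' @export
omega_choice <- function(params) {
  params$omega[seq_len(params$n_lags)]
}

#' @rdname omega_choice
#' @export
omega_stim <- function(params) {
  params$omega[params$n_lags + seq_len(params$n_lags)]
}

#' Ground-truth coefficients for synthetic lateralization epochs
#'
#' Coefficients used by [simulate_epochs()] to inject known effects into
#' synthetic beta-lateralization time courses (coded relative to the
#' up-coding hand, more negative = toward up):
#' a ramp whose slope scales with signed coherence (`a`) and single-trial
#' bias (`b`), a previous-choice beta-rebound component (`q`), and additive
#' Gaussian noise (`sigma`).
#'
#' Negative `a` and `b` reproduce the empirically expected direction of both
#' couplings: stronger evidence or bias toward up drives the lateralization
#' more negative.
#'
#' @param a Ramp coefficient per unit signed coherence (default -1).
#' @param b Ramp coefficient per unit single-trial bias (default -1).
#' @param q Amplitude of the previous-choice rebound bump (default 1).
#' @param sigma Standard deviation of i.i.d. Gaussian noise added to every
#'   timepoint (default 1).
#' @return An object of class `neural_coefs`.
#' @export
neural_coefs <- function(a = -1, b = -1, q = 1, sigma = 1) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(q),
            is.numeric(sigma), sigma >= 0)
  structure(list(a = a, b = b, q = q, sigma = sigma), class = "neural_coefs")
}
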