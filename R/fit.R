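#' Fit the history-kernel psychometric model
#'
#' Maximum-likelihood fit of the lapse-rate logistic model with history
#' kernels (see [model_params]) by bounded quasi-Newton optimisation
#' (`L-BFGS-B` with analytic gradients) from multiple restart points. The
#' likelihood is fully specified by the model, so direct constrained MLE is
#' used; restarts guard against local optima in the lapse/offset trade-off.
#'
#' Box constraints: \eqn{\gamma, \lambda \in [0, 0.45]} (so
#' \eqn{\gamma + \lambda \le 0.9}), \eqn{\delta' \in [-5, 5]},
#' \eqn{\alpha \in [0, 50]}, \eqn{\omega_k \in [-5, 5]}.
#'
#' When the table spans several sessions and `slope_by_session = TRUE`, one
#' slope parameter is fitted per session (all other parameters shared) and
#' the reported `alpha` is their mean.
#'
#' @param trials Trial tibble (at least one block; see [simulate_choices()]
#'   or [read_trials()] for the schema).
#' @param n_lags Model order `n >= 0`.
#' @param restarts Number of optimisation restarts (default 5).
#' @param seed Seed controlling the restart jitter; the fit is deterministic
#'   given the seed.
#' @param slope_by_session Fit the slope separately per session and average
#'   (default `TRUE`; a single-session table is unaffected).
#' @return An object of class `histbias_fit` with elements `params`
#'   ([model_params] at the optimum, `alpha` averaged across sessions),
#'   `alpha_by_session`, `loglik`, `converged`, `restarts_used`, `n_trials`.
#'   Non-convergence after all restarts is flagged, not an error.
#' @examples
#' env <- environment_spec("neutral", blocks = 2)
#' tr <- simulate_choices(simulate_stimuli(env, 1),
#'                        model_params(omega = c(0.1, 0.3)), 2)
#' fit <- fit_history_model(tr, n_lags = 1, restarts = 2)
#' tidy(fit)
#' @export
fit_history_model <- function(trials, n_lags, restarts = 5, seed = 1,
                              slope_by_session = TRUE) {
  n_lags <- if (n_lags == 0) 0L else assert_count(n_lags, "n_lags")
  restarts <- assert_count(restarts, "restarts")
  if (nrow(trials) < 10) stop("too few trials to fit", call. = FALSE)
  d <- ll_env(trials, n_lags, slope_by_session)
  S <- d$n_sess
  n_par <- 3 + S + 2 * n_lags
  lower <- c(0, 0, -5, rep(0, S), rep(-5, 2 * n_lags))
  upper <- c(0.45, 0.45, 5, rep(50, S), rep(5, 2 * n_lags))

  starts <- with_seed(seed, {
    base <- c(0.05, 0.05, 0, rep(1, S), rep(0, 2 * n_lags))
    jit <- purrr::map(seq_len(restarts - 1), function(i) {
      pmin(pmax(c(
        stats::runif(2, 0, 0.2),
        stats::rnorm(1, 0, 0.5),
        stats::runif(S, 0.5, 15),
        stats::rnorm(2 * n_lags, 0, 0.3)
      ), lower), upper)
    })
    c(list(base), jit)
  })

  neg_fn <- function(th) -ll_value_grad(th, d)$value
  neg_gr <- function(th) -ll_value_grad(th, d)$grad
  fits <- purrr::map(starts, function(st) {
    tryCatch(
      stats::optim(st, neg_fn, neg_gr, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 500)),
      error = function(e) NULL
    )
  })
  fits <- purrr::compact(fits)
  if (length(fits) == 0) stop("all optimisation restarts failed", call. = FALSE)
  vals <- purrr::map_dbl(fits, "value")
  best <- fits[[which.min(vals)]]
  # L-BFGS-B can overshoot a bound by machine epsilon
  theta <- pmin(pmax(best$par, lower), upper)
  alpha_s <- theta[3 + seq_len(S)]
  params <- model_params(
    gamma = theta[1], lambda = theta[2], delta0 = theta[3],
    alpha = mean(alpha_s),
    omega = theta[(3 + S) + seq_len(2 * n_lags)],
    n_lags = n_lags
  )
  structure(
    list(
      params = params,
      alpha_by_session = alpha_s,
      loglik = -best$value,
      converged = any(purrr::map_lgl(fits, ~ .x$convergence == 0)),
      restarts_used = length(fits),
      n_trials = d$n_trials,
      n_lags = n_lags
    ),
    class = "histbias_fit"
  )
}

#' @export
print.histbias_fit <- function(x, ...) {
  cat(sprintf("<histbias_fit> n_lags = %d, logLik = %.2f on %d trials%s\n",
              x$n_lags, x$loglik, x$n_trials,
              if (!x$converged) " (NOT converged)" else ""))
  print(x$params)
  invisible(x)
}

#' Tidy a fitted history-kernel model
#'
#' @param x A `histbias_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`term`, `estimate`).
#' @export
tidy.histbias_fit <- function(x, ...) {
  p <- x$params
  terms <- c("gamma", "lambda", "delta0", "alpha",
             if (p$n_lags > 0) c(paste0("choice_lag", seq_len(p$n_lags)),
                                 paste0("stim_lag", seq_len(p$n_lags))))
  tibble::tibble(
    term = terms,
    estimate = c(p$gamma, p$lambda, p$delta0, p$alpha, p$omega)
  )
}

#' @rdname tidy.histbias_fit
#' @export
glance.histbias_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik,
    n_lags = x$n_lags,
    nobs = x$n_trials,
    converged = x$converged,
    restarts_used = x$restarts_used
  )
}
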