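#' Psychometric fits conditioned on the previous stimulus category
#'
#' Fits the history-free (`n = 0`) lapse-rate logistic model separately to
#' the trials that followed an upward vs. a downward stimulus, per subject
#' and environment. Trials whose previous trial carried 0% coherence are
#' excluded (no defined previous category), as are first trials of a block.
#' Each condition's fit is fully independent (its own slope and lapses).
#'
#' The horizontal displacement of each conditioned curve is reported as
#' `shift = -delta0 / alpha` in signed-coherence units, and additionally as
#' `shift_rep = category * delta0 / alpha`, which is positive when the
#' shift is toward repeating the previous category.
#'
#' @param trials Trial tibble.
#' @param min_trials Conditions with fewer trials are flagged `low_power`
#'   (default 30).
#' @param restarts,seed Passed to [fit_history_model()].
#' @return A tibble with one row per subject x environment x previous
#'   category: fitted `gamma`, `lambda`, `delta0`, `alpha`, `shift`,
#'   `shift_rep`, `n_trials`, `low_power`.
#' @examples
#' \donttest{
#' sim <- simulate_experiment(1, environments = "repetitive", coefs = NULL,
#'                            blocks = 2, seed = 1)
#' fit_conditioned_psychometric(sim$trials)
#' }
#' @export
fit_conditioned_psychometric <- function(trials, min_trials = 30,
                                         restarts = 3, seed = 1) {
  prev <- trials |>
    dplyr::group_by(.data$subject, .data$environment, .data$block) |>
    dplyr::mutate(
      prev_cat = dplyr::lag(ifelse(.data$coherence > 0, .data$category, 0),
                            default = 0)
    ) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$prev_cat != 0)

  grid <- tidyr::expand_grid(
    dplyr::distinct(prev, .data$subject, .data$environment),
    prev_category = c(-1, 1)
  )
  purrr::pmap(grid, function(subject, environment, prev_category) {
    tb <- prev[prev$subject == subject & prev$environment == environment &
                 prev$prev_cat == prev_category, , drop = FALSE]
    fit <- fit_history_model(tb, n_lags = 0, restarts = restarts,
                             seed = derive_seed(seed, subject * 7 +
                                                  prev_category + 2))
    p <- fit$params
    tibble::tibble(
      subject = subject, environment = environment,
      prev_category = prev_category,
      gamma = p$gamma, lambda = p$lambda,
      delta0 = p$delta0, alpha = p$alpha,
      shift = -p$delta0 / p$alpha,
      shift_rep = prev_category * p$delta0 / p$alpha,
      n_trials = nrow(tb),
      low_power = nrow(tb) < min_trials
    )
  }) |>
    dplyr::bind_rows()
}

#' Bias-adjustment score between two environments
#'
#' Euclidean distance, in the plane spanned by the lag-1 previous-stimulus
#' and previous-choice kernel weights, between a subject's fits for the
#' repetitive and alternating environments:
#' \eqn{\sqrt{(\omega^{stim}_{rep} - \omega^{stim}_{alt})^2 +
#'            (\omega^{choice}_{rep} - \omega^{choice}_{alt})^2}}.
#' It measures how far the subject moved their history kernel between the
#' two structured environments; larger scores indicate stronger adaptation.
#'
#' @param fit_rep,fit_alt Either `histbias_fit` objects or named numeric
#'   vectors with elements `stim` and `choice` (lag-1 weights).
#' @return Non-negative scalar; 0 iff both lag-1 weight pairs are identical.
#' @examples
#' adjustment_score(c(stim = 0.5, choice = 0.3),
#'                  c(stim = -0.1, choice = -0.1))
#' @export
adjustment_score <- function(fit_rep, fit_alt) {
  w <- function(f) {
    if (inherits(f, "histbias_fit")) f <- f$params
    if (inherits(f, "model_params")) {
      if (f$n_lags < 1) stop("fit has no lag-1 weights", call. = FALSE)
      c(stim = omega_stim(f)[1], choice = omega_choice(f)[1])
    } else {
      if (!all(c("stim", "choice") %in% names(f))) {
        stop("weights must be named 'stim' and 'choice'", call. = FALSE)
      }
      f[c("stim", "choice")]
    }
  }
  sqrt(sum((w(fit_rep) - w(fit_alt))^2))
}

#' Partial Pearson correlation
#'
#' Correlation between `x` and `y` after removing the linear effect of a
#' covariate `z` from both: the Pearson correlation of the residuals of
#' `x ~ z` and `y ~ z`. Equivalent to the closed form
#' \eqn{(r_{xy} - r_{xz} r_{yz}) / \sqrt{(1 - r_{xz}^2)(1 - r_{yz}^2)}}.
#' The p-value uses the t distribution with `n - 3` degrees of freedom.
#'
#' @param x,y,z Equal-length numeric vectors, `n >= 4`.
#' @return A tibble with `estimate`, `statistic`, `p.value`, `n`.
#' @examples
#' set.seed(1)
#' z <- rnorm(30); x <- z + rnorm(30); y <- -z + rnorm(30)
#' partial_correlation(x, y, z)
#' @export
partial_correlation <- function(x, y, z) {
  n <- length(x)
  if (length(y) != n || length(z) != n) {
    stop("x, y, z must have equal length", call. = FALSE)
  }
  if (n < 4) stop("need at least 4 observations", call. = FALSE)
  rx <- stats::resid(stats::lm(x ~ z))
  ry <- stats::resid(stats::lm(y ~ z))
  if (is_constant(rx) || is_constant(ry)) {
    stop("a variable is (near-)collinear with the covariate; partial correlation undefined",
         call. = FALSE)
  }
  r <- stats::cor(rx, ry)
  df <- n - 3
  tstat <- r * sqrt(df / (1 - r^2))
  tibble::tibble(
    estimate = r,
    statistic = tstat,
    p.value = 2 * stats::pt(-abs(tstat), df),
    n = n
  )
}

#' Summarise lag-1 kernel weights across subjects
#'
#' Takes per-subject, per-environment lag-1 weights and produces the
#' group-level read-outs used for kernel statistics: per-environment means,
#' per-subject weight shifts relative to the neutral environment, and the
#' angles of those shifts in the (stimulus-weight, choice-weight) plane
#' (angle 0 = pure stimulus-weight shift, measured counter-clockwise;
#' inputs for circular tests such as [rayleigh_test()]).
#'
#' @param weights Tibble with columns `subject`, `environment`,
#'   `omega_stim1`, `omega_choice1` (see [kernel_weights()]).
#' @return A list with tibbles `means` (per environment) and `shifts`
#'   (per subject x biased environment, with `d_stim`, `d_choice`, `angle`).
#' @export
kernel_summary <- function(weights) {
  needed <- c("subject", "environment", "omega_stim1", "omega_choice1")
  if (!all(needed %in% names(weights))) {
    stop("`weights` must have columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  means <- weights |>
    dplyr::group_by(.data$environment) |>
    dplyr::summarise(
      mean_stim = mean(.data$omega_stim1),
      mean_choice = mean(.data$omega_choice1),
      sd_stim = stats::sd(.data$omega_stim1),
      sd_choice = stats::sd(.data$omega_choice1),
      n = dplyr::n(),
      .groups = "drop"
    )
  shifts <- NULL
  if ("neutral" %in% weights$environment) {
    neutral <- weights |>
      dplyr::filter(.data$environment == "neutral") |>
      dplyr::select("subject", neut_stim = "omega_stim1",
                    neut_choice = "omega_choice1")
    shifts <- weights |>
      dplyr::filter(.data$environment != "neutral") |>
      dplyr::inner_join(neutral, by = "subject") |>
      dplyr::mutate(
        d_stim = .data$omega_stim1 - .data$neut_stim,
        d_choice = .data$omega_choice1 - .data$neut_choice,
        angle = atan2(.data$d_choice, .data$d_stim)
      ) |>
      dplyr::select("subject", "environment", "d_stim", "d_choice", "angle")
  }
  list(means = means, shifts = shifts)
}

#' Per-subject lag-1 kernel weights from final fits
#'
#' Fits the model at the selected order for every subject x environment and
#' extracts the lag-1 stimulus and choice weights, the standard per-subject
#' input to [kernel_summary()] and [adjustment_score()].
#'
#' @inheritParams single_trial_bias
#' @return Tibble with `subject`, `environment`, `omega_stim1`,
#'   `omega_choice1`, `alpha`, `delta0`.
#' @export
kernel_weights <- function(trials, order, restarts = 3, seed = 1) {
  groups <- dplyr::distinct(trials, .data$subject, .data$environment)
  purrr::pmap(groups, function(subject, environment) {
    tb <- trials[trials$subject == subject &
                   trials$environment == environment, , drop = FALSE]
    n <- max(1L, lookup_order(order, subject, environment))
    fit <- fit_history_model(tb, n_lags = n, restarts = restarts,
                             seed = derive_seed(seed, subject * 13 + 1))
    p <- fit$params
    tibble::tibble(
      subject = subject, environment = environment,
      omega_stim1 = omega_stim(p)[1], omega_choice1 = omega_choice(p)[1],
      alpha = p$alpha, delta0 = p$delta0
    )
  }) |>
    dplyr::bind_rows()
}
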