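#' Single-trial regression of bias and evidence on lateralization amplitude
#'
#' Regresses the trial-wise lateralization amplitude at every timepoint on
#' the signed motion coherence and the single-trial history bias:
#' \deqn{y_t = \beta_0 + \beta_1\, coh + \beta_2\, bias}
#' with the outcome and both regressors z-scored across trials (the outcome
#' separately at each timepoint). Lateralization must be coded relative to
#' the up-coding hand, so injected negative couplings yield negative
#' coefficients.
#'
#' @param epochs A [neural_epochs] object (`vs_up_hand` coding).
#' @param coh Signed motion coherence per trial. Defaults to
#'   `epochs$trial_info$signed_stim`.
#' @param bias Single-trial bias per trial (e.g. the `delta` column of
#'   [single_trial_bias()]).
#' @return A tibble of class `regression_trace` with one row per timepoint
#'   and term (`coh`, `bias`): `time`, `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`.
#' @export
regress_amplitude <- function(epochs, coh = NULL, bias) {
  stopifnot(inherits(epochs, "neural_epochs"))
  if (epochs$coding != "vs_up_hand") {
    stop("amplitude regression requires `vs_up_hand` coding", call. = FALSE)
  }
  coh <- coh %||% epochs$trial_info$signed_stim
  trace_regression(epochs$y, epochs$times, coh, bias)
}

# shared core: per-column z-scored OLS of y on (coh, bias)
trace_regression <- function(y, times, coh, bias) {
  n <- nrow(y)
  stopifnot(length(coh) == n, length(bias) == n)
  if (is_constant(coh) || is_constant(bias)) {
    stop("regressors must vary across trials", call. = FALSE)
  }
  if (abs(stats::cor(coh, bias)) > 1 - 1e-8) {
    stop("coherence and bias are collinear; regression is rank deficient",
         call. = FALSE)
  }
  X <- cbind(intercept = 1, coh = zscore(coh), bias = zscore(bias))
  XtXinv <- solve(crossprod(X))
  out <- purrr::map(seq_along(times), function(j) {
    yj <- y[, j]
    if (is_constant(yj)) {
      stop(sprintf("degenerate (constant) outcome at time %.4f s", times[j]),
           call. = FALSE)
    }
    yz <- zscore(yj)
    beta <- unname(drop(XtXinv %*% crossprod(X, yz)))
    res <- yz - drop(X %*% beta)
    sigma2 <- sum(res^2) / (n - ncol(X))
    se <- unname(sqrt(diag(XtXinv) * sigma2))
    tstat <- beta / se
    tibble::tibble(
      time = times[j],
      term = c("intercept", "coh", "bias"),
      estimate = beta,
      std.error = se,
      statistic = tstat,
      p.value = 2 * stats::pt(-abs(tstat), n - ncol(X))
    )
  })
  out <- dplyr::bind_rows(out) |>
    dplyr::filter(.data$term != "intercept")
  class(out) <- c("regression_trace", class(out))
  out
}

#' Regression of the single-trial bias on the baseline lateralization
#'
#' Tests whether the pre-evidence baseline state of the lateralization
#' (mean over the baseline window, by default -0.35 to -0.10 s) carries the
#' single-trial bias: \eqn{y_{baseline} = \beta_0 + \beta_1\, bias}, both
#' z-scored. Signed coherence is not included because the evidence had not
#' yet appeared during the baseline.
#'
#' @inheritParams regress_amplitude
#' @return One-row tibble: `estimate`, `std.error`, `statistic`, `p.value`,
#'   `n`.
#' @export
regress_baseline <- function(epochs, bias) {
  stopifnot(inherits(epochs, "neural_epochs"))
  yb <- baseline_amplitude(epochs)
  n <- length(yb)
  stopifnot(length(bias) == n)
  if (is_constant(yb)) {
    stop("baseline amplitude is constant; z-scoring undefined", call. = FALSE)
  }
  if (is_constant(bias)) {
    stop("bias regressor is constant", call. = FALSE)
  }
  fit <- stats::lm(zscore(yb) ~ zscore(bias))
  sm <- summary(fit)$coefficients
  tibble::tibble(
    estimate = sm[2, 1], std.error = sm[2, 2],
    statistic = sm[2, 3], p.value = sm[2, 4], n = n
  )
}

#' Sliding-window regression on the local slope of lateralization
#'
#' Computes, per trial, the local OLS slope of the lateralization inside a
#' sliding window (200 ms by default, stepped at the epoch's resolution),
#' then regresses these single-trial slopes on signed coherence and bias at
#' every window center (slopes and regressors z-scored per center):
#' \deqn{slope_t = \beta_0 + \beta_1\, coh + \beta_2\, bias.}
#' Window centers whose window extends past the epoch are dropped.
#'
#' The regression is fitted separately for current up and down responses and
#' the two coefficient traces are averaged; all three are returned, flagged
#' by the `choices` column (`"up"`, `"down"`, `"mean"`). Set
#' `by_choice = FALSE` to pool all trials into a single fit.
#'
#' @inheritParams regress_amplitude
#' @param window_len Sliding-window length in seconds (default 0.2).
#' @param by_choice Fit separately per current choice and average (default
#'   `TRUE`).
#' @return A tibble of class `regression_trace` with `time` (window
#'   center), `choices`, `term`, `estimate` (and OLS inference columns for
#'   the per-choice fits).
#' @export
regress_slope <- function(epochs, coh = NULL, bias, window_len = 0.2,
                          by_choice = TRUE) {
  stopifnot(inherits(epochs, "neural_epochs"))
  if (epochs$coding != "vs_up_hand") {
    stop("slope regression requires `vs_up_hand` coding", call. = FALSE)
  }
  coh <- coh %||% epochs$trial_info$signed_stim
  sl <- local_slopes(epochs$y, epochs$times, window_len)
  if (!by_choice) {
    out <- trace_regression(sl$slopes, sl$centers, coh, bias)
    out$choices <- "all"
    return(out)
  }
  choice <- epochs$trial_info$choice
  if (is.null(choice)) {
    stop("per-choice fits need `choice` in the epochs' trial_info",
         call. = FALSE)
  }
  parts <- purrr::map(c(up = 1, down = -1), function(cc) {
    keep <- which(choice == cc)
    tr <- trace_regression(sl$slopes[keep, , drop = FALSE], sl$centers,
                           coh[keep], bias[keep])
    tr
  })
  up <- parts$up; up$choices <- "up"
  dn <- parts$down; dn$choices <- "down"
  avg <- up |>
    dplyr::select("time", "term") |>
    dplyr::mutate(
      estimate = (up$estimate + dn$estimate) / 2,
      std.error = NA_real_, statistic = NA_real_, p.value = NA_real_,
      choices = "mean"
    )
  out <- dplyr::bind_rows(up, dn, avg)
  class(out) <- c("regression_trace", class(out))
  out
}

# per-trial OLS slopes in sliding windows; returns slopes matrix + centers
local_slopes <- function(y, times, window_len) {
  half <- window_len / 2
  centers <- times[times - half >= min(times) - 1e-9 &
                     times + half <= max(times) + 1e-9]
  W <- vapply(centers, function(ct) {
    w <- numeric(length(times))
    idx <- which(times >= ct - half - 1e-9 & times <= ct + half + 1e-9)
    tt <- times[idx]
    w[idx] <- (tt - mean(tt)) / sum((tt - mean(tt))^2)
    w
  }, numeric(length(times)))
  list(slopes = y %*% W, centers = centers)
}

#' @export
tidy.regression_trace <- function(x, ...) tibble::as_tibble(x)
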