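#' Cross-validated selection of the history model order
#'
#' Chooses, separately for each subject and environment, the number of
#' history lags `n` that best predicts held-out choices. Blocks are split
#' into folds (by default one block per fold, i.e. leave-one-block-out with
#' six blocks). For every fold and every `n` in `0:max_lag` the model is
#' fitted on the training blocks and its log-likelihood evaluated on the
#' held-out block; fold-averaged log-likelihoods are maximised over `n`,
#' with exact ties resolved toward the smaller `n`.
#'
#' For the biased environments (`repetitive`, `alternating`) a selected
#' order of 0 in exactly one of the two substitutes `n_use = 1` for the
#' downstream behavioral analyses; a subject with order 0 in both biased
#' environments is flagged for exclusion (the subject did not adapt to the
#' environmental structure).
#'
#' @param trials Trial tibble (one or more subjects/environments).
#' @param max_lag Largest model order considered (default 7).
#' @param folds Number of folds; default one per block. Must not exceed the
#'   number of blocks.
#' @param restarts,seed Passed to [fit_history_model()] for each training
#'   fit (fewer restarts than a final fit; the CV landscape is smooth).
#' @return A tibble of class `model_order` with one row per
#'   subject-environment: `subject`, `environment`, `n_cv` (CV argmax),
#'   `n_use` (after the substitution rule), `exclude` (subject-level flag).
#'   The fold-averaged log-likelihood profile is attached as attribute
#'   `"cv_loglik"` (columns `subject`, `environment`, `n`, `loglik`).
#' @examples
#' \donttest{
#' sim <- simulate_experiment(1, environments = "neutral", coefs = NULL,
#'                            blocks = 3, seed = 1)
#' select_model_order(sim$trials, max_lag = 2)
#' }
#' @export
select_model_order <- function(trials, max_lag = 7, folds = NULL,
                               restarts = 2, seed = 1) {
  max_lag <- if (max_lag == 0) 0L else assert_count(max_lag, "max_lag")
  groups <- dplyr::distinct(trials, .data$subject, .data$environment)
  res <- purrr::pmap(groups, function(subject, environment) {
    tb <- trials[trials$subject == subject &
                   trials$environment == environment, , drop = FALSE]
    cv_one_group(tb, max_lag, folds, restarts,
                 derive_seed(seed, match(environment, unique(trials$environment)) +
                               17 * subject))
  })
  sel <- dplyr::bind_cols(groups, dplyr::bind_rows(purrr::map(res, "best")))
  prof <- dplyr::bind_rows(purrr::map2(
    seq_len(nrow(groups)), res,
    function(i, r) dplyr::bind_cols(groups[rep(i, nrow(r$profile)), ], r$profile)
  ))

  sel <- sel |>
    dplyr::group_by(.data$subject) |>
    dplyr::mutate(
      n_zero_biased = sum(.data$n_cv == 0 &
                            .data$environment %in% c("repetitive", "alternating")),
      n_use = dplyr::if_else(
        .data$n_cv == 0 &
          .data$environment %in% c("repetitive", "alternating") &
          .data$n_zero_biased == 1L,
        1L, .data$n_cv
      ),
      exclude = .data$n_zero_biased >= 2L
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-"n_zero_biased")

  attr(sel, "cv_loglik") <- prof
  class(sel) <- c("model_order", class(sel))
  sel
}

cv_one_group <- function(tb, max_lag, folds, restarts, seed) {
  blocks <- sort(unique(tb$block))
  n_blocks <- length(blocks)
  if (is.null(folds)) folds <- n_blocks
  folds <- assert_count(folds, "folds")
  if (folds > n_blocks) {
    stop(sprintf("cannot form %d folds from %d block(s)", folds, n_blocks),
         call. = FALSE)
  }
  fold_of <- rep(seq_len(folds), length.out = n_blocks)
  ll <- matrix(NA_real_, nrow = folds, ncol = max_lag + 1)
  for (f in seq_len(folds)) {
    test_blocks <- blocks[fold_of == f]
    train <- tb[!tb$block %in% test_blocks, , drop = FALSE]
    test <- tb[tb$block %in% test_blocks, , drop = FALSE]
    for (n in 0:max_lag) {
      fit <- fit_history_model(train, n_lags = n, restarts = restarts,
                               seed = derive_seed(seed, f * 100 + n))
      ll[f, n + 1] <- log_likelihood(fit$params, test)
    }
  }
  mean_ll <- colMeans(ll)
  n_cv <- which.max(mean_ll) - 1L # first maximum = smallest n on ties
  list(
    best = tibble::tibble(n_cv = n_cv),
    profile = tibble::tibble(n = 0:max_lag, loglik = mean_ll)
  )
}

#' @export
tidy.model_order <- function(x, ...) {
  tibble::as_tibble(x)
}
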