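#' Configuration for an end-to-end synthetic run
#'
#' Collects every tunable of the pipeline in one serializable list; a run is
#' reproducible from the config plus its seed alone. Defaults use the full
#' study-design generator settings (three environments, 6 blocks of 99
#' trials, balanced coherences) with analysis sizes chosen for desk-scale
#' runs (see the methods vignette).
#'
#' @param n_subjects Simulated subjects (default 3).
#' @param environments Environments to simulate.
#' @param blocks Blocks per environment (default 6).
#' @param params Generating agent parameters ([default_agent_params()]).
#' @param coefs Ground-truth neural coefficients ([neural_coefs()]).
#' @param max_lag Largest model order for CV selection (default 2).
#' @param restarts Optimisation restarts for fits (default 2).
#' @param n_draws Choice-balanced subsampling draws (default 1000).
#' @param min_bin_trials Minimum trials per choice per bias bin for the
#'   subsampling contrast (default 10).
#' @param buffer_start,buffer_end Build-up window buffers in seconds
#'   (defaults 0.25 and 0.05).
#' @param slope_window Sliding-window length for the slope regression
#'   (default 0.2 s).
#' @param n_perm Permutations for the group statistics (default 1000).
#' @param seed Root seed; all stage seeds derive from it.
#' @return A list of class `run_config`.
#' @export
pipeline_config <- function(n_subjects = 3,
                            environments = c("repetitive", "neutral",
                                             "alternating"),
                            blocks = 6,
                            params = default_agent_params(),
                            coefs = neural_coefs(),
                            max_lag = 2,
                            restarts = 2,
                            n_draws = 1000,
                            min_bin_trials = 10,
                            buffer_start = 0.25,
                            buffer_end = 0.05,
                            slope_window = 0.2,
                            n_perm = 1000,
                            seed = 1) {
  structure(
    list(
      n_subjects = assert_count(n_subjects, "n_subjects"),
      environments = environments,
      blocks = assert_count(blocks, "blocks"),
      params = params, coefs = coefs,
      max_lag = max_lag, restarts = restarts,
      n_draws = n_draws, min_bin_trials = min_bin_trials,
      buffer_start = buffer_start, buffer_end = buffer_end,
      slope_window = slope_window, n_perm = n_perm,
      seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full synthetic analysis pipeline
#'
#' Executes simulate -> fit -> select order -> cross-fitted bias -> binning
#' -> kernel psychometrics -> neural coupling (build-up window, rebound
#' removal, choice-balanced subsampling, bias-locked ramp slope, single-trial
#' regressions) -> group statistics, on data generated from the config.
#' All randomness derives from `config$seed`; running the same config twice
#' yields identical numeric output. Any stage failure halts with a
#' stage-tagged message.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, every stage artifact is
#'   written there (CSV/JSON) together with a run log of seeds and
#'   exclusions.
#' @return A list of class `histbias_pipeline` with elements `trials`,
#'   `order`, `bias`, `weights`, `adjustment`, `window`, `neural`
#'   (per-subject bias-locked traces and ramp slopes), `regressions`
#'   (amplitude/baseline/slope traces), `stats` and `log`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed

  sim <- run_stage("simulate", simulate_experiment(
    n_subjects = config$n_subjects, environments = config$environments,
    params = config$params, coefs = config$coefs,
    seed = seed, blocks = config$blocks
  ))
  trials <- sim$trials

  order <- run_stage("select-order", select_model_order(
    trials, max_lag = config$max_lag, restarts = config$restarts,
    seed = derive_seed(seed, 2)
  ))

  bias <- run_stage("bias", {
    b <- single_trial_bias(trials, order, restarts = config$restarts,
                           seed = derive_seed(seed, 3))
    bin_bias(b)
  })

  weights <- run_stage("psychometrics", kernel_weights(
    trials, order, restarts = config$restarts, seed = derive_seed(seed, 4)
  ))
  adjustment <- run_stage("psychometrics", {
    if (all(c("repetitive", "alternating") %in% weights$environment)) {
      weights |>
        tidyr::pivot_wider(id_cols = "subject",
                           names_from = "environment",
                           values_from = c("omega_stim1", "omega_choice1")) |>
        dplyr::rowwise() |>
        dplyr::mutate(score = adjustment_score(
          c(stim = .data$omega_stim1_repetitive,
            choice = .data$omega_choice1_repetitive),
          c(stim = .data$omega_stim1_alternating,
            choice = .data$omega_choice1_alternating)
        )) |>
        dplyr::ungroup() |>
        dplyr::select("subject", "score")
    }
  })

  neural <- run_stage("couple", pipeline_neural(sim, bias, config))

  stats_out <- run_stage("stats", {
    slopes <- neural$slopes$slope
    list(
      ramp_slope_test = if (length(slopes) >= 2) {
        permutation_test(slopes, tails = "less", n_perm = config$n_perm,
                         seed = derive_seed(seed, 8))
      },
      bias_amplitude_cluster = if (length(neural$bias_traces) >= 2) {
        cluster_permutation_1d(
          do.call(rbind, neural$bias_traces), n_perm = config$n_perm,
          seed = derive_seed(seed, 9), times = neural$times
        )
      }
    )
  })

  log <- list(
    seed = seed,
    package_version = as.character(utils::packageVersion("histbias")),
    excluded_subjects = unique(order$subject[order$exclude]),
    skipped_bins = neural$skipped
  )

  out <- structure(
    list(trials = trials, order = order, bias = bias, weights = weights,
         adjustment = adjustment, window = neural$window,
         neural = neural[c("bias_locked", "slopes", "times")],
         regressions = neural$regressions, stats = stats_out, log = log),
    class = "histbias_pipeline"
  )
  if (!is.null(out_dir)) write_bundle(out, sim, out_dir)
  out
}

# neural-coupling stage for every subject
pipeline_neural <- function(sim, bias, config) {
  subjects <- sort(unique(sim$trials$subject))
  times <- sim$epochs[[1]]$times
  per_subject <- purrr::map(subjects, function(s) {
    ep <- sim$epochs[[paste0("subject_", s)]]
    tb <- ep$trial_info
    bs <- bias[bias$subject == s, ]
    key_ep <- paste(tb$environment, tb$block, tb$trial)
    key_bs <- paste(bs$environment, bs$block, bs$trial)
    delta <- bs$delta[match(key_ep, key_bs)]
    bin <- bs$bin[match(key_ep, key_bs)]

    # window from the choice-locked mean build-up (epochs coded vs up hand,
    # so multiplying by the choice code gives the vs-button-press trace)
    mean_tc <- colMeans(ep$y * tb$choice)
    window <- bilinear_window(mean_tc, times,
                              buffer_start = config$buffer_start,
                              buffer_end = config$buffer_end)

    # rebound removal before the bias-binned contrast
    r <- rebound_template(ep)
    y_clean <- remove_rebound(ep$y, r)

    skipped <- character(0)
    bin_avg <- purrr::map(c(low = "low", high = "high"), function(bn) {
      idx <- which(bin == bn)
      counts <- table(factor(tb$choice[idx], levels = c(-1, 1)))
      if (any(counts < config$min_bin_trials)) {
        skipped <<- c(skipped, sprintf("subject %d bin %s", s, bn))
        return(NULL)
      }
      choice_balanced_subsample(y_clean[idx, , drop = FALSE], tb$choice[idx],
                                n_draws = config$n_draws,
                                seed = derive_seed(config$seed, 100 * s +
                                                     match(bn, c("low", "high"))))
    })
    bias_locked <- NULL
    slope <- NA_real_
    if (!is.null(bin_avg$low) && !is.null(bin_avg$high)) {
      bias_locked <- bias_locked_average(bin_avg$low, bin_avg$high)
      slope <- ramp_slope(bias_locked, times, window)
    }

    list(
      window = window,
      bias_locked = bias_locked,
      slope = slope,
      skipped = skipped,
      amplitude = regress_amplitude(ep, bias = delta),
      baseline = regress_baseline(ep, bias = delta),
      slope_trace = regress_slope(ep, bias = delta,
                                  window_len = config$slope_window)
    )
  })
  names(per_subject) <- paste0("subject_", subjects)

  list(
    window = purrr::map(per_subject, "window"),
    bias_locked = purrr::map(per_subject, "bias_locked"),
    bias_traces = purrr::compact(purrr::map(per_subject, "bias_locked")),
    slopes = tibble::tibble(
      subject = subjects,
      slope = purrr::map_dbl(per_subject, "slope")
    ) |> dplyr::filter(is.finite(.data$slope)),
    skipped = unlist(purrr::map(per_subject, "skipped")),
    regressions = list(
      amplitude = dplyr::bind_rows(purrr::map(per_subject, "amplitude"),
                                   .id = "subject"),
      baseline = dplyr::bind_rows(purrr::map(per_subject, "baseline"),
                                  .id = "subject"),
      slope = dplyr::bind_rows(purrr::map(per_subject, "slope_trace"),
                               .id = "subject")
    ),
    times = times
  )
}

write_bundle <- function(out, sim, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_trials(out$trials, file.path(out_dir, "trials.csv"))
  readr::write_csv(tibble::as_tibble(out$order), file.path(out_dir, "model_order.csv"))
  readr::write_csv(out$bias, file.path(out_dir, "bias.csv"))
  readr::write_csv(out$weights, file.path(out_dir, "kernel_weights.csv"))
  if (!is.null(out$adjustment)) {
    readr::write_csv(out$adjustment, file.path(out_dir, "adjustment.csv"))
  }
  for (s in names(sim$epochs)) {
    write_epochs(sim$epochs[[s]], file.path(out_dir, paste0("epochs_", s, ".csv")))
  }
  readr::write_csv(out$neural$slopes, file.path(out_dir, "ramp_slopes.csv"))
  readr::write_csv(out$regressions$amplitude,
                   file.path(out_dir, "regression_amplitude.csv"))
  readr::write_csv(out$regressions$baseline,
                   file.path(out_dir, "regression_baseline.csv"))
  readr::write_csv(out$regressions$slope,
                   file.path(out_dir, "regression_slope.csv"))
  stats_json <- list(
    ramp_slope_test = if (!is.null(out$stats$ramp_slope_test)) {
      tidy(out$stats$ramp_slope_test)
    },
    bias_amplitude_clusters = if (!is.null(out$stats$bias_amplitude_cluster)) {
      out$stats$bias_amplitude_cluster$clusters
    }
  )
  jsonlite::write_json(stats_json, file.path(out_dir, "stats.json"),
                       digits = NA, auto_unbox = TRUE, dataframe = "rows")
  jsonlite::write_json(out$log, file.path(out_dir, "run_log.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(out_dir)
}

#' @export
print.histbias_pipeline <- function(x, ...) {
  cat("<histbias_pipeline>\n")
  cat(sprintf("  %d trials, %d subject(s)\n", nrow(x$trials),
              dplyr::n_distinct(x$trials$subject)))
  if (nrow(x$neural$slopes) > 0) {
    cat(sprintf("  bias-locked ramp slopes: %s\n",
                paste(signif(x$neural$slopes$slope, 3), collapse = ", ")))
  }
  if (!is.null(x$stats$ramp_slope_test)) {
    cat(sprintf("  group slope permutation p = %.4f\n",
                x$stats$ramp_slope_test$p.value))
  }
  invisible(x)
}
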