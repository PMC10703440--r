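trials_schema <- c(
  subject = "integer", session = "integer", block = "integer",
  environment = "character", trial = "integer", category = "integer",
  coherence = "double", signed_stim = "double", choice = "integer",
  prev_choice = "integer", correct = "integer", hand_map = "integer",
  seed = "integer"
)

#' Read and write trial tables
#'
#' Trial tables are plain CSV files with the documented column set
#' (`subject`, `session`, `block`, `environment`, `trial`, `category`,
#' `coherence`, `signed_stim`, `choice`, `prev_choice`, `correct`,
#' `hand_map`, `seed`). On reading, the coding conventions are validated:
#' `category`, `choice` and `hand_map` in \{-1, +1\} (`choice` may be `NA`
#' for missed responses), `prev_choice` in \{-1, 0, +1\}, coherences in
#' `[0, 1]`. Unknown extra columns are kept with a warning; invalid codes
#' are rejected with the offending row named. Write-then-read round-trips
#' are exact.
#'
#' @param path File path.
#' @param trials Trial tibble to write.
#' @return `read_trials()` returns a validated tibble (an empty file yields
#'   an empty tibble); `write_trials()` returns `path` invisibly.
#' @export
read_trials <- function(path) {
  tb <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_guess()))
  if (nrow(tb) == 0 && ncol(tb) == 0) return(tibble::tibble())
  missing <- setdiff(names(trials_schema), names(tb))
  if (length(missing) > 0) {
    stop("trial table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(names(tb), names(trials_schema))
  if (length(extra) > 0) {
    warning("ignoring unknown columns: ", paste(extra, collapse = ", "),
            call. = FALSE)
  }
  for (col in c("subject", "session", "block", "trial", "category", "choice",
                "prev_choice", "correct", "hand_map", "seed")) {
    tb[[col]] <- as.integer(tb[[col]])
  }
  validate_codes(tb, "category", c(-1, 1))
  validate_codes(tb, "choice", c(-1, 1), allow_na = TRUE)
  validate_codes(tb, "prev_choice", c(-1, 0, 1))
  validate_codes(tb, "hand_map", c(-1, 1))
  if (any(tb$coherence < 0 | tb$coherence > 1)) {
    bad <- which(tb$coherence < 0 | tb$coherence > 1)[1]
    stop(sprintf("row %d: coherence outside [0, 1]", bad), call. = FALSE)
  }
  tb
}

validate_codes <- function(tb, col, codes, allow_na = FALSE) {
  x <- tb[[col]]
  bad <- if (allow_na) !is.na(x) & !x %in% codes else is.na(x) | !x %in% codes
  if (any(bad)) {
    stop(sprintf("row %d: invalid value in column '%s' (allowed: %s)",
                 which(bad)[1], col, paste(codes, collapse = ", ")),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' @rdname read_trials
#' @export
write_trials <- function(trials, path) {
  readr::write_csv(trials, path)
  invisible(path)
}

#' Read and write lateralization epochs
#'
#' Epoch matrices (trials x timepoints) are stored as a headerless CSV of
#' numbers, with a JSON sidecar (`<path>.json`) holding the time axis,
#' coding convention and baseline window. Round-trips preserve values to
#' full double precision.
#'
#' @param epochs A [neural_epochs] object.
#' @param path Path of the CSV matrix; the sidecar is written next to it.
#' @return `read_epochs()` returns a [neural_epochs] object;
#'   `write_epochs()` returns `path` invisibly. Trial metadata, if present,
#'   is stored inside the sidecar.
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "neural_epochs"))
  utils::write.table(
    format(epochs$y, digits = 17, scientific = TRUE, trim = TRUE),
    path, sep = ",", row.names = FALSE, col.names = FALSE, quote = FALSE
  )
  meta <- list(
    times = epochs$times,
    coding = epochs$coding,
    baseline_window = epochs$baseline_window,
    trial_info = epochs$trial_info
  )
  jsonlite::write_json(meta, paste0(path, ".json"), digits = NA,
                       auto_unbox = TRUE, null = "null", dataframe = "columns")
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  y <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(y) <- NULL
  ti <- meta$trial_info
  if (!is.null(ti)) ti <- tibble::as_tibble(ti)
  neural_epochs(y, meta$times, coding = meta$coding,
                baseline_window = meta$baseline_window, trial_info = ti)
}
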