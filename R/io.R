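# Trial-table validation and CSV/JSON interfaces.

#' Read a trial-level CSV
#'
#' Expects columns `subject_id` plus either `error_deg` or both `target_deg`
#' and `response_deg` (errors are then computed with [wrap_error()]).
#' Optional columns `group` and `timepoint` are carried through.
#'
#' @param path Path to a CSV file.
#' @return Tibble with at least `subject_id`, `group` (filled with `"all"`
#'   when absent) and `error_deg`.
#' @export
read_trials_csv <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_trials(raw, need_group = FALSE)
}

validate_trials <- function(trials, need_group = TRUE) {
  if (!("subject_id" %in% names(trials))) {
    stop("trial table needs a `subject_id` column", call. = FALSE)
  }
  trials <- tibble::as_tibble(trials)
  if (!("error_deg" %in% names(trials))) {
    if (!all(c("target_deg", "response_deg") %in% names(trials))) {
      stop("trial table needs `error_deg` or both `target_deg` and ",
           "`response_deg`", call. = FALSE)
    }
    trials$error_deg <- wrap_error(trials$target_deg, trials$response_deg)
  }
  if (any(!is.finite(trials$error_deg))) {
    stop("non-finite response errors in trial table", call. = FALSE)
  }
  trials$error_deg <- wrap_angle(trials$error_deg)
  if (!("group" %in% names(trials))) {
    if (need_group) stop("trial table needs a `group` column", call. = FALSE)
    trials$group <- "all"
  }
  trials$subject_id <- as.character(trials$subject_id)
  trials
}

#' Write a table of fit results to CSV
#'
#' @param fits Either a tibble of subject-level results or a named list of
#'   `mixture_fit` objects (names become `subject_id`).
#' @param path Output CSV path.
#' @return The written tibble, invisibly.
#' @export
write_fit_table <- function(fits, path) {
  if (is.data.frame(fits)) {
    tab <- tibble::as_tibble(fits)
  } else {
    tab <- dplyr::bind_rows(lapply(names(fits), function(id) {
      f <- fits[[id]]
      tibble::tibble(
        subject_id = id, method = f$method, pT = f$pT, kappa = f$kappa,
        loglik = f$loglik, converged = f$converged, n_trials = f$n_trials
      )
    }))
  }
  readr::write_csv(tab, path)
  invisible(tab)
}

#' Write run metadata as JSON
#'
#' Records the configuration and seed of an analysis run for provenance.
#'
#' @param meta Named list (configuration, seed, package version, ...).
#' @param path Output JSON path.
#' @export
write_run_metadata <- function(meta, path) {
  meta$written_at <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  meta$package_version <- as.character(utils::packageVersion("memprec"))
  jsonlite::write_json(meta, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
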