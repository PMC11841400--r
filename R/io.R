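read_csv_checked <- function(path, required, label) {
  if (!file.exists(path)) {
    stop(sprintf("%s file not found: %s", label, path), call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s file %s is missing column(s): %s",
                 label, path, paste(missing, collapse = ", ")), call. = FALSE)
  }
  df
}

#' Read the study input tables
#'
#' Reads and validates the rater-response table, the expert-rating table,
#' and (optionally) the historical code-frequency table.  Formats:
#' `responses.csv` with columns `rater_id, scenario_id, code`;
#' `experts.csv` with columns `scenario_id, expert_id, rating`;
#' `historical.csv` with columns `rater_id, pct_low_codes`.
#' The response and expert tables must cover exactly the same scenarios,
#' every (rater, scenario) and (scenario, expert) pair must appear exactly
#' once, and the grid must be complete.
#'
#' @param responses_path Path to the responses CSV.
#' @param experts_path Path to the expert-ratings CSV.
#' @param historical_path Optional path to the historical-statistics CSV.
#' @return A list with elements `responses` ([response_matrix()]),
#'   `experts` ([expert_ratings()]), and `historical`
#'   ([historical_code_stats()] or `NULL`).
#' @export
read_study_inputs <- function(responses_path, experts_path,
                              historical_path = NULL) {
  resp <- read_csv_checked(responses_path,
                           c("rater_id", "scenario_id", "code"), "responses")
  expr <- read_csv_checked(experts_path,
                           c("scenario_id", "expert_id", "rating"), "experts")

  if (anyDuplicated(resp[c("rater_id", "scenario_id")])) {
    stop("duplicated (rater_id, scenario_id) pair in responses file",
         call. = FALSE)
  }
  if (anyDuplicated(expr[c("scenario_id", "expert_id")])) {
    stop("duplicated (scenario_id, expert_id) pair in experts file",
         call. = FALSE)
  }

  resp_scen <- sort(unique(as.character(resp$scenario_id)))
  expr_scen <- sort(unique(as.character(expr$scenario_id)))
  if (!identical(resp_scen, expr_scen)) {
    stop("scenario sets differ between responses and experts files: ",
         paste(c(setdiff(resp_scen, expr_scen), setdiff(expr_scen, resp_scen)),
               collapse = ", "), call. = FALSE)
  }

  # preserve first-appearance order of ids
  rater_ids <- unique(as.character(resp$rater_id))
  scenario_ids <- unique(as.character(resp$scenario_id))
  codes <- matrix(NA_character_, length(rater_ids), length(scenario_ids),
                  dimnames = list(rater_ids, scenario_ids))
  codes[cbind(as.character(resp$rater_id), as.character(resp$scenario_id))] <-
    tolower(as.character(resp$code))
  if (anyNA(codes)) {
    stop("responses file does not cover the full rater x scenario grid",
         call. = FALSE)
  }

  expert_ids <- unique(as.character(expr$expert_id))
  ratings <- matrix(NA_integer_, length(scenario_ids), length(expert_ids),
                    dimnames = list(scenario_ids, expert_ids))
  ratings[cbind(as.character(expr$scenario_id), as.character(expr$expert_id))] <-
    as.integer(expr$rating)
  if (anyNA(ratings)) {
    stop("experts file does not cover the full scenario x expert grid",
         call. = FALSE)
  }

  historical <- NULL
  if (!is.null(historical_path)) {
    hist <- read_csv_checked(historical_path,
                             c("rater_id", "pct_low_codes"), "historical")
    historical <- historical_code_stats(hist$rater_id, hist$pct_low_codes)
  }

  list(responses = response_matrix(codes),
       experts = expert_ratings(ratings),
       historical = historical)
}

#' Write study input tables to CSV
#'
#' Emits the `responses.csv` / `experts.csv` / `historical.csv` files read
#' by [read_study_inputs()]; used by the synthetic-study generator.
#'
#' @param study List with `responses`, `experts`, optional `historical`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written (named list).
#' @export
write_study_inputs <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rm <- study$responses
  codes <- rm$codes
  if (is.null(codes)) {
    # binary-only matrix: emit representative codes on either side of the split
    codes <- matrix(ifelse(rm$binary == 1L, "yellow", "green"),
                    nrow(rm$binary), ncol(rm$binary),
                    dimnames = dimnames(rm$binary))
  }
  resp <- data.frame(
    rater_id = rep(rm$rater_ids, times = length(rm$scenario_ids)),
    scenario_id = rep(rm$scenario_ids, each = length(rm$rater_ids)),
    code = as.vector(codes),
    stringsAsFactors = FALSE
  )
  er <- study$experts
  expr <- data.frame(
    scenario_id = rep(er$scenario_ids, times = length(er$expert_ids)),
    expert_id = rep(er$expert_ids, each = length(er$scenario_ids)),
    rating = as.vector(er$ratings),
    stringsAsFactors = FALSE
  )
  paths <- list(responses = file.path(dir, "responses.csv"),
                experts = file.path(dir, "experts.csv"))
  utils::write.csv(resp, paths$responses, row.names = FALSE, quote = FALSE)
  utils::write.csv(expr, paths$experts, row.names = FALSE, quote = FALSE)
  if (!is.null(study$historical)) {
    paths$historical <- file.path(dir, "historical.csv")
    utils::write.csv(as.data.frame(study$historical), paths$historical,
                     row.names = FALSE, quote = FALSE)
  }
  invisible(paths)
}

fit_to_list <- function(fit) {
  list(rater_id = fit$rater_id,
       bt_mean = fit$bt_mean,
       bt_ci = as.numeric(fit$bt_ci),
       bm_means = as.numeric(fit$bm_means),
       bm_cis = unname(fit$bm_cis),
       scenario_ids = fit$scenario_ids,
       consistency_rate = fit$consistency_rate,
       diagnostics = list(rhat = as.numeric(fit$diagnostics$rhat),
                          ess = as.numeric(fit$diagnostics$ess),
                          converged = fit$diagnostics$converged))
}

#' Write the analysis results
#'
#' Serializes the agreement report and the per-rater fits as a single JSON
#' document (the canonical result file) plus flat CSV exports of the
#' pairwise kappa matrix and the per-scenario agreement table.
#'
#' @param report An `agreement_report` (see [agreement_report()]).
#' @param fits List of `rater_fit` objects from [fit_all()].
#' @param path Output path for the JSON document; the CSV exports are
#'   written next to it as `<stem>_kappa_matrix.csv` and
#'   `<stem>_per_scenario.csv`.
#' @param summary Optional summary list (as built by [run_pipeline()]).
#' @param predictivity Optional predictivity result list.
#' @return Invisibly, the JSON path.
#' @export
write_results <- function(report, fits, path, summary = NULL,
                          predictivity = NULL) {
  if (length(fits) == 0L) stop("fits must be non-empty", call. = FALSE)
  if (!inherits(report, "agreement_report")) {
    stop("report must be an agreement_report", call. = FALSE)
  }
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  doc <- list(
    fits = lapply(fits, fit_to_list),
    agreement = unclass(report),
    summary = summary,
    predictivity = predictivity
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)

  stem <- sub("\\.json$", "", path)
  km <- report$pairwise_kappa
  utils::write.csv(as.data.frame(km), paste0(stem, "_kappa_matrix.csv"),
                   row.names = TRUE)
  utils::write.csv(report$per_scenario, paste0(stem, "_per_scenario.csv"),
                   row.names = FALSE)
  invisible(path)
}

#' Read back a results JSON document
#'
#' Inverse of [write_results()]: reconstructs the agreement report and the
#' per-rater fit summaries from the JSON file.
#'
#' @param path Path to the JSON results document.
#' @return List with `fits`, `report` (an `agreement_report`), `summary`,
#'   and `predictivity` (possibly `NULL`).
#' @export
read_results <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  agr <- doc$agreement
  km <- as.matrix(agr$pairwise_kappa)
  dimnames(km) <- list(agr$rater_ids, agr$rater_ids)
  agr$pairwise_kappa <- km
  report <- structure(agr, class = "agreement_report")
  fits <- if (is.data.frame(doc$fits)) {
    lapply(seq_len(nrow(doc$fits)), function(i) as.list(doc$fits[i, ]))
  } else {
    doc$fits
  }
  list(fits = fits, report = report, summary = doc$summary,
       predictivity = doc$predictivity)
}
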