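#' Full agreement report for a panel of raters
#'
#' Computes every agreement quantity for the panel: the pairwise kappa
#' matrix and per-rater mean pairwise kappa on BT-adjusted decisions, each
#' rater's kappa against the dichotomized expert responses (both adjusted
#' and raw), qualitative bands for the adjusted kappas, the per-scenario
#' agreement profile, and the exclusion re-analysis.
#'
#' @param adjusted Binary rater x scenario matrix of BT-adjusted decisions.
#' @param raw Binary rater x scenario matrix of observed decisions.
#' @param experts An [expert_ratings()] aligned on scenarios.
#' @param exclude_k Number of lowest-agreement raters to drop in the
#'   exclusion re-analysis.
#' @return An `agreement_report`: list with `rater_ids`, `pairwise_kappa`,
#'   `mean_pairwise`, `kappa_vs_experts_adjusted`, `kappa_vs_experts_raw`,
#'   `bands`, `per_scenario` (data.frame), `exclusion`.
#' @export
agreement_report <- function(adjusted, raw, experts, exclude_k = 3L) {
  if (!identical(colnames(adjusted), experts$scenario_ids)) {
    stop("adjusted decisions are not aligned with the expert scenarios",
         call. = FALSE)
  }
  ed <- experts$dichotomized
  ids <- rownames(adjusted)
  if (nrow(adjusted) >= 2L) {
    mp <- mean_pairwise_kappa(adjusted)
    exclusion <- exclusion_reanalysis(adjusted, ed, exclude_k)
  } else {
    # single rater: the pairwise section is empty by construction
    mp <- list(pairwise = matrix(1, 1, 1, dimnames = list(ids, ids)),
               mean_pairwise = NULL)
    exclusion <- NULL
  }
  k_adj <- vapply(ids, function(r) kappa_vs_experts(adjusted[r, ], ed),
                  numeric(1))
  k_raw <- vapply(ids, function(r) kappa_vs_experts(raw[r, ], ed),
                  numeric(1))
  per_scen <- data.frame(
    scenario_id = experts$scenario_ids,
    expert_rating = as.integer(experts$averaged_rating),
    expert_dichotomized = as.integer(ed),
    proportion = as.numeric(per_scenario_agreement(adjusted, ed)),
    stringsAsFactors = FALSE
  )
  structure(
    list(rater_ids = ids,
         pairwise_kappa = mp$pairwise,
         mean_pairwise = mp$mean_pairwise,
         kappa_vs_experts_adjusted = k_adj,
         kappa_vs_experts_raw = k_raw,
         bands = agreement_band(k_adj),
         per_scenario = per_scen,
         exclusion = exclusion),
    class = "agreement_report"
  )
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> %d raters, %d scenarios\n",
              length(x$rater_ids), nrow(x$per_scenario)))
  cat(sprintf("  mean kappa vs experts (adjusted): %.3f\n",
              mean(x$kappa_vs_experts_adjusted)))
  if (!is.null(x$exclusion)) {
    cat(sprintf("  mean pairwise kappa: %.3f (%.3f after excluding %s)\n",
                mean(x$mean_pairwise), x$exclusion$mean_pairwise_kappa,
                paste(x$exclusion$excluded_ids, collapse = ", ")))
  }
  invisible(x)
}

#' Pipeline configuration
#'
#' Settings for [run_pipeline()].
#'
#' @param responses_path,experts_path,historical_path Input CSV paths
#'   (historical optional, enables the predictivity analysis).
#' @param out_dir Output directory for `results.json`, CSV exports and
#'   `report.md`; `NULL` disables writing.
#' @param mcmc An [mcmc_config()].
#' @param sigma Prior SD for the belonging-measure priors.
#' @param exclude_k Raters to drop in the exclusion re-analysis (>= 0).
#' @param bt_margins Length-2 vector: BTs below the first margin flag a
#'   tendency to over-triage, above the second to under-triage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(responses_path, experts_path,
                            historical_path = NULL, out_dir = NULL,
                            mcmc = mcmc_config(), sigma = 0.15,
                            exclude_k = 3L, bt_margins = c(0.30, 0.70)) {
  if (exclude_k < 0) stop("exclude_k must be >= 0", call. = FALSE)
  structure(
    list(responses_path = responses_path, experts_path = experts_path,
         historical_path = historical_path, out_dir = out_dir,
         mcmc = mcmc, sigma = sigma, exclude_k = as.integer(exclude_k),
         bt_margins = bt_margins),
    class = "pipeline_config"
  )
}

training_recommendation <- function(bt, kappa_adj, margins) {
  off_threshold <- bt < margins[1L] | bt > margins[2L]
  low_kappa <- kappa_adj <= 0.40
  out <- rep("none", length(bt))
  out[off_threshold & !low_kappa] <- "threshold-training"
  out[!off_threshold & low_kappa] <- "scenario-training"
  out[off_threshold & low_kappa] <- "threshold-and-scenario-training"
  out
}

#' Run the full analysis pipeline
#'
#' Part 1: builds the expert-informed priors and fits the model to every
#' rater.  Part 2 (when historical statistics are supplied): Spearman
#' predictivity correlation between estimated BTs and the historical
#' percentage of low-priority codes.  Part 3: raw and BT-adjusted kappas
#' against the experts, pairwise kappas, per-scenario agreement, and the
#' exclusion re-analysis.  All derived summary numbers (group mean BT with
#' its standard error, mean kappas, triage flags, training
#' recommendations) are computed here and serialized, so report rendering
#' involves no further computation.
#'
#' @param config A [pipeline_config()], or a list with in-memory `study`
#'   elements (`responses`, `experts`, optional `historical`) in place of
#'   the paths.
#' @param study Optional in-memory study (overrides the config paths).
#' @return List with `fits`, `report`, `summary`, `predictivity` (or
#'   `NULL`), and, when `out_dir` is set, `paths`.
#' @export
run_pipeline <- function(config, study = NULL) {
  if (is.null(study)) {
    study <- tryCatch(
      read_study_inputs(config$responses_path, config$experts_path,
                        config$historical_path),
      error = function(e) stop("[input] ", conditionMessage(e), call. = FALSE)
    )
  }
  responses <- study$responses
  experts <- study$experts

  # Part 1: priors + per-rater fits
  priors <- build_scenario_priors(experts, sigma = config$sigma)
  fits <- tryCatch(
    fit_all(responses, priors, config$mcmc),
    error = function(e) stop("[fit] ", conditionMessage(e), call. = FALSE)
  )
  bt_means <- vapply(fits, function(f) f$bt_mean, numeric(1))
  adjusted <- t(vapply(fits, function(f) adjust_decisions(f$bm_means),
                       integer(length(experts$scenario_ids))))
  dimnames(adjusted) <- list(responses$rater_ids, responses$scenario_ids)

  # Part 2: predictivity of the estimated BTs
  predictivity <- NULL
  if (!is.null(study$historical)) {
    hist <- study$historical
    m <- match(responses$rater_ids, hist$rater_id)
    if (anyNA(m)) {
      stop("[predictivity] historical statistics missing for rater(s): ",
           paste(responses$rater_ids[is.na(m)], collapse = ", "),
           call. = FALSE)
    }
    pct <- hist$pct_low_codes[m]
    ct <- suppressWarnings(
      stats::cor.test(bt_means, pct, method = "spearman", exact = FALSE)
    )
    predictivity <- list(rho = unname(ct$estimate), p_value = ct$p.value,
                         n = length(pct))
  }

  # Part 3: agreement, net of spurious (dis)agreements
  report <- tryCatch(
    agreement_report(adjusted, responses$binary, experts,
                     exclude_k = config$exclude_k),
    error = function(e) stop("[agreement] ", conditionMessage(e),
                             call. = FALSE)
  )

  margins <- config$bt_margins
  n <- length(bt_means)
  flags <- ifelse(bt_means < margins[1L], "tendency to over-triage",
                  ifelse(bt_means > margins[2L], "tendency to under-triage",
                         "none"))
  summary <- list(
    n_raters = n,
    n_scenarios = length(responses$scenario_ids),
    expert_concordance = if (length(experts$expert_ids) == 2L)
      expert_concordance(experts) else NULL,
    mean_bt = mean(bt_means), se_bt = sd(bt_means) / sqrt(n),
    bt_means = bt_means,
    bt_margins = margins,
    triage_flags = setNames(flags, names(bt_means)),
    training = setNames(
      training_recommendation(bt_means, report$kappa_vs_experts_adjusted,
                              margins),
      names(bt_means)),
    mean_kappa_vs_experts_adjusted = mean(report$kappa_vs_experts_adjusted),
    se_kappa_vs_experts_adjusted =
      sd(report$kappa_vs_experts_adjusted) / sqrt(n),
    mean_kappa_vs_experts_raw = mean(report$kappa_vs_experts_raw),
    mean_pairwise_kappa = mean(report$mean_pairwise),
    se_pairwise_kappa = sd(report$mean_pairwise) / sqrt(n),
    n_converged = sum(vapply(fits, function(f) f$diagnostics$converged,
                             logical(1))),
    seed = config$mcmc$seed
  )

  out <- list(fits = fits, report = report, summary = summary,
              predictivity = predictivity)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    json_path <- file.path(config$out_dir, "results.json")
    write_results(report, fits, json_path, summary = summary,
                  predictivity = predictivity)
    report_path <- file.path(config$out_dir, "report.md")
    writeLines(render_report(read_results(json_path)), report_path)
    out$paths <- list(results = json_path, report = report_path)
  }
  out
}

fmt <- function(x, digits = 3) formatC(as.numeric(x), digits = digits,
                                       format = "f")

#' Render a human-readable analysis report
#'
#' Formats the pipeline results as markdown.  Every number shown is taken
#' verbatim from the results document produced by [run_pipeline()] /
#' [write_results()]; the renderer performs no computation.
#'
#' @param results A list as returned by [run_pipeline()] or
#'   [read_results()]: must contain `report` and `summary` (fits are shown
#'   through the summary's per-rater BT table).
#' @return Character vector of markdown lines.
#' @export
render_report <- function(results) {
  s <- results$summary
  rep <- results$report
  if (is.null(s) || is.null(rep)) {
    stop("results are incomplete: summary and report are required",
         call. = FALSE)
  }
  lines <- c(
    "# Belonging-threshold and agreement analysis",
    "",
    sprintf("%d raters x %d scenarios; MCMC seed %s; %d/%d fits converged.",
            s$n_raters, s$n_scenarios, s$seed, s$n_converged, s$n_raters),
    "",
    "## Group threshold",
    "",
    sprintf("Mean BT = %s (SE = %s; SE is the sample SD divided by sqrt(n)).",
            fmt(s$mean_bt), fmt(s$se_bt)),
    sprintf("Flag margins: over-triage below %s, under-triage above %s.",
            fmt(s$bt_margins[1], 2), fmt(s$bt_margins[2], 2)),
    "",
    "## Per-rater estimates",
    "",
    "| rater | BT | kappa vs experts (adjusted) | band | flag | training |",
    "|---|---|---|---|---|---|"
  )
  ids <- rep$rater_ids
  for (i in seq_along(ids)) {
    lines <- c(lines, sprintf(
      "| %s | %s | %s | %s | %s | %s |",
      ids[i], fmt(s$bt_means[[i]]),
      fmt(rep$kappa_vs_experts_adjusted[[i]]),
      rep$bands[[i]], s$triage_flags[[i]], s$training[[i]]))
  }
  lines <- c(
    lines, "",
    "## Agreement with the reference experts",
    "",
    sprintf("Mean adjusted kappa = %s (SE = %s); mean raw kappa = %s.",
            fmt(s$mean_kappa_vs_experts_adjusted),
            fmt(s$se_kappa_vs_experts_adjusted),
            fmt(s$mean_kappa_vs_experts_raw)),
    "",
    "## Agreement among raters",
    "",
    sprintf("Mean pairwise kappa = %s (SE = %s).",
            fmt(s$mean_pairwise_kappa), fmt(s$se_pairwise_kappa)),
    if (!is.null(rep$exclusion)) {
      sprintf("After excluding %s: mean pairwise kappa = %s.",
              paste(rep$exclusion$excluded_ids, collapse = ", "),
              fmt(rep$exclusion$mean_pairwise_kappa))
    },
    "",
    "## Per-scenario agreement",
    "",
    "| scenario | expert rating | expert decision | proportion agreeing |",
    "|---|---|---|---|"
  )
  ps <- rep$per_scenario
  for (i in seq_len(nrow(ps))) {
    lines <- c(lines, sprintf(
      "| %s | %d | %s | %s |",
      ps$scenario_id[i], ps$expert_rating[i],
      if (ps$expert_dichotomized[i] == 1) "at least yellow" else
        "green or less",
      fmt(ps$proportion[i], 2)))
  }
  if (!is.null(results$predictivity) && !is.null(results$predictivity$rho)) {
    lines <- c(
      lines, "",
      "## Predictivity of the estimated thresholds",
      "",
      sprintf(
        "Spearman rho between BT and historical %% low codes = %s (p = %s, n = %d).",
        fmt(results$predictivity$rho), fmt(results$predictivity$p_value),
        results$predictivity$n))
  } else {
    lines <- c(lines, "",
               "Predictivity analysis skipped: no historical statistics supplied.")
  }
  lines
}
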