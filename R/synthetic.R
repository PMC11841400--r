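# Synthetic studies with known ground truth, mirroring the empirical
# design: 21 raters x 15 scenarios x 2 reference experts, severities
# spanning [0,1] nearly uniformly, hard-rule decisions y = I(bm > bt).

#' Generate scenario severities and reference-expert ratings
#'
#' Scenario severities are equally spaced on (0, 1) (midpoints of an
#' n-scenario partition), which guarantees the near-uniform coverage of the
#' severity continuum that accurate threshold estimation requires.  Each
#' expert's integer rating is `round(10 * severity + noise)` clamped to
#' 0..10, with Gaussian noise on the 0-10 rating scale.
#'
#' @param n_scenarios Number of scenarios (>= 2).
#' @param n_experts Number of reference experts.
#' @param expert_noise_sd SD of the expert rating noise, on the 0-10 scale.
#'   The default 1 (one Likert point) yields inter-expert rank correlations
#'   around 0.9, typical of well-trained expert pairs.
#' @param seed RNG seed.
#' @return List with `severities` (named numeric vector) and `experts`
#'   (an [expert_ratings()]).
#' @export
generate_scenarios_and_experts <- function(n_scenarios = 15L, n_experts = 2L,
                                           expert_noise_sd = 1, seed = 1L) {
  if (n_scenarios < 2L || n_experts < 1L) {
    stop("need at least 2 scenarios and 1 expert", call. = FALSE)
  }
  set.seed(seed)
  scenario_ids <- paste0("s", seq_len(n_scenarios))
  severities <- setNames((seq_len(n_scenarios) - 0.5) / n_scenarios,
                         scenario_ids)
  ratings <- matrix(NA_integer_, n_scenarios, n_experts,
                    dimnames = list(scenario_ids,
                                    paste0("e", seq_len(n_experts))))
  for (e in seq_len(n_experts)) {
    raw <- round(10 * severities + rnorm(n_scenarios, 0, expert_noise_sd))
    ratings[, e] <- as.integer(pmin(10, pmax(0, raw)))
  }
  list(severities = severities, experts = expert_ratings(ratings))
}

#' Generate raters' latent truth and observed decisions
#'
#' Each rater has a true belonging threshold (BT); each rater x scenario
#' belonging measure (BM) is drawn from a truncated normal on \[0, 1\]
#' centred at the scenario severity with SD `noise_sd`.  The observed
#' binary decision applies the hard rule exactly: `y = 1` iff BM strictly
#' exceeds BT (ties produce 0, since the decision requires the BM to
#' *exceed* the threshold).
#'
#' @param n_raters Number of raters.
#' @param bt_spec True thresholds: a numeric vector of length `n_raters`,
#'   or `list(type = "uniform", min =, max =)`, or
#'   `list(type = "truncnorm", mean =, sd =)` on \[0, 1\].  Default:
#'   uniform on \[0.3, 0.7\], bracketing the spread seen in practice.
#' @param severities Named per-scenario severities in \[0, 1\].
#' @param noise_sd SD of the BM dispersion around the severity (default
#'   0.15, matching the inference prior, i.e. the well-specified case).
#' @param seed RNG seed.
#' @return List with `truth` (a `simulation_truth`: `true_bts`,
#'   `true_bms`, `scenario_severities`, `seed`, `noise_sd`) and
#'   `responses` (a [response_matrix()] carrying 4-level codes consistent
#'   with the binary decisions).
#' @export
generate_raters <- function(n_raters = 21L,
                            bt_spec = list(type = "uniform",
                                           min = 0.3, max = 0.7),
                            severities, noise_sd = 0.15, seed = 1L) {
  set.seed(seed)
  n_scen <- length(severities)
  rater_ids <- paste0("r", seq_len(n_raters))
  if (is.numeric(bt_spec)) {
    if (length(bt_spec) != n_raters || any(bt_spec < 0 | bt_spec > 1)) {
      stop("explicit bt_spec must give one value in [0, 1] per rater",
           call. = FALSE)
    }
    bts <- as.numeric(bt_spec)
  } else if (identical(bt_spec$type, "uniform")) {
    bts <- runif(n_raters, bt_spec$min, bt_spec$max)
  } else if (identical(bt_spec$type, "truncnorm")) {
    bts <- rtruncnorm01(n_raters, bt_spec$mean, bt_spec$sd)
  } else {
    stop("invalid bt_spec", call. = FALSE)
  }
  names(bts) <- rater_ids

  bms <- matrix(NA_real_, n_raters, n_scen,
                dimnames = list(rater_ids, names(severities)))
  for (i in seq_len(n_scen)) {
    bms[, i] <- rtruncnorm01(n_raters, severities[i], noise_sd)
  }
  binary <- (bms > bts) * 1L
  storage.mode(binary) <- "integer"
  # 4-level codes consistent with the dichotomy: split each side at the
  # midpoint between the threshold and the scale end
  codes <- matrix("green", n_raters, n_scen, dimnames = dimnames(binary))
  codes[binary == 0L & bms <= bts / 2] <- "white"
  codes[binary == 1L] <- "yellow"
  codes[binary == 1L & bms > (1 + bts) / 2] <- "red"

  truth <- structure(
    list(true_bts = bts, true_bms = bms,
         scenario_severities = severities,
         seed = as.integer(seed), noise_sd = noise_sd),
    class = "simulation_truth"
  )
  list(truth = truth, responses = response_matrix(codes))
}

#' Generate historical code-frequency statistics
#'
#' Simulates each rater's percentage of low-priority ("green code or
#' less") decisions over `n_calls` calls with severities drawn uniformly
#' on \[0, 1\] and the same BM noise as the main task; a call gets a low
#' code when its BM does not exceed the rater's true BT, so the expected
#' percentage increases with the threshold.
#'
#' @param true_bts Named vector of true thresholds.
#' @param n_calls Calls per rater in the reference period (default 1000,
#'   roughly a year of triage activity).
#' @param noise_sd BM dispersion around call severity.
#' @param seed RNG seed.
#' @return A [historical_code_stats()].
#' @export
generate_historical_codes <- function(true_bts, n_calls = 1000L,
                                      noise_sd = 0.15, seed = 1L) {
  if (n_calls < 1L) stop("n_calls must be >= 1", call. = FALSE)
  set.seed(seed)
  pct <- vapply(true_bts, function(bt) {
    sev <- runif(n_calls)
    bm <- rtruncnorm01(n_calls, sev, noise_sd)
    100 * mean(bm <= bt)
  }, numeric(1))
  historical_code_stats(names(true_bts), pct)
}

#' Generate a complete synthetic study
#'
#' Bundles scenario/expert generation, rater generation, and historical
#' statistics into one fixture mirroring the empirical design (21 raters x
#' 15 scenarios x 2 experts by default).  Optionally writes the CSV files
#' consumed by [read_study_inputs()] plus a `truth.json` with the ground
#' truth.
#'
#' @param n_raters,n_scenarios,n_experts Design dimensions.
#' @param bt_spec,noise_sd,expert_noise_sd,n_calls Generator settings; see
#'   [generate_raters()], [generate_scenarios_and_experts()],
#'   [generate_historical_codes()].
#' @param seed Base RNG seed (component generators use fixed offsets).
#' @param dir Optional directory; when given, `responses.csv`,
#'   `experts.csv`, `historical.csv` and `truth.json` are written there.
#' @return List with `responses`, `experts`, `historical`, `truth`,
#'   `severities`, and (when `dir` is given) `paths`.
#' @export
make_fixture_study <- function(n_raters = 21L, n_scenarios = 15L,
                               n_experts = 2L,
                               bt_spec = list(type = "uniform",
                                              min = 0.3, max = 0.7),
                               noise_sd = 0.15, expert_noise_sd = 1,
                               n_calls = 1000L, seed = 1L, dir = NULL) {
  sc <- generate_scenarios_and_experts(n_scenarios, n_experts,
                                       expert_noise_sd, seed = seed)
  rt <- generate_raters(n_raters, bt_spec, sc$severities, noise_sd,
                        seed = seed + 1L)
  hist <- generate_historical_codes(rt$truth$true_bts, n_calls, noise_sd,
                                    seed = seed + 2L)
  study <- list(responses = rt$responses, experts = sc$experts,
                historical = hist, truth = rt$truth,
                severities = sc$severities)
  if (!is.null(dir)) {
    paths <- write_study_inputs(study, dir)
    paths$truth <- file.path(dir, "truth.json")
    jsonlite::write_json(
      list(true_bts = as.list(rt$truth$true_bts),
           true_bms = rt$truth$true_bms,
           scenario_severities = as.list(sc$severities),
           seed = seed, noise_sd = noise_sd),
      paths$truth, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    study$paths <- paths
  }
  study
}
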