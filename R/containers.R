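#' Response matrix of rater decisions
#'
#' Container for a complete rater x scenario grid of priority codes and the
#' corresponding dichotomized 0/1 decisions (0 = "green code or less",
#' 1 = "at least yellow code").
#'
#' @param codes Character matrix (raters x scenarios) of priority codes,
#'   with rownames = rater ids and colnames = scenario ids.  May be `NULL`
#'   when only binary decisions exist (e.g. synthetic data emitted directly
#'   as 0/1); then `binary` must be given.
#' @param binary Optional integer 0/1 matrix; computed from `codes` when
#'   omitted.
#' @return An object of class `response_matrix` with elements `rater_ids`,
#'   `scenario_ids`, `codes`, `binary`.
#' @examples
#' codes <- matrix(c("red", "green", "yellow", "white"), 2, 2,
#'                 dimnames = list(c("r1", "r2"), c("s1", "s2")))
#' response_matrix(codes)
#' @export
response_matrix <- function(codes = NULL, binary = NULL) {
  if (is.null(codes) && is.null(binary)) {
    stop("one of codes or binary must be supplied", call. = FALSE)
  }
  if (!is.null(codes)) {
    if (!is.matrix(codes) || is.null(rownames(codes)) || is.null(colnames(codes))) {
      stop("codes must be a matrix with rater rownames and scenario colnames",
           call. = FALSE)
    }
    if (anyNA(codes)) stop("missing responses are not allowed", call. = FALSE)
    codes[] <- assert_priority_code(codes)
    derived <- matrix(dichotomize_code(codes), nrow(codes), ncol(codes),
                      dimnames = dimnames(codes))
    if (is.null(binary)) binary <- derived
    if (!identical(unname(derived), unname(binary * 1L) * 1L) &&
        !all(derived == binary)) {
      stop("binary decisions inconsistent with the dichotomized codes",
           call. = FALSE)
    }
  }
  if (!is.matrix(binary) || is.null(rownames(binary)) || is.null(colnames(binary))) {
    stop("binary must be a matrix with rater rownames and scenario colnames",
         call. = FALSE)
  }
  if (anyNA(binary) || !all(binary %in% c(0L, 1L))) {
    stop("binary decisions must be complete and in {0, 1}", call. = FALSE)
  }
  rater_ids <- rownames(binary)
  scenario_ids <- colnames(binary)
  if (anyDuplicated(rater_ids)) stop("duplicate rater ids", call. = FALSE)
  if (anyDuplicated(scenario_ids)) stop("duplicate scenario ids", call. = FALSE)
  storage.mode(binary) <- "integer"
  structure(
    list(rater_ids = rater_ids, scenario_ids = scenario_ids,
         codes = codes, binary = binary),
    class = "response_matrix"
  )
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf("<response_matrix> %d raters x %d scenarios\n",
              length(x$rater_ids), length(x$scenario_ids)))
  cat(sprintf("  'at least yellow' decisions: %.1f%%\n", 100 * mean(x$binary)))
  invisible(x)
}

#' Reference-expert ratings
#'
#' Per-scenario integer severity ratings (0-10) from one or more reference
#' experts, with the derived forms used downstream: the ceiling-rounded
#' average rating, its normalization onto \[0,1\] (rating / 10), and its
#' dichotomization (1 iff the averaged rating exceeds 5).
#'
#' @param ratings Integer matrix (scenarios x experts) with scenario ids as
#'   rownames and expert ids as colnames; values in 0..10.
#' @return An object of class `expert_ratings` with elements `scenario_ids`,
#'   `expert_ids`, `ratings`, `averaged_rating`, `normalized`, `dichotomized`.
#' @examples
#' m <- matrix(c(3, 7, 4, 8), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("e1", "e2")))
#' expert_ratings(m)
#' @export
expert_ratings <- function(ratings) {
  if (!is.matrix(ratings) || is.null(rownames(ratings)) || is.null(colnames(ratings))) {
    stop("ratings must be a matrix with scenario rownames and expert colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(ratings))) stop("duplicate scenario ids", call. = FALSE)
  if (anyDuplicated(colnames(ratings))) stop("duplicate expert ids", call. = FALSE)
  avg <- apply(ratings, 1L, average_expert_ratings)
  structure(
    list(scenario_ids = rownames(ratings),
         expert_ids = colnames(ratings),
         ratings = ratings,
         averaged_rating = avg,
         normalized = avg / 10,
         dichotomized = dichotomize_expert_rating(avg)),
    class = "expert_ratings"
  )
}

#' @export
print.expert_ratings <- function(x, ...) {
  cat(sprintf("<expert_ratings> %d scenarios x %d experts\n",
              length(x$scenario_ids), length(x$expert_ids)))
  cat("  averaged ratings:", paste(x$averaged_rating, collapse = " "), "\n")
  invisible(x)
}

#' Historical code-frequency statistics
#'
#' Per-rater percentage of low-priority codes (white or green) over the
#' total calls handled in a reference period; used to test the predictivity
#' of the estimated belonging thresholds.
#'
#' @param rater_id Character vector of rater ids.
#' @param pct_low_codes Numeric vector, percentages in \[0, 100\].
#' @return An object of class `historical_code_stats` (a data.frame).
#' @export
historical_code_stats <- function(rater_id, pct_low_codes) {
  if (length(rater_id) != length(pct_low_codes)) {
    stop("rater_id and pct_low_codes must have equal length", call. = FALSE)
  }
  if (anyDuplicated(rater_id)) stop("duplicate rater ids", call. = FALSE)
  if (anyNA(pct_low_codes) || any(pct_low_codes < 0 | pct_low_codes > 100)) {
    stop("pct_low_codes must lie in [0, 100]", call. = FALSE)
  }
  structure(
    data.frame(rater_id = as.character(rater_id),
               pct_low_codes = as.numeric(pct_low_codes),
               stringsAsFactors = FALSE),
    class = c("historical_code_stats", "data.frame")
  )
}
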