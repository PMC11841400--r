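#' Priority codes of the Italian dispatch system
#'
#' The four priority codes, ordered from least to most urgent.  White and
#' green codes dispatch an ordinary vehicle; yellow and red codes dispatch a
#' vehicle with emergency devices.
#'
#' @format Character vector of length 4.
#' @export
PRIORITY_CODES <- c("white", "green", "yellow", "red")

#' The standard belonging threshold
#'
#' The value 0.5: the common threshold that minimizes spurious agreements
#' and disagreements between raters, and the threshold attributed by
#' definition to the reference experts.
#'
#' @export
STD_BT <- 0.5

assert_priority_code <- function(code) {
  code <- tolower(as.character(code))
  bad <- setdiff(unique(code), PRIORITY_CODES)
  if (length(bad) > 0L) {
    stop("unrecognized priority code(s): ", paste(sQuote(bad), collapse = ", "),
         "; expected one of ", paste(PRIORITY_CODES, collapse = ", "),
         call. = FALSE)
  }
  code
}

#' Dichotomize a priority code
#'
#' Collapses the four-level code onto the practically decisive binary
#' decision: 0 for "green code or less" (white, green), 1 for "at least
#' yellow code" (yellow, red).  Codes are matched case-insensitively.
#'
#' @param code Character vector of priority codes
#'   (`"white"|"green"|"yellow"|"red"`).
#' @return Integer vector of 0/1 decisions.
#' @examples
#' dichotomize_code(c("white", "green", "yellow", "red"))
#' @export
dichotomize_code <- function(code) {
  code <- assert_priority_code(code)
  as.integer(code %in% c("yellow", "red"))
}

#' Average reference-expert ratings for one scenario
#'
#' The experts' integer ratings (0-10 Likert scale) are averaged and, when
#' the mean is not an integer, rounded up to the nearest larger integer --
#' emulating a single expert responding on the integer Likert scale.
#' Integer means pass through unchanged.
#'
#' @param ratings Integer vector of ratings in 0..10, one per expert.
#' @return Single integer in 0..10 (the ceiling of the mean).
#' @examples
#' average_expert_ratings(c(7, 8)) # 8
#' average_expert_ratings(c(6, 6)) # 6
#' @export
average_expert_ratings <- function(ratings) {
  if (length(ratings) == 0L) {
    stop("ratings must be a non-empty vector", call. = FALSE)
  }
  if (anyNA(ratings) || !is.numeric(ratings) ||
      any(ratings != as.integer(ratings)) ||
      any(ratings < 0 | ratings > 10)) {
    stop("ratings must be integers in [0, 10]", call. = FALSE)
  }
  as.integer(ceiling(mean(ratings)))
}

#' Dichotomize an expert severity rating
#'
#' Ratings 0-5 correspond to "green code or less" (0); ratings 6-10 to
#' "at least yellow code" (1).
#'
#' @param rating Integer vector of ratings in 0..10.
#' @return Integer vector of 0/1 decisions.
#' @examples
#' dichotomize_expert_rating(c(5, 6)) # 0 1
#' @export
dichotomize_expert_rating <- function(rating) {
  if (anyNA(rating) || !is.numeric(rating) ||
      any(rating != as.integer(rating)) ||
      any(rating < 0 | rating > 10)) {
    stop("rating must be an integer in [0, 10]", call. = FALSE)
  }
  as.integer(rating > 5)
}
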