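#' Threshold belonging measures at the standard threshold
#'
#' Dichotomizes estimated belonging measures at the standard belonging
#' threshold: 1 ("at least yellow code") iff BM > 0.5, 0 ("green code or
#' less") iff BM <= 0.5.  These are the BT-adjusted decisions: the overt
#' decisions the rater would have produced with the ideal threshold.
#'
#' @param bm_means Numeric vector of belonging measures in \[0, 1\].
#' @param threshold Threshold value; fixed at the standard 0.5.
#' @return Integer 0/1 vector.
#' @examples
#' adjust_decisions(c(0.3, 0.6, 0.5)) # 0 1 0
#' @export
adjust_decisions <- function(bm_means, threshold = STD_BT) {
  if (anyNA(bm_means) || any(bm_means < 0 | bm_means > 1)) {
    stop("belonging measures must lie in [0, 1]", call. = FALSE)
  }
  as.integer(bm_means > threshold)
}

#' Cohen's kappa for two binary raters
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with
#' marginal-product expected agreement.  Degenerate cases: two identical
#' constant vectors give 1 (perfect agreement; the raw formula is 0/0);
#' constant but different vectors fall through the formula (yielding 0).
#'
#' @param a,b Binary (0/1) vectors of equal length >= 1.
#' @return Kappa in \[-1, 1\].
#' @examples
#' cohen_kappa(c(1, 0, 1, 1, 0), c(1, 0, 1, 1, 0)) # 1
#' cohen_kappa(c(1, 0, 1, 0), c(0, 1, 0, 1))       # -1
#' @export
cohen_kappa <- function(a, b) {
  if (length(a) != length(b) || length(a) == 0L) {
    stop("a and b must be non-empty vectors of equal length", call. = FALSE)
  }
  if (anyNA(a) || anyNA(b) || !all(a %in% c(0, 1)) || !all(b %in% c(0, 1))) {
    stop("a and b must be 0/1 vectors", call. = FALSE)
  }
  po <- mean(a == b)
  pa <- mean(a == 1)
  pb <- mean(b == 1)
  pe <- pa * pb + (1 - pa) * (1 - pb)
  if (pe == 1) {
    return(1) # both constant and identical
  }
  (po - pe) / (1 - pe)
}

#' Kappa between one rater and the reference experts
#'
#' Cohen's kappa between a rater's binary decisions (either raw observed
#' decisions or BT-adjusted decisions from estimated belonging measures)
#' and the dichotomized expert responses.
#'
#' @param decisions Binary vector for the rater.
#' @param experts_dichotomized Binary vector of dichotomized expert
#'   responses, aligned on scenarios.
#' @return Kappa in \[-1, 1\].
#' @export
kappa_vs_experts <- function(decisions, experts_dichotomized) {
  cohen_kappa(decisions, experts_dichotomized)
}

#' Mean pairwise kappa per rater
#'
#' For each rater, Cohen's kappa against every other rater, averaged.  With
#' 21 raters each mean is over exactly 20 pairwise values.
#'
#' @param decisions Binary rater x scenario matrix (rownames = rater ids).
#' @return List with `pairwise` (symmetric kappa matrix, unit diagonal) and
#'   `mean_pairwise` (named per-rater means).
#' @export
mean_pairwise_kappa <- function(decisions) {
  n <- nrow(decisions)
  if (is.null(n) || n < 2L) {
    stop("at least two raters are required", call. = FALSE)
  }
  ids <- rownames(decisions)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  km <- diag(1, n)
  dimnames(km) <- list(ids, ids)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      km[i, j] <- km[j, i] <- cohen_kappa(decisions[i, ], decisions[j, ])
    }
  }
  mp <- (rowSums(km) - 1) / (n - 1)
  names(mp) <- ids
  list(pairwise = km, mean_pairwise = mp)
}

#' Per-scenario agreement with the reference experts
#'
#' For each scenario, the proportion of raters whose (BT-adjusted) decision
#' equals the experts' dichotomized response.
#'
#' @param adjusted Binary rater x scenario matrix of adjusted decisions.
#' @param experts_dichotomized Binary vector, one entry per scenario.
#' @return Named numeric vector of proportions in \[0, 1\].
#' @export
per_scenario_agreement <- function(adjusted, experts_dichotomized) {
  if (ncol(adjusted) != length(experts_dichotomized)) {
    stop("adjusted decisions and expert vector are misaligned", call. = FALSE)
  }
  out <- colMeans(sweep(adjusted, 2L, experts_dichotomized, "==") * 1)
  names(out) <- colnames(adjusted)
  out
}

#' Qualitative agreement band for a kappa value
#'
#' Banding used in healthcare and clinical research: acceptable
#' (kappa > 0.60), moderate (0.40 < kappa <= 0.60), fair
#' (0.20 < kappa <= 0.40), slight (0 <= kappa <= 0.20), below-chance
#' (kappa < 0).
#'
#' @param kappa Numeric vector of kappa values in \[-1, 1\].
#' @return Character vector of band labels.
#' @examples
#' agreement_band(c(0.61, 0.5, 0.1, -0.2))
#' @export
agreement_band <- function(kappa) {
  if (anyNA(kappa) || any(kappa < -1 | kappa > 1)) {
    stop("kappa must lie in [-1, 1]", call. = FALSE)
  }
  out <- character(length(kappa))
  out[kappa > 0.60] <- "acceptable"
  out[kappa > 0.40 & kappa <= 0.60] <- "moderate"
  out[kappa > 0.20 & kappa <= 0.40] <- "fair"
  out[kappa >= 0 & kappa <= 0.20] <- "slight"
  out[kappa < 0] <- "below-chance"
  names(out) <- names(kappa)
  out
}

#' Exclusion re-analysis of inter-rater agreement
#'
#' Removes the `k` raters with the lowest (adjusted) kappa against the
#' reference experts and recomputes the overall mean pairwise kappa among
#' the remaining raters.  Ties at the cutoff break lexicographically by
#' rater id.
#'
#' @param decisions Binary rater x scenario matrix (adjusted decisions).
#' @param experts_dichotomized Binary expert vector.
#' @param k Number of raters to exclude (0 <= k < number of raters).
#' @return List with `excluded_ids`, `mean_pairwise_kappa` (overall mean of
#'   the per-rater means after exclusion), and `per_rater` (the remaining
#'   raters' mean pairwise kappas).
#' @export
exclusion_reanalysis <- function(decisions, experts_dichotomized, k = 3L) {
  n <- nrow(decisions)
  if (k < 0 || k >= n) {
    stop("k must satisfy 0 <= k < number of raters", call. = FALSE)
  }
  ids <- rownames(decisions)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  kv <- vapply(seq_len(n), function(i) {
    kappa_vs_experts(decisions[i, ], experts_dichotomized)
  }, numeric(1))
  ord <- order(kv, ids) # lowest kappa first, ties by id
  excluded <- ids[ord[seq_len(k)]]
  keep <- setdiff(ids, excluded)
  mp <- mean_pairwise_kappa(decisions[keep, , drop = FALSE])
  list(excluded_ids = sort(excluded),
       mean_pairwise_kappa = mean(mp$mean_pairwise),
       per_rater = mp$mean_pairwise)
}

#' Spearman rank correlation
#'
#' Rank correlation with midrank handling of ties; used for the
#' BT-versus-historical-codes predictivity analysis and for the
#' inter-expert concordance check.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Correlation in \[-1, 1\].
#' @examples
#' spearman_rho(1:4, c(2, 1, 4, 3)) # 0.6
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("x and y must have equal length >= 3", call. = FALSE)
  }
  stats::cor(x, y, method = "spearman")
}

#' Concordance between two reference experts
#'
#' Spearman rank correlation between two experts' raw rating vectors; a
#' reliability check on the gold standard before averaging.
#'
#' @param experts An [expert_ratings()] with exactly two experts.
#' @return Spearman correlation.
#' @export
expert_concordance <- function(experts) {
  if (length(experts$expert_ids) != 2L) {
    stop("expert concordance is defined for exactly two experts",
         call. = FALSE)
  }
  spearman_rho(experts$ratings[, 1L], experts$ratings[, 2L])
}
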