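# In-code fixtures shared across test files.

# tiny 2-rater x 3-scenario study written to CSV
write_tiny_fixture <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(c(
    "rater_id,scenario_id,code",
    "r1,s1,white", "r1,s2,yellow", "r1,s3,red",
    "r2,s1,green", "r2,s2,green", "r2,s3,yellow"
  ), file.path(dir, "responses.csv"))
  writeLines(c(
    "scenario_id,expert_id,rating",
    "s1,e1,2", "s1,e2,3",
    "s2,e1,7", "s2,e2,8",
    "s3,e1,10", "s3,e2,9"
  ), file.path(dir, "experts.csv"))
  writeLines(c(
    "rater_id,pct_low_codes",
    "r1,45.5", "r2,60.0"
  ), file.path(dir, "historical.csv"))
  dir
}

tiny_priors <- function(mu, sigma = 0.15) {
  data.frame(scenario_id = sprintf("s%d", seq_along(mu)), mu = mu,
             sigma = rep_len(sigma, length(mu)), stringsAsFactors = FALSE)
}

# reduced sampler settings for property-style loops where only point
# estimates matter (not the convergence thresholds)
fast_config <- function(seed = 1L) {
  mcmc_config(n_chains = 2L, n_iterations = 800L, n_warmup = 300L,
              seed = seed)
}

# brute-force kappa from the 2x2 contingency table, kept deliberately
# independent of cohen_kappa()
kappa_bruteforce <- function(a, b) {
  tab <- matrix(0, 2, 2)
  for (i in seq_along(a)) {
    tab[a[i] + 1, b[i] + 1] <- tab[a[i] + 1, b[i] + 1] + 1
  }
  n <- sum(tab)
  po <- (tab[1, 1] + tab[2, 2]) / n
  pe <- (sum(tab[1, ]) * sum(tab[, 1]) + sum(tab[2, ]) * sum(tab[, 2])) / n^2
  if (pe == 1) return(1)
  (po - pe) / (1 - pe)
}
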