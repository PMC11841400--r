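test_that("cohen_kappa reproduces worked values and handles degenerate input", {
  expect_equal(cohen_kappa(c(1, 0, 1, 1, 0), c(1, 0, 1, 1, 0)), 1)
  expect_equal(cohen_kappa(c(1, 0, 1, 0), c(0, 1, 0, 1)), -1)
  expect_equal(cohen_kappa(c(1, 1, 1, 1, 0, 0, 0, 0),
                           c(1, 1, 1, 0, 1, 0, 0, 0)), 0.5)
  expect_equal(cohen_kappa(rep(1, 5), rep(1, 5)), 1)  # identical constants
  expect_equal(cohen_kappa(rep(1, 5), rep(0, 5)), 0)  # different constants
  expect_error(cohen_kappa(c(1, 0), c(1, 0, 1)), "equal length")
  expect_error(cohen_kappa(numeric(0), numeric(0)), "non-empty")
  expect_error(cohen_kappa(c(1, 2), c(0, 1)), "0/1")
})

test_that("cohen_kappa equals the brute-force contingency computation and is symmetric", {
  set.seed(99)
  for (i in 1:200) {
    n <- sample(5:40, 1)
    a <- rbinom(n, 1, runif(1, 0.2, 0.8))
    b <- rbinom(n, 1, runif(1, 0.2, 0.8))
    k <- cohen_kappa(a, b)
    expect_equal(k, kappa_bruteforce(a, b), tolerance = 1e-12)
    expect_equal(k, cohen_kappa(b, a), tolerance = 1e-12)
    expect_equal(k, cohen_kappa(1 - a, 1 - b), tolerance = 1e-12) # relabeling
    expect_true(k >= -1 && k <= 1)
  }
})

test_that("adjust_decisions thresholds at the standard BT and is idempotent", {
  expect_identical(adjust_decisions(0.50), 0L)
  expect_identical(adjust_decisions(0.51), 1L)
  expect_identical(adjust_decisions(c(0.3, 0.6, 0.5)), c(0L, 1L, 0L))
  expect_error(adjust_decisions(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(1)
  bm <- runif(50)
  once <- adjust_decisions(bm)
  expect_identical(adjust_decisions(once), once)
})

test_that("agreement bands follow the clinical-research cutpoints", {
  expect_identical(unname(agreement_band(c(0.61, 0.5, 0.1, -0.2))),
                   c("acceptable", "moderate", "slight", "below-chance"))
  expect_identical(unname(agreement_band(c(0.60, 0.40, 0.20, 0.30, 0))),
                   c("moderate", "fair", "slight", "fair", "slight"))
  expect_error(agreement_band(1.5), "\\[-1, 1\\]")
})

test_that("mean pairwise kappa averages each rater against all others", {
  m <- matrix(rep(c(1, 0, 1, 1, 0), 3), 3, 5, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), NULL))
  mp <- mean_pairwise_kappa(m)
  expect_equal(unname(mp$mean_pairwise), c(1, 1, 1))
  expect_equal(diag(mp$pairwise), c(a = 1, b = 1, c = 1))

  set.seed(3)
  m2 <- matrix(rbinom(3 * 12, 1, 0.5), 3, 12,
               dimnames = list(c("a", "b", "c"), NULL))
  mp2 <- mean_pairwise_kappa(m2)
  k_ab <- cohen_kappa(m2["a", ], m2["b", ])
  k_ac <- cohen_kappa(m2["a", ], m2["c", ])
  k_bc <- cohen_kappa(m2["b", ], m2["c", ])
  expect_equal(unname(mp2$mean_pairwise),
               c((k_ab + k_ac) / 2, (k_ab + k_bc) / 2, (k_ac + k_bc) / 2))
  expect_equal(mp2$pairwise, t(mp2$pairwise))
  expect_error(mean_pairwise_kappa(m2[1, , drop = FALSE]), "two raters")
})

test_that("per-scenario agreement is the fraction of raters matching the experts", {
  adj <- rbind(r1 = c(1, 0, 1), r2 = c(1, 1, 0), r3 = c(1, 0, 0))
  colnames(adj) <- paste0("s", 1:3)
  expect_equal(unname(per_scenario_agreement(adj, c(1, 0, 1))),
               c(1, 2 / 3, 1 / 3))
  expect_equal(unname(per_scenario_agreement(adj, c(0, 1, 0))),
               c(0, 1 / 3, 2 / 3))
  expect_error(per_scenario_agreement(adj, c(1, 0)), "misaligned")
})

test_that("exclusion re-analysis drops the least expert-concordant raters", {
  set.seed(11)
  experts <- rbinom(15, 1, 0.5)
  # 5 concordant raters (small perturbations) + 3 planted discordant raters
  flip <- function(x, k) { i <- sample(seq_along(x), k); x[i] <- 1 - x[i]; x }
  dec <- rbind(
    a = flip(experts, 1), b = flip(experts, 1), c = flip(experts, 2),
    d = flip(experts, 1), e = flip(experts, 2),
    x1 = 1 - experts, x2 = flip(1 - experts, 1), x3 = flip(1 - experts, 2)
  )
  colnames(dec) <- paste0("s", 1:15)
  res <- exclusion_reanalysis(dec, experts, k = 3L)
  expect_identical(res$excluded_ids, c("x1", "x2", "x3"))
  full <- mean(mean_pairwise_kappa(dec)$mean_pairwise)
  expect_gt(res$mean_pairwise_kappa, full)

  # k = 0 leaves the mean unchanged
  res0 <- exclusion_reanalysis(dec, experts, k = 0L)
  expect_equal(res0$mean_pairwise_kappa, full)
  expect_error(exclusion_reanalysis(dec, experts, k = 8L), "k must")

  # ties at the cutoff break lexicographically by rater id
  tied <- rbind(b = experts, a = experts, c = 1 - experts, d = 1 - experts)
  colnames(tied) <- paste0("s", 1:15)
  res_tie <- exclusion_reanalysis(tied, experts, k = 1L)
  expect_identical(res_tie$excluded_ids, "c")
})

test_that("decision pairs classify into the true/spurious taxonomy", {
  expect_identical(classify_decision_pair(0.6, 0.6, 0.3, 0.7),
                   "spurious_disagreement")
  expect_identical(classify_decision_pair(0.3, 0.7, 0.2, 0.6),
                   "spurious_agreement")
  expect_identical(classify_decision_pair(0.6, 0.6, 0.5, 0.5),
                   "true_agreement")
  expect_identical(classify_decision_pair(0.3, 0.8, 0.5, 0.5),
                   "true_disagreement")
  expect_error(classify_decision_pair(0.6, 0.6, -0.1, 0.5), "\\[0, 1\\]")

  # with both thresholds at the standard value nothing is ever spurious
  set.seed(4)
  lab <- classify_decision_pair(runif(500), runif(500), 0.5, 0.5)
  expect_true(all(lab %in% c("true_agreement", "true_disagreement")))
})

test_that("spurious rate matches the closed form 2a(1-a) and vanishes at 0.5", {
  grid <- seq(0.1, 0.9, by = 0.1)
  sw <- spurious_rate_sweep(grid, n_sim = 20000L, seed = 8L)
  expect_equal(sw$argmin, 0.5)
  expect_equal(sw$spurious_rate[grid == 0.5], 0)
  a <- abs(grid - 0.5)
  expected <- 2 * a * (1 - a)
  se <- sqrt(expected * (1 - expected) / 20000)
  expect_true(all(abs(sw$spurious_rate - expected) <= pmax(3 * se, 1e-12)))
  expect_error(spurious_rate_sweep(numeric(0)), "non-empty")
})

test_that("threshold adjustment recovers implicit agreement for biased raters", {
  # 100 synthetic raters with a shifted threshold: kappa vs experts computed
  # from standard-threshold labels is at least as high, on average, as kappa
  # from the raters' overt (biased-threshold) decisions
  set.seed(12)
  sev <- (1:15 - 0.5) / 15
  experts_dich <- as.integer(sev > 0.5)
  k_raw <- k_adj <- numeric(100)
  for (r in 1:100) {
    bm <- pmin(1, pmax(0, sev + rnorm(15, 0, 0.15)))
    bt <- 0.75
    k_raw[r] <- cohen_kappa(as.integer(bm > bt), experts_dich)
    k_adj[r] <- cohen_kappa(as.integer(bm > 0.5), experts_dich)
  }
  expect_gt(mean(k_adj), mean(k_raw))
})

test_that("spearman_rho matches rank-based hand computations", {
  expect_equal(spearman_rho(1:5, 2 * (1:5) + 3), 1)
  expect_equal(spearman_rho(1:5, -(1:5)), -1)
  expect_equal(spearman_rho(1:4, c(2, 1, 4, 3)), 0.6)
  expect_error(spearman_rho(1:3, 1:4), "equal length")

  # concordance of two noiseless experts is a perfect rank correlation
  sc <- generate_scenarios_and_experts(10, 2, expert_noise_sd = 0, seed = 2)
  expect_equal(expert_concordance(sc$experts), 1)
})
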