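test_that("priority codes dichotomize onto the practical binary decision", {
  expect_identical(dichotomize_code(c("white", "green")), c(0L, 0L))
  expect_identical(dichotomize_code(c("yellow", "red")), c(1L, 1L))
  expect_identical(dichotomize_code(c("White", "RED")), c(0L, 1L)) # case-insensitive
  expect_error(dichotomize_code("blue"), "blue")
})

test_that("expert averaging rounds non-integer means up to the next integer", {
  expect_identical(average_expert_ratings(c(7, 8)), 8L)
  expect_identical(average_expert_ratings(c(6, 6)), 6L)
  expect_identical(average_expert_ratings(c(0, 1)), 1L)
  expect_error(average_expert_ratings(integer(0)), "non-empty")
  expect_error(average_expert_ratings(c(3, 11)), "\\[0, 10\\]")
  expect_error(average_expert_ratings(c(3.5, 4)), "integers")

  # ceiling property: avg >= mean and avg - mean < 1, for random panels
  set.seed(42)
  for (i in 1:50) {
    x <- sample(0:10, sample(2:5, 1), replace = TRUE)
    a <- average_expert_ratings(x)
    expect_gte(a, mean(x))
    expect_lt(a - mean(x), 1)
  }
})

test_that("expert ratings dichotomize at the 5/6 boundary", {
  expect_identical(dichotomize_expert_rating(5L), 0L)
  expect_identical(dichotomize_expert_rating(6L), 1L)
  expect_identical(dichotomize_expert_rating(0L), 0L)
  expect_identical(dichotomize_expert_rating(0:10), as.integer(0:10 > 5))
  expect_error(dichotomize_expert_rating(11L), "\\[0, 10\\]")
})

test_that("expert_ratings derives averaged, normalized and dichotomized forms", {
  m <- matrix(c(3L, 7L, 10L, 4L, 8L, 9L), 3, 2,
              dimnames = list(c("s1", "s2", "s3"), c("e1", "e2")))
  er <- expert_ratings(m)
  expect_identical(unname(er$averaged_rating), c(4L, 8L, 10L))
  expect_equal(unname(er$normalized), c(0.4, 0.8, 1.0))
  expect_identical(unname(er$dichotomized), c(0L, 1L, 1L))
})

test_that("response_matrix validates completeness and binary consistency", {
  codes <- matrix(c("red", "green", "yellow", "white"), 2, 2,
                  dimnames = list(c("r1", "r2"), c("s1", "s2")))
  rm <- response_matrix(codes)
  expect_identical(unname(rm$binary), matrix(c(1L, 0L, 1L, 0L), 2, 2))
  codes[1, 1] <- NA
  expect_error(response_matrix(codes), "missing")
  expect_error(
    response_matrix(matrix("red", 2, 1,
                           dimnames = list(c("r1", "r1"), "s1"))),
    "duplicate rater")
})

test_that("read_study_inputs round-trips a valid fixture and rejects bad ones", {
  dir <- write_tiny_fixture(withr::local_tempdir())
  study <- read_study_inputs(file.path(dir, "responses.csv"),
                             file.path(dir, "experts.csv"),
                             file.path(dir, "historical.csv"))
  expect_identical(dim(study$responses$binary), c(2L, 3L))
  expect_identical(study$responses$scenario_ids, c("s1", "s2", "s3"))
  expect_identical(unname(study$responses$binary["r1", ]), c(0L, 1L, 1L))
  expect_identical(unname(study$experts$averaged_rating), c(3L, 8L, 10L))
  expect_equal(study$historical$pct_low_codes, c(45.5, 60.0))

  # read -> write -> read reproduces identical objects
  dir2 <- withr::local_tempdir()
  write_study_inputs(study, dir2)
  study2 <- read_study_inputs(file.path(dir2, "responses.csv"),
                              file.path(dir2, "experts.csv"),
                              file.path(dir2, "historical.csv"))
  expect_identical(study2$responses$binary, study$responses$binary)
  expect_identical(study2$responses$codes, study$responses$codes)
  expect_identical(study2$experts$ratings, study$experts$ratings)
  expect_equal(study2$historical, study$historical)

  # scenario present in experts but absent from responses
  writeLines(c("rater_id,scenario_id,code",
               "r1,s1,white", "r2,s1,green"),
             file.path(dir, "responses_bad.csv"))
  expect_error(read_study_inputs(file.path(dir, "responses_bad.csv"),
                                 file.path(dir, "experts.csv")),
               "scenario sets differ")

  # duplicated (rater, scenario) row
  writeLines(c("rater_id,scenario_id,code",
               "r1,s1,white", "r1,s1,green"),
             file.path(dir, "responses_dup.csv"))
  expect_error(read_study_inputs(file.path(dir, "responses_dup.csv"),
                                 file.path(dir, "experts.csv")),
               "duplicated")

  # missing column
  writeLines(c("rater_id,code", "r1,white"),
             file.path(dir, "responses_col.csv"))
  expect_error(read_study_inputs(file.path(dir, "responses_col.csv"),
                                 file.path(dir, "experts.csv")),
               "missing column")

  # incomplete grid
  writeLines(c("rater_id,scenario_id,code",
               "r1,s1,white", "r1,s2,green", "r1,s3,red",
               "r2,s1,green", "r2,s2,red"),
             file.path(dir, "responses_hole.csv"))
  expect_error(read_study_inputs(file.path(dir, "responses_hole.csv"),
                                 file.path(dir, "experts.csv")),
               "full rater x scenario grid")
})

test_that("results serialize to JSON and round-trip losslessly", {
  st <- make_fixture_study(n_raters = 4L, n_scenarios = 6L, seed = 3L)
  pr <- build_scenario_priors(st$experts)
  fits <- suppressWarnings(fit_all(st$responses, pr, fast_config(5L)))
  adjusted <- t(vapply(fits, function(f) adjust_decisions(f$bm_means),
                       integer(6)))
  dimnames(adjusted) <- dimnames(st$responses$binary)
  rep <- agreement_report(adjusted, st$responses$binary, st$experts,
                          exclude_k = 1L)

  path <- file.path(withr::local_tempdir(), "results.json")
  write_results(rep, fits, path)
  back <- read_results(path)
  expect_equal(back$report$pairwise_kappa, rep$pairwise_kappa)
  expect_equal(as.numeric(back$report$kappa_vs_experts_adjusted),
               as.numeric(rep$kappa_vs_experts_adjusted))
  expect_equal(back$report$per_scenario$proportion,
               rep$per_scenario$proportion)
  expect_true(file.exists(sub("\\.json$", "_kappa_matrix.csv", path)))
  expect_true(file.exists(sub("\\.json$", "_per_scenario.csv", path)))

  # degenerate inputs
  expect_error(write_results(rep, list(), path), "non-empty")
  one <- agreement_report(adjusted[1, , drop = FALSE],
                          st$responses$binary[1, , drop = FALSE],
                          st$experts, exclude_k = 0L)
  expect_null(one$exclusion)
  path1 <- file.path(withr::local_tempdir(), "one.json")
  write_results(one, fits[1], path1)
  expect_true(file.exists(path1))
})
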