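test_that("the ground truth is calibrated to the reported figures", {
  gt <- ground_truth_network()
  expect_length(validate_network(gt), 0L)
  m <- marginals(gt)
  expect_equal(m$HRUB[["yes"]], 0.248, tolerance = 1e-9)
  expect_equal(m$MaritalStatus[["yes"]], 0.736, tolerance = 1e-9)
  expect_equal(m$PreviousAccident[["major accident"]], 0.0411,
               tolerance = 1e-9)
  expect_equal(m$EducationalLevel[["high school"]], 0.595, tolerance = 1e-9)
  expect_equal(posterior(gt, "HRUB", c(Training = "s3"))[["yes"]], 0.123,
               tolerance = 1e-9)
  # every CPT row is a distribution
  for (v in names(gt$cpts))
    expect_equal(unname(rowSums(sbsbn:::cpt_to_rows(gt$cpts[[v]]))),
                 rep(1, nrow(sbsbn:::cpt_to_rows(gt$cpts[[v]]))),
                 tolerance = 1e-12)
})

test_that("sampling is seeded and respects edge cases", {
  gt <- ground_truth_network()
  expect_identical(nrow(sample_observations(gt, 0)), 0L)
  a <- sample_observations(gt, 100, missing_rate = 0.3, seed = 42)
  b <- sample_observations(gt, 100, missing_rate = 0.3, seed = 42)
  expect_identical(a, b)
  c2 <- sample_observations(gt, 100, missing_rate = 0.3, seed = 43)
  expect_false(identical(a, c2))
  expect_error(sample_observations(gt, -1), "count")
  expect_error(sample_observations(gt, 10, missing_rate = 1), "missing_rate")
  # simulate() methods delegate to the sampler
  expect_identical(simulate(gt, seed = 7, n = 25),
                   sample_observations(gt, 25, seed = 7))
})

test_that("empirical state frequencies sit in 3-sigma binomial bands", {
  gt <- ground_truth_network()
  n <- 50000
  obs <- sample_observations(gt, n, seed = 17)
  m <- marginals(gt)
  for (v in names(m)) {
    for (s in names(m[[v]])) {
      p <- m[[v]][[s]]
      phat <- mean(obs[[v]] == s)
      expect_lt(abs(phat - p), 3 * sqrt(p * (1 - p) / n) + 1e-12)
    }
  }
})

test_that("masking hits the requested MCAR rate", {
  gt <- ground_truth_network()
  n <- 20000
  rate <- 0.2
  obs <- sample_observations(gt, n, missing_rate = rate, seed = 23)
  cells <- n * ncol(obs)
  frac <- sum(is.na(obs)) / cells
  expect_lt(abs(frac - rate), 3 * sqrt(rate * (1 - rate) / cells))
})

test_that("fit + sensitivity on synthetic data ranks training first", {
  gt <- ground_truth_network()
  obs <- sample_observations(gt, 10000, seed = 29)
  fit <- bn_fit(default_study_network(), obs)
  rep <- sensitivity_report(fit)
  expect_identical(rep$variable[rep$rank == 1], "Training")
  expect_lt(attr(rep, "variations")$Training[["s3"]], 0)
})
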