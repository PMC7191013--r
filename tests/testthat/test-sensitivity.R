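test_that("state variations are relative percent changes of the outcome", {
  # toy network calibrated by hand: baseline P(t) = 0.25 and
  # P(t | X = s1) = 0.30 gives +20%
  sch <- make_scheme(list(X = c("s1", "s2"), T = c("no", "yes")),
                     target = "T")
  st <- bn_structure(list(X = character(0), T = "X"))
  net <- bn_network(sch, st, list(
    X = make_cpt("X", character(0), sch, values = c(0.5, 0.5)),
    T = make_cpt("T", "X", sch, rows = rbind(c(0.70, 0.30), c(0.80, 0.20)))))
  v <- state_variations(net, "X", adverse = "yes")
  expect_equal(v[["s1"]], 20, tolerance = 1e-9)
  expect_equal(v[["s2"]], -20, tolerance = 1e-9)
  # consistency: baseline * (1 + V/100) equals the conditional posterior
  base_p <- posterior(net, "T")[["yes"]]
  for (s in names(v))
    expect_equal(base_p * (1 + v[[s]] / 100),
                 posterior(net, "T", c(X = s))[["yes"]], tolerance = 1e-9)
  expect_error(state_variations(net, "T"), "differ")
})

test_that("variables independent of the target show zero variation and MI", {
  sch <- make_scheme(list(X = c("s1", "s2"), T = c("no", "yes")),
                     target = "T")
  st <- bn_structure(list(X = character(0), T = character(0)))
  net <- bn_network(sch, st, list(
    X = make_cpt("X", character(0), sch, values = c(0.6, 0.4)),
    T = make_cpt("T", character(0), sch, values = c(0.75, 0.25))))
  expect_equal(unname(state_variations(net, "X")), c(0, 0),
               tolerance = 1e-9)
  expect_equal(mutual_information(net, "X", "T"), 0, tolerance = 1e-12)
})

test_that("mean absolute variation matches the published arithmetic", {
  # per-state sensitivity entries from the study's published table
  expect_equal(absolute_mean_variation(c(-4.03, 7.69, 33.33)), 15.02,
               tolerance = 0.005)
  expect_equal(absolute_mean_variation(c(48.72, 5.86, -49.82)), 34.80,
               tolerance = 0.005)
  expect_equal(absolute_mean_variation(c(13.19, 24.18, -23.44)), 20.27,
               tolerance = 0.005)
  expect_equal(absolute_mean_variation(c(-9.52, 26.37)), 17.95,
               tolerance = 0.005)
  expect_equal(absolute_mean_variation(c(-7.69, 5.13, 5.13)), 5.98,
               tolerance = 0.005)
  expect_error(absolute_mean_variation(numeric(0)), "empty")
})

test_that("mutual information has its closed-form values and symmetry", {
  # two perfectly correlated uniform binary nodes share exactly 1 bit
  sch <- make_scheme(list(A = c("a1", "a2"), B = c("b1", "b2")),
                     target = "B")
  st <- bn_structure(list(A = character(0), B = "A"))
  mirror <- bn_network(sch, st, list(
    A = make_cpt("A", character(0), sch, values = c(0.5, 0.5)),
    B = make_cpt("B", "A", sch, rows = rbind(c(1, 0), c(0, 1)))))
  expect_equal(mutual_information(mirror, "A", "B"), 1, tolerance = 1e-12)
  expect_equal(mutual_information(mirror, "A", "B", base = exp(1)), log(2),
               tolerance = 1e-12)

  # 2x2 joint (0.4, 0.1, 0.1, 0.4) checked against direct summation
  net <- chain_bn(pa1 = 0.5, pb1_a1 = 0.8, pb1_a2 = 0.2)
  hand <- sum(sapply(c(0.4, 0.1, 0.1, 0.4), function(p)
    p * log2(p / 0.25)))
  expect_equal(mutual_information(net, "A", "B"), hand, tolerance = 1e-12)

  # symmetry and non-negativity across random networks
  for (seed in c(3, 14, 27, 58)) {
    rb <- random_bn(seed)
    nodes <- rb$structure$nodes
    pair <- sample(nodes, 2)
    m1 <- mutual_information(rb, pair[1], pair[2])
    m2 <- mutual_information(rb, pair[2], pair[1])
    expect_gte(m1, 0)
    expect_equal(m1, m2, tolerance = 1e-9)
  }
})

test_that("ranking reproduces the published order including the MI tie-break", {
  published <- data.frame(
    variable = c("Previous Accident", "Experience", "Age",
                 "Education Level", "Marital Status", "Week Day",
                 "Day Time", "Training"),
    abs_mean_variation = c(15.02, 20.27, 17.22, 15.02, 17.95, 16.00,
                           5.98, 34.80),
    mutual_information = c(0.00597, 0.01270, 0.00764, 0.00570, 0.00674,
                           0.00597, 0.00061, 0.05451))
  ranked <- rank_variables(published)
  want <- c("Training" = 1L, "Experience" = 2L, "Marital Status" = 3L,
            "Age" = 4L, "Week Day" = 5L, "Previous Accident" = 6L,
            "Education Level" = 7L, "Day Time" = 8L)
  expect_identical(setNames(ranked$rank, ranked$variable)[names(want)],
                   want)
  # the 15.02 tie is broken by higher mutual information
  expect_lt(ranked$rank[ranked$variable == "Previous Accident"],
            ranked$rank[ranked$variable == "Education Level"])
  # single entry gets rank 1
  expect_identical(rank_variables(published[1, ])$rank, 1L)
  # full tie falls back to the variable name, deterministically
  tie <- data.frame(variable = c("Zeta", "Alpha"),
                    abs_mean_variation = c(5, 5),
                    mutual_information = c(0.1, 0.1))
  expect_identical(rank_variables(tie)$rank, c(2L, 1L))
  # ranking does not depend on input order
  shuffled <- published[c(5, 2, 8, 1, 7, 3, 6, 4), ]
  r2 <- rank_variables(shuffled)
  expect_identical(setNames(r2$rank, r2$variable)[names(want)], want)
})

test_that("the assembled report is coherent with the posteriors", {
  gt <- ground_truth_network()
  rep <- sensitivity_report(gt)
  expect_identical(sort(rep$rank), 1:8)
  expect_identical(rep$variable[rep$rank == 1], "Training")
  # training's strongest reduction comes from its highest course level
  vt <- attr(rep, "variations")$Training
  expect_identical(names(which.min(vt)), "s3")
  expect_lt(vt[["s3"]], 0)
  # abs mean equals the mean of absolute per-state variations
  for (v in rep$variable)
    expect_equal(rep$abs_mean_variation[rep$variable == v],
                 mean(abs(attr(rep, "variations")[[v]])), tolerance = 1e-12)
  # two-state variables contribute two terms only
  expect_length(attr(rep, "variations")$MaritalStatus, 2L)
  expect_true(is.na(rep$state3[rep$variable == "MaritalStatus"]))
  # conditionals table consistent with the variations
  cond <- attr(rep, "conditionals")
  base_p <- attr(rep, "baseline")
  tr3 <- cond$probability[cond$variable == "Training" & cond$state == "s3"]
  expect_equal(tr3, base_p * (1 + vt[["s3"]] / 100), tolerance = 1e-9)
  expect_equal(tr3, 0.123, tolerance = 1e-9)
})
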