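test_that("the study structure wires age through its mediators", {
  st <- default_study_network()
  expect_length(st$parents$HRUB, 7L)
  expect_false("Age" %in% st$parents$HRUB)
  expect_length(st$parents$Age, 0L)
  children_of_age <- names(Filter(function(p) "Age" %in% p, st$parents))
  expect_setequal(children_of_age, c("Experience", "MaritalStatus"))
  expect_identical(st$parents$Training, "PreviousAccident")
})

test_that("cyclic structures are rejected and validation flags bad CPTs", {
  st <- default_study_network()
  cyc <- st$parents
  cyc$Age <- "HRUB"          # closes Age -> Experience -> HRUB -> Age
  expect_error(bn_structure(cyc), "cycle")

  net <- chain_bn()
  expect_length(validate_network(net), 0L)
  bad <- net
  bad$cpts$B[, 1] <- c(0.5, 0.4)   # row sums to 0.9
  expect_match(validate_network(bad), "sums to", all = FALSE)
  neg <- net
  neg$cpts$A <- array(c(1.2, -0.2), dim = 2L)
  expect_match(validate_network(neg), "negative", all = FALSE)
  # dimension mismatch is caught at assembly
  sch <- net$scheme
  expect_error(bn_network(sch, net$structure,
                          list(A = net$cpts$A, B = net$cpts$A)),
               "dimensions")
})

test_that("joint probability is the product of selected CPT entries", {
  net <- chain_bn(pa1 = 0.3, pb1_a1 = 0.5)
  expect_equal(joint_probability(net, c(A = "a1", B = "b1")), 0.15)
  expect_equal(joint_probability(net, c(A = "a1", B = "b1"), log = TRUE),
               log(0.15))
  expect_equal(joint_probability(deterministic_bn(),
                                 c(A = "a1", B = "b1")), 1)
  expect_error(joint_probability(net, c(A = "a1")), "incomplete")

  # the full joint of the study ground truth is normalized, and
  # joint_probability agrees with the enumerated cell
  gt <- ground_truth_network()
  grid <- oracle_joint(gt)
  expect_equal(sum(grid$prob), 1, tolerance = 1e-9)
  set.seed(4)
  for (i in sample(nrow(grid), 5)) {
    assign_labels <- vapply(gt$structure$nodes, function(v)
      gt$scheme$variables[[v]]$states[grid[i, v]], character(1))
    expect_equal(joint_probability(gt, assign_labels), grid$prob[i],
                 tolerance = 1e-12)
  }
})

test_that("posteriors follow Bayes' rule and degenerate cases", {
  net <- chain_bn(pa1 = 0.3, pb1_a1 = 0.5, pb1_a2 = 0.2)
  # root with no evidence returns its prior
  expect_equal(posterior(net, "A"), c(a1 = 0.3, a2 = 0.7))
  # hand application of Bayes' rule: P(a1 | b1) = .15 / .29
  expect_equal(posterior(net, "A", c(B = "b1"))[["a1"]], 0.15 / 0.29,
               tolerance = 1e-12)
  # querying an evidenced variable yields a point mass
  expect_equal(posterior(net, "B", c(B = "b2")), c(b1 = 0, b2 = 1))
  # contradicting a deterministic network is impossible evidence
  expect_error(posterior(deterministic_bn(), "B", c(A = "a2")),
               "impossible evidence")
  expect_error(posterior(net, "A", c(B = "nope")), "invalid state")
})

test_that("marginals are normalized and hit the calibrated outcome rate", {
  gt <- ground_truth_network()
  m <- marginals(gt)
  expect_equal(m$HRUB[["yes"]], 0.248, tolerance = 1e-9)
  for (v in names(m)) expect_equal(sum(m[[v]]), 1, tolerance = 1e-12)
  md <- marginals(deterministic_bn())
  expect_equal(md$A, c(a1 = 1, a2 = 0))
  expect_equal(md$B, c(b1 = 1, b2 = 0))
})
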