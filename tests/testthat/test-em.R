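test_that("EM on complete data reduces to frequency counting", {
  net <- chain_bn()
  sch <- net$scheme
  # 10 hand-built records: A=a1 in 4, among them B=b1 in 3;
  # A=a2 in 6, among them B=b1 in 1
  obs <- data.frame(
    A = rep(c("a1", "a2"), c(4, 6)),
    B = c("b1", "b1", "b1", "b2", "b1", rep("b2", 5)))
  fit <- bn_fit(net$structure, obs, scheme = sch, pseudocount = 0)
  expect_identical(fit$iterations, 2L)
  expect_true(fit$converged)
  expect_equal(as.numeric(fit$network$cpts$A), c(0.4, 0.6))
  expect_equal(as.numeric(fit$network$cpts$B[, 1]), c(3 / 4, 1 / 4))
  expect_equal(as.numeric(fit$network$cpts$B[, 2]), c(1 / 6, 5 / 6))
  # with Laplace smoothing the counts shift by the pseudocount
  fit1 <- bn_fit(net$structure, obs, scheme = sch, pseudocount = 1)
  expect_equal(as.numeric(fit1$network$cpts$A), c(5 / 12, 7 / 12))
})

test_that("log-likelihood is additive and marginalizes missing cells exactly", {
  net <- chain_bn(pa1 = 0.3, pb1_a1 = 0.5, pb1_a2 = 0.2)
  one <- data.frame(A = "a1", B = "b2")
  expect_equal(log_likelihood(net, one),
               log(joint_probability(net, c(A = "a1", B = "b2"))))
  two <- rbind(one, one)
  expect_equal(log_likelihood(net, two), 2 * log_likelihood(net, one))
  # record with B missing: enumeration over B's states
  part <- data.frame(A = "a1", B = NA_character_)
  expect_equal(log_likelihood(net, part),
               log(joint_probability(net, c(A = "a1", B = "b1")) +
                   joint_probability(net, c(A = "a1", B = "b2"))))
  # impossible record reports its index
  imp <- data.frame(A = c("a1", "a1"), B = c("b1", "b1"))
  impnet <- chain_bn(pa1 = 0.3, pb1_a1 = 0)
  ll <- log_likelihood(impnet, imp)
  expect_identical(as.numeric(ll), -Inf)
  expect_identical(attr(ll, "record"), 1L)
  expect_error(log_likelihood(net, data.frame(A = character(0))), "empty")
})

test_that("EM log-likelihood trace is non-decreasing with missing data", {
  gt <- ground_truth_network()
  obs <- sample_observations(gt, 300, missing_rate = 0.15, seed = 8)
  fit <- bn_fit(default_study_network(), obs, init = "random", seed = 2,
                max_iter = 40)
  expect_gte(length(fit$loglik_trace), 2L)
  expect_true(all(diff(fit$loglik_trace) >= -1e-8))
  # and equals the standalone likelihood of the fitted network
  expect_equal(log_likelihood(fit, obs),
               fit$loglik_trace[length(fit$loglik_trace)], tolerance = 1e-9)
})

test_that("EM recovers a known 3-node network from 20% MCAR data", {
  sch <- make_scheme(list(A = c("a1", "a2", "a3"),
                          B = c("b1", "b2"),
                          C = c("c1", "c2")), target = "C")
  st <- bn_structure(list(A = character(0), B = "A", C = "A"))
  truth <- bn_network(sch, st, list(
    A = make_cpt("A", character(0), sch, values = c(0.5, 0.3, 0.2)),
    B = make_cpt("B", "A", sch, rows = rbind(c(0.8, 0.2), c(0.4, 0.6),
                                             c(0.1, 0.9))),
    C = make_cpt("C", "A", sch, rows = rbind(c(0.3, 0.7), c(0.6, 0.4),
                                             c(0.9, 0.1)))))
  obs <- sample_observations(truth, 5000, missing_rate = 0.2, seed = 31)
  fit <- bn_fit(st, obs, scheme = sch)
  for (v in c("A", "B", "C"))
    expect_lt(max(abs(fit$network$cpts[[v]] - truth$cpts[[v]])), 0.05)
  expect_true(fit$converged)
})

test_that("EM runs are deterministic given data and configuration", {
  gt <- ground_truth_network()
  obs <- sample_observations(gt, 200, missing_rate = 0.1, seed = 5)
  f1 <- bn_fit(default_study_network(), obs, init = "random", seed = 9,
               max_iter = 15)
  f2 <- bn_fit(default_study_network(), obs, init = "random", seed = 9,
               max_iter = 15)
  expect_identical(f1, f2)
})

test_that("fitted marginals recover the generator at n = 10,000", {
  gt <- ground_truth_network()
  obs <- sample_observations(gt, 10000, seed = 12)
  fit <- bn_fit(default_study_network(), obs)
  mf <- marginals(fit$network)
  mt <- marginals(gt)
  for (v in names(mt))
    expect_lt(max(abs(mf[[v]] - mt[[v]])), 0.02)
})

test_that("degenerate inputs are handled", {
  gt <- ground_truth_network()
  expect_error(bn_fit(default_study_network(), data.frame(HRUB = character(0))),
               "empty")
  # a fully missing record contributes its prior expectation, not an error
  obs <- sample_observations(gt, 20, seed = 3)
  obs[3, ] <- NA_character_
  fit <- bn_fit(default_study_network(), obs, max_iter = 5)
  expect_s3_class(fit, "bn_fit")
  expect_true(all(is.finite(fit$loglik_trace)))
  # unknown dataset variable is rejected
  bad <- cbind(obs, Extra = "x")
  expect_error(bn_fit(default_study_network(), bad), "Extra|unknown")
})
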