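test_that("default scheme declares the nine study variables and states", {
  sch <- default_scheme()
  card <- sapply(sch$variables, function(v) length(v$states))
  expect_length(card, 9L)
  expect_identical(sum(card), 25L)
  expect_identical(unname(card[c("MaritalStatus", "HRUB")]), c(2L, 2L))
  expect_true(all(card[setdiff(names(card), c("MaritalStatus", "HRUB"))] == 3L))
  expect_identical(sch$target, "HRUB")
  expect_identical(sch$variables$Training$states, c("s1", "s2", "s3"))
  expect_identical(sch$variables$HRUB$states, c("no", "yes"))
})

test_that("discretization maps raw values with lower-inclusive bins", {
  expect_identical(unname(discretize(list(Age = 25))), "under 30 years")
  expect_identical(unname(discretize(list(Age = 30))), "from 30 to 40 years")
  expect_identical(unname(discretize(list(Age = 40))), "above 40 years")
  expect_identical(unname(discretize(list(Experience = 5))), "above 5 years")
  expect_identical(unname(discretize(list(Training = 5))), "s3")
  expect_identical(unname(discretize(list(Training = 2))), "s1")
  expect_identical(unname(discretize(list(Daytime = "13:00"))),
                   "from 11am to 2pm")
  expect_identical(unname(discretize(list(Daytime = 18))), "from 2pm to 6pm")
  expect_identical(unname(discretize(list(Weekday = 5))), "middle days")
  expect_identical(unname(discretize(list(Weekday = 7))), "last days")
})

test_that("discretization accepts labels, propagates missing, rejects out-of-domain", {
  # canonical label pass-through, case-insensitive with whitespace
  expect_identical(unname(discretize(list(MaritalStatus = " YES "))), "yes")
  expect_identical(unname(discretize(list(HRUB = "No"))), "no")
  expect_true(is.na(discretize(list(Age = NA))[["Age"]]))
  expect_error(discretize(list(Age = -3)), "Age")
  expect_error(discretize(list(Training = 0)), "Training")
  expect_error(discretize(list(Daytime = 19)), "Daytime")
  expect_error(discretize(list(MaritalStatus = "divorced")), "invalid state")
  expect_error(discretize(list(Bogus = 1)), "unknown variable")
})

test_that("observation CSV write/read round-trips record-for-record", {
  net <- ground_truth_network()
  obs <- sample_observations(net, 30, missing_rate = 0.2, seed = 11)
  path <- withr::local_tempfile(fileext = ".csv")
  write_observations(obs, path)
  back <- read_observations(path)
  expect_identical(as.data.frame(back), as.data.frame(obs))
})

test_that("reading reports invalid cells with their row number", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Age,Training,HRUB",
               "under 30 years,s1,no",
               "under 30 years,,yes",
               "40-50,s2,no"), path)
  expect_error(read_observations(path), "40-50")
  expect_error(read_observations(path), "row 3")
  # drop the offending row: missing Training cell must come back as NA
  writeLines(c("Age,Training,HRUB",
               "under 30 years,s1,no",
               "under 30 years,,yes"), path)
  obs <- read_observations(path)
  expect_identical(nrow(obs), 2L)
  expect_true(is.na(obs$Training[2]))
  expect_identical(obs$HRUB, c("no", "yes"))
  # unknown columns are rejected
  writeLines(c("Age,Shoe", "under 30 years,9"), path)
  expect_error(read_observations(path), "unknown column")
})
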