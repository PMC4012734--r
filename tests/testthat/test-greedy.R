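test_that("looDeltas isolates a single discordant outlier", {
  x <- asProfile(c(1, 2, 3, 4, 5, 10), sprintf("S%d", 1:6))
  y <- asProfile(c(1, 2, 3, 4, 5, -10), sprintf("S%d", 1:6))
  d <- looDeltas(x, y)
  expect_identical(d$sample_id, names(x))
  # every r_without reproduced by an explicit 5-point correlation
  for (i in seq_along(x)) {
    expect_equal(d$r_without[i], brutePearson(x[-i], y[-i]),
                 tolerance = 1e-12)
  }
  expect_equal(d$r_without[d$sample_id == "S6"], 1.0)
  expect_identical(d$sample_id[which.max(d$delta)], "S6")
  expect_true(all(d$delta[d$sample_id != "S6"] < max(d$delta)))
})

test_that("looDeltas on a perfectly correlated pair never shows an improvement", {
  x <- asProfile(rnorm(8))
  d <- looDeltas(x, asProfile(2 * x + 1, names(x)))
  expect_true(all(d$delta <= 1e-12))
})

test_that("looDeltas flags undefined leave-one-out correlations instead of failing", {
  # removing S4 leaves x constant -> that member's candidacy is undefined
  x <- asProfile(c(1, 1, 1, 2), sprintf("S%d", 1:4))
  y <- asProfile(c(1, 2, 3, 4), sprintf("S%d", 1:4))
  d <- suppressMessages(looDeltas(x, y))
  expect_true(is.na(d$r_without[d$sample_id == "S4"]))
  expect_false(anyNA(d$r_without[d$sample_id != "S4"]))
  expect_error(looDeltas(x[1:3], y[1:3]), "at least 4")
})

test_that("greedySplit removes the outlier then stops, and leaves perfect pairs intact", {
  x <- asProfile(c(1, 2, 3, 4, 5, 10), sprintf("S%d", 1:6))
  y <- asProfile(c(1, 2, 3, 4, 5, -10), sprintf("S%d", 1:6))
  p <- greedySplit(x, y, minCohort1 = 4)
  expect_identical(cohort2(p), "S6")
  expect_equal(correlationTrace(p)[2], 1.0)
  expect_length(correlationTrace(p), 2L)

  z <- asProfile(rnorm(10))
  p2 <- greedySplit(z, asProfile(z + 0, names(z)), minCohort1 = 4)
  expect_length(cohort2(p2), 0L)
  expect_equal(correlationTrace(p2), 1.0)
})

test_that("greedySplit matches an independent exhaustive-scan reference", {
  set.seed(21)
  for (i in 1:8) {
    n <- sample(10:24, 1)
    x <- asProfile(rnorm(n))
    y <- asProfile(rnorm(n), names(x))
    ref <- bruteGreedy(x, y, minCohort1 = 4)
    for (method in c("recompute", "downdate")) {
      p <- greedySplit(x, y, minCohort1 = 4, method = method)
      expect_identical(cohort2(p), ref$cohort2)
      expect_identical(sort(cohort1(p)), sort(ref$cohort1))
      expect_equal(correlationTrace(p), ref$trace, tolerance = 1e-10)
    }
  }
})

test_that("greedySplit is deterministic, monotone and terminates at the floor", {
  set.seed(33)
  x <- asProfile(rnorm(40))
  y <- asProfile(0.4 * x + rnorm(40), names(x))
  p1 <- greedySplit(x, y, minCohort1 = 5)
  p2 <- greedySplit(x, y, minCohort1 = 5)
  expect_identical(cohort1(p1), cohort1(p2))
  expect_identical(cohort2(p1), cohort2(p2))
  tr <- correlationTrace(p1)
  expect_true(all(diff(tr) > 0))
  expect_gte(tail(tr, 1), tr[1])
  expect_lte(length(cohort2(p1)), 40 - 5)
  expect_gte(length(cohort1(p1)), 5)
})

test_that("downdating fast path agrees with from-scratch recomputation", {
  set.seed(55)
  for (i in 1:6) {
    n <- sample(c(30, 60, 120), 1)
    rho <- runif(1, -0.5, 0.9)
    pair <- simulateCorrelatedPair(n, rho)
    x <- asProfile(pair$x)
    y <- asProfile(pair$y, names(x))
    pa <- greedySplit(x, y, minCohort1 = 5, method = "recompute")
    pb <- greedySplit(x, y, minCohort1 = 5, method = "downdate")
    expect_identical(cohort2(pa), cohort2(pb))
    expect_equal(correlationTrace(pa), correlationTrace(pb),
                 tolerance = 1e-10)
  }
})

test_that("greedySplit validates its inputs", {
  x <- asProfile(rnorm(6))
  expect_error(greedySplit(x, asProfile(rnorm(6), names(x)),
                           minCohort1 = 2), "at least 3")
  expect_error(greedySplit(x, asProfile(rnorm(6), names(x))),
               "at least max")  # default floor of 10 exceeds n = 6
  expect_error(greedySplit(asProfile(rep(1, 12)),
                           asProfile(rnorm(12), sprintf("S%03d", 1:12)),
                           minCohort1 = 4), "zero variance")
})

test_that("partition tables expose membership, removal order and the trace", {
  set.seed(60)
  x <- asProfile(rnorm(15))
  y <- asProfile(0.2 * x + rnorm(15), names(x))
  p <- greedySplit(x, y, minCohort1 = 4)
  pt <- partitionTable(p)
  expect_setequal(pt$sample_id, names(x))
  expect_identical(pt$sample_id[pt$cohort == 2L], cohort2(p))
  expect_identical(pt$removal_order[pt$cohort == 2L],
                   seq_along(cohort2(p)))
  tt <- traceTable(p)
  expect_identical(tt$step, seq_along(correlationTrace(p)) - 1L)
  expect_identical(tt$n_cohort1[1], 15L)
  expect_equal(tt$r, correlationTrace(p))
})
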