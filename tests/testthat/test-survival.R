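test_that("kmEstimate reproduces hand-computed product-limit tables", {
  # all censored: no event times, S(t) = 1 throughout
  s0 <- data.frame(sample_id = paste0("S", 1:5), time = 1:5,
                   event = rep(0L, 5))
  k0 <- kmEstimate(s0)
  expect_length(k0@time, 0L)

  # one event among five subjects: S = 1 - 1/5
  s1 <- data.frame(sample_id = paste0("S", 1:5), time = c(5, 6, 7, 8, 9),
                   event = c(1L, 0L, 0L, 0L, 0L))
  k1 <- as.data.frame(kmEstimate(s1))
  expect_equal(k1$surv, 0.8)
  expect_equal(k1$n_risk, 5L)

  # times (1+, 2, 3, 4+, 5): S = (1-1/4), (1-1/4)(1-1/3), then 0
  s2 <- data.frame(sample_id = paste0("S", 1:5),
                   time = c(1, 2, 3, 4, 5),
                   event = c(0L, 1L, 1L, 0L, 1L))
  k2 <- as.data.frame(kmEstimate(s2))
  expect_equal(k2$time, c(2, 3, 5))
  expect_equal(k2$surv, c(0.75, 0.50, 0.0))
  expect_equal(k2$n_risk, c(4L, 3L, 1L))
})

test_that("without censoring the KM curve is one minus the empirical CDF", {
  set.seed(12)
  for (i in 1:10) {
    n <- sample(5:60, 1)
    s <- randomSurvTable(n)
    km <- as.data.frame(kmEstimate(s))
    ec <- stats::ecdf(s$time)
    expect_equal(km$surv, 1 - ec(km$time), tolerance = 1e-12)
  }
})

test_that("logRank agrees with explicit O/E/V arithmetic and with survdiff", {
  a <- data.frame(sample_id = paste0("A", 1:3), time = c(3, 5, 7),
                  event = c(1L, 0L, 1L))
  b <- data.frame(sample_id = paste0("B", 1:3), time = c(2, 4, 6),
                  event = c(1L, 1L, 0L))
  lr <- logRank(a, b)
  hand <- bruteLogRank(a, b)
  expect_equal(chisqStatistic(lr), hand$stat, tolerance = 1e-12)
  expect_equal(pValue(lr), pchisq(hand$stat, 1, lower.tail = FALSE))
  # and on larger random censored tables
  set.seed(19)
  for (i in 1:5) {
    ra <- randomSurvTable(30, censorRate = log(2) / 20, prefix = "A")
    rb <- randomSurvTable(25, hazard = log(2) / 8,
                          censorRate = log(2) / 20, prefix = "B")
    expect_equal(chisqStatistic(logRank(ra, rb)), bruteLogRank(ra, rb)$stat,
                 tolerance = 1e-10)
  }
})

test_that("logRank symmetry and degenerate-case conventions hold", {
  set.seed(23)
  a <- randomSurvTable(20, censorRate = log(2) / 20, prefix = "A")
  b <- randomSurvTable(20, hazard = log(2) / 6, censorRate = log(2) / 20,
                       prefix = "B")
  expect_equal(chisqStatistic(logRank(a, b)), chisqStatistic(logRank(b, a)),
               tolerance = 1e-12)

  # a duplicate of a group compared with itself: O = E exactly, statistic 0
  b2 <- a
  b2$sample_id <- paste0("dup_", a$sample_id)
  lr <- logRank(a, b2)
  expect_identical(chisqStatistic(lr), 0)
  expect_identical(pValue(lr), 1)

  # an observation censored before the first event enters no risk set:
  # neither the statistic nor the KM values at event times move
  firstEvent <- min(c(a$time[a$event == 1L], b$time[b$event == 1L]))
  early <- data.frame(sample_id = "B999", time = firstEvent / 2, event = 0L)
  expect_equal(chisqStatistic(logRank(a, rbind(b, early))),
               chisqStatistic(logRank(a, b)), tolerance = 1e-12)
  kmB <- as.data.frame(kmEstimate(b))
  kmB2 <- as.data.frame(kmEstimate(rbind(b, early)))
  expect_equal(kmB2$surv, kmB$surv)
  expect_equal(kmB2$n_risk, kmB$n_risk)

  # no events at all is an error, not a silent NaN
  c0 <- data.frame(sample_id = "C1", time = 1, event = 0L)
  d0 <- data.frame(sample_id = "D1", time = 2, event = 0L)
  expect_error(logRank(c0, d0), "no events")
})

test_that("splitByExpression dichotomises at the requested quantile", {
  prof <- asProfile(c(10, 20, 30, 40), paste0("S", 1:4))
  s <- data.frame(sample_id = paste0("S", 1:4), time = 1:4,
                  event = rep(1L, 4))
  sp <- splitByExpression(prof, s)
  expect_setequal(sp$low$sample_id, c("S1", "S2"))
  expect_setequal(sp$high$sample_id, c("S3", "S4"))

  expect_error(splitByExpression(asProfile(rep(7, 4), paste0("S", 1:4)), s),
               "high.*group empty")

  prof8 <- asProfile(as.numeric(1:8), paste0("S", 1:8))
  s8 <- data.frame(sample_id = paste0("S", 1:8), time = 1:8,
                   event = rep(1L, 8))
  sp8 <- splitByExpression(prof8, s8, cutoff = 0.75)
  expect_equal(nrow(sp8$low), 6L)
  expect_equal(nrow(sp8$high), 2L)
})

test_that("comparePartitionSurvival restricts to cohorts and propagates errors", {
  set.seed(31)
  x <- asProfile(rnorm(20))
  y <- asProfile(0.3 * x + rnorm(20), names(x))
  p <- greedySplit(x, y, minCohort1 = 6)
  s <- randomSurvTable(20, censorRate = log(2) / 20)
  s$sample_id <- names(x)
  cmp <- comparePartitionSurvival(p, s)
  expect_s4_class(cmp$logrank, "LogRankResult")
  expect_equal(unname(cmp$n["cohort1"]), length(cohort1(p)))
  expect_equal(cmp$km$cohort1@n, length(cohort1(p)))

  # empty cohort 2 cannot be compared
  z <- asProfile(rnorm(10))
  pz <- greedySplit(z, asProfile(z, names(z)), minCohort1 = 4)
  expect_error(comparePartitionSurvival(pz, s), "empty cohort 2")
})
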