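test_that("simulateCorrelatedPair hits its population correlation", {
  p1 <- simulateCorrelatedPair(100, 1, seed = 1)
  expect_equal(p1$y, p1$x)                       # degenerate Cholesky
  p0 <- simulateCorrelatedPair(10000, 0, seed = 2)
  expect_lt(abs(cor(p0$x, p0$y)), 0.05)          # ~1/sqrt(n) bound
  p9 <- simulateCorrelatedPair(10000, 0.9, seed = 3)
  expect_lt(abs(cor(p9$x, p9$y) - 0.9), 0.05)
  expect_error(simulateCorrelatedPair(10, 1.2), "rho")
  expect_error(simulateCorrelatedPair(1, 0.5), "at least 2")
})

test_that("simConfig validates its fields before any generation", {
  expect_error(simConfig(nSamples = 2), "nSamples")
  expect_error(simConfig(fInteraction = 1.2), "fInteraction")
  expect_error(simConfig(rhoIn = -2), "correlations")
  expect_error(simConfig(noiseSigma = 0), "noiseSigma")
  expect_error(simConfig(baselineHazard = -1), "positive")
  expect_error(simConfig(hazardGroup = "sideways"))
})

test_that("simulated datasets are reproducible and structurally sound", {
  cfg <- simConfig(nSamples = 30, nBackgroundProbes = 20, seed = 9)
  d1 <- simulateDataset(cfg)
  d2 <- simulateDataset(cfg)
  expect_identical(d1$exprs, d2$exprs)
  expect_identical(d1$surv, d2$surv)
  expect_identical(d1$truth, d2$truth)
  expect_equal(dim(d1$exprs), c(22L, 30L))
  expect_identical(colnames(d1$exprs), d1$surv$sample_id)
  expect_true(all(d1$surv$time > 0))
  expect_true(all(d1$surv$event %in% c(0L, 1L)))
  # planted membership size is exactly floor(f * n)
  cfg2 <- simConfig(nSamples = 33, fInteraction = 0.4,
                    nBackgroundProbes = 5, seed = 1)
  d3 <- simulateDataset(cfg2)
  expect_equal(sum(d3$truth$group == "interaction"), floor(0.4 * 33))
})

test_that("a fully planted cohort carries the focal correlation through ranking", {
  d <- simulateDataset(simConfig(nSamples = 500, nBackgroundProbes = 300,
                                 fInteraction = 1, rhoIn = 0.9, seed = 13))
  rk <- rankTransform(d$exprs)
  r <- pearsonCor(extractProfile(rk, "TP63"), extractProfile(rk, "MMP13"))
  expect_gt(r, 0.8)
  # rank-based r sits near the generating rho (small Pearson-to-Spearman
  # attenuation for bivariate normals)
  expect_lt(abs(r - 0.89), 0.06)
})

test_that("background probes stay uncorrelated with the focal pair", {
  d <- simulateDataset(simConfig(nSamples = 200, nBackgroundProbes = 100,
                                 seed = 17))
  a <- d$exprs["TP63", ]
  bg <- d$exprs[grep("^bg_", rownames(d$exprs)), ]
  rs <- apply(bg, 1L, cor, y = a)
  expect_lt(max(abs(rs)), 0.3)
})

test_that("survival marginals match the exponential model", {
  # effectively uncensored draw: empirical median near ln(2)/hazard = 12
  d <- simulateDataset(simConfig(nSamples = 2000, nBackgroundProbes = 2,
                                 baselineHazard = log(2) / 12,
                                 censoringRate = 1e-9, seed = 21))
  expect_true(all(d$surv$event == 1L))
  expect_lt(abs(median(d$surv$time) - 12), 1.2)  # ~3 SE of the sample median
  # hazard-group flag lands on the designated samples
  dh <- simulateDataset(simConfig(nSamples = 50, nBackgroundProbes = 2,
                                  hazardRatio = 3,
                                  hazardGroup = "interaction", seed = 22))
  expect_identical(dh$truth$hazard_flag,
                   as.integer(dh$truth$group == "interaction"))
})

test_that("writeDataset emits the standard dialects and round-trips", {
  d <- simulateDataset(simConfig(nSamples = 12, nBackgroundProbes = 6,
                                 seed = 25))
  dir <- withr::local_tempdir()
  writeDataset(d, dir)
  m <- suppressMessages(readExpressionMatrix(file.path(dir, "expression.tsv")))
  expect_identical(m, d$exprs)
  s <- readSurvivalTable(file.path(dir, "survival.tsv"))
  expect_equal(s$time, d$surv$time)
  expect_identical(s$event, d$surv$event)
  cfgEcho <- jsonlite::read_json(file.path(dir, "config.json"))
  expect_equal(cfgEcho$nSamples, 12L)
  gt <- read.delim(file.path(dir, "ground_truth.tsv"))
  expect_equal(nrow(gt), 12L)
})
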