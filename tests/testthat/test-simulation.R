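test_that("AR(1) simulation reproduces the closed-form lag-1 autocorrelation", {
  A <- array(0.5, c(1, 1, 1))
  spec <- simulationSpec(d = 1, p = 1, N = 150, trials = 200,
                         schedule = list(list(from = 1L, to = 150L, A = A)),
                         sigma = diag(1), seed = 61)
  sim <- simulateTVMVAR(spec)
  v <- tsValues(sim$data)
  ac <- cor(as.vector(v[, 1, -150]), as.vector(v[, 1, -1]))
  expect_equal(ac, 0.5, tolerance = 0.02)
  # and the stationary variance 1/(1 - a^2)
  expect_equal(var(as.vector(v)), 1 / (1 - 0.25), tolerance = 0.1)
})

test_that("zero coefficients yield uncorrelated white noise", {
  A <- array(0, c(3, 3, 1))
  spec <- simulationSpec(d = 3, p = 1, N = 100, trials = 100,
                         schedule = list(list(from = 1L, to = 100L, A = A)),
                         sigma = diag(3), seed = 62)
  sim <- simulateTVMVAR(spec)
  v <- tsValues(sim$data)
  flat <- matrix(aperm(v, c(1, 3, 2)), 100 * 100, 3)
  cc <- cor(flat)
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.03)
  lag1 <- cor(as.vector(v[, 1, -100]), as.vector(v[, 1, -1]))
  expect_lt(abs(lag1), 0.03)
})

test_that("unstable coefficient schedules are rejected, naming the segment", {
  good <- array(0, c(2, 2, 1)); diag(good[, , 1]) <- 0.5
  bad <- array(0, c(2, 2, 1)); diag(bad[, , 1]) <- 1.05
  expect_error(
    simulationSpec(d = 2, p = 1, N = 50, trials = 1,
                   schedule = list(list(from = 1L, to = 20L, A = good),
                                   list(from = 21L, to = 50L, A = bad)),
                   seed = 1),
    "segment 2.*spectral radius")
  expect_gte(spectralRadius(bad), 1)
  expect_lt(spectralRadius(good), 1)
})

test_that("simulations are exactly reproducible from (spec, seed)", {
  s1 <- simulateTVMVAR(evokedSimulationSpec(trials = 4, samples = 60,
                                            onset = 25, offset = 45,
                                            seed = 63))
  s2 <- simulateTVMVAR(evokedSimulationSpec(trials = 4, samples = 60,
                                            onset = 25, offset = 45,
                                            seed = 63))
  expect_identical(tsValues(s1$data), tsValues(s2$data))
  s3 <- simulateTVMVAR(evokedSimulationSpec(trials = 4, samples = 60,
                                            onset = 25, offset = 45,
                                            seed = 64))
  expect_false(identical(tsValues(s1$data), tsValues(s3$data)))
})

test_that("ground-truth coefficients follow the schedule", {
  spec <- evokedSimulationSpec(trials = 2, samples = 100, onset = 40,
                               offset = 70, seed = 65)
  sim <- simulateTVMVAR(spec)
  expect_equal(sim$coefficients[2, 1, 1, 39], 0)
  expect_equal(sim$coefficients[2, 1, 1, 40], 0.35)
  expect_equal(sim$coefficients[2, 1, 1, 70], 0.35)
  expect_equal(sim$coefficients[2, 1, 1, 71], 0)
  expect_equal(trueEdges(spec),
               cbind(c(2, 3, 4, 5, 4), c(1, 1, 1, 2, 3)))
})

test_that("SC scenarios encode agreement and deliberate conflicts with true edges", {
  edges <- cbind(c(2, 3, 4, 5, 4), c(1, 1, 1, 2, 3))
  co <- scMatrix(scScenario(edges, "concordant", d = 5))
  expect_equal(co[edges], rep(1, 5))
  expect_equal(unname(diag(co)), rep(1, 5))
  expect_equal(sum(co), 10)  # 5 true edges + diagonal

  fn <- scMatrix(scScenario(edges, "sc_false_negative", d = 5))
  expect_equal(fn[2, 1], 0)
  expect_equal(sum(fn), 9)

  fp <- scMatrix(scScenario(edges, "sc_false_positive", d = 5,
                            edge = c(3, 2)))
  expect_equal(fp[3, 2], 1)
  expect_equal(sum(fp), 11)

  du <- scMatrix(scScenario(edges, "dense_uniform", d = 5))
  expect_true(all(du == 1))

  expect_error(scScenario(edges, "sc_false_negative", d = 5,
                          edge = c(1, 2)), "existing true edge")
  expect_error(scScenario(edges, "sc_false_positive", d = 5,
                          edge = c(2, 1)), "without true FC")
  expect_error(scScenario(cbind(2, 2), "concordant", d = 5), "off-diagonal")
})

test_that("noise mixing is convex, seeded, and anchored at r = 0", {
  y <- randomTimeSeries(3, 4, 50, seed = 66)
  expect_identical(mixNoise(y, 0), y)           # bitwise at zero ratio
  a <- mixNoise(y, 0.3, seed = 5)
  b <- mixNoise(y, 0.3, seed = 5)
  expect_identical(tsValues(a), tsValues(b))
  c2 <- mixNoise(y, 0.3, seed = 6)
  expect_false(identical(tsValues(a), tsValues(c2)))
  # additive independent noise: variance exceeds the attenuated signal part
  h <- mixNoise(y, 0.5, seed = 7)
  expect_gt(var(as.vector(tsValues(h))), 0.25 * var(as.vector(tsValues(y))))
  # noise amplitude contract: sd of the pure-noise part equals the 95th
  # percentile of |data|
  eta <- (tsValues(mixNoise(y, 0.5, seed = 8)) - 0.5 * tsValues(y)) / 0.5
  expect_equal(sd(as.vector(eta)),
               quantile(abs(tsValues(y)), 0.95, names = FALSE),
               tolerance = 0.05)
  expect_error(mixNoise(y, 1), "ratio")
})

test_that("STOK identifies the simulated driver at post-onset latencies", {
  hits <- 0L
  for (run in 1:30) {
    fx <- evokedFixture(seed = 700 + run, trials = 25, samples = 120)
    m <- stokFit(fx$data, order = 2)
    sl <- mdiValues(mdi(m))[, , round(120 * 0.6)]
    scores <- vapply(1:5, function(n) driverScore(sl, n), numeric(1))
    if (which.max(scores) == 1L) hits <- hits + 1L
  }
  expect_gte(hits, 27L)
})

test_that("noise benchmark: zero ratio gives consistency 1 and leaves the input unchanged", {
  fx <- evokedFixture(seed = 67, trials = 20, samples = 100)
  pr <- scScenario(fx$edges, "concordant", d = 5)
  snapshot <- tsValues(fx$data)
  br <- runNoiseBenchmark(fx$data, pr, ratios = 0, iters = 1,
                          peakT = 60, driver = 1, seed = 9)
  res <- benchmarkResults(br)
  expect_equal(res$consistency[res$ratio == 0], c(1, 1))
  expect_identical(tsValues(fx$data), snapshot)   # pure-function contract
})

test_that("noise benchmark degrades gracefully and reports both filters", {
  fx <- evokedFixture(seed = 68, trials = 20, samples = 100)
  pr <- scScenario(fx$edges, "concordant", d = 5)
  br <- runNoiseBenchmark(fx$data, pr, ratios = c(0, 0.25, 0.5), iters = 5,
                          peakT = 60, driver = 1, seed = 10)
  res <- benchmarkResults(br)
  expect_setequal(unique(res$filter), c("stok", "si_stok"))
  expect_equal(sum(res$ratio > 0), 2 * 2 * 5)
  expect_true(all(res$consistency >= 0 & res$consistency <= 1))
  med <- aggregate(consistency ~ filter + ratio, res, median)
  for (f in c("stok", "si_stok")) {
    m <- med$consistency[med$filter == f][order(med$ratio[med$filter == f])]
    # non-increasing across the grid, allowing one inversion
    expect_lte(sum(diff(m) > 1e-12), 1)
  }
  # reproducibility of the full harness
  br2 <- runNoiseBenchmark(fx$data, pr, ratios = c(0, 0.25, 0.5), iters = 5,
                           peakT = 60, driver = 1, seed = 10)
  expect_identical(benchmarkResults(br2), res)
})
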