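test_that("rest state is a fixed point and decay is monotone", {
  net <- singlePop()
  for (k in 1:50) stepNetwork(net, dt = 1)
  expect_equal(unname(activities(net)[["p"]]), 0)

  # start above baseline with no input: non-increasing towards baseline
  for (b in c(0, 0.2)) {
    net <- singlePop(baseline = b, activity = 0.9)
    tr <- runNetwork(net, duration = 300)
    a <- tr@activity[, "p"]
    expect_true(all(diff(a) <= 1e-12))
    expect_equal(a[length(a)], b, tolerance = 1e-3)
  }
})

test_that("constant-input equilibrium matches the bisection oracle", {
  for (inp in c(0.4, 0.8, 1.5)) {
    for (w in c(0, 1)) {
      net <- singlePop(selfWeight = w)
      for (k in 1:4000) stepNetwork(net, c(p = inp), dt = 0.5)
      expect_equal(unname(activities(net)[["p"]]),
                   bisectFixedPoint(inp, selfWeight = w),
                   tolerance = 1e-6)
    }
  }
})

test_that("activities stay in [0, 1] under extreme stimulation", {
  net <- RateNetwork()
  addPopulation(net, "a", selfWeight = 2)
  addPopulation(net, "b")
  addLink(net, "a", "b", 5)
  addLink(net, "b", "a", -5)
  sch <- data.frame(id = c("a", "b", "a"), onset = c(0, 100, 400),
                    offset = c(300, 500, 600), amplitude = c(10, 10, 0.2))
  tr <- runNetwork(net, sch, duration = 700)
  expect_true(all(tr@activity >= 0 & tr@activity <= 1))
})

test_that("the WM parameter set is bistable and persists after a pulse", {
  # low fixed point: stays at rest without input
  net <- singlePop(selfWeight = 2)
  tr <- runNetwork(net, duration = 500)
  expect_lt(max(tr@activity), 1e-6)

  # high fixed point: a 100 ms suprathreshold pulse leaves reverberating
  # activity that holds >= 50% of its pulse-offset level 1000 ms later
  net <- singlePop(selfWeight = 2)
  tr <- runNetwork(net, data.frame(id = "p", onset = 0, offset = 100,
                                   amplitude = 1), duration = 1100)
  a <- tr@activity[, "p"]
  atOffset <- a[101]
  expect_gt(atOffset, 0.3)
  expect_gt(a[length(a)], 0.5 * atOffset)
})

test_that("step halving leaves traces unchanged within tolerance", {
  # simple excitatory chain: halving dt moves the trace by < 1e-3
  chain <- function() {
    net <- RateNetwork()
    addPopulation(net, "a"); addPopulation(net, "b")
    addLink(net, "a", "b", 2)
    net
  }
  sch <- data.frame(id = "a", onset = 20, offset = 120, amplitude = 1)
  tr1 <- runNetwork(chain(), sch, duration = 300, dt = 0.1)
  tr2 <- runNetwork(chain(), sch, duration = 300, dt = 0.05)
  common <- round(tr2@time, 6) %in% round(tr1@time, 6)
  expect_lt(max(abs(tr2@activity[common, ] - tr1@activity)), 1e-3)

  # recurrent bistable circuit: error is larger but halves with dt
  # (first-order convergence of the explicit scheme)
  build <- function() {
    net <- RateNetwork()
    addPopulation(net, "a"); addPopulation(net, "b", selfWeight = 2)
    addPopulation(net, "c", bias = 1)
    addLink(net, "a", "b", 1.5); addLink(net, "c", "b", -2)
    addLink(net, "b", "c", 0.5)
    net
  }
  sch <- data.frame(id = "a", onset = c(20, 200), offset = c(120, 260),
                    amplitude = c(1, 0.6))
  trA <- runNetwork(build(), sch, duration = 400, dt = 1)
  trB <- runNetwork(build(), sch, duration = 400, dt = 0.5)
  trC <- runNetwork(build(), sch, duration = 400, dt = 0.25)
  eAB <- max(abs(trB@activity[trB@time %in% trA@time, ] - trA@activity))
  eBC <- max(abs(trC@activity[trC@time %in% trB@time, ] - trB@activity))
  expect_lt(eAB, 0.01)
  expect_lt(eBC, 0.75 * eAB)
})

test_that("causal propagation: downstream peak lags upstream peak", {
  net <- RateNetwork()
  addPopulation(net, "a"); addPopulation(net, "b")
  addLink(net, "a", "b", 2)
  tr <- runNetwork(net, data.frame(id = "a", onset = 10, offset = 60,
                                   amplitude = 1), duration = 200)
  expect_gt(which.max(tr@activity[, "b"]), which.max(tr@activity[, "a"]))
})

test_that("total activity sums populations and runs handle empty networks", {
  net <- RateNetwork()
  addPopulation(net, "a", baseline = 0.2, activity = 0.2)
  addPopulation(net, "b", baseline = 0.3, activity = 0.3)
  tr <- runNetwork(net, duration = 50)
  expect_equal(totalActivity(tr), rowSums(tr@activity))
  expect_equal(unname(totalActivity(tr)[1]), 0.5, tolerance = 1e-9)

  # one-population trace: total is that series
  net <- singlePop(activity = 0.4)
  tr <- runNetwork(net, duration = 30)
  expect_equal(totalActivity(tr), unname(tr@activity[, 1]))

  # empty network: empty trace with a correct time grid
  tr <- runNetwork(RateNetwork(), duration = 25, dt = 5)
  expect_equal(tr@time, seq(0, 25, by = 5))
  expect_equal(ncol(tr@activity), 0L)
  expect_error(totalActivity(tr), "empty")
})

test_that("argument and wiring errors are raised", {
  net <- singlePop()
  expect_error(stepNetwork(net, dt = 0), "dt")
  expect_error(stepNetwork(net, c(nosuch = 1)), "unknown population")
  expect_error(addLink(net, "p", "nosuch", 1), "unknown population")
  expect_error(addLink(net, "p", "p", Inf), "finite")
  expect_error(addPopulation(net, "p"), "duplicate")
  sch <- data.frame(id = "p", onset = 10, offset = 5, amplitude = 1)
  expect_error(validateSchedule(sch), "onsets")
  sch <- data.frame(id = "p", onset = 0, offset = 5, amplitude = -1)
  expect_error(validateSchedule(sch), ">= 0")
  sch <- data.frame(id = "q", onset = 0, offset = 5, amplitude = 1)
  expect_error(runNetwork(net, sch, duration = 10), "unknown population")
})

test_that("gated links deliver input only while their gate is active", {
  net <- RateNetwork()
  addPopulation(net, "src"); addPopulation(net, "tgt"); addPopulation(net, "g")
  addLink(net, "src", "tgt", 2, gate = "g")
  tr <- runNetwork(net, data.frame(id = c("src", "g"),
                                   onset = c(0, 300), offset = c(600, 600),
                                   amplitude = 1), duration = 600)
  expect_lt(max(tr@activity[1:300, "tgt"]), 1e-9)
  expect_gt(max(tr@activity[, "tgt"]), 0.2)
})

test_that("network JSON round-trips and traces serialize as CSV", {
  net <- RateNetwork()
  addPopulation(net, "a", tau = 12, selfWeight = 2)
  addPopulation(net, "b", bias = 1)
  addLink(net, "a", "b", -1.5)
  js <- networkToJSON(net)
  net2 <- networkFromJSON(js)
  expect_equal(populationIds(net2), populationIds(net))
  tr1 <- runNetwork(net, data.frame(id = "a", onset = 0, offset = 50,
                                    amplitude = 1), duration = 100)
  tr2 <- runNetwork(net2, data.frame(id = "a", onset = 0, offset = 50,
                                     amplitude = 1), duration = 100)
  expect_equal(tr1@activity, tr2@activity)

  path <- tempfile(fileext = ".csv")
  writeTrace(tr1, path)
  df <- read.csv(path)
  expect_named(df, c("time_ms", "population_id", "activity"))
  expect_equal(nrow(df), length(tr1@time) * 2)
})
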