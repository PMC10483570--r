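test_that("subthreshold constant drive yields a spike-free decaying trace", {
  m <- makeModel("LIF", regime = "benchmark")
  p <- StimulusProtocol("constant", amplitude = 0,
                        grid = SimulationGrid(m@dt, 300L))
  rec <- runTrace(m, p)
  expect_length(spikeSteps(rec), 0L)
  v <- membraneTrace(rec)
  expect_true(all(diff(abs(v)) <= 0))          # monotone decay toward 0
  expect_lt(abs(v[300]), abs(m@vInit))
})

test_that("a pulse that ends before threshold leaves no spikes and the trace relaxes", {
  m <- makeModel("LIF", regime = "benchmark")
  grid <- SimulationGrid(m@dt, 400L)
  ## amplitude 0.5 can never reach vTh = 1 (steady state = 0.5)
  p <- StimulusProtocol("pulse", amplitude = 0.5, grid = grid,
                        onsetStep = 50L, offsetStep = 200L)
  rec <- runTrace(m, p)
  expect_length(spikeSteps(rec), 0L)
  v <- membraneTrace(rec)
  expect_gt(v[200], v[50])                      # charged during the pulse
  expect_lt(v[400], v[200])                     # relaxes after offset
})

test_that("LIF interspike interval converges to the analytic value", {
  ## constant suprathreshold drive: ISI = tau log(I / (I - vTh))
  tau <- 4; I <- 2
  isiTrue <- tau * log(I / (I - 1))             # 4 log 2 ~ 2.7726
  for (dt in c(0.04, 0.004)) {
    m <- makeModel("LIF", regime = "benchmark", overrides = list(dt = dt))
    p <- StimulusProtocol("constant", amplitude = I,
                          grid = SimulationGrid(dt, as.integer(20 / dt)))
    gaps <- diff(spikeSteps(runTrace(m, p))) * dt
    expect_gt(length(gaps), 2)
    expect_lt(max(abs(gaps - isiTrue)), 2 * dt)
  }
})

test_that("spike counts grow monotonically with drive for LIF and quadratic QIF", {
  for (nm in c("LIF", "QIF")) {
    m <- makeModel(nm, regime = "benchmark")
    counts <- simulateSamples(m, seq(0, 6, by = 0.5))
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("per-sample drive respects the published benchmark dynamics", {
  lif <- makeModel("LIF", regime = "benchmark")
  expect_identical(simulateSamples(lif, 0), 0L)          # cannot reach vTh
  expect_gte(simulateSamples(lif, 5), 1L)                # steady state 5 >> 1

  izh <- makeModel("Izhikevich", regime = "benchmark")
  expect_gte(simulateSamples(izh, 0), 1L)                # +140 forces firing
})

test_that("state is re-initialised per sample (no carry-over) and runs are reproducible", {
  m <- makeModel("IFSFA", regime = "benchmark")
  a <- simulateSamples(m, c(3, 3, 3))
  expect_identical(a[1], a[2])
  expect_identical(a[2], a[3])
  b <- simulateSamples(m, c(3, 3, 3))
  expect_identical(a, b)
})

test_that("trace runs demand a matching grid and record reproducible metadata", {
  m <- makeModel("LIF", regime = "benchmark")
  badGrid <- SimulationGrid(0.5, 10L)
  p <- StimulusProtocol("constant", amplitude = 1, grid = badGrid)
  expect_error(runTrace(m, p), "dt")

  rec <- pulseResponse("LIF", regime = "trace", nSteps = 200L)
  expect_identical(rec@params$model, "LIF")
  expect_identical(rec@params$variant, "B")
  expect_identical(rec@params$onsetStep, 20L)
  expect_identical(rec@params$offsetStep, 120L)
})

test_that("refractory models keep consecutive spikes at least the period apart", {
  mb <- makeModel("QIF", regime = "trace")      # tauRef 2, dt 0.1 -> 20 steps
  p <- StimulusProtocol("constant", amplitude = 20,
                        grid = SimulationGrid(mb@dt, 500L))
  gaps <- diff(spikeSteps(runTrace(mb, p)))
  expect_gt(length(gaps), 3)
  expect_true(all(gaps >= 20L))

  mi <- makeModel("Izhikevich", regime = "trace")  # 100-step refractory
  p <- StimulusProtocol("constant", amplitude = 20,
                        grid = SimulationGrid(mi@dt, 2000L))
  gaps <- diff(spikeSteps(runTrace(mi, p)))
  expect_gt(length(gaps), 1)
  expect_true(all(gaps >= 100L))
})

test_that("every model produces a finite pulse-response trace in its trace regime", {
  for (nm in modelNames()) {
    rec <- pulseResponse(nm, regime = "trace", nSteps = 500L)
    expect_true(all(is.finite(membraneTrace(rec))))
  }
})

test_that("spike records serialise to CSV with the documented columns", {
  rec <- pulseResponse("NLIF", regime = "trace", nSteps = 100L)
  f <- file.path(tempdir(), "rec.csv")
  writeSpikeRecord(rec, f)
  df <- read.csv(f)
  expect_identical(names(df), c("step", "time", "V", "spiked", "amplitude"))
  expect_identical(nrow(df), 100L)
  expect_identical(which(df$spiked == 1L), as.integer(spikeSteps(rec)))
  ## the NLIF spike amplitude tag is 0.7 and is display-only
  if (length(spikeSteps(rec)))
    expect_true(all(df$amplitude[df$spiked == 1L] == 0.7))
  meta <- jsonlite::read_json(paste0(f, ".json"))
  expect_identical(meta$params$model, "NLIF")
  unlink(c(f, paste0(f, ".json")))
})
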