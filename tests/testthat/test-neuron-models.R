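## Step-kernel unit tests: frozen single-step arithmetic values, reset
## rules, and the shared invariants (fixed points, gating bounds,
## determinism, oracle agreement).

test_that("LIF single-step arithmetic and threshold/reset behave as derived", {
  m <- makeModel("LIF", regime = "benchmark")  # tau 4, vTh 1, vReset 0
  r <- stepNeuron(m, list(V = 0), 0)
  expect_identical(r$state$V, 0)               # rest is a fixed point
  expect_false(r$spiked)

  r <- stepNeuron(m, list(V = 0.5), 0)
  expect_equal(r$state$V, 0.4875, tolerance = 1e-12)
  expect_false(r$spiked)

  ## candidate 0.99 + (10 - 0.99)/4 * 0.1 = 1.21525 >= 1 -> spike, reset
  r <- stepNeuron(m, list(V = 0.99), 10)
  expect_true(r$spiked)
  expect_identical(r$state$V, 0)
})

test_that("NLIF applies the post-integration spike map and beta leak", {
  m <- makeModel("NLIF", regime = "benchmark") # alpha 0.5, beta 0.5
  ## drive the integrated candidate to exactly 2.0: V + (-V + I)/40 = 2
  V0 <- 1.9
  I <- (2 - V0) * 40 + V0
  r <- stepNeuron(m, list(V = V0), I)
  expect_true(r$spiked)
  expect_equal(r$state$V, 0 + 0.5 * (2 - 1), tolerance = 1e-12)  # 0.5

  ## subthreshold: candidate 0.5 -> halved by beta
  V0 <- 0.4
  I <- (0.5 - V0) * 40 + V0
  r <- stepNeuron(m, list(V = V0), I)
  expect_false(r$spiked)
  expect_equal(r$state$V, 0.25, tolerance = 1e-12)

  r <- stepNeuron(m, list(V = 0), 0)
  expect_identical(r$state$V, 0)               # zero fixed point
})

test_that("AdEx drift at the boundary matches the derived value and large drive spikes", {
  m <- makeModel("AdEx", regime = "benchmark")
  ## V = vSpike = 1: dV/dt = (-1 + 0 - 0.5 + 1)/4 = -0.125 (post-update check)
  r <- stepNeuron(m, list(V = 1), 0)
  expect_false(r$spiked)
  expect_equal(r$state$V, 0.9875, tolerance = 1e-12)

  ## subthreshold downward drift is permitted
  r <- stepNeuron(m, list(V = 0), 0)
  expect_lt(r$state$V, 0)
  expect_false(r$spiked)

  ## strong drive spikes within finitely many steps
  st <- initState(m, 1L)
  spiked <- FALSE
  for (i in 1:200) {
    res <- stepNeuron(m, st, 10)
    st <- res$state
    if (res$spiked) { spiked <- TRUE; break }
  }
  expect_true(spiked)

  ## an overflowing exponential is itself the spike
  r <- stepNeuron(m, list(V = 800), 0)
  expect_true(r$spiked)
  expect_identical(r$state$V, m@vReset)
})

test_that("IF-SFA adaptation increments after spikes and holds its joint fixed point", {
  m <- makeModel("IFSFA", regime = "benchmark") # vRest 0, b 0.01
  r <- stepNeuron(m, list(V = 0, w = 0), 0)     # V = vRest, w = 0, I = 0
  expect_identical(r$state$V, 0)
  expect_identical(r$state$w, 0)
  expect_false(r$spiked)

  ## force a spike; w gains b on top of its decayed value
  st <- list(V = 0.999, w = 0.2)
  r <- stepNeuron(m, st, 50)
  expect_true(r$spiked)
  wDecay <- 0.2 + (0.1 * (0.999 - 0) - 0.2) / 100 * 0.1
  expect_equal(r$state$w, wDecay + 0.01, tolerance = 1e-12)
  expect_identical(r$state$V, 0)               # reset to vRest

  ## variant B floor: V may never fall below vR
  mb <- makeModel("IFSFA", regime = "trace")
  r <- stepNeuron(mb, list(V = -59.9, w = 4000), 0)  # huge w drives V down
  expect_gte(r$state$V, mb@vR)
})

test_that("theta neuron: variant-B fixed point at -58 and variant-A sinusoid phase", {
  mb <- makeModel("ThetaNeuron", regime = "trace")  # vR -70, g 1.5, theta -50
  Vstar <- (mb@vR + mb@g * mb@theta) / (1 + mb@g)
  expect_equal(Vstar, -58)
  r <- stepNeuron(mb, list(V = Vstar), 0)
  expect_equal(r$state$V, Vstar, tolerance = 1e-12)
  ## long stepping converges to the same point
  st <- initState(mb, 1L)
  for (i in 1:5000) st <- stepNeuron(mb, st, 0)$state
  expect_equal(st$V, Vstar, tolerance = 1e-6)

  ## variant A with phase pi/2 at t = 0 contributes exactly iThetaMax
  ma <- makeModel("ThetaNeuron", regime = "benchmark",
                  overrides = list(iThetaMax = 2, fTheta = 1, phi = pi / 2))
  r <- stepNeuron(ma, list(V = 0), 0, tstep = 0L)
  expect_equal(r$state$V, 2 / 4 * 0.1, tolerance = 1e-12)

  ## benchmark default degenerates to an LIF at rest
  m0 <- makeModel("ThetaNeuron", regime = "benchmark")
  expect_identical(stepNeuron(m0, list(V = 0), 0)$state$V, 0)
})

test_that("HH gating stays in [0, 1] and rest is quiescent within 1 mV", {
  m <- makeModel("HH", regime = "benchmark",
                 overrides = list(vDetect = 0))  # physiological detection
  st <- initState(m, 1L)
  set.seed(42)
  for (i in 1:500) {
    st <- stepNeuron(m, st, runif(1, -10, 10))$state
    expect_true(all(c(st$n, st$m, st$h) >= 0 & c(st$n, st$m, st$h) <= 1))
  }

  ## resting equilibrium: the tabulated initials are the fixed point
  st <- initState(m, 1L)
  spikes <- 0L
  for (i in 1:1000) {
    res <- stepNeuron(m, st, 0)
    st <- res$state
    spikes <- spikes + res$spiked
  }
  expect_lt(abs(st$V - (-65)), 1)
  expect_identical(spikes, 0L)

  ## all conductances zero and I = 0: dV/dt = 0 exactly
  m0 <- makeModel("HH", regime = "benchmark",
                  overrides = list(gNa = 0, gK = 0, gL = 0, vDetect = 0))
  r <- stepNeuron(m0, list(V = -65, n = 0.3, m = 0.1, h = 0.6), 0)
  expect_identical(r$state$V, -65)
})

test_that("QIF variants: quadratic drift value, refractory hold, origin fixed point", {
  mc <- makeModel("QIF", regime = "benchmark")  # variant C, tau 4, beta 0.5
  expect_identical(mc@variant, "C")
  expect_identical(stepNeuron(mc, list(V = 0), 0)$state$V, 0)
  r <- stepNeuron(mc, list(V = 1), 0)
  expect_equal(r$state$V, 0.9875, tolerance = 1e-12)  # (-1+0.5)/4*0.1

  ## variant B: spike starts a 20-step hold at the reset potential
  mb <- makeModel("QIF", regime = "trace")      # tauRef 2, dt 0.1
  st <- initState(mb, 1L)
  res <- stepNeuron(mb, list(V = 0.99, ref = 0L), 20)  # force a spike
  expect_true(res$spiked)
  st <- res$state
  expect_identical(st$ref, 20L)
  for (i in 1:20) {
    res <- stepNeuron(mb, st, 20)
    st <- res$state
    expect_false(res$spiked)
    if (i < 20) expect_identical(st$V, mb@vReset)
  }
})

test_that("Izhikevich constant-140 term dominates near v = 0 and resets per the after-spike rule", {
  m <- makeModel("Izhikevich", regime = "benchmark") # vPeak 0.8, c 0.1, d 0.06
  r <- stepNeuron(m, list(V = 0, u = 0), 0)
  ## candidate v' = 14.0 >= 0.8 -> spike, v <- c, u <- 0 + d
  expect_true(r$spiked)
  expect_identical(r$state$V, 0.1)
  expect_equal(r$state$u, 0.06, tolerance = 1e-12)

  ## du = a (b v - u) dt = 0 at v = 0, u = 0 without a spike
  m2 <- makeModel("Izhikevich", regime = "benchmark",
                  overrides = list(vPeak = 100))
  r <- stepNeuron(m2, list(V = 0, u = 0), 0)
  expect_equal(r$state$u, 0)
  expect_equal(r$state$V, 14, tolerance = 1e-12)
})

test_that("SRM synaptic decay and post-spike increments follow the printed updates", {
  m <- makeModel("SRM", regime = "benchmark")  # tauS = tauR = 10
  r <- stepNeuron(m, list(V = 0, s = 1, r = 0), 0)
  expect_equal(r$state$s, 0.99, tolerance = 1e-12)

  ## zero state with zero input is a fixed point
  r <- stepNeuron(m, list(V = 0, s = 0, r = 0), 0)
  expect_identical(r$state$V, 0)
  expect_identical(r$state$s, 0)
  expect_identical(r$state$r, 0)
  expect_false(r$spiked)

  ## on a spike both synaptic variables gain 1 and V resets
  ## (note the negated drive: a negative current depolarises)
  st <- list(V = 0.999, s = 0.5, r = 0.5)
  r <- stepNeuron(m, st, -100)
  expect_true(r$spiked)
  expect_identical(r$state$V, m@vReset)
  expect_gt(r$state$s, 1.4)
  expect_gt(r$state$r, 1.4)
})

test_that("non-finite membrane potential or input is rejected with an overflow signal", {
  m <- makeModel("LIF", regime = "benchmark")
  expect_error(stepNeuron(m, list(V = NaN), 0), "overflow")
  expect_error(stepNeuron(m, list(V = 0), NA_real_), "overflow")
})

test_that("exact-zero rest states are preserved over 10,000 steps", {
  for (nm in c("LIF", "NLIF", "QIF", "ThetaNeuron", "SRM", "IFSFA")) {
    m <- makeModel(nm, regime = "benchmark")
    st <- initState(m, 1L)
    st$V <- 0
    for (i in 1:10000) st <- stepNeuron(m, st, 0, tstep = i - 1L)$state
    expect_identical(st$V, 0)
  }
})

test_that("every step kernel matches its independent scalar oracle to 1e-12", {
  set.seed(2024)
  rng <- function(a, b) runif(1, a, b)
  for (m in oracleModelSet()) {
    worst <- 0
    for (k in 1:100) {
      st <- randomState(m, rng)
      I <- rng(-3, 6)
      d <- oracleDiscrepancy(m, st, I)
      worst <- max(worst, d$maxAbsDiff)
      expect_true(d$spikeAgree)
    }
    expect_lt(worst, 1e-12)
  }
})

test_that("identical inputs produce bit-identical spike records", {
  for (nm in c("LIF", "HH", "Izhikevich")) {
    r1 <- pulseResponse(nm, regime = "trace", nSteps = 300L)
    r2 <- pulseResponse(nm, regime = "trace", nSteps = 300L)
    expect_identical(membraneTrace(r1), membraneTrace(r2))
    expect_identical(spikeSteps(r1), spikeSteps(r2))
  }
})
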