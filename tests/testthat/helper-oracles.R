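## Independent straight-line scalar re-implementations of every step
## kernel, written directly from the update equations and kept free of any
## package code. They exist solely to cross-check stepNeuron(): same
## parameters, independent arithmetic.

oracleLIF <- function(m, V, I, dt) {
  drive <- if (m@variant == "B") m@rM * I / m@gLeak else I
  Vc <- V + (-V + drive) / m@tau * dt
  if (Vc >= m@vTh) list(V = m@vReset, spiked = TRUE)
  else list(V = Vc, spiked = FALSE)
}

oracleNLIF <- function(m, V, I, dt) {
  if (m@variant == "B") {
    Vc <- V + (-V + m@rM * I / m@gLeak + V * V) / m@tau * dt
    if (Vc >= m@vTh) list(V = m@vReset, spiked = TRUE)
    else list(V = Vc, spiked = FALSE)
  } else {
    Vc <- V + (-V + I) / m@tau * dt
    if (Vc >= m@vTh)
      list(V = m@vReset + m@alpha * (Vc - m@vTh), spiked = TRUE)
    else list(V = Vc * m@beta, spiked = FALSE)
  }
}

oracleAdEx <- function(m, V, w, I, dt) {
  if (m@variant == "B") {
    Vc <- V + (-V + m@rM * I / m@gLeak +
               w * exp((V - m@vTh) / m@tauM)) / m@tauM * dt
    wc <- w + (m@a * (V - m@vReset) - w) / m@tauW * dt
    if (!is.finite(Vc) || Vc >= m@vTh)
      list(V = m@vReset, w = wc + m@b, spiked = TRUE)
    else list(V = Vc, w = wc, spiked = FALSE)
  } else {
    Vc <- V + (-V + m@tauM * I - m@vRheo +
               m@deltaT * exp((V - m@vSpike) / m@deltaT)) / m@tauM * dt
    if (!is.finite(Vc) || Vc >= m@vSpike)
      list(V = m@vReset, spiked = TRUE)
    else list(V = Vc, spiked = FALSE)
  }
}

oracleIFSFA <- function(m, V, w, I, dt) {
  if (m@variant == "B") {
    Vc <- V + m@rM * (0.04 * V * V + 140 - w + I) / m@cM * dt
    wc <- w + m@aAdapt * (m@K * (V - m@vR) - w) * dt
    spiked <- !is.finite(Vc) || Vc >= m@vPeak
    if (spiked) { Vc <- m@cReset; wc <- wc + m@dJump }
    if (Vc < m@vR) Vc <- m@vR
    list(V = Vc, w = wc, spiked = spiked)
  } else {
    wc <- w + (m@A * (V - m@vRest) - w) / m@tauW * dt
    Vc <- V + (-V + I - wc) / m@tauM * dt
    if (Vc >= m@vTh) list(V = m@vRest, w = wc + m@b, spiked = TRUE)
    else list(V = Vc, w = wc, spiked = FALSE)
  }
}

oracleTheta <- function(m, V, I, dt, tstep) {
  if (m@variant == "B") {
    Vc <- V + (-(V - m@vR) + m@g * (m@theta - V) + I) / m@tau * dt
    if (Vc >= m@theta) list(V = m@vReset, spiked = TRUE)
    else list(V = Vc, spiked = FALSE)
  } else {
    iT <- m@iThetaMax * sin(2 * pi * m@fTheta * (tstep * dt) + m@phi)
    Vc <- V + (-V + I + iT) / m@tau * dt
    if (Vc >= m@vTh) list(V = m@vReset, spiked = TRUE)
    else list(V = Vc, spiked = FALSE)
  }
}

oracleHH <- function(m, V, n, mm, h, I, dt) {
  an <- if (abs(V + 55) < 1e-7) 0.1 else
    0.01 * (V + 55) / (1 - exp(-(V + 55) / 10))
  bn <- 0.125 * exp(-(V + 65) / 80)
  am <- if (abs(V + 40) < 1e-7) 1 else
    0.1 * (V + 40) / (1 - exp(-(V + 40) / 10))
  bm <- 4 * exp(-(V + 65) / 18)
  ah <- 0.07 * exp(-(V + 65) / 20)
  bh <- 1 / (1 + exp(-(V + 35) / 10))
  nc <- min(1, max(0, n + (an * (1 - n) - bn * n) * dt))
  mc <- min(1, max(0, mm + (am * (1 - mm) - bm * mm) * dt))
  hc <- min(1, max(0, h + (ah * (1 - h) - bh * h) * dt))
  iNa <- m@gNa * mc^3 * hc * (V - m@eNa)
  iK <- m@gK * nc^4 * (V - m@eK)
  iL <- m@gL * (V - m@eL)
  Vc <- V + (I - iNa - iK - iL) / m@cM * dt
  spiked <- !is.finite(Vc) || Vc >= m@vDetect
  if (spiked) Vc <- m@vReset
  list(V = Vc, n = nc, m = mc, h = hc, spiked = spiked)
}

oracleQIF <- function(m, V, ref, I, dt) {
  if (m@variant == "B") {
    inRef <- ref > 0L
    if (inRef) ref <- ref - 1L
    Vc <- V + (-V + m@cM * I) / m@tauRef * dt
    if (inRef) Vc <- m@vReset
    spiked <- !inRef && Vc >= m@vTh
    if (spiked) { Vc <- m@vReset; ref <- as.integer(round(m@tauRef / dt)) }
    list(V = Vc, ref = ref, spiked = spiked)
  } else if (m@variant == "A") {
    Vc <- V + dt / m@C * (m@gSyn * (m@vSyn - V) + I)
    if (Vc >= m@vTh) list(V = m@vReset, spiked = TRUE)
    else list(V = Vc, spiked = FALSE)
  } else {
    Vc <- V + (-V + m@beta * V * V + I) / m@tau * dt
    spiked <- !is.finite(Vc) || Vc >= m@vTh
    if (spiked) Vc <- m@vReset
    list(V = Vc, spiked = spiked)
  }
}

oracleIzh <- function(m, v, u, ref, I, dt) {
  if (m@variant == "B") {
    inRef <- ref > 0L
    if (inRef) ref <- ref - 1L
    vc <- v + m@rM * (0.04 * v * v + 5 * v + 140 - u + I) / m@tau * dt
    uc <- u + m@a * (m@b * v - u) * dt
    if (inRef) vc <- m@c
    spiked <- !inRef && vc >= m@vPeak
    if (spiked) { vc <- m@c; uc <- uc + m@d; ref <- m@refracSteps }
    list(V = vc, u = uc, ref = ref, spiked = spiked)
  } else {
    vc <- v + (0.04 * v * v + 5 * v + 140 - u + I) * dt
    uc <- u + m@a * (m@b * v - u) * dt
    spiked <- !is.finite(vc) || vc >= m@vPeak
    if (spiked) { vc <- m@c; uc <- uc + m@d }
    list(V = vc, u = uc, spiked = spiked)
  }
}

oracleSRM <- function(m, V, s, r, lastSpike, I, dt, tstep) {
  if (m@variant == "B") {
    sc <- s + (-s + m@A * lastSpike) / m@tauS * dt
    Vc <- V + (-(V - m@vR) + m@g * (m@theta - V) +
               sc * m@A * (m@eS - V) + I) / (m@tau * m@cM) * dt
    period <- max(1L, as.integer(round(m@tauRef / dt)))
    if (tstep %% period == 0L) Vc <- Vc + m@gL * (m@v0 - Vc) * dt
    spiked <- Vc >= m@theta
    if (spiked) Vc <- m@vReset
    list(V = Vc, s = sc, lastSpike = as.numeric(spiked), spiked = spiked)
  } else {
    sc <- s + (-s / m@tauS + r) * dt
    rc <- r + (-r / m@tauR) * dt
    Vc <- V + (-V - I + 0) / m@tauS * dt
    spiked <- Vc >= m@theta
    if (spiked) { Vc <- m@vReset; sc <- sc + 1; rc <- rc + 1 }
    list(V = Vc, s = sc, r = rc, spiked = spiked)
  }
}

## Step the package kernel and the oracle from the same random scalar state
## and return the maximum absolute discrepancy across state fields plus
## spike-flag agreement.
oracleDiscrepancy <- function(m, st, I, dt = m@dt, tstep = 0L) {
  res <- stepNeuron(m, st, I, dt, tstep)
  orc <- switch(class(m),
    LIFModel = oracleLIF(m, st$V, I, dt),
    NLIFModel = oracleNLIF(m, st$V, I, dt),
    AdExModel = oracleAdEx(m, st$V, if (is.null(st$w)) 0 else st$w, I, dt),
    IFSFAModel = oracleIFSFA(m, st$V, st$w, I, dt),
    ThetaModel = oracleTheta(m, st$V, I, dt, tstep),
    HHModel = oracleHH(m, st$V, st$n, st$m, st$h, I, dt),
    QIFModel = oracleQIF(m, st$V, if (is.null(st$ref)) 0L else st$ref, I, dt),
    IzhModel = oracleIzh(m, st$V, st$u,
                         if (is.null(st$ref)) 0L else st$ref, I, dt),
    SRMModel = oracleSRM(m, st$V, st$s,
                         if (is.null(st$r)) 0 else st$r,
                         if (is.null(st$lastSpike)) 0 else st$lastSpike,
                         I, dt, tstep))
  fields <- intersect(names(orc), names(res$state))
  dv <- max(vapply(fields,
                   function(f) abs(orc[[f]] - res$state[[f]]), 0))
  list(maxAbsDiff = dv,
       spikeAgree = identical(as.logical(orc$spiked),
                              as.logical(res$spiked)))
}

## Random scalar states in a model-appropriate range, under the given seed.
randomState <- function(m, rng) {
  mvRange <- inherits(m, "HHModel") ||
    (m@variant == "B" && class(m) %in% c("IzhModel", "SRMModel",
                                         "ThetaModel", "IFSFAModel"))
  V <- if (mvRange) rng(-90, -40) else rng(-2, 2)
  st <- initState(m, 1L)
  st$V <- V
  if (!is.null(st$w)) st$w <- rng(0, 1)
  if (!is.null(st$u)) st$u <- rng(-1, 1)
  if (!is.null(st$s)) st$s <- rng(0, 1)
  if (!is.null(st$r)) st$r <- rng(0, 1)
  if (!is.null(st$n)) { st$n <- rng(0, 1); st$m <- rng(0, 1); st$h <- rng(0, 1) }
  if (!is.null(st$ref)) st$ref <- sample(0:3, 1)
  if (!is.null(st$lastSpike)) st$lastSpike <- sample(0:1, 1)
  st
}

## Every model/variant pair exercised by the oracle-equivalence checks.
oracleModelSet <- function() {
  list(
    makeModel("LIF", regime = "benchmark"),
    makeModel("LIF", regime = "trace"),
    makeModel("NLIF", regime = "benchmark"),
    makeModel("NLIF", regime = "trace"),
    makeModel("AdEx", regime = "benchmark"),
    makeModel("AdEx", regime = "trace"),
    makeModel("IFSFA", regime = "benchmark"),
    makeModel("IFSFA", regime = "trace"),
    makeModel("ThetaNeuron", regime = "benchmark"),
    makeModel("ThetaNeuron", regime = "trace"),
    makeModel("HH", regime = "benchmark"),
    makeModel("QIF", regime = "benchmark"),        # variant C
    makeModel("QIF", regime = "trace"),            # variant B
    makeModel("Izhikevich", regime = "benchmark"),
    makeModel("Izhikevich", regime = "trace"),
    makeModel("SRM", regime = "benchmark"),
    makeModel("SRM", regime = "trace")
  )
}
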