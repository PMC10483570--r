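## Step kernels for the nine neuron models.
##
## Shared conventions (applied uniformly):
##  * explicit forward Euler with the regime dt; no adaptive stepping;
##  * the spike test uses the membrane value AFTER the update, with >= so a
##    tie at threshold spikes;
##  * while a refractory counter is positive it is decremented before the
##    update, the potential is held at the reset value, and no spike occurs;
##  * all state fields are vectors: one call advances n independent neurons.

.checkFinite <- function(state, input) {
  if (!all(is.finite(state$V)))
    stop("numeric overflow: non-finite membrane potential", call. = FALSE)
  if (!all(is.finite(input)))
    stop("numeric overflow: non-finite input current", call. = FALSE)
}

.state <- function(...) {
  st <- list(...)
  st
}

## -- LIF --------------------------------------------------------------------

#' @describeIn stepNeuron Leaky integrate-and-fire.
#' @export
setMethod("stepNeuron", "LIFModel",
function(model, state, input, dt = model@dt, tstep = 0L) {
  .checkFinite(state, input)
  V <- state$V
  drive <- if (model@variant == "B") model@rM * input / model@gLeak else input
  V <- V + (-V + drive) / model@tau * dt
  spiked <- V >= model@vTh
  V[spiked] <- model@vReset
  state$V <- V
  list(state = state, spiked = spiked)
})

setMethod("initState", "LIFModel", function(model, n = 1L)
  .state(V = rep(model@vInit, n)))

## -- NLIF -------------------------------------------------------------------

#' @describeIn stepNeuron Non-linear integrate-and-fire. The Euler step runs
#'   first; the threshold/leak case split is applied to the integrated value
#'   (spike: `vReset + alpha (V - vTh)`; otherwise multiply by `beta` in
#'   variant A).
#' @export
setMethod("stepNeuron", "NLIFModel",
function(model, state, input, dt = model@dt, tstep = 0L) {
  .checkFinite(state, input)
  V <- state$V
  if (model@variant == "B") {
    V <- V + (-V + model@rM * input / model@gLeak + V^2) / model@tau * dt
    spiked <- !is.finite(V) | V >= model@vTh
    V[spiked] <- model@vReset
  } else {
    V <- V + (-V + input) / model@tau * dt
    spiked <- V >= model@vTh
    V <- ifelse(spiked, model@vReset + model@alpha * (V - model@vTh),
                V * model@beta)
  }
  state$V <- V
  list(state = state, spiked = spiked)
})

## -- AdEx -------------------------------------------------------------------

#' @describeIn stepNeuron Adaptive exponential integrate-and-fire. An
#'   overflowing exponential term is treated as the spike itself (the
#'   divergence is the spike in exponential integrate-and-fire models).
#' @export
setMethod("stepNeuron", "AdExModel",
function(model, state, input, dt = model@dt, tstep = 0L) {
  .checkFinite(state, input)
  V <- state$V
  if (model@variant == "B") {
    w <- state$w
    dV <- (-V + model@rM * input / model@gLeak +
           w * exp((V - model@vTh) / model@tauM)) / model@tauM
    Vn <- V + dV * dt
    w <- w + (model@a * (V - model@vReset) - w) / model@tauW * dt
    spiked <- !is.finite(Vn) | Vn >= model@vTh
    Vn[spiked] <- model@vReset
    w[spiked] <- w[spiked] + model@b
    state$V <- Vn
    state$w <- w
  } else {
    dV <- (-V + model@tauM * input - model@vRheo +
           model@deltaT * exp((V - model@vSpike) / model@deltaT)) / model@tauM
    Vn <- V + dV * dt
    spiked <- !is.finite(Vn) | Vn >= model@vSpike
    Vn[spiked] <- model@vReset
    state$V <- Vn
  }
  list(state = state, spiked = spiked)
})

setMethod("initState", "AdExModel", function(model, n = 1L)
  .state(V = rep(model@vInit, n), w = rep(0, n)))

## -- IF-SFA -----------------------------------------------------------------

#' @describeIn stepNeuron Integrate-and-fire with spike-frequency
#'   adaptation. Variant A updates the adaptation current first, then the
#'   membrane; variant B applies the spike cutoff at `vPeak`, the after-spike
#'   reset/jump, and the floor holding `V >= vR`.
#' @export
setMethod("stepNeuron", "IFSFAModel",
function(model, state, input, dt = model@dt, tstep = 0L) {
  .checkFinite(state, input)
  V <- state$V
  w <- state$w
  if (model@variant == "B") {
    dV <- model@rM * (0.04 * V^2 + 140 - w + input) / model@cM
    Vn <- V + dV * dt
    w <- w + model@aAdapt * (model@K * (V - model@vR) - w) * dt
    spiked <- !is.finite(Vn) | Vn >= model@vPeak
    Vn[spiked] <- model@cReset
    w[spiked] <- w[spiked] + model@dJump
    Vn[Vn < model@vR] <- model@vR
    state$V <- Vn
    state$w <- w
  } else {
    w <- w + (model@A * (V - model@vRest) - w) / model@tauW * dt
    Vn <- V + (-V + input - w) / model@tauM * dt
    spiked <- Vn >= model@vTh
    Vn[spiked] <- model@vRest
    w[spiked] <- w[spiked] + model@b
    state$V <- Vn
    state$w <- w
  }
  list(state = state, spiked = spiked)
})

setMethod("initState", "IFSFAModel", function(model, n = 1L)
  .state(V = rep(model@vInit, n), w = rep(0, n)))

## -- Theta ------------------------------------------------------------------

#' @describeIn stepNeuron Theta neuron. Variant A adds the theta-rhythm
#'   sinusoid evaluated at absolute time `tstep * dt`; variant B relaxes
#'   toward a conductance-weighted mixture of rest and threshold.
#' @export
setMethod("stepNeuron", "ThetaModel",
function(model, state, input, dt = model@dt, tstep = 0L) {
  .checkFinite(state, input)
  V <- state$V
  if (model@variant == "B") {
    V <- V + (-(V - model@vR) + model@g * (model@theta - V) + input) /
      model@tau * dt
    spiked <- V >= model@theta
    V[spiked] <- model@vReset
  } else {
    iTheta <- model@iThetaMax *
      sin(2 * pi * model@fTheta * (tstep * dt) + model@phi)
    V <- V + (-V + input + iTheta) / model@tau * dt
    spiked <- V >= model@vTh
    V[spiked] <- model@vReset
  }
  state$V <- V
  list(state = state, spiked = spiked)
})

setMethod("initState", "ThetaModel", function(model, n = 1L)
  .state(V = rep(model@vInit, n)))

## -- Hodgkin-Huxley ---------------------------------------------------------

## Canonical squid-axon rate functions (1 / ms, potentials in mV relative to
## a -65 mV rest). The two removable singularities are evaluated by their
## limits.
hhRates <- function(V) {
  an <- ifelse(abs(V + 55) < 1e-7, 0.1,
               0.01 * (V + 55) / (1 - exp(-(V + 55) / 10)))
  bn <- 0.125 * exp(-(V + 65) / 80)
  am <- ifelse(abs(V + 40) < 1e-7, 1,
               0.1 * (V + 40) / (1 - exp(-(V + 40) / 10)))
  bm <- 4 * exp(-(V + 65) / 18)
  ah <- 0.07 * exp(-(V + 65) / 20)
  bh <- 1 / (1 + exp(-(V + 35) / 10))
  list(an = an, bn = bn, am = am, bm = bm, ah = ah, bh = bh)
}

#' @describeIn stepNeuron Hodgkin-Huxley. Gating variables advance from the
#'   pre-step potential and are clamped to [0, 1]; the membrane update uses
#'   `dV/dt = (I - I_Na - I_K - I_L)/cM`.
#' @export
setMethod("stepNeuron", "HHModel",
function(model, state, input, dt = model@dt, tstep = 0L) {
  .checkFinite(state, input)
  V <- state$V
  r <- hhRates(V)
  n <- pmin(1, pmax(0, state$n + (r$an * (1 - state$n) - r$bn * state$n) * dt))
  m <- pmin(1, pmax(0, state$m + (r$am * (1 - state$m) - r$bm * state$m) * dt))
  h <- pmin(1, pmax(0, state$h + (r$ah * (1 - state$h) - r$bh * state$h) * dt))
  iNa <- model@gNa * m^3 * h * (V - model@eNa)
  iK <- model@gK * n^4 * (V - model@eK)
  iL <- model@gL * (V - model@eL)
  V <- V + (input - iNa - iK - iL) / model@cM * dt
  spiked <- !is.finite(V) | V >= model@vDetect
  V[spiked] <- model@vReset
  state$V <- V
  state$n <- n
  state$m <- m
  state$h <- h
  list(state = state, spiked = spiked)
})

setMethod("initState", "HHModel", function(model, n = 1L)
  .state(V = rep(model@vInit, n), n = rep(model@n0, n),
         m = rep(model@m0, n), h = rep(model@h0, n)))

## -- QIF --------------------------------------------------------------------

#' @describeIn stepNeuron Quadratic integrate-and-fire. Variant A draws its
#'   noise term from the caller's RNG stream (pass a seeded stream for
#'   reproducibility); variant B enforces the refractory hold; variant C is
#'   the quadratic rule used by the classification benchmark.
#' @export
setMethod("stepNeuron", "QIFModel",
function(model, state, input, dt = model@dt, tstep = 0L) {
  .checkFinite(state, input)
  V <- state$V
  if (model@variant == "A") {
    noise <- if (model@iNoiseSd > 0)
      stats::rnorm(length(V), 0, model@iNoiseSd) else 0
    V <- V + dt / model@C * (model@gSyn * (model@vSyn - V) + input + noise)
    spiked <- V >= model@vTh
    V[spiked] <- model@vReset
    state$V <- V
    return(list(state = state, spiked = spiked))
  }
  if (model@variant == "B") {
    ref <- state$ref
    inRef <- ref > 0L
    ref[inRef] <- ref[inRef] - 1L
    Vn <- V + (-V + model@cM * input) / model@tauRef * dt
    Vn[inRef] <- model@vReset
    spiked <- !inRef & Vn >= model@vTh
    Vn[spiked] <- model@vReset
    ref[spiked] <- as.integer(round(model@tauRef / dt))
    state$V <- Vn
    state$ref <- ref
    return(list(state = state, spiked = spiked))
  }
  ## variant C: dV/dt = (-V + beta V^2 + I)/tau
  V <- V + (-V + model@beta * V^2 + input) / model@tau * dt
  spiked <- !is.finite(V) | V >= model@vTh
  V[spiked] <- model@vReset
  state$V <- V
  list(state = state, spiked = spiked)
})

setMethod("initState", "QIFModel", function(model, n = 1L) {
  st <- .state(V = rep(model@vInit, n))
  if (model@variant == "B") st$ref <- integer(n)
  st
})

## -- Izhikevich -------------------------------------------------------------

#' @describeIn stepNeuron Izhikevich two-variable model. The recovery
#'   variable advances from the pre-step potential; spikes reset `v` to `c`
#'   and increment `u` by `d`.
#' @export
setMethod("stepNeuron", "IzhModel",
function(model, state, input, dt = model@dt, tstep = 0L) {
  .checkFinite(state, input)
  v <- state$V
  u <- state$u
  if (model@variant == "B") {
    ref <- state$ref
    inRef <- ref > 0L
    ref[inRef] <- ref[inRef] - 1L
    dv <- model@rM * (0.04 * v^2 + 5 * v + 140 - u + input) / model@tau
    vn <- v + dv * dt
    u <- u + model@a * (model@b * v - u) * dt
    vn[inRef] <- model@c
    spiked <- !inRef & vn >= model@vPeak
    vn[spiked] <- model@c
    u[spiked] <- u[spiked] + model@d
    ref[spiked] <- model@refracSteps
    state$V <- vn
    state$u <- u
    state$ref <- ref
  } else {
    vn <- v + (0.04 * v^2 + 5 * v + 140 - u + input) * dt
    u <- u + model@a * (model@b * v - u) * dt
    spiked <- !is.finite(vn) | vn >= model@vPeak
    vn[spiked] <- model@c
    u[spiked] <- u[spiked] + model@d
    state$V <- vn
    state$u <- u
  }
  list(state = state, spiked = spiked)
})

setMethod("initState", "IzhModel", function(model, n = 1L) {
  st <- .state(V = rep(model@vInit, n), u = rep(model@uInit, n))
  if (model@variant == "B") st$ref <- integer(n)
  st
})

## -- SRM --------------------------------------------------------------------

#' @describeIn stepNeuron Spike response model. Variant A follows the
#'   printed update (note the negated input-current term); on a spike the
#'   synaptic and refractory variables are incremented by 1. Variant B
#'   drives `s` from the previous step's spike, adds the synaptic current
#'   `s A (eS - V)`, and applies the periodic leak pull.
#' @export
setMethod("stepNeuron", "SRMModel",
function(model, state, input, dt = model@dt, tstep = 0L) {
  .checkFinite(state, input)
  V <- state$V
  s <- state$s
  if (model@variant == "B") {
    s <- s + (-s + model@A * state$lastSpike) / model@tauS * dt
    V <- V + (-(V - model@vR) + model@g * (model@theta - V) +
              s * model@A * (model@eS - V) + input) /
      (model@tau * model@cM) * dt
    period <- max(1L, as.integer(round(model@tauRef / dt)))
    if (tstep %% period == 0L)
      V <- V + model@gL * (model@v0 - V) * dt
    spiked <- V >= model@theta
    V[spiked] <- model@vReset
    state$V <- V
    state$s <- s
    state$lastSpike <- as.numeric(spiked)
  } else {
    r <- state$r
    synIn <- if (length(model@weights) && !is.null(state$preS))
      as.numeric(model@weights %*% state$preS) else 0
    s <- s + (-s / model@tauS + r) * dt
    r <- r + (-r / model@tauR) * dt
    V <- V + (-V - input + synIn) / model@tauS * dt
    spiked <- V >= model@theta
    V[spiked] <- model@vReset
    s[spiked] <- s[spiked] + 1
    r[spiked] <- r[spiked] + 1
    state$V <- V
    state$s <- s
    state$r <- r
  }
  list(state = state, spiked = spiked)
})

setMethod("initState", "SRMModel", function(model, n = 1L) {
  st <- .state(V = rep(model@vInit, n), s = rep(0, n))
  if (model@variant == "B") st$lastSpike <- rep(0, n) else st$r <- rep(0, n)
  st
})

## -- names and amplitudes ---------------------------------------------------

#' @describeIn stepNeuron Canonical identifier of a model object.
#' @export
setMethod("modelName", "NeuronModel", function(model) {
  switch(class(model),
         LIFModel = "LIF", NLIFModel = "NLIF", AdExModel = "AdEx",
         IFSFAModel = "IFSFA", ThetaModel = "ThetaNeuron", HHModel = "HH",
         QIFModel = "QIF", IzhModel = "Izhikevich", SRMModel = "SRM",
         class(model))
})
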