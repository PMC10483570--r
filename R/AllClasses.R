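#' @import methods
NULL

## ---------------------------------------------------------------------------
## Simulation scaffolding
## ---------------------------------------------------------------------------

#' Time grid for a fixed-step simulation
#'
#' A forward-Euler integration grid: a step duration `dt` (model time units;
#' milliseconds in the trace regime, dimensionless in the benchmark regime)
#' and a non-negative number of steps.
#'
#' @slot dt Positive step duration.
#' @slot nSteps Non-negative integer step count.
#' @export
setClass("SimulationGrid",
  representation(dt = "numeric", nSteps = "integer"),
  validity = function(object) {
    if (length(object@dt) != 1L || !is.finite(object@dt) || object@dt <= 0)
      return("dt must be a single positive finite number")
    if (length(object@nSteps) != 1L || object@nSteps < 0L)
      return("nSteps must be a single non-negative integer")
    TRUE
  })

#' @param dt Positive step duration.
#' @param nSteps Non-negative step count.
#' @rdname SimulationGrid-class
#' @export
SimulationGrid <- function(dt, nSteps) {
  new("SimulationGrid", dt = as.numeric(dt), nSteps = as.integer(nSteps))
}

#' Stimulus protocol for a trace run
#'
#' Either a constant current for the whole run, or a rectangular current
#' pulse: `amplitude` inside `[onsetStep, offsetStep)`, zero outside.
#'
#' @slot kind `"constant"` or `"pulse"`.
#' @slot amplitude Input current value.
#' @slot onsetStep,offsetStep Pulse window (ignored for `"constant"`).
#' @slot grid A [SimulationGrid].
#' @export
setClass("StimulusProtocol",
  representation(kind = "character", amplitude = "numeric",
                 onsetStep = "integer", offsetStep = "integer",
                 grid = "SimulationGrid"),
  validity = function(object) {
    if (!object@kind %in% c("constant", "pulse"))
      return("kind must be 'constant' or 'pulse'")
    if (!is.finite(object@amplitude))
      return("amplitude must be finite")
    if (object@kind == "pulse") {
      if (object@onsetStep > object@offsetStep)
        return("onsetStep must be <= offsetStep")
      if (object@offsetStep > object@grid@nSteps)
        return("offsetStep must be <= nSteps")
      if (object@onsetStep < 0L)
        return("onsetStep must be >= 0")
    }
    TRUE
  })

#' @param kind `"constant"` or `"pulse"`.
#' @param amplitude Current amplitude.
#' @param grid A [SimulationGrid].
#' @param onsetStep,offsetStep Pulse window in steps (pulse kind only).
#' @rdname StimulusProtocol-class
#' @export
StimulusProtocol <- function(kind = c("constant", "pulse"), amplitude, grid,
                             onsetStep = 0L, offsetStep = grid@nSteps) {
  kind <- match.arg(kind)
  new("StimulusProtocol", kind = kind, amplitude = as.numeric(amplitude),
      onsetStep = as.integer(onsetStep), offsetStep = as.integer(offsetStep),
      grid = grid)
}

#' Recorded membrane trace and spike train
#'
#' Output of [runTrace()]: the per-step membrane potential, the indices of
#' spike emissions (1-based, strictly increasing), the model's plotting
#' amplitude tag for spikes, and a parameter snapshot sufficient to
#' reproduce the run.
#'
#' @slot trace Numeric membrane potential per step (value after the update).
#' @slot spikeSteps Integer indices of steps on which a spike was emitted.
#' @slot dt Step duration used.
#' @slot amplitude Model-specific spike plotting amplitude (display only).
#' @slot params Named list snapshot of model parameters and protocol.
#' @slot seed Integer seed recorded for the run (NA when none used).
#' @export
setClass("SpikeRecord",
  representation(trace = "numeric", spikeSteps = "integer", dt = "numeric",
                 amplitude = "numeric", params = "list", seed = "integer"),
  validity = function(object) {
    ss <- object@spikeSteps
    if (length(ss) && (any(ss < 1L) || any(ss > length(object@trace))))
      return("spikeSteps out of range of trace")
    if (length(ss) > 1L && any(diff(ss) <= 0L))
      return("spikeSteps must be strictly increasing")
    TRUE
  })

#' Two-class Gaussian benchmark dataset
#'
#' Balanced scalar-feature dataset: `nPerClass` draws from N(0, 1) labelled 0
#' and `nPerClass` draws from N(3, 1) labelled 1, jointly shuffled by a
#' seeded random permutation.
#'
#' @slot features Numeric feature per sample (length `2 * nPerClass`).
#' @slot labels Integer class labels in {0, 1}.
#' @slot nPerClass Samples per class.
#' @slot seed RNG seed used for drawing and shuffling.
#' @export
setClass("LabeledDataset",
  representation(features = "numeric", labels = "integer",
                 nPerClass = "integer", seed = "integer"),
  validity = function(object) {
    if (length(object@features) != length(object@labels))
      return("features and labels must have equal length")
    if (!all(object@labels %in% c(0L, 1L)))
      return("labels must be 0 or 1")
    if (sum(object@labels == 0L) != object@nPerClass ||
        sum(object@labels == 1L) != object@nPerClass)
      return("dataset must contain exactly nPerClass samples of each class")
    TRUE
  })

#' Itemised arithmetic cost of neuron updates
#'
#' Non-negative operation counts by kind; `total` always equals the sum of
#' the components.
#'
#' @slot additions,subtractions,multiplications,divisions Counts.
#' @slot exponentials,comparisons Counts.
#' @slot total Sum of all components.
#' @export
setClass("OperationCount",
  representation(additions = "numeric", subtractions = "numeric",
                 multiplications = "numeric", divisions = "numeric",
                 exponentials = "numeric", comparisons = "numeric",
                 total = "numeric"),
  validity = function(object) {
    comp <- c(object@additions, object@subtractions, object@multiplications,
              object@divisions, object@exponentials, object@comparisons)
    if (any(comp < 0) || any(comp != floor(comp)))
      return("operation counts must be non-negative integers")
    if (object@total != sum(comp))
      return("total must equal the sum of the components")
    TRUE
  })

#' @param additions,subtractions,multiplications,divisions,exponentials,comparisons
#'   Non-negative counts (default 0).
#' @rdname OperationCount-class
#' @export
OperationCount <- function(additions = 0, subtractions = 0,
                           multiplications = 0, divisions = 0,
                           exponentials = 0, comparisons = 0) {
  new("OperationCount",
      additions = as.numeric(additions), subtractions = as.numeric(subtractions),
      multiplications = as.numeric(multiplications),
      divisions = as.numeric(divisions),
      exponentials = as.numeric(exponentials),
      comparisons = as.numeric(comparisons),
      total = additions + subtractions + multiplications + divisions +
              exponentials + comparisons)
}

#' Benchmark evaluation report
#'
#' Per-model mean classification accuracy and error on the synthetic
#' benchmark, per-seed accuracies, spike totals, the pairwise
#' performance-loss matrix, and a configuration snapshot.
#'
#' @slot accuracy Named numeric vector of mean accuracies (percent).
#' @slot error Named numeric vector of mean error rates (percent),
#'   `100 - accuracy`.
#' @slot perSeed Matrix of per-seed accuracies (seeds x models).
#' @slot spikeTotals Named numeric vector: per model, the number of samples
#'   (across all seeds) on which it emitted at least one spike.
#' @slot lossMatrix Pairwise relative performance loss (percent), `NA` diagonal.
#' @slot seeds Integer seeds used.
#' @slot config Named list snapshot of the benchmark configuration.
#' @export
setClass("EvaluationReport",
  representation(accuracy = "numeric", error = "numeric", perSeed = "matrix",
                 spikeTotals = "numeric", lossMatrix = "matrix",
                 seeds = "integer", config = "list"),
  validity = function(object) {
    if (any(object@accuracy < 0 | object@accuracy > 100))
      return("accuracies must lie in [0, 100]")
    if (max(abs(object@accuracy + object@error - 100)) > 1e-9)
      return("error must equal 100 - accuracy")
    TRUE
  })

## ---------------------------------------------------------------------------
## Neuron model classes
## ---------------------------------------------------------------------------

#' Virtual parent of all neuron model classes
#'
#' Common slots: the model identifier, the equation variant in use
#' (`"A"` = dimensionless benchmark formulation, `"B"` = millivolt trace
#' formulation, `"C"` = the quadratic integrate-and-fire rule), the default
#' integration step `dt`, and the spike plotting `amplitude` tag.
#'
#' @export
setClass("NeuronModel",
  representation("VIRTUAL", variant = "character", dt = "numeric",
                 amplitude = "numeric"),
  prototype(variant = "A", dt = 0.1, amplitude = 1),
  validity = function(object) {
    if (!object@variant %in% c("A", "B", "C"))
      return("variant must be 'A', 'B' or 'C'")
    if (!is.finite(object@dt) || object@dt <= 0)
      return("dt must be positive")
    TRUE
  })

#' Leaky integrate-and-fire model
#'
#' Variant A: `dV/dt = (-V + I)/tau`. Variant B divides the drive by the
#' leak conductance: `dV/dt = (-V + Rm I / gLeak)/tau`. Spike and reset at
#' `V >= vTh`.
#'
#' @slot tau Membrane time constant (> 0).
#' @slot rM Membrane resistance (variant B).
#' @slot gLeak Leak conductance (> 0, variant B).
#' @slot vTh Spike threshold.
#' @slot vReset Post-spike reset potential.
#' @slot vInit Initial potential.
#' @export
setClass("LIFModel", contains = "NeuronModel",
  representation(tau = "numeric", rM = "numeric", gLeak = "numeric",
                 vTh = "numeric", vReset = "numeric", vInit = "numeric"),
  prototype(rM = 1, gLeak = 1),
  validity = function(object) {
    if (object@tau <= 0) return("tau must be > 0")
    if (object@variant == "A" && object@vTh <= object@vReset)
      return("vTh must exceed vReset in the benchmark formulation")
    if (object@variant == "B" && object@gLeak <= 0)
      return("gLeak must be > 0 when used")
    TRUE
  })

#' Non-linear integrate-and-fire model
#'
#' Variant A integrates like the LIF, then applies a post-integration map:
#' spike with `V <- vReset + alpha (V - vTh)` at threshold, otherwise
#' `V <- beta V` (subthreshold multiplicative leak). Variant B adds a `V^2`
#' term to the drift and resets plainly to `vReset`.
#'
#' @slot alpha Post-spike depolarisation scale (>= 0).
#' @slot beta Subthreshold leak multiplier in [0, 1].
#' @export
setClass("NLIFModel", contains = "LIFModel",
  representation(alpha = "numeric", beta = "numeric"),
  prototype(alpha = 0, beta = 1),
  validity = function(object) {
    if (object@alpha < 0) return("alpha must be >= 0")
    if (object@beta < 0 || object@beta > 1) return("beta must lie in [0, 1]")
    TRUE
  })

#' Adaptive exponential integrate-and-fire model
#'
#' Variant A: `dV/dt = (-V + tauM I - vRheo + deltaT exp((V - vSpike)/deltaT))/tauM`,
#' spike at `V >= vSpike`; a diverging (overflowing) exponential is itself
#' treated as the spike. Variant B follows the trace formulation with an
#' adaptation current `w` (subthreshold growth `a (V - vReset)`, decay
#' `tauW`, spike-triggered increment `b`).
#'
#' @slot tauM Membrane time constant (> 0).
#' @slot vRheo Rheobase potential.
#' @slot deltaT Slope factor (> 0).
#' @slot vSpike Spike threshold potential (variant A).
#' @slot vTh Threshold used by the variant-B exponential and spike test.
#' @slot a Subthreshold adaptation conductance.
#' @slot b Spike-triggered adaptation increment.
#' @slot tauW Adaptation time constant (> 0).
#' @slot rM,gLeak Variant-B drive scaling.
#' @slot vReset,vInit Reset / initial potential.
#' @export
setClass("AdExModel", contains = "NeuronModel",
  representation(tauM = "numeric", vRheo = "numeric", deltaT = "numeric",
                 vSpike = "numeric", vTh = "numeric", a = "numeric",
                 b = "numeric", tauW = "numeric", rM = "numeric",
                 gLeak = "numeric", vReset = "numeric", vInit = "numeric"),
  prototype(deltaT = 1, tauW = 1, a = 0, b = 0, rM = 1, gLeak = 1, vTh = 1,
            vSpike = 1, vRheo = 0),
  validity = function(object) {
    if (object@deltaT <= 0) return("deltaT must be > 0")
    if (object@tauM <= 0 || object@tauW <= 0)
      return("tauM and tauW must be > 0")
    TRUE
  })

#' Integrate-and-fire with spike-frequency adaptation
#'
#' Variant A couples the LIF membrane to an adaptation current `w` with
#' strength `A`, decay `tauW`, and post-spike increment `b`; the membrane
#' resets to `vRest`. Variant B is the trace formulation
#' `dV/dt = Rm (0.04 V^2 + 140 - U + I)/Cm`, `dU/dt = a (K (V - vR) - U)`,
#' with spike cutoff `vPeak`, after-spike reset `cReset`, adaptation jump
#' `dJump`, and a floor holding `V >= vR`.
#'
#' @slot tauM,tauW Time constants (> 0).
#' @slot A Adaptation strength (variant A).
#' @slot vRest Resting / reset potential (variant A).
#' @slot vTh Spike threshold (variant A).
#' @slot b Post-spike adaptation increment (variant A).
#' @slot deltaT Slope factor (stored from the benchmark table; unused by the
#'   printed update equations).
#' @slot cM Membrane capacitance (> 0, variant B).
#' @slot K Membrane-potential sensitivity (variant B).
#' @slot vR Resting potential and floor (variant B).
#' @slot aAdapt Adaptation conductance (variant B).
#' @slot vPeak Spike cutoff (variant B).
#' @slot cReset After-spike reset potential (variant B).
#' @slot dJump After-spike adaptation jump (variant B).
#' @slot rM Membrane resistance (variant B).
#' @slot vInit Initial potential.
#' @export
setClass("IFSFAModel", contains = "NeuronModel",
  representation(tauM = "numeric", tauW = "numeric", A = "numeric",
                 vRest = "numeric", vTh = "numeric", b = "numeric",
                 deltaT = "numeric", cM = "numeric", K = "numeric",
                 vR = "numeric", aAdapt = "numeric", vPeak = "numeric",
                 cReset = "numeric", dJump = "numeric", rM = "numeric",
                 vInit = "numeric"),
  prototype(tauM = 1, tauW = 1, A = 0, b = 0, deltaT = 1, cM = 1, K = 0,
            vR = 0, aAdapt = 0, vPeak = 1, cReset = 0, dJump = 0, rM = 1),
  validity = function(object) {
    if (object@tauM <= 0 || object@tauW <= 0)
      return("tauM and tauW must be > 0")
    if (object@variant == "B" && object@cM <= 0)
      return("cM must be > 0 when used")
    TRUE
  })

#' Theta neuron model
#'
#' Variant A adds a sinusoidal theta-rhythm current
#' `iThetaMax sin(2 pi fTheta t + phi)` to the LIF drive and resets at
#' `vTh`. Variant B is the threshold formulation
#' `dV/dt = (-(V - vR) + g (theta - V) + I)/tau` with spike at `V >= theta`.
#'
#' @slot iThetaMax Sinusoid amplitude (variant A, >= 0 typical).
#' @slot fTheta Theta frequency (>= 0).
#' @slot phi Phase.
#' @slot tau Membrane time constant (> 0).
#' @slot vTh Spike threshold (variant A).
#' @slot vReset Reset potential (both variants).
#' @slot vInit Initial potential.
#' @slot vR Rest potential (variant B).
#' @slot g Input conductance (>= 0, variant B).
#' @slot theta Threshold potential (variant B).
#' @export
setClass("ThetaModel", contains = "NeuronModel",
  representation(iThetaMax = "numeric", fTheta = "numeric", phi = "numeric",
                 tau = "numeric", vTh = "numeric", vReset = "numeric",
                 vInit = "numeric", vR = "numeric", g = "numeric",
                 theta = "numeric"),
  prototype(iThetaMax = 0, fTheta = 0, phi = 0, vR = 0, g = 0, theta = 1),
  validity = function(object) {
    if (object@tau <= 0) return("tau must be > 0")
    if (object@fTheta < 0) return("fTheta must be >= 0")
    if (object@g < 0) return("g must be >= 0")
    TRUE
  })

#' Hodgkin-Huxley model
#'
#' Canonical squid-axon conductance model: gating variables `n, m, h`
#' governed by the voltage-dependent rate functions, ionic currents
#' `I_Na = gNa m^3 h (V - eNa)`, `I_K = gK n^4 (V - eK)`,
#' `I_L = gL (V - eL)`, and membrane update
#' `dV/dt = (I - I_Na - I_K - I_L)/cM`. A spike is registered when `V`
#' reaches `vDetect`, after which `V` is set to `vReset`; gating variables
#' are clamped to [0, 1] every step.
#'
#' @slot cM Membrane capacitance (> 0).
#' @slot gNa,gK,gL Maximal conductances (>= 0).
#' @slot eNa,eK,eL Reversal potentials.
#' @slot n0,m0,h0 Initial gating values in [0, 1].
#' @slot vDetect Spike-detection threshold.
#' @slot vReset Post-detection reset potential.
#' @slot vInit Initial potential.
#' @export
setClass("HHModel", contains = "NeuronModel",
  representation(cM = "numeric", gNa = "numeric", gK = "numeric",
                 gL = "numeric", eNa = "numeric", eK = "numeric",
                 eL = "numeric", n0 = "numeric", m0 = "numeric",
                 h0 = "numeric", vDetect = "numeric", vReset = "numeric",
                 vInit = "numeric"),
  prototype(cM = 1, vDetect = -66, vReset = -65, vInit = -65,
            n0 = 0.3177, m0 = 0.0529, h0 = 0.5961),
  validity = function(object) {
    if (object@cM <= 0) return("cM must be > 0")
    if (any(c(object@gNa, object@gK, object@gL) < 0))
      return("conductances must be >= 0")
    g <- c(object@n0, object@m0, object@h0)
    if (any(g < 0 | g > 1)) return("initial gating values must lie in [0, 1]")
    TRUE
  })

#' Quadratic integrate-and-fire model
#'
#' Three published formulations. Variant A (conductance form):
#' `V <- V + dt/C (gSyn (vSyn - V) + I + noise)`. Variant B:
#' `dV/dt = (-V + cM I)/tauRef` with a hard refractory period of
#' `round(tauRef/dt)` steps during which `V` is held at `vReset`.
#' Variant C (the genuinely quadratic rule used by the benchmark):
#' `dV/dt = (-V + beta V^2 + I)/tau`.
#'
#' @slot C Capacitance (variant A, > 0).
#' @slot gSyn Synaptic conductance (variant A).
#' @slot vSyn Synaptic reversal potential (variant A).
#' @slot iNoiseSd Noise scale for variant A (0 disables noise).
#' @slot cM Capacitance factor (variant B, > 0).
#' @slot tauRef Refractory time constant (variant B, > 0).
#' @slot tau Membrane time constant (variant C, > 0).
#' @slot beta Quadratic coefficient (variant C).
#' @slot vTh,vReset,vInit Threshold, reset, initial potentials.
#' @export
setClass("QIFModel", contains = "NeuronModel",
  representation(C = "numeric", gSyn = "numeric", vSyn = "numeric",
                 iNoiseSd = "numeric", cM = "numeric", tauRef = "numeric",
                 tau = "numeric", beta = "numeric", vTh = "numeric",
                 vReset = "numeric", vInit = "numeric"),
  prototype(C = 1, gSyn = 0, vSyn = 0, iNoiseSd = 0, cM = 1, tauRef = 1,
            tau = 1, beta = 0),
  validity = function(object) {
    if (object@variant == "A" && object@C <= 0)
      return("C must be > 0 when used")
    if (object@variant == "B" && (object@cM <= 0 || object@tauRef <= 0))
      return("cM and tauRef must be > 0 when used")
    if (object@variant == "C" && object@tau <= 0)
      return("tau must be > 0")
    TRUE
  })

#' Izhikevich model
#'
#' Two-variable model: membrane potential `v` and recovery variable `u`.
#' Variant A: `dv/dt = 0.04 v^2 + 5 v + 140 - u + I`, `du/dt = a (b v - u)`;
#' at `v >= vPeak` the neuron spikes, `v <- c`, `u <- u + d`. Variant B
#' scales `dv/dt` by `rM/tau` and enforces a refractory hold of
#' `refracSteps` steps at the reset potential.
#'
#' @slot a Recovery time scale (> 0).
#' @slot b Recovery sensitivity.
#' @slot c After-spike membrane reset.
#' @slot d After-spike recovery jump.
#' @slot vPeak Spike threshold.
#' @slot uInit Initial recovery value.
#' @slot rM Membrane resistance (variant B).
#' @slot tau Membrane time constant (> 0, variant B).
#' @slot refracSteps Refractory period in steps (variant B).
#' @slot vInit Initial potential.
#' @export
setClass("IzhModel", contains = "NeuronModel",
  representation(a = "numeric", b = "numeric", c = "numeric", d = "numeric",
                 vPeak = "numeric", uInit = "numeric", rM = "numeric",
                 tau = "numeric", refracSteps = "integer", vInit = "numeric"),
  prototype(vPeak = 30, uInit = 0, rM = 1, tau = 1, refracSteps = 0L),
  validity = function(object) {
    if (object@a <= 0) return("a must be > 0")
    if (object@tau <= 0) return("tau must be > 0")
    if (object@refracSteps < 0L) return("refracSteps must be >= 0")
    TRUE
  })

#' Spike response model
#'
#' Variant A: synaptic variable `s` (decay `tauS`, driven by the refractory
#' variable `r`, which decays with `tauR`) and membrane
#' `dV/dt = (-V - I + sum_i w_i s_i)/tauS`; on a spike `V <- vReset` and
#' both `s` and `r` are incremented by 1. The presynaptic sum is zero for an
#' isolated neuron. Variant B: `ds/dt = (-s + A spike)/tauS`,
#' `dV/dt = (-(V - vR) + g (theta - V) + s A (eS - V) + I)/(tau cM)`, with a
#' leak pull `gL (v0 - V)` applied every `round(tauRef/dt)` steps.
#'
#' @slot tauS Synaptic time constant (> 0).
#' @slot tauR Refractory-variable time constant (> 0).
#' @slot tau Membrane time constant (> 0).
#' @slot tauRef Leak application period (variant B).
#' @slot A Synaptic weight.
#' @slot theta Threshold potential.
#' @slot vReset Reset potential.
#' @slot vR Rest potential (variant B).
#' @slot gL Leak conductance (variant B).
#' @slot eS Synaptic reversal potential (variant B).
#' @slot g Input conductance (variant B).
#' @slot cM Membrane capacitance (variant B).
#' @slot v0 Leak target / initial potential (variant B).
#' @slot vInit Initial potential.
#' @slot weights Per-connection input weights (empty for an isolated neuron).
#' @export
setClass("SRMModel", contains = "NeuronModel",
  representation(tauS = "numeric", tauR = "numeric", tau = "numeric",
                 tauRef = "numeric", A = "numeric", theta = "numeric",
                 vReset = "numeric", vR = "numeric", gL = "numeric",
                 eS = "numeric", g = "numeric", cM = "numeric",
                 v0 = "numeric", vInit = "numeric", weights = "numeric"),
  prototype(tauS = 1, tauR = 1, tau = 1, tauRef = 1, A = 0, theta = 1,
            vReset = 0, vR = 0, gL = 0, eS = 0, g = 0, cM = 1, v0 = 0,
            vInit = 0, weights = numeric(0)),
  validity = function(object) {
    if (object@tauS <= 0 || object@tauR <= 0 || object@tau <= 0)
      return("tauS, tauR and tau must be > 0")
    TRUE
  })
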