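#' Load a parameter regime table
#'
#' Reads one of the two bundled parameter regimes (or a user-supplied YAML
#' file with the same layout): a document keyed by model name whose keys
#' mirror the published parameter-table row labels. Cells marked "X" in the
#' tables are simply omitted keys.
#'
#' @param regime `"benchmark"` (dimensionless classification regime),
#'   `"trace"` (millivolt spiking-activity regime), or a path to a YAML
#'   file with the same structure.
#' @return Named list of per-model parameter lists.
#' @export
loadRegime <- function(regime = c("benchmark", "trace")) {
  path <- if (file.exists(regime[1L])) {
    regime[1L]
  } else {
    regime <- match.arg(regime)
    system.file("extdata", paste0("regime_", regime, ".yaml"),
                package = "snnbench", mustWork = TRUE)
  }
  yaml::read_yaml(path)
}

#' The nine supported model identifiers
#' @export
modelNames <- function() {
  c("LIF", "NLIF", "AdEx", "IFSFA", "ThetaNeuron", "HH", "QIF",
    "Izhikevich", "SRM")
}

## value from config by row label, with default; NULL default = required
.gv <- function(cfg, label, default = NULL) {
  v <- cfg[[label]]
  if (is.null(v)) {
    if (is.null(default))
      stop("regime table is missing required entry '", label, "'",
           call. = FALSE)
    return(default)
  }
  as.numeric(v)
}

## D8: spike plotting amplitude tags
.amplitudeTag <- function(name) {
  switch(name, NLIF = 0.7, AdEx = 0.9, 1)
}

#' Configure a neuron model from a parameter regime
#'
#' Builds one of the nine neuron models from a regime table (or explicit
#' slot overrides), validated against the model's parameter invariants.
#' The default equation variant follows the regime: benchmark-regime models
#' use the dimensionless formulation (variant `"A"`, except QIF, whose
#' benchmark parameters — `tau` and `beta` — parameterise the quadratic
#' rule, variant `"C"`), trace-regime models use the millivolt formulation
#' (variant `"B"`; the Hodgkin-Huxley model has a single formulation).
#'
#' @param name One of [modelNames()].
#' @param variant `"A"`, `"B"` or `"C"`; default chosen by regime as above.
#' @param regime `"benchmark"`, `"trace"`, or a YAML path (see
#'   [loadRegime()]).
#' @param overrides Named list of slot values that replace the
#'   regime-derived ones (applied before validation).
#' @return A validated [NeuronModel] subclass object.
#' @examples
#' makeModel("LIF", regime = "benchmark")
#' makeModel("HH", regime = "trace")
#' @export
makeModel <- function(name, variant = NULL,
                      regime = c("benchmark", "trace"),
                      overrides = list()) {
  if (!name %in% modelNames())
    stop("unknown model name '", name, "'; expected one of: ",
         paste(modelNames(), collapse = ", "), call. = FALSE)
  regime <- match.arg(regime)
  isTrace <- identical(regime, "trace")
  cfg <- loadRegime(regime)[[name]]
  if (is.null(cfg))
    stop("regime '", regime, "' has no entry for model '", name, "'",
         call. = FALSE)
  if (is.null(variant))
    variant <- if (isTrace) "B" else if (name == "QIF") "C" else "A"
  dt <- .gv(cfg, "Time step")
  common <- list(variant = variant, dt = dt, amplitude = .amplitudeTag(name))

  slots <- if (isTrace) {
    .traceSlots(name, cfg)
  } else {
    .benchmarkSlots(name, cfg)
  }
  slots <- utils::modifyList(c(common, slots), overrides)
  cls <- switch(name, LIF = "LIFModel", NLIF = "NLIFModel",
                AdEx = "AdExModel", IFSFA = "IFSFAModel",
                ThetaNeuron = "ThetaModel", HH = "HHModel", QIF = "QIFModel",
                Izhikevich = "IzhModel", SRM = "SRMModel")
  do.call(new, c(list(cls), slots))
}

.benchmarkSlots <- function(name, cfg) {
  switch(name,
    LIF = list(tau = .gv(cfg, "Tau"),
               vTh = .gv(cfg, "Threshold value"),
               vReset = .gv(cfg, "Reset potential"),
               vInit = .gv(cfg, "Initial potential")),
    NLIF = list(tau = .gv(cfg, "Tau"),
                vTh = .gv(cfg, "Threshold value"),
                vReset = .gv(cfg, "Reset potential"),
                vInit = .gv(cfg, "Initial potential"),
                alpha = .gv(cfg, "Alpha"),
                beta = .gv(cfg, "Beta")),
    AdEx = list(tauM = .gv(cfg, "Tau"),
                vRheo = .gv(cfg, "Rheobase potential"),
                vSpike = .gv(cfg, "Threshold potential"),
                deltaT = .gv(cfg, "Slope factor"),
                vReset = .gv(cfg, "Reset potential"),
                vInit = .gv(cfg, "Initial potential")),
    IFSFA = list(tauM = .gv(cfg, "Tau"),
                 tauW = .gv(cfg, "Adaptation time constant"),
                 A = .gv(cfg, "Adaptation conductance"),
                 b = .gv(cfg, "Adaptation control"),
                 deltaT = .gv(cfg, "Slope factor", 1),
                 vRest = .gv(cfg, "Reset potential"),
                 vTh = .gv(cfg, "Threshold value"),
                 vInit = .gv(cfg, "Initial potential")),
    ThetaNeuron = list(tau = .gv(cfg, "Tau"),
                       vTh = .gv(cfg, "Threshold value"),
                       vReset = .gv(cfg, "Reset potential"),
                       vInit = .gv(cfg, "Initial potential"),
                       iThetaMax = .gv(cfg, "Theta amplitude", 0),
                       fTheta = .gv(cfg, "Theta frequency", 0),
                       phi = .gv(cfg, "Theta phase", 0)),
    HH = list(vReset = .gv(cfg, "Reset potential"),
              vInit = .gv(cfg, "Initial potential"),
              n0 = .gv(cfg, "Activation variable for potassium"),
              m0 = .gv(cfg, "Activation variable for sodium"),
              h0 = .gv(cfg, "Inactivation variable for sodium"),
              gNa = .gv(cfg, "Maximum conductance gNa"),
              gK = .gv(cfg, "Maximum conductance gK"),
              gL = .gv(cfg, "Maximum conductance gL"),
              eNa = .gv(cfg, "Sodium reversal potential"),
              eK = .gv(cfg, "Potassium reversal potential"),
              eL = .gv(cfg, "Leak reversal potential"),
              cM = .gv(cfg, "Membrane capacitance", 1),
              vDetect = .gv(cfg, "Threshold value", -66)),
    QIF = list(tau = .gv(cfg, "Tau"),
               beta = .gv(cfg, "Beta"),
               vTh = .gv(cfg, "Threshold value"),
               vReset = .gv(cfg, "Reset potential"),
               vInit = .gv(cfg, "Initial potential")),
    Izhikevich = list(vPeak = .gv(cfg, "Threshold value"),
                      vInit = .gv(cfg, "Initial potential"),
                      uInit = .gv(cfg, "Recovery variable initial"),
                      a = .gv(cfg, "Time scale RV"),
                      b = .gv(cfg, "Sensitivity RV"),
                      c = .gv(cfg, "After-spike reset MP"),
                      d = .gv(cfg, "After-spike reset RV")),
    SRM = {
      tauR <- .gv(cfg, "Synaptic time constants")
      list(tau = .gv(cfg, "Tau"),
           tauR = tauR,
           ## the table prints a single synaptic time constant; it applies
           ## to both synaptic variables
           tauS = .gv(cfg, "Synaptic time constant s", tauR),
           theta = .gv(cfg, "Threshold value"),
           vReset = .gv(cfg, "Reset potential"),
           vInit = .gv(cfg, "Initial potential"))
    })
}

.traceSlots <- function(name, cfg) {
  switch(name,
    LIF = list(tau = .gv(cfg, "Time constant"),
               rM = .gv(cfg, "Membrane resistance"),
               gLeak = .gv(cfg, "Leak conductance"),
               vTh = .gv(cfg, "Threshold value"),
               vReset = .gv(cfg, "Reset membrane potential"),
               vInit = .gv(cfg, "Initial potential")),
    NLIF = list(tau = .gv(cfg, "Time constant"),
                rM = .gv(cfg, "Membrane resistance"),
                gLeak = .gv(cfg, "Leak conductance"),
                vTh = .gv(cfg, "Threshold value"),
                vReset = .gv(cfg, "Reset membrane potential"),
                vInit = .gv(cfg, "Initial potential")),
    AdEx = list(tauM = .gv(cfg, "Time constant"),
                rM = .gv(cfg, "Membrane resistance"),
                gLeak = .gv(cfg, "Leak conductance"),
                vTh = .gv(cfg, "Threshold value"),
                vReset = .gv(cfg, "Reset membrane potential"),
                vInit = .gv(cfg, "Initial potential"),
                tauW = .gv(cfg, "Adaptation time constant"),
                a = .gv(cfg, "Adaptation conductance"),
                b = .gv(cfg, "Adaptation increment")),
    HH = list(cM = .gv(cfg, "Membrane capacitance", 1),
              gNa = .gv(cfg, "Sodium conductance"),
              gK = .gv(cfg, "Potassium conductance"),
              gL = .gv(cfg, "Leak conductance"),
              eNa = .gv(cfg, "Sodium reversal"),
              eK = .gv(cfg, "Potassium reversal"),
              eL = .gv(cfg, "Leak reversal"),
              vDetect = .gv(cfg, "Threshold value"),
              vReset = .gv(cfg, "Reset membrane potential"),
              vInit = .gv(cfg, "Initial potential")),
    Izhikevich = {
      dt <- .gv(cfg, "Time step")
      list(tau = .gv(cfg, "Time constant"),
           rM = .gv(cfg, "Membrane resistance"),
           vPeak = .gv(cfg, "Threshold value"),
           vInit = .gv(cfg, "Initial potential"),
           uInit = .gv(cfg, "Recovery variable initial", 0),
           a = .gv(cfg, "Recovery variable"),
           b = .gv(cfg, "Sensitivity"),
           c = .gv(cfg, "After-spike reset"),
           d = .gv(cfg, "After-spike reset RV"),
           refracSteps = as.integer(round(.gv(cfg, "Refractory period") / dt)))
    },
    SRM = list(tau = .gv(cfg, "Time constant"),
               tauS = .gv(cfg, "Synaptic time constant"),
               tauR = .gv(cfg, "Synaptic time constant"),
               tauRef = .gv(cfg, "Refractory period"),
               theta = .gv(cfg, "Threshold value"),
               vReset = .gv(cfg, "Reset membrane potential"),
               vR = .gv(cfg, "Reset membrane potential"),
               vInit = .gv(cfg, "Initial potential"),
               v0 = .gv(cfg, "Initial potential"),
               gL = .gv(cfg, "Leak conductance"),
               cM = .gv(cfg, "Membrane capacitance"),
               g = .gv(cfg, "Input conductance"),
               eS = .gv(cfg, "Synaptic reversal potential"),
               A = .gv(cfg, "Synaptic weight")),
    IFSFA = list(rM = .gv(cfg, "Membrane resistance"),
                 cM = .gv(cfg, "Membrane capacitance"),
                 K = .gv(cfg, "Sensitivity"),
                 vR = .gv(cfg, "Reset membrane potential"),
                 vPeak = .gv(cfg, "Threshold value"),
                 cReset = .gv(cfg, "After-spike reset"),
                 dJump = .gv(cfg, "After-spike reset RV"),
                 aAdapt = .gv(cfg, "Adaptation conductance"),
                 tauW = .gv(cfg, "Adaptation time constant"),
                 b = .gv(cfg, "Adaptation increment"),
                 vInit = .gv(cfg, "Initial potential")),
    QIF = list(cM = .gv(cfg, "Membrane capacitance"),
               tauRef = .gv(cfg, "Refractory period"),
               vTh = .gv(cfg, "Threshold value"),
               vReset = .gv(cfg, "Reset membrane potential"),
               vInit = .gv(cfg, "Initial potential")),
    ThetaNeuron = list(tau = .gv(cfg, "Time constant"),
                       theta = .gv(cfg, "Threshold value"),
                       vReset = .gv(cfg, "Reset membrane potential"),
                       vR = .gv(cfg, "Reset membrane potential"),
                       vInit = .gv(cfg, "Initial potential"),
                       g = .gv(cfg, "Input conductance")))
}

#' Default pulse amplitude for a model's demonstration trace
#'
#' The published pulse-response figure does not print its drive values;
#' these package-level defaults (the "Pulse amplitude" key of the regime
#' files) are chosen so each model visibly responds.
#'
#' @inheritParams makeModel
#' @export
defaultPulseAmplitude <- function(name, regime = c("benchmark", "trace")) {
  cfg <- loadRegime(regime)[[name]]
  if (is.null(cfg)) stop("unknown model '", name, "'", call. = FALSE)
  .gv(cfg, "Pulse amplitude", 1)
}
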