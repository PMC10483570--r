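#' Advance a neuron model by one Euler step
#'
#' Every model shares one step contract: given the current state, the input
#' current, and the step duration, return the updated state and a logical
#' spike flag. All state fields are vectors, so a single call advances any
#' number of independent neurons (or independent samples) elementwise.
#'
#' A spike is emitted when the updated membrane potential reaches the
#' model's threshold (ties at equality spike); the model-specific reset
#' rules then apply. While a refractory counter is positive the potential is
#' held at the reset value and no spike can occur.
#'
#' @param model A [NeuronModel] subclass object.
#' @param state Named list of state vectors as produced by [initState()].
#' @param input Numeric input current, recycled to the state length.
#' @param dt Step duration; defaults to the model's regime `dt`.
#' @param tstep 0-based index of the step being taken (the theta-rhythm
#'   sinusoid and periodic-leak rules need absolute time `tstep * dt`).
#' @return A list with elements `state` (updated state list) and `spiked`
#'   (logical vector).
#' @examples
#' m <- makeModel("LIF", regime = "benchmark")
#' st <- initState(m, 1)
#' stepNeuron(m, st, input = 2)$spiked
#' @export
setGeneric("stepNeuron", function(model, state, input, dt = model@dt,
                                  tstep = 0L)
  standardGeneric("stepNeuron"))

#' Initial state for a neuron model
#'
#' @param model A [NeuronModel] object.
#' @param n Number of independent neurons (state vector length).
#' @return Named list of state vectors (always `V`; model-specific
#'   auxiliaries such as `w`, `u`, `s`, `r`, `n`, `m`, `h`; and an integer
#'   refractory countdown `ref` where the model has a refractory period).
#' @export
setGeneric("initState", function(model, n = 1L) standardGeneric("initState"))

#' Model identifier
#' @param model A [NeuronModel] object.
#' @return The canonical model name, e.g. `"LIF"` or `"HH"`.
#' @export
setGeneric("modelName", function(model) standardGeneric("modelName"))

## ---------------------------------------------------------------------------
## Accessors for the data containers
## ---------------------------------------------------------------------------

#' @rdname LabeledDataset-class
#' @param x Object.
#' @export
setGeneric("features", function(x) standardGeneric("features"))
#' @rdname LabeledDataset-class
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @rdname SpikeRecord-class
#' @param x Object.
#' @export
setGeneric("membraneTrace", function(x) standardGeneric("membraneTrace"))
#' @rdname SpikeRecord-class
#' @export
setGeneric("spikeSteps", function(x) standardGeneric("spikeSteps"))
#' @rdname SpikeRecord-class
#' @export
setGeneric("spikeTimes", function(x) standardGeneric("spikeTimes"))

#' @rdname EvaluationReport-class
#' @param x Object.
#' @export
setGeneric("accuracies", function(x) standardGeneric("accuracies"))
#' @rdname EvaluationReport-class
#' @export
setGeneric("errorRates", function(x) standardGeneric("errorRates"))
#' @rdname EvaluationReport-class
#' @export
setGeneric("lossMatrix", function(x) standardGeneric("lossMatrix"))

#' @rdname OperationCount-class
#' @param x Object.
#' @export
setGeneric("opsTotal", function(x) standardGeneric("opsTotal"))
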