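#' @describeIn LabeledDataset-class Feature vector accessor.
#' @export
setMethod("features", "LabeledDataset", function(x) x@features)

#' @describeIn LabeledDataset-class Class label accessor.
#' @export
setMethod("classLabels", "LabeledDataset", function(x) x@labels)

#' @describeIn SpikeRecord-class Per-step membrane potential.
#' @export
setMethod("membraneTrace", "SpikeRecord", function(x) x@trace)

#' @describeIn SpikeRecord-class 1-based step indices of spikes.
#' @export
setMethod("spikeSteps", "SpikeRecord", function(x) x@spikeSteps)

#' @describeIn SpikeRecord-class Spike times (`spikeSteps * dt`).
#' @export
setMethod("spikeTimes", "SpikeRecord", function(x) x@spikeSteps * x@dt)

#' @describeIn EvaluationReport-class Mean accuracies (percent) per model.
#' @export
setMethod("accuracies", "EvaluationReport", function(x) x@accuracy)

#' @describeIn EvaluationReport-class Mean error rates (percent) per model.
#' @export
setMethod("errorRates", "EvaluationReport", function(x) x@error)

#' @describeIn EvaluationReport-class Pairwise performance-loss matrix.
#' @export
setMethod("lossMatrix", "EvaluationReport", function(x) x@lossMatrix)

#' @describeIn OperationCount-class Total operation count.
#' @export
setMethod("opsTotal", "OperationCount", function(x) x@total)

setMethod("show", "LabeledDataset", function(object) {
  cat(sprintf("LabeledDataset: %d samples (%d per class), seed %d\n",
              length(object@features), object@nPerClass, object@seed))
  cat(sprintf("  class 0 mean %.3f, class 1 mean %.3f\n",
              mean(object@features[object@labels == 0L]),
              mean(object@features[object@labels == 1L])))
})

setMethod("show", "SpikeRecord", function(object) {
  cat(sprintf("SpikeRecord: %d steps (dt = %g), %d spikes\n",
              length(object@trace), object@dt, length(object@spikeSteps)))
  if (length(object@spikeSteps))
    cat("  first spikes at steps:",
        paste(utils::head(object@spikeSteps, 8L), collapse = ", "), "\n")
})

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf("EvaluationReport: %d models, %d seeds\n",
              length(object@accuracy), length(object@seeds)))
  df <- data.frame(accuracy_pct = round(object@accuracy, 2),
                   error_pct = round(object@error, 2))
  print(df)
})

setMethod("show", "OperationCount", function(object) {
  cat(sprintf(paste0("OperationCount: %g add, %g sub, %g mult, %g div, ",
                     "%g exp, %g cmp (total %g)\n"),
              object@additions, object@subtractions, object@multiplications,
              object@divisions, object@exponentials, object@comparisons,
              object@total))
})

setMethod("show", "NeuronModel", function(object) {
  cat(sprintf("%s neuron model (variant %s, dt = %g)\n",
              modelName(object), object@variant, object@dt))
})
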