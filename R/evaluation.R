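#' Classify the benchmark dataset with a spiking neuron
#'
#' Each sample's feature is applied as a constant input current for a fixed
#' window (see [simulateSamples()]); the sample is predicted class 1 when
#' the neuron emits at least one spike. In `"population"` mode the sample
#' drives `nNeurons` neurons through weights drawn from N(0, 1) under
#' `weightSeed`, and the prediction is class 1 when more than half the
#' population spikes.
#'
#' @param model A [NeuronModel].
#' @param dataset A [LabeledDataset].
#' @param mapping `"unit"` (default: single unit-weight neuron) or
#'   `"population"`.
#' @param windowSteps Steps per sample window.
#' @param nNeurons Population size for `"population"` mapping.
#' @param weightSeed Seed for the population weights.
#' @return Integer vector of 0/1 predictions, one per sample.
#' @export
classifyDataset <- function(model, dataset, mapping = c("unit", "population"),
                            windowSteps = 100L, nNeurons = 1000L,
                            weightSeed = 1L) {
  mapping <- match.arg(mapping)
  x <- features(dataset)
  if (!length(x)) stop("dataset is empty", call. = FALSE)
  if (mapping == "unit") {
    counts <- simulateSamples(model, x, windowSteps)
    return(as.integer(counts >= 1L))
  }
  set.seed(weightSeed)
  w <- stats::rnorm(nNeurons)
  ## currents for (sample, neuron) pairs, flattened sample-major
  currents <- as.numeric(outer(x, w))
  counts <- simulateSamples(model, currents, windowSteps)
  frac <- rowMeans(matrix(counts >= 1L, nrow = length(x)))
  as.integer(frac > 0.5)
}

#' Classification accuracy and error rate
#'
#' Accuracy is 100 times the mean elementwise agreement between predictions
#' and labels; the error rate is its complement, `100 - accuracy`.
#'
#' @param predictions,labels Equal-length vectors of 0/1 values.
#' @return Named numeric vector `c(accuracy, error)`, in percent.
#' @examples
#' accuracyError(c(0, 1, 1, 1), c(0, 1, 0, 1))
#' @export
accuracyError <- function(predictions, labels) {
  if (length(predictions) != length(labels) || !length(labels))
    stop("predictions and labels must have equal positive length",
         call. = FALSE)
  acc <- 100 * mean(predictions == labels)
  c(accuracy = acc, error = 100 - acc)
}

#' Pairwise performance-loss matrix
#'
#' Relative accuracy difference of every model pair:
#' `L(A, B) = 100 (acc_A - acc_B) / acc_B`, i.e. by how many percent model
#' A's accuracy deviates from reference model B's. The diagonal is
#' inapplicable (`NA`). `L(A, B)` and `L(B, A)` always have opposite signs
#' unless both are zero.
#'
#' @param accuracies Named numeric vector of accuracies (> 0, percent).
#' @return Square matrix with `NA` diagonal; rows are the compared models,
#'   columns the reference models.
#' @examples
#' performanceLossMatrix(c(A = 90, B = 45))
#' @export
performanceLossMatrix <- function(accuracies) {
  if (any(accuracies <= 0))
    stop("all accuracies must be > 0 for a relative loss", call. = FALSE)
  k <- length(accuracies)
  L <- 100 * (matrix(accuracies, k, k) /
              matrix(accuracies, k, k, byrow = TRUE) - 1)
  diag(L) <- NA_real_
  dimnames(L) <- list(model = names(accuracies),
                      reference = names(accuracies))
  L
}

#' Run the full classification benchmark
#'
#' Generates one dataset per seed, classifies it with every requested model
#' (spike emission as the class signal), and reports per-model mean
#' accuracy and error, per-seed accuracies, total spike counts, and the
#' pairwise performance-loss matrix computed from the mean accuracies.
#'
#' @param models Character vector of model names (default all nine).
#' @param regime Parameter regime for [makeModel()] (default
#'   `"benchmark"`).
#' @param nPerClass Samples per class per dataset (default 1000).
#' @param seeds Integer vector of dataset seeds (default `1:10`).
#' @param mapping,windowSteps,nNeurons Passed to [classifyDataset()].
#' @return An [EvaluationReport].
#' @examples
#' rep <- runBenchmark(models = c("LIF", "Izhikevich"), nPerClass = 100,
#'                     seeds = 1:2)
#' accuracies(rep)
#' @export
runBenchmark <- function(models = modelNames(), regime = "benchmark",
                         nPerClass = 1000L, seeds = 1:10,
                         mapping = "unit", windowSteps = 100L,
                         nNeurons = 1000L) {
  stopifnot(length(seeds) >= 1L)
  cfgModels <- lapply(models, makeModel, regime = regime)
  names(cfgModels) <- models
  perSeed <- matrix(NA_real_, nrow = length(seeds), ncol = length(models),
                    dimnames = list(seed = seeds, model = models))
  spikeTotals <- stats::setNames(numeric(length(models)), models)
  for (si in seq_along(seeds)) {
    ds <- generateDataset(nPerClass, seed = seeds[si])
    for (mi in seq_along(models)) {
      pred <- classifyDataset(cfgModels[[mi]], ds, mapping = mapping,
                              windowSteps = windowSteps,
                              nNeurons = nNeurons,
                              weightSeed = seeds[si])
      perSeed[si, mi] <- accuracyError(pred, classLabels(ds))[["accuracy"]]
      spikeTotals[mi] <- spikeTotals[mi] + sum(pred)
    }
  }
  acc <- colMeans(perSeed)
  new("EvaluationReport",
      accuracy = acc, error = 100 - acc, perSeed = perSeed,
      spikeTotals = spikeTotals,
      lossMatrix = performanceLossMatrix(acc),
      seeds = as.integer(seeds),
      config = list(regime = regime, nPerClass = nPerClass,
                    mapping = mapping, windowSteps = windowSteps,
                    nNeurons = if (mapping == "population") nNeurons else NA))
}

#' Write benchmark outputs to a directory
#'
#' Writes `metrics.csv` (model, accuracy_pct, error_pct), `loss_matrix.csv`
#' and `report.json` (full report including per-seed accuracies, seeds and
#' configuration) into `dir`.
#'
#' @param report An [EvaluationReport].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
writeEvaluationReport <- function(report, dir) {
  stopifnot(is(report, "EvaluationReport"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(data.frame(model = names(report@accuracy),
                              accuracy_pct = report@accuracy,
                              error_pct = report@error),
                   file.path(dir, "metrics.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(report@lossMatrix),
                   file.path(dir, "loss_matrix.csv"))
  jsonlite::write_json(
    list(accuracy = as.list(report@accuracy),
         error = as.list(report@error),
         spikeTotals = as.list(report@spikeTotals),
         perSeed = report@perSeed, seeds = report@seeds,
         config = report@config),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
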