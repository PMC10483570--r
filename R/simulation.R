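#' Run a model over a stimulus protocol and record the trace
#'
#' Fixed-step simulation of a single neuron: at each step the input is the
#' protocol amplitude (inside the pulse window for `"pulse"` protocols,
#' always for `"constant"`), the model advances by one Euler step, and the
#' post-update membrane potential and any spike are recorded.
#'
#' @param model A [NeuronModel].
#' @param protocol A [StimulusProtocol]; its grid `dt` must match the
#'   model's regime `dt`.
#' @param seed Optional integer seed recorded in the output and applied to
#'   the RNG for models with stochastic terms.
#' @return A [SpikeRecord].
#' @examples
#' m <- makeModel("LIF", regime = "benchmark")
#' p <- StimulusProtocol("constant", amplitude = 2,
#'                       grid = SimulationGrid(m@dt, 200))
#' runTrace(m, p)
#' @export
runTrace <- function(model, protocol, seed = NA_integer_) {
  stopifnot(is(model, "NeuronModel"), is(protocol, "StimulusProtocol"))
  if (abs(protocol@grid@dt - model@dt) > 1e-12)
    stop("protocol grid dt (", protocol@grid@dt,
         ") does not match the model dt (", model@dt, ")", call. = FALSE)
  nSteps <- protocol@grid@nSteps
  dt <- protocol@grid@dt
  if (!is.na(seed)) set.seed(seed)
  state <- initState(model, 1L)
  vTrace <- numeric(nSteps)
  spikes <- logical(nSteps)
  for (i in seq_len(nSteps)) {
    inp <- if (protocol@kind == "constant" ||
               (i > protocol@onsetStep && i <= protocol@offsetStep))
      protocol@amplitude else 0
    res <- tryCatch(stepNeuron(model, state, inp, dt, tstep = i - 1L),
                    error = function(e)
                      stop("simulation aborted at step ", i, ": ",
                           conditionMessage(e), call. = FALSE))
    state <- res$state
    vTrace[i] <- state$V[1L]
    spikes[i] <- res$spiked[1L]
    if (!is.finite(vTrace[i]))
      stop("simulation aborted at step ", i,
           ": non-finite membrane potential", call. = FALSE)
  }
  new("SpikeRecord", trace = vTrace, spikeSteps = which(spikes), dt = dt,
      amplitude = model@amplitude,
      params = c(list(model = modelName(model), variant = model@variant,
                      kind = protocol@kind,
                      amplitude = protocol@amplitude,
                      onsetStep = protocol@onsetStep,
                      offsetStep = protocol@offsetStep),
                 modelParamList(model)),
      seed = as.integer(seed))
}

#' Pulse-response experiment with package defaults
#'
#' Convenience wrapper reproducing the pulse-response setup: a rectangular
#' current pulse switched on at 10 % and off at 60 % of the run, with a
#' per-model default amplitude from the regime file.
#'
#' @inheritParams makeModel
#' @param nSteps Number of steps (default 1000).
#' @param amplitude Pulse amplitude; default from the regime file.
#' @return A [SpikeRecord].
#' @export
pulseResponse <- function(name, regime = c("benchmark", "trace"),
                          nSteps = 1000L, amplitude = NULL) {
  regime <- match.arg(regime)
  model <- makeModel(name, regime = regime)
  if (is.null(amplitude)) amplitude <- defaultPulseAmplitude(name, regime)
  grid <- SimulationGrid(model@dt, nSteps)
  p <- StimulusProtocol("pulse", amplitude = amplitude, grid = grid,
                        onsetStep = as.integer(round(0.1 * nSteps)),
                        offsetStep = as.integer(round(0.6 * nSteps)))
  runTrace(model, p)
}

#' Spike counts for per-sample constant-current drive
#'
#' The benchmark drive: each sample's feature (times an optional weight)
#' becomes a constant input current applied for `windowSteps` steps from
#' the model's initial state, with no carry-over between samples. All
#' samples are advanced together, one vectorised Euler step at a time.
#'
#' @param model A [NeuronModel].
#' @param currents Numeric vector of input currents (one per sample).
#' @param windowSteps Steps per sample window (>= 1, default 100).
#' @param seed Optional seed for models with stochastic terms.
#' @return Integer vector of spike counts, one per current.
#' @examples
#' m <- makeModel("LIF", regime = "benchmark")
#' simulateSamples(m, c(0, 5))
#' @export
simulateSamples <- function(model, currents, windowSteps = 100L,
                            seed = NA_integer_) {
  stopifnot(is(model, "NeuronModel"), windowSteps >= 1L)
  if (!is.na(seed)) set.seed(seed)
  n <- length(currents)
  state <- initState(model, n)
  counts <- integer(n)
  for (i in seq_len(windowSteps)) {
    res <- stepNeuron(model, state, currents, model@dt, tstep = i - 1L)
    state <- res$state
    counts <- counts + res$spiked
  }
  counts
}

## snapshot of every numeric slot of a model (for record sidecars)
modelParamList <- function(model) {
  sl <- methods::slotNames(class(model))
  out <- lapply(sl, function(s) methods::slot(model, s))
  names(out) <- sl
  out[vapply(out, function(v) is.numeric(v) && length(v) == 1L, TRUE)]
}

#' Serialize a spike record
#'
#' Writes the trace as CSV (columns `step`, `time`, `V`, `spiked`,
#' `amplitude`) and a JSON sidecar `<csvPath>.json` with the parameter
#' snapshot and seed.
#'
#' @param x A [SpikeRecord].
#' @param csvPath Output CSV path.
#' @return `csvPath`, invisibly.
#' @export
writeSpikeRecord <- function(x, csvPath) {
  stopifnot(is(x, "SpikeRecord"))
  n <- length(x@trace)
  spiked <- logical(n)
  spiked[x@spikeSteps] <- TRUE
  df <- data.frame(step = seq_len(n), time = seq_len(n) * x@dt, V = x@trace,
                   spiked = as.integer(spiked),
                   amplitude = ifelse(spiked, x@amplitude, 0))
  utils::write.csv(df, csvPath, row.names = FALSE)
  jsonlite::write_json(list(params = x@params, seed = x@seed,
                            dt = x@dt, nSteps = n),
                       paste0(csvPath, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(csvPath)
}

#' Plot a spike record
#'
#' Membrane trace with spike markers, in the style of a single panel of a
#' multi-model spiking-activity comparison figure.
#'
#' @param x A [SpikeRecord].
#' @param ... Passed to [plot()].
#' @export
plotSpikeRecord <- function(x, ...) {
  stopifnot(is(x, "SpikeRecord"))
  t <- seq_along(x@trace) * x@dt
  plot(t, x@trace, type = "l", xlab = "time", ylab = "membrane potential",
       ...)
  if (length(x@spikeSteps))
    graphics::points(x@spikeSteps * x@dt, x@trace[x@spikeSteps],
                     pch = 4, col = "red")
  invisible(x)
}
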