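test_that("accuracy and error follow the mean-agreement definition", {
  expect_identical(accuracyError(c(0, 1), c(0, 1)),
                   c(accuracy = 100, error = 0))
  expect_identical(accuracyError(c(1, 0), c(0, 1)),
                   c(accuracy = 0, error = 100))
  expect_identical(accuracyError(c(0, 1, 1, 1), c(0, 1, 0, 1)),
                   c(accuracy = 75, error = 25))
  expect_error(accuracyError(c(0, 1), c(0, 1, 1)), "equal")
})

test_that("constant predictors score exactly 50% on balanced data", {
  ds <- generateDataset(300L, seed = 4)
  nlif <- makeModel("NLIF", regime = "benchmark")   # never spikes
  izh <- makeModel("Izhikevich", regime = "benchmark") # always spikes
  predNever <- classifyDataset(nlif, ds)
  predAlways <- classifyDataset(izh, ds)
  expect_identical(sum(predNever), 0L)
  expect_identical(sum(predAlways), 600L)
  expect_identical(accuracyError(predNever, classLabels(ds))[["accuracy"]], 50)
  expect_identical(accuracyError(predAlways, classLabels(ds))[["accuracy"]], 50)
})

test_that("an ideal midpoint thresholder approaches the reference accuracy", {
  ds <- generateDataset(20000L, seed = 6)
  pred <- as.integer(features(ds) > 1.5)
  acc <- accuracyError(pred, classLabels(ds))[["accuracy"]]
  expect_lt(abs(acc - bayesReferenceAccuracy()), 1)
})

test_that("any fixed prediction rule is chance-level under label permutation", {
  set.seed(31)
  ds <- generateDataset(200L, seed = 31)
  pred <- as.integer(features(ds) > 1.5)
  y <- classLabels(ds)
  accs <- replicate(300, accuracyError(pred, sample(y))[["accuracy"]])
  expect_lt(abs(mean(accs) - 50), 2)
})

test_that("performance loss is the relative accuracy difference with an inapplicable diagonal", {
  L <- performanceLossMatrix(c(A = 90, B = 45))
  expect_true(is.na(L["A", "A"]) && is.na(L["B", "B"]))
  expect_identical(L["A", "B"], 100)                  # doubling
  expect_equal(L["B", "A"], -50, tolerance = 1e-12)

  L <- performanceLossMatrix(c(x = 70, y = 70, z = 70))
  expect_true(all(L[!is.na(L)] == 0))                 # equal accuracies

  ## worked relative difference, frozen from direct arithmetic
  L <- performanceLossMatrix(c(a = 71.20, b = 90.05))
  expect_equal(L["a", "b"], 100 * (71.20 - 90.05) / 90.05, tolerance = 1e-12)
  expect_equal(L["a", "b"], -20.9328, tolerance = 1e-4)

  expect_error(performanceLossMatrix(c(A = 90, B = 0)), "> 0")
})

test_that("loss entries of a pair have opposite signs unless both are zero", {
  set.seed(77)
  for (k in 1:20) {
    acc <- runif(5, 40, 95)
    names(acc) <- letters[1:5]
    L <- performanceLossMatrix(acc)
    for (i in 1:5) for (j in 1:5) {
      if (i == j) next
      if (L[i, j] == 0) expect_identical(L[j, i], 0)
      else expect_lt(L[i, j] * L[j, i], 0)
    }
  }
})

test_that("the benchmark report is structurally complete and deterministic", {
  rep <- runBenchmark(nPerClass = 60L, seeds = 1:2)
  expect_length(accuracies(rep), 9L)
  expect_identical(dim(lossMatrix(rep)), c(9L, 9L))
  expect_true(all(is.na(diag(lossMatrix(rep)))))
  expect_equal(accuracies(rep) + errorRates(rep), rep_len(100, 9),
               ignore_attr = TRUE)

  ## identical configurations under the same seeds agree exactly
  rep2 <- runBenchmark(models = c("LIF", "LIF"), nPerClass = 60L, seeds = 1:2)
  expect_identical(accuracies(rep2)[[1]], accuracies(rep2)[[2]])
})

test_that("seed-averaged accuracies concentrate around the per-seed values", {
  rep <- runBenchmark(models = "LIF", nPerClass = 200L, seeds = 1:6)
  perSeed <- rep@perSeed[, 1]
  expect_lt(abs(mean(perSeed) - accuracies(rep)[["LIF"]]), 1e-12)
  expect_lt(sd(perSeed), 5)
})

test_that("population mapping with random weights yields valid predictions", {
  ds <- generateDataset(15L, seed = 9)
  m <- makeModel("LIF", regime = "benchmark")
  pred <- classifyDataset(m, ds, mapping = "population", nNeurons = 40L,
                          weightSeed = 3L)
  expect_length(pred, 30L)
  expect_true(all(pred %in% c(0L, 1L)))
  ## reproducible under the same weight seed
  pred2 <- classifyDataset(m, ds, mapping = "population", nNeurons = 40L,
                           weightSeed = 3L)
  expect_identical(pred, pred2)
})

test_that("benchmark outputs serialise to metrics, loss matrix and JSON report", {
  rep <- runBenchmark(models = c("LIF", "Izhikevich"), nPerClass = 40L,
                      seeds = 1:2)
  d <- file.path(tempdir(), "benchout")
  writeEvaluationReport(rep, d)
  metrics <- read.csv(file.path(d, "metrics.csv"))
  expect_identical(names(metrics), c("model", "accuracy_pct", "error_pct"))
  expect_identical(nrow(metrics), 2L)
  expect_true(file.exists(file.path(d, "loss_matrix.csv")))
  js <- jsonlite::read_json(file.path(d, "report.json"))
  expect_identical(length(js$accuracy), 2L)
  expect_identical(unlist(js$seeds), 1:2)
  unlink(d, recursive = TRUE)
})
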