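test_that("LOEO folds partition observations by environment", {
  ds <- tinyDataset()
  folds <- loeoFolds(ds)
  expect_length(folds, 3)
  obs <- observations(ds)
  test_sets <- lapply(folds, `[[`, "testRows")
  expect_equal(sort(unname(unlist(test_sets))), seq_len(nrow(obs)))
  for (f in folds) {
    expect_false(f$testEnv %in% obs$env[f$trainRows])
    expect_true(all(obs$env[f$testRows] == f$testEnv))
    expect_length(intersect(f$trainRows, f$testRows), 0)
  }
  one_env <- new("MetDataset",
                 observations = obs[obs$env == "E1", ],
                 markers = markers(ds), envCovariates = envCovariates(ds),
                 indices = msIndices(ds)[obs$env == "E1", , drop = FALSE],
                 traits = traitNames(ds), truth = NULL)
  expect_error(loeoFolds(one_env), "at least 2")
})

test_that("nrmse matches hand calculations and is scale-free", {
  expect_equal(nrmse(c(2, 2), c(2, 2)), 0)
  expect_equal(nrmse(c(1, 3), c(2, 2)), 50)
  # scaling both vectors leaves the mean-normalized value unchanged
  set.seed(2)
  y <- runif(20, 5, 10); p <- y + rnorm(20)
  expect_equal(nrmse(3 * y, 3 * p), nrmse(y, p))
  expect_equal(nrmse(y, p, "sd"),
               100 * sqrt(mean((y - p)^2)) / sd(y))
  expect_equal(nrmse(y, p, "range"),
               100 * sqrt(mean((y - p)^2)) / diff(range(y)))
  expect_error(nrmse(c(-1, 1), c(0, 0)), "zero")
  expect_error(nrmse(1:3, 1:2), "length")
})

test_that("relative efficiency is oriented so better models gain", {
  expect_equal(relativeEfficiency(2.82, 4.34), (4.34 / 2.82 - 1) * 100)
  expect_equal(relativeEfficiency(3, 3), 0)
  # strictly decreasing in the model's NRMSE at fixed reference
  grid <- seq(1, 5, by = 0.5)
  re <- relativeEfficiency(grid, 5)
  expect_true(all(diff(re) < 0))
  # the printed orientation gives the negated-ratio form
  expect_equal(relativeEfficiency(2, 4, printedOrientation = TRUE), -50)
  expect_error(relativeEfficiency(0, 4), "positive")
})

test_that("win counts follow strict NRMSE dominance with ties void", {
  cells <- data.frame(
    dataset = "d", trait = "t1", environment = "e1",
    model = c("A", "B"), nrmse = c(1, 2))
  wc <- winCounts(cells)
  expect_equal(wc$byEnv$wins[wc$byEnv$model == "A"], 1L)
  expect_equal(wc$byEnv$wins[wc$byEnv$model == "B"], 0L)

  # no ties: total wins in one cell group = choose(m, 2)
  set.seed(3)
  m <- 6
  cells2 <- data.frame(dataset = "d", trait = "t", environment = "e",
                       model = paste0("M", 1:m), nrmse = sample(m))
  expect_equal(sum(winCounts(cells2)$byEnv$wins), choose(m, 2))

  # all-tie grid scores nothing
  cells3 <- data.frame(dataset = "d",
                       trait = rep(c("t1", "t2"), each = 2),
                       environment = "e",
                       model = rep(c("A", "B"), 2), nrmse = 1)
  expect_true(all(winCounts(cells3)$byEnv$wins == 0))

  # a genuinely missing cell (model present elsewhere) is an error
  cells4 <- data.frame(dataset = "d",
                       trait = rep(c("t1", "t2"), each = 2),
                       environment = "e",
                       model = rep(c("A", "B"), 2),
                       nrmse = c(1, 2, 3, 4))
  expect_error(winCounts(cells4[-1, ]), "incomplete")
})

test_that("across-dataset aggregation averages summary columns", {
  s <- data.frame(dataset = rep(c("d1", "d2"), each = 2),
                  model = rep(c("A", "B"), 2),
                  nrmse = c(2, 3, 4, 5), re = c(10, 0, 20, 0))
  agg <- aggregateAcrossDatasets(s)
  expect_equal(agg$nrmse[agg$model == "A"], 3)
  expect_equal(agg$re[agg$model == "A"], 15)
  # single dataset: identity
  one <- aggregateAcrossDatasets(s[s$dataset == "d1", ])
  expect_equal(one$nrmse, c(2, 3))
  # identical summaries aggregate to themselves
  same <- rbind(s[1:2, ], transform(s[1:2, ], dataset = "d9"))
  agg2 <- aggregateAcrossDatasets(same)
  expect_equal(agg2$nrmse, s$nrmse[1:2])
  expect_error(aggregateAcrossDatasets(s[-1, ]), "missing from dataset")
})

test_that("report invariants hold: worst model at zero RE, M0 anchored", {
  cells <- expand.grid(dataset = "d", trait = c("t1", "t2"),
                       environment = c("e1", "e2"),
                       model = c("M0", "M6", "M7"),
                       stringsAsFactors = FALSE)
  set.seed(8)
  cells$nrmse <- runif(nrow(cells), 1, 6)
  rep <- summarizeCells(cells)
  s <- cvSummary(rep)
  expect_equal(s$re[which.max(s$nrmse)], 0)
  expect_true(all(s$re >= 0))
  expect_equal(s$reM0[s$model == "M0"], 0)
})

test_that("a small LOEO study runs end to end, deterministically", {
  cfg <- simConfig(nEnvs = 3, nLines = 15, nMarkers = 20, nDays = 3,
                   nTraits = 2, seed = 91)
  ds <- simulateMet(cfg)
  r1 <- runStudy(ds, modelIds = "M0", traits = c("trait1", "trait2"),
                 mcmc = list(nIter = 400, burnIn = 100, thin = 2),
                 seed = 5)
  cells <- cvCells(r1)
  expect_equal(nrow(cells), 3 * 2)  # folds x traits for one model
  expect_true(all(is.finite(cells$nrmse) & cells$nrmse >= 0))
  r2 <- runStudy(ds, modelIds = "M0", traits = c("trait1", "trait2"),
                 mcmc = list(nIter = 400, burnIn = 100, thin = 2),
                 seed = 5)
  expect_identical(cvCells(r1), cvCells(r2))
  expect_identical(cvSummary(r1), cvSummary(r2))
})

test_that("test-fold responses never leak into selection or scaling", {
  cfg <- simConfig(nEnvs = 4, nLines = 20, nMarkers = 25, nDays = 4,
                   nTraits = 1, nInformativeEcs = 2, betaEc = 2, seed = 95)
  ds <- simulateMet(cfg)
  obs <- observations(ds)
  fold <- loeoFolds(ds)[[1]]
  corrupt <- ds
  corrupt@observations$trait1[fold$testRows] <- 9999

  s1 <- selectForModel("M3", ds, "trait1", fold$trainRows, seed = 3)
  s2 <- selectForModel("M3", corrupt, "trait1", fold$trainRows, seed = 3)
  expect_identical(selectedColumns(s1), selectedColumns(s2))
  expect_identical(thresholdUsed(s1), thresholdUsed(s2))

  b1 <- selectForModel("M13", ds, "trait1", fold$trainRows, seed = 3,
                       borutaIter = 8, borutaTrees = 50)
  b2 <- selectForModel("M13", corrupt, "trait1", fold$trainRows, seed = 3,
                       borutaIter = 8, borutaTrees = 50)
  expect_identical(borutaStatus(b1), borutaStatus(b2))

  # standardization statistics come from training rows only
  z1 <- standardizeMatrix(msIndices(ds), fold$trainRows)
  z2 <- standardizeMatrix(msIndices(corrupt), fold$trainRows)
  expect_identical(z1@columnMeans, z2@columnMeans)
  expect_identical(z1@columnScales, z2@columnScales)

  # and the assembled specs differ in nothing except the masked response
  spec1 <- assembleModelSpec("M6", ds, "trait1", fold$trainRows, s1,
                             mcmc = fastMcmc(1))
  spec2 <- assembleModelSpec("M6", corrupt, "trait1", fold$trainRows, s2,
                             mcmc = fastMcmc(1))
  expect_equal(spec1@rkhsTerms, spec2@rkhsTerms)
  expect_equal(spec1@ridgeTerms, spec2@ridgeTerms)
  expect_equal(spec1@y[fold$trainRows], spec2@y[fold$trainRows])
})
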