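test_that("generated datasets honour the shape contract", {
  cfg <- simConfig(nEnvs = 4, nLines = 50, nMarkers = 100, nDays = 10,
                   seed = 1)
  ds <- simulateMet(cfg)
  expect_s4_class(ds, "MetDataset")
  expect_equal(ncol(envCovariates(ds)), 14 * 10)
  expect_equal(dim(markers(ds)), c(50, 100))
  obs <- observations(ds)
  expect_false(anyDuplicated(obs[, c("env", "line")]) > 0)
  expect_equal(nrow(msIndices(ds)), nrow(obs))
  expect_equal(traitNames(ds), c("trait1", "trait2", "trait3"))
  expect_true(all(obs$line %in% rownames(markers(ds))))
  expect_true(all(obs$env %in% rownames(envCovariates(ds))))
  # every line appears at least once
  expect_setequal(unique(obs$line), rownames(markers(ds)))
})

test_that("same seed gives identical datasets, different seeds differ", {
  cfg <- simConfig(nEnvs = 3, nLines = 20, nMarkers = 30, nDays = 5,
                   seed = 7)
  d1 <- simulateMet(cfg)
  d2 <- simulateMet(cfg)
  expect_identical(observations(d1), observations(d2))
  expect_identical(markers(d1), markers(d2))
  expect_identical(envCovariates(d1), envCovariates(d2))
  cfg2 <- simConfig(nEnvs = 3, nLines = 20, nMarkers = 30, nDays = 5,
                    seed = 8)
  expect_false(identical(observations(simulateMet(cfg2)),
                         observations(d1)))
})

test_that("genotype-only variance flows into the phenotype", {
  # all variance from the genomic term: var(y) approx varG over replicates
  vg <- 2
  vars <- vapply(1:200, function(s) {
    cfg <- simConfig(nEnvs = 2, nLines = 80, nMarkers = 40, nDays = 2,
                     nWeatherVars = 3, nTraits = 1,
                     nInformativeEcs = 0, betaEc = numeric(0),
                     varE = 0, varG = vg, varGE = 0, varEps = 0,
                     betaM = c(0, 0, 0), indexSignal = 0, seed = 5000 + s)
    var(observations(simulateMet(cfg))$trait1)
  }, numeric(1))
  # E var(y) = varG * mean(diag K_g) = varG * (J-1)/J under sample-sd scaling
  expect_equal(mean(vars), vg * 79 / 80, tolerance = 0.1)
})

test_that("marker frequencies respect the minor-allele floor", {
  cfg <- simConfig(nEnvs = 2, nLines = 1500, nMarkers = 300, nDays = 2,
                   nWeatherVars = 2, nInformativeEcs = 2, seed = 3)
  M <- markers(simulateMet(cfg))
  maf <- colMeans(M) / 2
  maf <- pmin(maf, 1 - maf)
  expect_true(all(maf >= 0.05 - 0.025))  # binomial tolerance at J = 1500
  expect_true(all(M %in% 0:2))
})

test_that("generating kernels are symmetric PSD", {
  cfg <- simConfig(nEnvs = 5, nLines = 30, nMarkers = 60, nDays = 6,
                   seed = 9)
  ds <- simulateMet(cfg)
  obs <- observations(ds)
  He <- envRelationship(standardizeMatrix(envCovariates(ds)))
  Kg <- genomicKernel(standardizeMatrix(markers(ds)))
  Ze <- envDesign(obs$env, sort(rownames(envCovariates(ds))))
  Zg <- genoDesign(obs$line, sort(rownames(markers(ds))))
  Kgec <- interactionKernel(expandedEnvKernel(Ze, He), Zg, Kg)
  for (K in list(He, Kg, Kgec)) {
    expect_equal(K, t(K), tolerance = 1e-10)
    expect_true(min(eigen(K, symmetric = TRUE,
                          only.values = TRUE)$values) >= -1e-8)
  }
})

test_that("planted covariate effects are recoverable by regression", {
  # complete design: line effects are absorbed into the intercept of an
  # environment-mean regression, so OLS standard errors are honest
  hits <- 0L; total <- 0L
  for (s in 1:10) {
    cfg <- simConfig(nEnvs = 40, nLines = 50, nMarkers = 80, nDays = 10,
                     nTraits = 1, envsPerLine = 40,
                     nInformativeEcs = 5, betaEc = 0.5,
                     varE = 0, varG = 1, varGE = 0, varEps = 1,
                     betaM = c(0, 0, 0), indexSignal = 0, seed = 400 + s)
    ds <- simulateMet(cfg)
    tru <- datasetTruth(ds)
    obs <- observations(ds)
    expect_equal(nrow(obs), 2000)
    ybar <- tapply(obs$trait1, obs$env, mean)
    Xs <- standardizeMatrix(envCovariates(ds))@values[
      names(ybar), tru$informativeColumns, drop = FALSE]
    fit <- lm(ybar ~ Xs)
    est <- coef(fit)[-1]
    se <- sqrt(diag(vcov(fit)))[-1]
    hits <- hits + sum(abs(est - tru$betaEc) <= 2 * se)
    total <- total + length(est)
  }
  expect_gte(hits / total, 0.85)  # nominal 95% coverage
})

test_that("truth records the generating parameters", {
  cfg <- simConfig(nEnvs = 3, nLines = 15, nMarkers = 20, nDays = 4,
                   nInformativeEcs = 3, seed = 2)
  tru <- datasetTruth(simulateMet(cfg))
  expect_length(tru$informativeColumns, 3)
  expect_true(all(tru$informativeColumns %in%
                    colnames(envCovariates(simulateMet(cfg)))))
  expect_equal(unname(tru$varComponents),
               c(cfg$varE, cfg$varG, cfg$varGE, cfg$varEps))
  expect_named(tru$perTrait, traitNames(simulateMet(cfg)))
})

test_that("splitByYear partitions observations and restricts markers", {
  cfg <- simConfig(nEnvs = 6, nLines = 30, nMarkers = 25, nDays = 4,
                   replication = 0.5, seed = 21)
  ds <- simulateMet(cfg)
  groups <- setNames(rep(c("y1", "y2"), each = 3),
                     sort(rownames(envCovariates(ds))))
  parts <- splitByYear(ds, groups)
  expect_named(parts, c("y1", "y2"))
  expect_equal(sum(vapply(parts, function(p) nrow(observations(p)),
                          numeric(1))),
               nrow(observations(ds)))
  # union of observations equals input
  all_obs <- do.call(rbind, lapply(parts, observations))
  o1 <- all_obs[order(all_obs$env, all_obs$line), ]
  o2 <- observations(ds)[order(observations(ds)$env,
                               observations(ds)$line), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2)
  # a line present in both groups appears in both marker submatrices
  shared <- intersect(observations(parts$y1)$line,
                      observations(parts$y2)$line)
  for (ln in shared) {
    expect_true(ln %in% rownames(markers(parts$y1)))
    expect_true(ln %in% rownames(markers(parts$y2)))
  }
  # one group: identity
  one <- splitByYear(ds, setNames(rep("all", 6),
                                  sort(rownames(envCovariates(ds)))))
  expect_length(one, 1)
  expect_equal(observations(one$all), observations(ds))
  expect_error(splitByYear(ds, groups[-1]), "without a group")
})

test_that("infeasible configurations are rejected", {
  expect_error(simConfig(nEnvs = 1, nLines = 5, nMarkers = 5, seed = 1),
               "nEnvs")
  expect_error(simConfig(nEnvs = 3, nLines = 5, nMarkers = 5,
                         varG = -1, seed = 1), "variances")
  expect_error(simConfig(nEnvs = 3, nLines = 5, nMarkers = 5,
                         replication = 1.5, seed = 1), "replication")
  expect_error(simConfig(nEnvs = 3, nLines = 5, nMarkers = 5, nDays = 2,
                         nWeatherVars = 2, nInformativeEcs = 10,
                         seed = 1), "exceeds")
  expect_error(simConfig(nEnvs = 3, nLines = 5, nMarkers = 5,
                         envsPerLine = 7, seed = 1), "envsPerLine")
  expect_error(simConfig(nEnvs = 3, nLines = 5, nMarkers = 5), "seed")
})
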