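test_that("intercept-only fit on a zero signal predicts zero", {
  spec <- kernelModelSpec(y = rep(0, 4), trainRows = 1:4,
                          mcmc = fastMcmc(3))
  fit <- fitKernelModel(spec)
  expect_true(all(abs(predictions(fit)) < 0.05))
})

test_that("fixed-variance ridge matches the conjugate closed form", {
  set.seed(42)
  n <- 25; q <- 3
  X <- matrix(rnorm(n * q), n, q, dimnames = list(NULL, paste0("b", 1:q)))
  y <- drop(X %*% c(1, -0.5, 0.25)) + rnorm(n, sd = 0.5)
  s2 <- 0.25; s2b <- 1
  spec <- kernelModelSpec(
    ridgeTerms = list(X = X), y = y, trainRows = 1:n,
    mcmc = list(nIter = 6000, burnIn = 1000, thin = 2, seed = 7),
    fixedVariances = c(X = s2b, residual = s2))
  fit <- fitKernelModel(spec)
  # flat-prior intercept integrates to the centered ridge solution
  Xc <- scale(X, scale = FALSE)
  bhat <- solve(crossprod(Xc) / s2 + diag(q) / s2b,
                crossprod(Xc, y - mean(y)) / s2)
  est <- posteriorMeans(fit)$coefficients$X
  se <- fit@diagnostics$coefficientMCSE$X
  expect_true(all(abs(est - drop(bhat)) <= 3 * se))
})

test_that("identity-kernel RKHS equals ridge on indicators", {
  set.seed(10)
  n <- 20
  y <- rnorm(n, sd = 1.5)
  s2 <- 0.5; s2u <- 2
  spec <- kernelModelSpec(
    rkhsTerms = list(u = diag(n)), y = y, trainRows = 1:n,
    mcmc = list(nIter = 8000, burnIn = 2000, thin = 2, seed = 11),
    fixedVariances = c(u = s2u, residual = s2))
  fit <- fitKernelModel(spec)
  # oracle: u | y with flat intercept integrated out
  Pc <- diag(n) - matrix(1 / n, n, n)
  u_hat <- solve(Pc / s2 + diag(n) / s2u, Pc %*% y / s2)
  est <- posteriorMeans(fit)$effects$u
  expect_equal(unname(est), drop(u_hat), tolerance = 0.12)
  # predictions are intercept + effect
  expect_equal(predictions(fit),
               posteriorMeans(fit)$intercept + est, tolerance = 1e-8)
})

test_that("held-out predictions use the kernel conditional mean", {
  # strong-signal sanity: training predictions track the response
  set.seed(15)
  cfg <- simConfig(nEnvs = 4, nLines = 25, nMarkers = 60, nDays = 4,
                   nTraits = 1, varG = 2, varEps = 0.3, seed = 16)
  ds <- simulateMet(cfg)
  obs <- observations(ds)
  n <- nrow(obs)
  lines <- sort(rownames(markers(ds)))
  Zg <- genoDesign(obs$line, lines)
  Kg_obs <- Zg %*% genomicKernel(standardizeMatrix(markers(ds)[lines, ])) %*%
    t(Zg)
  tr <- which(obs$env != "env01")
  spec <- kernelModelSpec(rkhsTerms = list(g = Kg_obs), y = obs$trait1,
                          trainRows = tr, mcmc = fastMcmc(17))
  fit <- fitKernelModel(spec)
  expect_gt(cor(predict(fit, tr), obs$trait1[tr]), 0.5)
  # held-out rows get finite, non-degenerate predictions
  te <- setdiff(seq_len(n), tr)
  expect_true(all(is.finite(predict(fit, te))))
})

test_that("row permutation permutes the posterior predictions", {
  # the posterior is permutation-equivariant; individual chains are
  # not bitwise so, because the eigenbasis reorders the random draws —
  # agreement is therefore asserted within joint Monte-Carlo error
  set.seed(20)
  n <- 15
  K <- crossprod(matrix(rnorm(n * n), n)) / n
  X <- matrix(rnorm(n * 2), n, 2)
  y <- rnorm(n)
  long <- list(nIter = 6000, burnIn = 1000, thin = 2, seed = 21)
  f1 <- fitKernelModel(kernelModelSpec(
    rkhsTerms = list(k = K), ridgeTerms = list(x = X),
    y = y, trainRows = 1:n, mcmc = long))
  ord <- sample(n)
  f2 <- fitKernelModel(kernelModelSpec(
    rkhsTerms = list(k = K[ord, ord]),
    ridgeTerms = list(x = X[ord, , drop = FALSE]),
    y = y[ord], trainRows = 1:n, mcmc = long))
  joint_se <- sqrt(f1@diagnostics$predictionMCSE[ord]^2 +
                     f2@diagnostics$predictionMCSE^2)
  expect_gte(mean(abs(predictions(f2) - predictions(f1)[ord]) <=
                    3 * joint_se), 0.95)
})

test_that("chains with different seeds agree within Monte-Carlo error", {
  set.seed(23)
  n <- 20
  K <- crossprod(matrix(rnorm(n * n), n)) / n
  y <- rnorm(n)
  mk <- function(seed) kernelModelSpec(
    rkhsTerms = list(k = K), y = y, trainRows = 1:n,
    mcmc = list(nIter = 6000, burnIn = 1000, thin = 2, seed = seed))
  f1 <- fitKernelModel(mk(1))
  f2 <- fitKernelModel(mk(2))
  joint_se <- sqrt(f1@diagnostics$predictionMCSE^2 +
                     f2@diagnostics$predictionMCSE^2)
  # per-row agreement at 3 joint MC standard errors (autocorrelation
  # makes the naive se slightly optimistic; allow a single exceedance)
  expect_gte(mean(abs(predictions(f1) - predictions(f2)) <=
                    3 * joint_se), 0.95)
})

test_that("invalid specifications are rejected", {
  y <- rnorm(6)
  expect_error(
    fitKernelModel(kernelModelSpec(y = y, trainRows = 1:6,
                                   mcmc = list(nIter = 100, burnIn = 200))),
    "nIter")
  bad <- diag(6); bad[1, 1] <- -5
  expect_error(
    fitKernelModel(kernelModelSpec(rkhsTerms = list(b = bad), y = y,
                                   trainRows = 1:6, mcmc = fastMcmc(1))),
    "not PSD")
  expect_error(
    kernelModelSpec(y = c(NA, y[-1]), trainRows = 1:6,
                    mcmc = fastMcmc(1)),
    "observed y")
})

test_that("variance components are recovered on moderate simulated data", {
  # single-seed spot check; the averaged version runs in the acceptance suite
  cfg <- simConfig(nEnvs = 6, nLines = 60, nMarkers = 120, nDays = 6,
                   nTraits = 1, envsPerLine = 3,
                   nInformativeEcs = 0, betaEc = numeric(0),
                   varE = 1, varG = 1, varGE = 0.5, varEps = 1,
                   betaM = c(0, 0, 0), indexSignal = 0, seed = 61)
  ds <- simulateMet(cfg)
  obs <- observations(ds)
  envs <- sort(rownames(envCovariates(ds)))
  lines <- sort(rownames(markers(ds)))
  Ze <- envDesign(obs$env, envs)
  Zg <- genoDesign(obs$line, lines)
  He <- envRelationship(standardizeMatrix(envCovariates(ds)))
  Kg <- genomicKernel(standardizeMatrix(markers(ds)[lines, ]))
  Kec <- expandedEnvKernel(Ze, He)
  spec <- kernelModelSpec(
    rkhsTerms = list(env = Kec, geno = Zg %*% Kg %*% t(Zg),
                     ge = interactionKernel(Kec, Zg, Kg)),
    y = obs$trait1, trainRows = seq_len(nrow(obs)),
    mcmc = list(nIter = 2500, burnIn = 500, thin = 2, seed = 62))
  v <- posteriorMeans(fitKernelModel(spec))$variances
  expect_true(all(v > 0))
  # residual is well-identified at n = 180
  expect_lt(abs(v[["residual"]] - 1), 0.6)
})
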