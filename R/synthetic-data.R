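#' @include AllClasses.R kernels.R
NULL

#' Configuration for the synthetic MET generator
#'
#' Describes one simulated multi-environment trial: its dimensions, the
#' weather-covariate structure, which covariates carry signal, the
#' variance components of the generating model and the multispectral
#' index coefficients. All randomness flows from `seed`.
#'
#' The generating model for each trait is
#' `Y_ij = mu + E_i + g_j + gE_ij + sum_k X_ik beta_k +
#'  sum_l M_ijl beta_Ml + eps_ij`
#' with `E ~ N(0, varE * H_e)`, `g ~ N(0, varG * K_g)`,
#' `gE ~ N(0, varGE * K_gec)` and i.i.d. Gaussian error, the kernels
#' built from the generated markers and covariates themselves.
#'
#' @param nEnvs number of environments (>= 2).
#' @param nLines number of lines.
#' @param nMarkers number of SNP markers.
#' @param nWeatherVars daily weather variables measured per environment
#'   (default 14: the usual station set of temperatures, humidity, soil
#'   measurements, precipitation, radiation and evapotranspiration).
#' @param nDays days in the growing season; covariate columns are one
#'   per variable x day (default 207).
#' @param replication fraction of lines observed in more than one
#'   environment (every line appears in at least one). Ignored when
#'   `envsPerLine` is set.
#' @param envsPerLine optional: every line is observed in exactly this
#'   many (randomly chosen) environments, for balanced or
#'   densely-replicated layouts; `NA` (default) uses the
#'   `replication` lottery.
#' @param nInformativeEcs number of covariate columns that enter the
#'   phenotype linearly.
#' @param betaEc effect sizes of the informative columns (on the
#'   standardized covariate scale); recycled to `nInformativeEcs`.
#' @param varE,varG,varGE,varEps variance components of the generating
#'   model (environment, genotype, genotype-by-environment, residual).
#' @param betaM the three multispectral index coefficients.
#' @param indexSignal gamma: how strongly the indices track the true
#'   genetic-plus-environment signal (0 = pure noise).
#' @param indexNoiseSd standard deviation of index noise.
#' @param mafMin minor-allele-frequency floor for simulated loci.
#' @param arCorr day-to-day AR(1) correlation of each weather series,
#'   so adjacent daily columns are collinear as real weather is.
#' @param nTraits number of traits generated (independent random
#'   effects, shared markers/covariates/signal columns).
#' @param mu grand mean.
#' @param seed integer seed (required).
#' @return a validated list of class `SimConfig`.
#' @examples
#' cfg <- simConfig(nEnvs = 4, nLines = 50, nMarkers = 100,
#'                  nDays = 10, seed = 1)
#' @export
simConfig <- function(nEnvs, nLines, nMarkers,
                      nWeatherVars = 14L, nDays = 207L,
                      replication = 0.25, envsPerLine = NA_integer_,
                      nInformativeEcs = 10L, betaEc = 0.3,
                      varE = 0.3, varG = 1, varGE = 0.2, varEps = 1,
                      betaM = c(0.2, 0.2, 0.2),
                      indexSignal = 0.7, indexNoiseSd = 1,
                      mafMin = 0.05, arCorr = 0.9,
                      nTraits = 3L, mu = 10, seed) {
  if (missing(seed)) stop("seed is required")
  r <- nWeatherVars * nDays
  if (nEnvs < 2) stop("nEnvs must be >= 2")
  if (any(c(varE, varG, varGE, varEps) < 0)) stop("variances must be >= 0")
  if (nInformativeEcs > r) {
    stop("nInformativeEcs exceeds the number of covariate columns (", r, ")")
  }
  if (replication < 0 || replication > 1) {
    stop("replication must lie in [0, 1]")
  }
  if (!is.na(envsPerLine) && (envsPerLine < 1 || envsPerLine > nEnvs)) {
    stop("envsPerLine must lie in [1, nEnvs]")
  }
  if (mafMin < 0 || mafMin >= 0.5) stop("mafMin must lie in [0, 0.5)")
  if (length(betaM) != 3L) stop("betaM must have length 3")
  cfg <- list(nEnvs = as.integer(nEnvs), nLines = as.integer(nLines),
              nMarkers = as.integer(nMarkers),
              nWeatherVars = as.integer(nWeatherVars),
              nDays = as.integer(nDays),
              replication = replication,
              envsPerLine = as.integer(envsPerLine),
              nInformativeEcs = as.integer(nInformativeEcs),
              betaEc = rep_len(betaEc, nInformativeEcs),
              varE = varE, varG = varG, varGE = varGE, varEps = varEps,
              betaM = betaM, indexSignal = indexSignal,
              indexNoiseSd = indexNoiseSd,
              mafMin = mafMin, arCorr = arCorr,
              nTraits = as.integer(nTraits), mu = mu,
              seed = as.integer(seed))
  class(cfg) <- "SimConfig"
  cfg
}

# draw from N(0, sigma2 * K) via Cholesky with a small ridge
rmvnKernel <- function(sigma2, K) {
  n <- nrow(K)
  if (sigma2 <= 0) return(numeric(n))
  U <- chol(K + diag(1e-8, n))
  drop(t(U) %*% stats::rnorm(n)) * sqrt(sigma2)
}

#' Generate a synthetic multi-environment trial data set
#'
#' Draws markers, daily weather covariates, an unbalanced line x
#' environment layout, multispectral indices and phenotypes from the
#' generating model described in [simConfig()], and records the ground
#' truth (informative columns, effect sizes, realized random effects)
#' for recovery tests.
#'
#' Markers are {0, 1, 2} allele counts with per-locus allele frequency
#' uniform on `[mafMin, 0.5]`. Each weather variable is an AR(1)
#' series around an environment-specific level plus a seasonal sine,
#' so day-adjacent columns are correlated. The indices are
#' `gamma * (scaled genetic + environment signal) + noise`, then enter
#' the phenotype through `betaM`, mirroring the premise that phenomic
#' indices are informative about performance.
#'
#' @param config a `SimConfig` from [simConfig()].
#' @return a [MetDataset-class] with `datasetTruth()` populated.
#' @export
simulateMet <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  I <- config$nEnvs; J <- config$nLines; p <- config$nMarkers
  r <- config$nWeatherVars * config$nDays

  envs <- sprintf("env%02d", seq_len(I))
  lines <- sprintf("line%04d", seq_len(J))

  # markers: {0,1,2} allele counts, frequency uniform on [mafMin, 0.5]
  freq <- stats::runif(p, config$mafMin, 0.5)
  M <- matrix(stats::rbinom(J * p, 2L, rep(freq, each = J)), J, p,
              dimnames = list(lines, sprintf("snp%05d", seq_len(p))))

  # daily weather: env level + seasonal sine + AR(1) noise per variable
  phi <- config$arCorr
  day_frac <- seq_len(config$nDays) / config$nDays
  X <- matrix(0, I, r)
  cn <- character(r)
  col <- 0L
  for (v in seq_len(config$nWeatherVars)) {
    phase <- stats::runif(1, 0, 2 * pi)
    season <- 0.5 * sin(2 * pi * day_frac + phase)
    idx <- col + seq_len(config$nDays)
    cn[idx] <- sprintf("var%02d_d%03d", v, seq_len(config$nDays))
    for (i in seq_len(I)) {
      level <- stats::rnorm(1)
      e <- numeric(config$nDays)
      e[1] <- stats::rnorm(1)
      if (config$nDays > 1) {
        z <- stats::rnorm(config$nDays - 1)
        for (d in 2:config$nDays) {
          e[d] <- phi * e[d - 1] + sqrt(1 - phi^2) * z[d - 1]
        }
      }
      X[i, idx] <- level + season + e
    }
    col <- col + config$nDays
  }
  dimnames(X) <- list(envs, cn)

  # layout: either a fixed number of environments per line, or one
  # home environment with a second added by lottery (unbalanced)
  home <- rep_len(seq_len(I), J)
  resample <- function(x, k) x[sample.int(length(x), k)]
  if (!is.na(config$envsPerLine)) {
    k <- config$envsPerLine
    env_sets <- lapply(seq_len(J), function(j) {
      if (k >= I) seq_len(I) else
        sort(c(home[j], resample(setdiff(seq_len(I), home[j]), k - 1L)))
    })
  } else {
    env_sets <- lapply(seq_len(J), function(j) {
      s <- home[j]
      if (I > 1 && stats::runif(1) < config$replication) {
        s <- c(s, resample(setdiff(seq_len(I), s), 1L))
      }
      sort(s)
    })
  }
  obs <- data.frame(
    env = envs[unlist(env_sets)],
    line = rep(lines, lengths(env_sets)),
    stringsAsFactors = FALSE
  )
  obs <- obs[order(obs$env, obs$line), , drop = FALSE]
  rownames(obs) <- NULL
  n <- nrow(obs)

  # kernels of the generating model, built from the generated data
  Xs <- standardizeMatrix(X)
  He <- envRelationship(Xs)
  Kg <- genomicKernel(standardizeMatrix(M))
  Ze <- envDesign(obs$env, envs)
  Zg <- genoDesign(obs$line, lines)
  Kec <- expandedEnvKernel(Ze, He)
  Kgec <- interactionKernel(Kec, Zg, Kg)

  # informative covariate columns act through the standardized scale
  inf_cols <- sort(sample(colnames(Xs@values), config$nInformativeEcs))
  beta_ec <- stats::setNames(config$betaEc, inf_cols)
  ec_env <- drop(Xs@values[, inf_cols, drop = FALSE] %*% beta_ec)

  env_of <- match(obs$env, envs)
  line_of <- match(obs$line, lines)

  traits <- sprintf("trait%d", seq_len(config$nTraits))
  per_trait <- vector("list", config$nTraits)
  names(per_trait) <- traits
  signals <- matrix(0, n, config$nTraits)
  for (t in seq_along(traits)) {
    E <- rmvnKernel(config$varE, He)
    g <- rmvnKernel(config$varG, Kg)
    gE <- rmvnKernel(config$varGE, Kgec)
    signals[, t] <- E[env_of] + g[line_of] + gE + ec_env[env_of]
    per_trait[[t]] <- list(E = stats::setNames(E, envs),
                           g = stats::setNames(g, lines),
                           gE = gE)
  }
  # one shared index triple per plot, tracking the first trait's signal
  ssd <- stats::sd(signals[, 1])
  sc <- if (is.finite(ssd) && ssd > 0) signals[, 1] / ssd else signals[, 1] * 0
  idx_all <- config$indexSignal * matrix(sc, n, 3) +
    matrix(stats::rnorm(n * 3, sd = config$indexNoiseSd), n, 3)
  dimnames(idx_all) <- list(NULL, paste0("index", 1:3))
  for (t in seq_along(traits)) {
    eps <- stats::rnorm(n, sd = sqrt(config$varEps))
    obs[[traits[t]]] <- config$mu + signals[, t] +
      drop(idx_all %*% config$betaM) + eps
  }

  truth <- list(
    config = config,
    informativeColumns = inf_cols,
    betaEc = beta_ec,
    betaM = config$betaM,
    varComponents = c(varE = config$varE, varG = config$varG,
                      varGE = config$varGE, varEps = config$varEps),
    mu = config$mu,
    perTrait = per_trait
  )

  new("MetDataset",
      observations = obs,
      markers = M,
      envCovariates = X,
      indices = idx_all,
      traits = traits,
      truth = truth)
}

#' Split a MET data set into groups of environments
#'
#' Partitions a data set by an environment-to-group mapping (e.g.
#' harvest years), restricting the marker matrix of each part to the
#' lines actually present. The union of the parts equals the input.
#'
#' @param dataset a [MetDataset-class].
#' @param groups named character/factor: names are environment ids,
#'   values are group labels. Every environment must be assigned.
#' @return named list of [MetDataset-class] objects, one per group.
#' @export
splitByYear <- function(dataset, groups) {
  envs <- envLevels(dataset)
  missing_envs <- setdiff(envs, names(groups))
  if (length(missing_envs)) {
    stop("environments without a group: ", paste(missing_envs, collapse = ", "))
  }
  unknown <- setdiff(names(groups), rownames(envCovariates(dataset)))
  if (length(unknown)) {
    stop("unknown environments in groups: ", paste(unknown, collapse = ", "))
  }
  obs <- observations(dataset)
  out <- lapply(split(envs, unname(groups[envs])), function(genvs) {
    keep <- obs$env %in% genvs
    sub_obs <- obs[keep, , drop = FALSE]
    rownames(sub_obs) <- NULL
    sub_lines <- sort(unique(sub_obs$line))
    truth <- dataset@truth
    if (!is.null(truth)) {
      truth$perTrait <- lapply(truth$perTrait, function(tt) {
        list(E = tt$E[genvs], g = tt$g[sub_lines], gE = tt$gE[keep])
      })
    }
    new("MetDataset",
        observations = sub_obs,
        markers = dataset@markers[sub_lines, , drop = FALSE],
        envCovariates = dataset@envCovariates[genvs, , drop = FALSE],
        indices = dataset@indices[keep, , drop = FALSE],
        traits = dataset@traits,
        truth = truth)
  })
  out
}
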