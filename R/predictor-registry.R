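#' @include AllClasses.R kernels.R covariates.R bayes-model.R
NULL

# registry rows:
# envK, geK, Kg, block, selection, tentative, markerSel, kernelsFromMk
.registry <- list(
  M0  = list("K_e",  "K_ge",  TRUE,  "none",    "none", "n/a",   FALSE, FALSE),
  M1  = list("K_e",  "K_ge",  TRUE,  "X_e",     "none", "n/a",   FALSE, FALSE),
  M2  = list("K_ec", "K_gec", TRUE,  "none",    "C",    "n/a",   FALSE, FALSE),
  M3  = list("K_e",  "K_ge",  TRUE,  "X_e",     "C",    "n/a",   FALSE, FALSE),
  M4  = list("K_ec", "K_gec", TRUE,  "X_e",     "C",    "n/a",   FALSE, FALSE),
  M5  = list("K_e",  "K_ge",  TRUE,  "X_e2",    "C",    "n/a",   FALSE, FALSE),
  M6  = list("K_e",  "K_ge",  TRUE,  "X_e.avg", "C",    "n/a",   FALSE, FALSE),
  M7  = list("K_ec", "K_gec", TRUE,  "X_e.avg", "C",    "n/a",   FALSE, FALSE),
  M8  = list("K_ec", "K_gec", TRUE,  "X_e.avg", "C&B",  "n/a",   FALSE, FALSE),
  M9  = list("K_e",  "K_ge",  FALSE, "X_gec",   "B",    "true",  TRUE,  FALSE),
  M10 = list("K_e",  "K_ge",  TRUE,  "X_e",     "B",    "true",  TRUE,  TRUE),
  M11 = list("K_ec", "K_gec", TRUE,  "X_e.avg", "B",    "false", TRUE,  TRUE),
  M12 = list("K_ec", "K_ge",  TRUE,  "X_e.avg", "B",    "true",  FALSE, FALSE),
  M13 = list("K_ec", "K_gec", TRUE,  "X_e.avg", "B",    "true",  FALSE, FALSE),
  M14 = list("K_ec", "K_gec", TRUE,  "X_e.avg", "B",    "false", FALSE, FALSE)
)

#' Look up a predictor configuration
#'
#' Returns the immutable description of one of the fifteen shipped
#' predictor configurations: which environmental and
#' genotype-by-environment kernels it uses, whether the standalone
#' genomic kernel enters, which covariate block it carries, and the
#' covariate-selection method. The multispectral block is part of
#' every predictor.
#'
#' M12 is registered as printed in the published configuration table
#' (interaction kernel `K_ge`); `useProseM12 = TRUE` switches to the
#' alternative reading in which M12 matches M11's `K_gec`.
#'
#' @param modelId one of `"M0"` .. `"M14"`.
#' @param useProseM12 see above.
#' @return a [PredictorConfig-class].
#' @examples
#' predictorConfig("M7")
#' @export
predictorConfig <- function(modelId, useProseM12 = FALSE) {
  if (!modelId %in% names(.registry)) {
    stop("unknown model id '", modelId, "'; valid ids: ",
         paste(names(.registry), collapse = ", "))
  }
  row <- .registry[[modelId]]
  if (modelId == "M12" && useProseM12) row[[2]] <- "K_gec"
  new("PredictorConfig",
      modelId = modelId,
      envKernel = row[[1]], geKernel = row[[2]], includeKg = row[[3]],
      covariateBlock = row[[4]], selection = row[[5]],
      tentative = row[[6]], markerSelection = row[[7]],
      kernelsFromSelectedMarkers = row[[8]],
      includeM = TRUE)
}

#' The full predictor registry as a table
#'
#' @return `data.frame` with one row per predictor, mirroring the
#'   published configuration table.
#' @export
predictorTable <- function() {
  do.call(rbind, lapply(names(.registry), function(id) {
    cfg <- predictorConfig(id)
    data.frame(model = id, envKernel = cfg@envKernel,
               geKernel = cfg@geKernel, includeKg = cfg@includeKg,
               covariates = cfg@covariateBlock, selection = cfg@selection,
               tentative = cfg@tentative,
               markerSelection = cfg@markerSelection,
               kernelsFromSelectedMarkers = cfg@kernelsFromSelectedMarkers,
               multispectral = cfg@includeM,
               stringsAsFactors = FALSE)
  }))
}

#' Build the kernel set for a predictor on one fold
#'
#' Constructs `K_env` (either the incidence kernel `K_e = Z_e Z_e'/I`
#' or the covariate-informed `K_ec = Z_e H_e Z_e'`), the genomic
#' kernel `K_g` and the interaction kernel (`K_env ⊙ Z_g K_g Z_g'`).
#' Environment-level covariates are standardized over the *training*
#' environments only. When a configuration asks for `K_ec`/`K_gec`
#' but the selection is empty, the baseline kernels are used instead
#' (with a warning), so the model degrades gracefully to its
#' no-covariate form.
#'
#' @param config a [PredictorConfig-class].
#' @param dataset a [MetDataset-class].
#' @param trainRows training observation rows of the fold.
#' @param selection a [SelectionResult-class] for this fold.
#' @return a [KernelSet-class].
#' @export
buildKernelSet <- function(config, dataset, trainRows, selection) {
  obs <- observations(dataset)
  envs <- sort(rownames(envCovariates(dataset)))
  lines <- sort(rownames(markers(dataset)))
  Ze <- envDesign(obs$env, envs)
  Zg <- genoDesign(obs$line, lines)

  mk_names <- colnames(markers(dataset))
  sel_mk <- intersect(selectedColumns(selection), mk_names)
  if (config@kernelsFromSelectedMarkers && length(sel_mk)) {
    Mstd <- standardizeMatrix(markers(dataset)[lines, sel_mk, drop = FALSE])
  } else {
    if (config@kernelsFromSelectedMarkers && !length(sel_mk)) {
      warning(config@modelId, ": no markers selected; using all markers")
    }
    Mstd <- standardizeMatrix(markers(dataset)[lines, , drop = FALSE])
  }
  Kg <- genomicKernel(Mstd)

  sel_ec <- intersect(selectedColumns(selection),
                      colnames(envCovariates(dataset)))
  Ke <- baselineEnvKernel(Ze)
  prov <- c(kG = "K_g = M M'/p")
  needs_ec <- config@envKernel == "K_ec" || config@geKernel == "K_gec"
  Kec <- NULL
  if (needs_ec) {
    if (length(sel_ec)) {
      train_envs <- sort(unique(obs$env[trainRows]))
      Xe <- envCovariates(dataset)[envs, sel_ec, drop = FALSE]
      Xe_std <- standardizeMatrix(Xe, match(train_envs, envs))
      He <- envRelationship(Xe_std)
      Kec <- expandedEnvKernel(Ze, He)
    } else {
      warning(config@modelId,
              ": empty covariate selection; falling back to K_e/K_ge")
    }
  }
  if (config@envKernel == "K_ec" && !is.null(Kec)) {
    kEnv <- Kec
    prov["kEnv"] <- "K_ec = Z_e H_e Z_e'"
  } else {
    kEnv <- Ke
    prov["kEnv"] <- "K_e = Z_e Z_e'/I"
  }
  if (config@geKernel == "K_gec" && !is.null(Kec)) {
    kGE <- interactionKernel(Kec, Zg, Kg)
    prov["kGE"] <- "K_gec = K_ec o Z_g K_g Z_g'"
  } else {
    kGE <- interactionKernel(Ke, Zg, Kg)
    prov["kGE"] <- "K_ge = K_e o Z_g K_g Z_g'"
  }
  new("KernelSet", kEnv = kEnv, kG = Kg, kGE = kGE, provenance = prov)
}

#' Assemble the Bayesian model specification for one predictor and fold
#'
#' Wires kernels, engineered covariate blocks and the multispectral
#' block into a [KernelModelSpec-class] exactly as the predictor's
#' configuration prescribes. The response is masked (`NA`) outside the
#' training rows. The multispectral block is centered and scaled with
#' training-row statistics and then zeroed at test rows, so phenomic
#' information never enters test predictions (indices are not
#' available for an unobserved environment).
#'
#' @param modelId `"M0"` .. `"M14"`.
#' @param dataset a [MetDataset-class].
#' @param trait trait name.
#' @param trainRows training rows of the fold.
#' @param selection a [SelectionResult-class] matching the
#'   configuration's selection method.
#' @param mcmc,priors passed to [kernelModelSpec()].
#' @param useProseM12 see [predictorConfig()].
#' @return a [KernelModelSpec-class].
#' @export
assembleModelSpec <- function(modelId, dataset, trait, trainRows,
                              selection, mcmc = list(), priors = list(),
                              useProseM12 = FALSE) {
  config <- predictorConfig(modelId, useProseM12)
  obs <- observations(dataset)
  n <- nrow(obs)
  trainRows <- as.integer(trainRows)
  testRows <- setdiff(seq_len(n), trainRows)
  ks <- buildKernelSet(config, dataset, trainRows, selection)

  lines <- sort(rownames(markers(dataset)))
  Zg <- genoDesign(obs$line, lines)
  KgObs <- Zg %*% ks@kG %*% t(Zg)

  rkhs <- list(env = ks@kEnv)
  if (config@includeKg) rkhs$geno <- KgObs
  rkhs$ge <- ks@kGE

  ridge <- list()
  sel_ec <- intersect(selectedColumns(selection),
                      colnames(envCovariates(dataset)))
  if (config@covariateBlock == "X_e" && config@selection == "none") {
    sel_ec <- colnames(envCovariates(dataset))  # M1: all covariates
  }
  if (config@covariateBlock != "none") {
    if (config@covariateBlock == "X_gec") {
      sel_mk <- intersect(selectedColumns(selection),
                          colnames(markers(dataset)))
      cand <- cbind(
        markers(dataset)[obs$line, sel_mk, drop = FALSE],
        expandEnvToObs(
          envCovariates(dataset)[, sel_ec, drop = FALSE], obs$env))
      if (ncol(cand)) {
        ridge$X_gec <- standardizeMatrix(cand, trainRows)@values
      } else {
        warning(modelId, ": empty selection; dropping X_gec block")
      }
    } else if (length(sel_ec)) {
      Xobs <- expandEnvToObs(
        envCovariates(dataset)[, sel_ec, drop = FALSE], obs$env)
      Xstd <- standardizeMatrix(Xobs, trainRows)@values
      y_all <- obs[[trait]]
      if (config@covariateBlock == "X_e") {
        ridge$X_e <- Xstd
      } else if (config@covariateBlock == "X_e2") {
        ridge$X_e2 <- squareAugment(Xstd, trainRows)@values
      } else { # X_e.avg
        ridge$X_e.avg <- signedAverage(Xstd, y_all, trainRows)@values
      }
    } else {
      warning(modelId, ": empty covariate selection; dropping ",
              config@covariateBlock, " block")
    }
  }
  if (config@includeM) {
    Mstd <- standardizeMatrix(msIndices(dataset), trainRows)@values
    if (length(testRows)) Mstd[testRows, ] <- 0
    ridge$M <- Mstd
  }

  y <- obs[[trait]]
  if (length(testRows)) y[testRows] <- NA_real_
  kernelModelSpec(rkhsTerms = rkhs, ridgeTerms = ridge, y = y,
                  trainRows = trainRows, mcmc = mcmc, priors = priors)
}
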