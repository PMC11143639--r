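#' @import methods
NULL

setClassUnion("listOrNULL", c("list", "NULL"))

#' MetDataset: a multi-environment trial data set
#'
#' Container for the joined inputs of a multi-environment genomic
#' prediction study: a long observation table (one row per line within
#' an environment, with one column per trait), a line-by-marker
#' genotype matrix, an environment-by-covariate weather matrix whose
#' columns are daily measurements flattened as `"<variable>_d<day>"`,
#' and three multispectral indices per observation.
#'
#' @slot observations `data.frame` with columns `env`, `line` and one
#'   numeric column per trait.
#' @slot markers numeric matrix, lines x markers, rownames are line ids.
#' @slot envCovariates numeric matrix, environments x covariates,
#'   rownames are environment ids.
#' @slot indices numeric matrix, observations x 3, the multispectral
#'   indices aligned row-for-row with `observations`.
#' @slot traits character vector naming the trait columns.
#' @slot truth for simulated data, the generating parameters (list);
#'   `NULL` for real data.
#'
#' @seealso [simulateMet()], [readMetDataset()], [loeoFolds()]
#' @export
setClass("MetDataset",
  representation(
    observations = "data.frame",
    markers = "matrix",
    envCovariates = "matrix",
    indices = "matrix",
    traits = "character",
    truth = "listOrNULL"
  ),
  prototype(truth = NULL)
)

setValidity("MetDataset", function(object) {
  obs <- object@observations
  msg <- character()
  if (!all(c("env", "line") %in% colnames(obs))) {
    msg <- c(msg, "observations must have 'env' and 'line' columns")
  } else {
    if (anyDuplicated(obs[, c("env", "line")])) {
      msg <- c(msg, "duplicated (env, line) observation rows")
    }
    bad_line <- setdiff(unique(obs$line), rownames(object@markers))
    if (length(bad_line)) {
      msg <- c(msg, paste0("lines absent from marker matrix: ",
                           paste(utils::head(bad_line, 5), collapse = ", ")))
    }
    bad_env <- setdiff(unique(obs$env), rownames(object@envCovariates))
    if (length(bad_env)) {
      msg <- c(msg, paste0("environments absent from covariate matrix: ",
                           paste(utils::head(bad_env, 5), collapse = ", ")))
    }
  }
  if (!all(object@traits %in% colnames(obs))) {
    msg <- c(msg, "every trait must be a column of observations")
  }
  if (nrow(object@indices) != nrow(obs)) {
    msg <- c(msg, "indices must have one row per observation")
  }
  if (ncol(object@indices) != 3L) {
    msg <- c(msg, "indices must have exactly 3 columns")
  }
  if (length(msg)) msg else TRUE
})

#' StandardizedMatrix: a centered-and-scaled matrix with frozen statistics
#'
#' Holds a matrix standardized column-wise with statistics computed on a
#' designated subset of rows (the training rows), so the same transform
#' can be applied to held-out rows without leakage. Columns with zero
#' variance on the fitting rows are dropped and recorded.
#'
#' @slot values the transformed matrix (all rows, retained columns).
#' @slot columnMeans,columnScales per-column statistics from the fitting rows.
#' @slot dropped names of zero-variance columns removed.
#' @slot fitRows integer indices of the rows the statistics came from.
#' @export
setClass("StandardizedMatrix",
  representation(
    values = "matrix",
    columnMeans = "numeric",
    columnScales = "numeric",
    dropped = "character",
    fitRows = "integer"
  )
)

#' KernelSet: the relationship kernels for one predictor configuration
#'
#' @slot kEnv observation-level environmental kernel (K_e or K_ec, n x n).
#' @slot kG line-level genomic relationship matrix (J x J).
#' @slot kGE observation-level genotype-by-environment kernel
#'   (K_ge or K_gec, n x n).
#' @slot provenance named character recording which formula produced
#'   each slot.
#' @export
setClass("KernelSet",
  representation(
    kEnv = "matrix",
    kG = "matrix",
    kGE = "matrix",
    provenance = "character"
  )
)

setValidity("KernelSet", function(object) {
  msg <- character()
  for (nm in c("kEnv", "kG", "kGE")) {
    k <- slot(object, nm)
    if (nrow(k) != ncol(k)) msg <- c(msg, paste(nm, "is not square"))
    else if (max(abs(k - t(k))) > 1e-10) msg <- c(msg, paste(nm, "is not symmetric"))
  }
  if (nrow(object@kEnv) != nrow(object@kGE)) {
    msg <- c(msg, "kEnv and kGE must share observation indexing")
  }
  if (length(msg)) msg else TRUE
})

#' SelectionResult: outcome of a covariate-selection procedure
#'
#' @slot method one of `"correlation"`, `"boruta"`,
#'   `"correlation_and_boruta"` or `"none"`.
#' @slot selectedColumns names of the selected columns.
#' @slot thresholdUsed the correlation threshold that fired
#'   (`NA` when none did or the method has no threshold).
#' @slot borutaStatus per-column status (`Confirmed`/`Tentative`/
#'   `Rejected`), empty for correlation-only selection.
#' @slot scope `"env_only"` or `"markers_and_env"`.
#' @slot trainRows the training rows the selection was computed on.
#' @export
setClass("SelectionResult",
  representation(
    method = "character",
    selectedColumns = "character",
    thresholdUsed = "numeric",
    borutaStatus = "character",
    scope = "character",
    trainRows = "integer"
  ),
  prototype(thresholdUsed = NA_real_, borutaStatus = character(),
            scope = "env_only")
)

setValidity("SelectionResult", function(object) {
  ok_m <- c("correlation", "boruta", "correlation_and_boruta", "none")
  msg <- character()
  if (!object@method %in% ok_m) msg <- c(msg, "unknown selection method")
  if (!is.na(object@thresholdUsed) &&
      !object@thresholdUsed %in% c(0.7, 0.6, 0.5, 0.4, 0.3)) {
    msg <- c(msg, "thresholdUsed must be one of 0.7, 0.6, 0.5, 0.4, 0.3 or NA")
  }
  if (!object@scope %in% c("env_only", "markers_and_env")) {
    msg <- c(msg, "unknown scope")
  }
  if (length(msg)) msg else TRUE
})

#' CovariateBlock: an observation-level engineered covariate matrix
#'
#' @slot values n x q numeric matrix.
#' @slot kind `"raw"`, `"squared_augmented"` or `"averaged"`.
#' @slot sourceColumns provenance of the columns.
#' @slot fitRows training rows whose statistics were used.
#' @export
setClass("CovariateBlock",
  representation(
    values = "matrix",
    kind = "character",
    sourceColumns = "character",
    fitRows = "integer"
  )
)

setValidity("CovariateBlock", function(object) {
  msg <- character()
  if (!object@kind %in% c("raw", "squared_augmented", "averaged")) {
    msg <- c(msg, "unknown covariate block kind")
  }
  if (object@kind == "averaged" && ncol(object@values) != 1L) {
    msg <- c(msg, "averaged block must have exactly one column")
  }
  if (length(msg)) msg else TRUE
})

#' PredictorConfig: one of the fifteen predictor configurations M0-M14
#'
#' Immutable description of which kernels, covariate blocks and
#' selection method a predictor uses.
#'
#' @slot modelId `"M0"` .. `"M14"`.
#' @slot envKernel `"K_e"` or `"K_ec"`.
#' @slot geKernel `"K_ge"` or `"K_gec"`.
#' @slot includeKg whether the standalone genomic kernel term enters.
#' @slot covariateBlock `"none"`, `"X_e"`, `"X_e2"`, `"X_e.avg"` or
#'   `"X_gec"`.
#' @slot selection `"none"`, `"C"`, `"B"` or `"C&B"`.
#' @slot tentative `"n/a"`, `"true"` or `"false"` — whether
#'   Tentative-status Boruta features count as selected.
#' @slot markerSelection whether the Boruta candidate set is the
#'   column-concatenation of markers and environmental covariates.
#' @slot kernelsFromSelectedMarkers whether the genomic kernels are
#'   rebuilt from the Boruta-selected markers (M10, M11).
#' @slot includeM whether the multispectral ridge block enters (always
#'   `TRUE` in the shipped registry).
#' @export
setClass("PredictorConfig",
  representation(
    modelId = "character",
    envKernel = "character",
    geKernel = "character",
    includeKg = "logical",
    covariateBlock = "character",
    selection = "character",
    tentative = "character",
    markerSelection = "logical",
    kernelsFromSelectedMarkers = "logical",
    includeM = "logical"
  )
)

#' KernelModelSpec: a fully assembled Bayesian multi-kernel model
#'
#' @slot rkhsTerms named list of n x n kernels, each a random effect
#'   with covariance sigma2_term * K.
#' @slot ridgeTerms named list of n x q covariate blocks whose
#'   coefficients get i.i.d. normal priors (Bayesian ridge).
#' @slot y response of length n; test rows may be `NA`.
#' @slot trainRows rows contributing to the likelihood.
#' @slot priors list with `df` and optional per-term `scale`; scales
#'   default to an R2-split of the training variance.
#' @slot mcmc list with `nIter`, `burnIn`, `thin`, `seed`.
#' @slot fixedVariances named numeric; named variances are held fixed
#'   instead of sampled (used for conjugate checks).
#' @export
setClass("KernelModelSpec",
  representation(
    rkhsTerms = "list",
    ridgeTerms = "list",
    y = "numeric",
    trainRows = "integer",
    priors = "list",
    mcmc = "list",
    fixedVariances = "numeric"
  ),
  prototype(fixedVariances = stats::setNames(numeric(), character()))
)

setValidity("KernelModelSpec", function(object) {
  n <- length(object@y)
  msg <- character()
  for (nm in names(object@rkhsTerms)) {
    k <- object@rkhsTerms[[nm]]
    if (!is.matrix(k) || nrow(k) != n || ncol(k) != n) {
      msg <- c(msg, paste0("rkhs term '", nm, "' must be ", n, " x ", n))
    }
  }
  for (nm in names(object@ridgeTerms)) {
    x <- object@ridgeTerms[[nm]]
    if (!is.matrix(x) || nrow(x) != n) {
      msg <- c(msg, paste0("ridge term '", nm, "' must have ", n, " rows"))
    }
  }
  if (!length(object@trainRows)) msg <- c(msg, "trainRows must be non-empty")
  if (anyNA(object@y[object@trainRows])) {
    msg <- c(msg, "training rows must have observed y")
  }
  mc <- object@mcmc
  if (!is.null(mc$nIter) && !is.null(mc$burnIn) && mc$nIter <= mc$burnIn) {
    msg <- c(msg, "nIter must exceed burnIn")
  }
  if (length(msg)) msg else TRUE
})

#' KernelModelFit: posterior summaries from the Gibbs sampler
#'
#' @slot posteriorMeans list: `intercept`, `effects` (per RKHS term,
#'   length-n vectors), `coefficients` (per ridge term), `variances`.
#' @slot predictions posterior-predictive mean for every observation.
#' @slot diagnostics list with draw counts and Monte-Carlo standard
#'   errors for the ridge coefficients.
#' @slot seed the seed the chain was run with.
#' @export
setClass("KernelModelFit",
  representation(
    posteriorMeans = "list",
    predictions = "numeric",
    diagnostics = "list",
    seed = "integer"
  )
)

#' CvReport: results of a leave-one-environment-out study
#'
#' @slot cells `data.frame` with one NRMSE per
#'   (dataset, trait, environment, model).
#' @slot summary per-model means with RE (vs the worst model) and
#'   RE_M0 (vs the no-covariate baseline) when M0 is present.
#' @slot winEnv,winTrait win-count tables.
#' @slot seed study seed.
#' @export
setClass("CvReport",
  representation(
    cells = "data.frame",
    summary = "data.frame",
    winEnv = "data.frame",
    winTrait = "data.frame",
    seed = "integer"
  )
)
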