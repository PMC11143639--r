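#' @include AllClasses.R
NULL

#' Accessors for MetDataset
#'
#' @param object a [MetDataset-class].
#' @return `observations()` the long observation table; `markers()` the
#'   line-by-marker matrix; `envCovariates()` the
#'   environment-by-covariate matrix; `msIndices()` the per-observation
#'   multispectral index matrix; `traitNames()` the trait column names;
#'   `envLevels()` / `lineLevels()` the sorted environment / line ids;
#'   `datasetTruth()` the generating parameters of a simulated data set
#'   (or `NULL`).
#' @name MetDataset-accessors
#' @aliases observations markers envCovariates msIndices traitNames
#'   envLevels lineLevels datasetTruth
NULL

#' @rdname MetDataset-accessors
#' @export
setGeneric("observations", function(object) standardGeneric("observations"))
#' @rdname MetDataset-accessors
#' @export
setGeneric("markers", function(object) standardGeneric("markers"))
#' @rdname MetDataset-accessors
#' @export
setGeneric("envCovariates", function(object) standardGeneric("envCovariates"))
#' @rdname MetDataset-accessors
#' @export
setGeneric("msIndices", function(object) standardGeneric("msIndices"))
#' @rdname MetDataset-accessors
#' @export
setGeneric("traitNames", function(object) standardGeneric("traitNames"))
#' @rdname MetDataset-accessors
#' @export
setGeneric("envLevels", function(object) standardGeneric("envLevels"))
#' @rdname MetDataset-accessors
#' @export
setGeneric("lineLevels", function(object) standardGeneric("lineLevels"))
#' @rdname MetDataset-accessors
#' @export
setGeneric("datasetTruth", function(object) standardGeneric("datasetTruth"))

#' @rdname MetDataset-accessors
setMethod("observations", "MetDataset", function(object) object@observations)
#' @rdname MetDataset-accessors
setMethod("markers", "MetDataset", function(object) object@markers)
#' @rdname MetDataset-accessors
setMethod("envCovariates", "MetDataset", function(object) object@envCovariates)
#' @rdname MetDataset-accessors
setMethod("msIndices", "MetDataset", function(object) object@indices)
#' @rdname MetDataset-accessors
setMethod("traitNames", "MetDataset", function(object) object@traits)
#' @rdname MetDataset-accessors
setMethod("envLevels", "MetDataset",
          function(object) sort(unique(object@observations$env)))
#' @rdname MetDataset-accessors
setMethod("lineLevels", "MetDataset",
          function(object) sort(rownames(object@markers)))
#' @rdname MetDataset-accessors
setMethod("datasetTruth", "MetDataset", function(object) object@truth)

#' Selection-result accessors
#'
#' @param object a [SelectionResult-class].
#' @return `selectedColumns()` the selected column names;
#'   `borutaStatus()` the per-column Confirmed/Tentative/Rejected
#'   labels (empty for correlation selection); `thresholdUsed()` the
#'   correlation threshold that fired, or `NA`.
#' @name SelectionResult-accessors
NULL

#' @rdname SelectionResult-accessors
#' @export
setGeneric("selectedColumns",
           function(object) standardGeneric("selectedColumns"))
#' @rdname SelectionResult-accessors
#' @export
setGeneric("borutaStatus", function(object) standardGeneric("borutaStatus"))
#' @rdname SelectionResult-accessors
#' @export
setGeneric("thresholdUsed", function(object) standardGeneric("thresholdUsed"))

#' @rdname SelectionResult-accessors
setMethod("selectedColumns", "SelectionResult",
          function(object) object@selectedColumns)
#' @rdname SelectionResult-accessors
setMethod("borutaStatus", "SelectionResult",
          function(object) object@borutaStatus)
#' @rdname SelectionResult-accessors
setMethod("thresholdUsed", "SelectionResult",
          function(object) object@thresholdUsed)

#' Fit and report accessors
#'
#' @param object a [KernelModelFit-class] or [CvReport-class].
#' @return `predictions()` the posterior-predictive mean for every
#'   observation; `posteriorMeans()` the list of posterior summaries;
#'   `cvCells()` the per-(dataset, trait, environment, model) NRMSE
#'   table; `cvSummary()` the per-model summary with RE and RE_M0.
#' @name fit-accessors
NULL

#' @rdname fit-accessors
#' @export
setGeneric("predictions", function(object) standardGeneric("predictions"))
#' @rdname fit-accessors
#' @export
setGeneric("posteriorMeans", function(object) standardGeneric("posteriorMeans"))
#' @rdname fit-accessors
#' @export
setGeneric("cvCells", function(object) standardGeneric("cvCells"))
#' @rdname fit-accessors
#' @export
setGeneric("cvSummary", function(object) standardGeneric("cvSummary"))

#' @rdname fit-accessors
setMethod("predictions", "KernelModelFit", function(object) object@predictions)
#' @rdname fit-accessors
setMethod("posteriorMeans", "KernelModelFit",
          function(object) object@posteriorMeans)
#' @rdname fit-accessors
setMethod("cvCells", "CvReport", function(object) object@cells)
#' @rdname fit-accessors
setMethod("cvSummary", "CvReport", function(object) object@summary)

setMethod("show", "MetDataset", function(object) {
  obs <- object@observations
  cat("MetDataset:", nrow(obs), "observations,",
      length(unique(obs$env)), "environments,",
      nrow(object@markers), "lines\n")
  cat("  markers:", ncol(object@markers), " env covariates:",
      ncol(object@envCovariates), " traits:",
      paste(object@traits, collapse = ", "), "\n")
  if (!is.null(object@truth)) cat("  simulated (truth recorded)\n")
  invisible(object)
})

setMethod("show", "SelectionResult", function(object) {
  cat("SelectionResult [", object@method, ", scope=", object@scope, "]: ",
      length(object@selectedColumns), " columns selected", sep = "")
  if (!is.na(object@thresholdUsed)) cat(" at |r| >=", object@thresholdUsed)
  cat("\n")
  if (length(object@borutaStatus)) {
    cat("  Boruta: ",
        sum(object@borutaStatus == "Confirmed"), " Confirmed, ",
        sum(object@borutaStatus == "Tentative"), " Tentative, ",
        sum(object@borutaStatus == "Rejected"), " Rejected\n", sep = "")
  }
  invisible(object)
})

setMethod("show", "PredictorConfig", function(object) {
  terms <- c(object@envKernel,
             if (object@includeKg) "K_g",
             object@geKernel,
             if (object@covariateBlock != "none") object@covariateBlock,
             if (object@includeM) "M")
  cat("PredictorConfig ", object@modelId, ": ",
      paste(terms, collapse = ", "), sep = "")
  if (object@selection != "none") {
    cat("  [selection ", object@selection,
        if (object@tentative != "n/a") paste0(", tentative ", object@tentative),
        "]", sep = "")
  }
  cat("\n")
  invisible(object)
})

setMethod("show", "KernelModelFit", function(object) {
  pm <- object@posteriorMeans
  cat("KernelModelFit:", length(pm$effects), "RKHS terms,",
      length(pm$coefficients), "ridge blocks\n")
  cat("  intercept:", signif(pm$intercept, 4), "\n")
  cat("  variances:", paste(names(pm$variances),
                            signif(pm$variances, 3),
                            sep = "=", collapse = ", "), "\n")
  invisible(object)
})

setMethod("show", "CvReport", function(object) {
  cat("CvReport:", nrow(object@cells), "cells (",
      length(unique(object@cells$model)), "models x",
      length(unique(object@cells$trait)), "traits x",
      length(unique(object@cells$environment)), "environments )\n")
  print(object@summary, digits = 4)
  invisible(object)
})
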