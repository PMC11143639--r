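#' @include AllClasses.R kernels.R
NULL

#' Cascading Pearson-correlation covariate selection
#'
#' Works down a ladder of correlation thresholds (default 0.7, 0.6,
#' 0.5, 0.4, 0.3): at the first threshold for which at least one column
#' has `|cor(x, y)| >= TC` on the training rows, all such columns are
#' selected and the cascade stops. If no column reaches the lowest
#' threshold the selection is empty and training proceeds without
#' environmental covariates. Correlations use training rows only;
#' zero-variance columns are excluded before computing correlations.
#'
#' @param X observation-level covariate matrix restricted to training
#'   rows (environment-level covariates replicated to each observation
#'   in the environment).
#' @param y training response, same rows as `X`.
#' @param thresholds descending threshold ladder.
#' @param trainRows identifier of the training rows (recorded in the
#'   result; defaults to all rows of `X`).
#' @return a [SelectionResult-class] with `method = "correlation"`.
#' @export
pearsonCascade <- function(X, y,
                           thresholds = c(0.7, 0.6, 0.5, 0.4, 0.3),
                           trainRows = seq_len(nrow(X))) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("X and y must have the same rows")
  if (stats::sd(y) == 0) stop("response has zero variance")
  sds <- apply(X, 2, stats::sd)
  usable <- which(is.finite(sds) & sds > 0)
  ac <- abs(suppressWarnings(
    stats::cor(X[, usable, drop = FALSE], y)))[, 1]
  sel <- character()
  thr <- NA_real_
  for (tc in sort(thresholds, decreasing = TRUE)) {
    hit <- names(ac)[ac >= tc]
    if (length(hit)) {
      sel <- hit
      thr <- tc
      break
    }
  }
  new("SelectionResult", method = "correlation",
      selectedColumns = sel, thresholdUsed = thr,
      borutaStatus = character(), scope = "env_only",
      trainRows = as.integer(trainRows))
}

#' Boruta shadow-feature selection
#'
#' All-relevant feature selection by comparison against permuted
#' copies. Each iteration: (1) build a shadow set by independently
#' permuting every column; (2) fit a random forest on the originals
#' and shadows together; (3) score a "hit" for each original whose
#' importance strictly exceeds the maximum shadow importance. After
#' `maxIter` iterations a two-sided binomial test of the hit count
#' against p = 0.5 (Bonferroni-corrected across columns) classifies
#' each column: `Confirmed` (significantly more hits than chance),
#' `Rejected` (significantly fewer), otherwise `Tentative`.
#'
#' @param X numeric predictor matrix (rows = training observations).
#' @param y numeric training response.
#' @param maxIter number of shadow iterations (default 100).
#' @param alpha significance level before Bonferroni correction
#'   (default 0.01).
#' @param numTrees trees per forest (default 500).
#' @param seed integer seed controlling permutation and forests.
#' @param scope recorded scope label (`"env_only"` or
#'   `"markers_and_env"`).
#' @param trainRows identifier of the training rows (recorded).
#' @param includeTentative whether `Tentative` columns count as
#'   selected (default `FALSE`: confirmed only).
#' @param details when `TRUE`, return a list with the
#'   [SelectionResult-class] plus the raw per-iteration importance
#'   matrix, the per-iteration maximum shadow importance and the hit
#'   counts, so the accounting can be audited.
#' @return a [SelectionResult-class] with `method = "boruta"` and a
#'   status for every column (or the detail list, see `details`).
#' @export
borutaSelect <- function(X, y, maxIter = 100L, alpha = 0.01,
                         numTrees = 500L, seed = 1L,
                         scope = "env_only",
                         trainRows = seq_len(nrow(X)),
                         includeTentative = FALSE, details = FALSE) {
  X <- as.matrix(X)
  if (maxIter < 1L) stop("maxIter must be >= 1")
  if (nrow(X) < 2L || ncol(X) < 1L) stop("need >= 2 rows and >= 1 column")
  if (!all(is.finite(X)) || !all(is.finite(y))) {
    stop("non-finite values in predictors or response")
  }
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  q <- ncol(X)
  hits <- stats::setNames(integer(q), colnames(X))
  set.seed(seed)
  shadow_names <- paste0(".shadow", seq_len(q))
  imp_log <- if (details) matrix(0, maxIter, q,
                                 dimnames = list(NULL, colnames(X)))
  max_shadow_log <- if (details) numeric(maxIter)
  for (it in seq_len(maxIter)) {
    shadows <- apply(X, 2, sample)
    colnames(shadows) <- shadow_names
    df <- data.frame(.y = y, X, shadows, check.names = FALSE)
    fit <- ranger::ranger(
      dependent.variable.name = ".y", data = df,
      num.trees = numTrees, importance = "impurity",
      seed = sample.int(.Machine$integer.max, 1),
      num.threads = 1, verbose = FALSE)
    imp <- fit$variable.importance
    max_shadow <- max(imp[shadow_names])
    hits <- hits + as.integer(imp[colnames(X)] > max_shadow)
    if (details) {
      imp_log[it, ] <- imp[colnames(X)]
      max_shadow_log[it] <- max_shadow
    }
  }
  # two-sided binomial test of hit counts against p = 0.5
  a <- alpha / q
  p_hi <- stats::pbinom(hits - 1L, maxIter, 0.5, lower.tail = FALSE)
  p_lo <- stats::pbinom(hits, maxIter, 0.5)
  p_two <- pmin(1, 2 * pmin(p_hi, p_lo))
  status <- rep("Tentative", q)
  status[p_two <= a & hits > maxIter / 2] <- "Confirmed"
  status[p_two <= a & hits < maxIter / 2] <- "Rejected"
  names(status) <- colnames(X)
  keep <- if (includeTentative) c("Confirmed", "Tentative") else "Confirmed"
  res <- new("SelectionResult", method = "boruta",
             selectedColumns = names(status)[status %in% keep],
             thresholdUsed = NA_real_, borutaStatus = status,
             scope = scope, trainRows = as.integer(trainRows))
  if (details) {
    list(result = res, importance = imp_log,
         maxShadow = max_shadow_log, hits = hits)
  } else {
    res
  }
}

#' Dispatch covariate selection for a predictor configuration
#'
#' Runs the selection procedure a predictor calls for, on training
#' rows only. Correlation models (M2-M8) run the Pearson cascade on
#' the environmental covariates; Boruta models with
#' `markers_and_env` scope (M9-M11) run Boruta on the
#' column-concatenation of markers and environmental covariates;
#' M8 runs the cascade first and Boruta on the survivors, keeping the
#' Boruta-positive columns (intersection reading of "C & B"). M0/M1
#' perform no selection.
#'
#' @param modelId `"M0"` .. `"M14"`.
#' @param dataset a [MetDataset-class].
#' @param trait trait name (response column).
#' @param trainRows integer indices into the observation table.
#' @param seed seed for Boruta.
#' @param borutaIter,borutaTrees,alpha Boruta settings.
#' @return a [SelectionResult-class]. Column names of environmental
#'   covariates are the `envCovariates` column names; marker columns
#'   (scope `markers_and_env`) keep their marker names.
#' @export
selectForModel <- function(modelId, dataset, trait, trainRows,
                           seed = 1L, borutaIter = 100L,
                           borutaTrees = 500L, alpha = 0.01) {
  cfg <- predictorConfig(modelId)
  obs <- observations(dataset)
  y <- obs[[trait]][trainRows]
  if (cfg@selection == "none") {
    return(new("SelectionResult", method = "none",
               selectedColumns = character(),
               thresholdUsed = NA_real_, borutaStatus = character(),
               scope = "env_only", trainRows = as.integer(trainRows)))
  }
  Xec <- expandEnvToObs(envCovariates(dataset), obs$env)[trainRows, ,
                                                         drop = FALSE]
  tentative <- identical(cfg@tentative, "true")
  scope <- if (cfg@markerSelection) "markers_and_env" else "env_only"
  if (cfg@selection == "C") {
    res <- pearsonCascade(Xec, y, trainRows = trainRows)
  } else if (cfg@selection == "B") {
    if (scope == "markers_and_env") {
      Xmk <- markers(dataset)[obs$line[trainRows], , drop = FALSE]
      cand <- cbind(Xmk, Xec)
      res <- borutaSelect(cand, y, maxIter = borutaIter, alpha = alpha,
                          numTrees = borutaTrees, seed = seed,
                          scope = scope, trainRows = trainRows,
                          includeTentative = tentative)
    } else {
      res <- borutaSelect(Xec, y, maxIter = borutaIter, alpha = alpha,
                          numTrees = borutaTrees, seed = seed,
                          scope = scope, trainRows = trainRows,
                          includeTentative = tentative)
    }
  } else { # C & B
    casc <- pearsonCascade(Xec, y, trainRows = trainRows)
    if (!length(selectedColumns(casc))) return(casc)
    sub <- Xec[, selectedColumns(casc), drop = FALSE]
    bor <- borutaSelect(sub, y, maxIter = borutaIter, alpha = alpha,
                        numTrees = borutaTrees, seed = seed,
                        scope = "env_only", trainRows = trainRows,
                        includeTentative = tentative)
    res <- new("SelectionResult", method = "correlation_and_boruta",
               selectedColumns = selectedColumns(bor),
               thresholdUsed = thresholdUsed(casc),
               borutaStatus = borutaStatus(bor),
               scope = "env_only", trainRows = as.integer(trainRows))
  }
  res
}

#' Tabular view of a selection result
#'
#' @param result a [SelectionResult-class].
#' @return `data.frame` with one row per classified column.
#' @export
selectionTable <- function(result) {
  cols <- if (length(result@borutaStatus)) names(result@borutaStatus) else
    result@selectedColumns
  data.frame(
    column = cols,
    method = result@method,
    selected = cols %in% result@selectedColumns,
    status = if (length(result@borutaStatus))
      unname(result@borutaStatus[cols]) else NA_character_,
    threshold = result@thresholdUsed,
    stringsAsFactors = FALSE)
}
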