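#' @include AllClasses.R predictor-registry.R feature-selection.R
NULL

#' Leave-one-environment-out folds
#'
#' One fold per environment: the test set is every observation of that
#' environment, the training set is everything else. This is the CV0
#' scheme — tested lines in an untested environment.
#'
#' @param dataset a [MetDataset-class] with at least 2 environments.
#' @return named list of folds, each `list(trainRows, testRows,
#'   testEnv)`.
#' @export
loeoFolds <- function(dataset) {
  envs <- envLevels(dataset)
  if (length(envs) < 2L) stop("LOEO needs at least 2 environments")
  obs <- observations(dataset)
  out <- lapply(envs, function(e) {
    test <- which(obs$env == e)
    list(trainRows = setdiff(seq_len(nrow(obs)), test),
         testRows = test, testEnv = e)
  })
  names(out) <- envs
  out
}

#' Normalized root mean squared error
#'
#' `100 * RMSE / normalizer(observed)`, with the mean of the observed
#' values as default normalizer (sd and range are available), giving a
#' scale-free percentage comparable across traits.
#'
#' @param yObs observed values.
#' @param yPred predicted values, same length.
#' @param normalizer `"mean"`, `"sd"` or `"range"`.
#' @return non-negative scalar.
#' @examples
#' nrmse(c(1, 3), c(2, 2))  # 50
#' @export
nrmse <- function(yObs, yPred, normalizer = c("mean", "sd", "range")) {
  normalizer <- match.arg(normalizer)
  if (length(yObs) != length(yPred)) stop("length mismatch")
  if (!length(yObs)) stop("empty input")
  rmse <- sqrt(mean((yObs - yPred)^2))
  denom <- switch(normalizer,
                  mean = mean(yObs),
                  sd = stats::sd(yObs),
                  range = diff(range(yObs)))
  if (!is.finite(denom) || denom == 0) stop("zero or undefined normalizer")
  100 * rmse / denom
}

#' Relative efficiency of a model against a reference
#'
#' Percentage gain of a model over a reference (the worst model, or
#' the no-covariate baseline M0):
#' `RE = (NRMSE(reference) / NRMSE(model) - 1) * 100`, so better
#' models score positive gains. `printedOrientation = TRUE` evaluates
#' the transposed ratio (model NRMSE in the numerator), under which
#' better models score negative values.
#'
#' @param nrmseModel model NRMSE (> 0).
#' @param nrmseReference reference NRMSE (> 0).
#' @param printedOrientation see above.
#' @return RE in percent.
#' @examples
#' relativeEfficiency(2.82, 4.34)  # 53.9
#' @export
relativeEfficiency <- function(nrmseModel, nrmseReference,
                               printedOrientation = FALSE) {
  if (any(nrmseModel <= 0) || any(nrmseReference <= 0)) {
    stop("NRMSE values must be positive")
  }
  if (printedOrientation) {
    (nrmseModel / nrmseReference - 1) * 100
  } else {
    (nrmseReference / nrmseModel - 1) * 100
  }
}

#' Pairwise win counts by environment and by trait
#'
#' Within every (trait, environment) cell group, model m scores a win
#' over model m' when its NRMSE is strictly smaller; ties score for
#' neither. Wins are then summed per environment (over traits and
#' opponents) and per trait (over environments and opponents).
#'
#' @param cells `data.frame` with columns `trait`, `environment`,
#'   `model`, `nrmse` — a complete grid.
#' @return list with `byEnv` and `byTrait` win-count `data.frame`s.
#' @export
winCounts <- function(cells) {
  need <- c("trait", "environment", "model", "nrmse")
  if (!all(need %in% colnames(cells))) {
    stop("cells must have columns ", paste(need, collapse = ", "))
  }
  models <- sort(unique(cells$model))
  grid <- table(cells$trait, cells$environment, cells$model)
  if (any(grid != 1)) {
    gap <- which(grid != 1, arr.ind = TRUE)[1, ]
    stop("incomplete cell grid near trait=", dimnames(grid)[[1]][gap[1]],
         ", environment=", dimnames(grid)[[2]][gap[2]])
  }
  wins <- do.call(rbind, lapply(
    split(cells, list(cells$trait, cells$environment), drop = TRUE),
    function(g) {
      v <- stats::setNames(g$nrmse, g$model)[models]
      w <- vapply(models, function(m) sum(v[m] < v[models != m]),
                  numeric(1))
      data.frame(trait = g$trait[1], environment = g$environment[1],
                 model = models, wins = as.integer(w),
                 stringsAsFactors = FALSE, row.names = NULL)
    }))
  byEnv <- stats::aggregate(wins ~ environment + model, wins, sum)
  byTrait <- stats::aggregate(wins ~ trait + model, wins, sum)
  # opponents per group: (n_models - 1) comparisons per cell group
  n_traits <- length(unique(cells$trait))
  n_envs <- length(unique(cells$environment))
  byEnv$total <- (length(models) - 1L) * n_traits
  byEnv$pct <- 100 * byEnv$wins / byEnv$total
  byTrait$total <- (length(models) - 1L) * n_envs
  byTrait$pct <- 100 * byTrait$wins / byTrait$total
  list(byEnv = byEnv, byTrait = byTrait)
}

#' Average per-dataset model summaries across data sets
#'
#' Arithmetic mean over data sets of every numeric summary column
#' (won counts, won percentages, NRMSE, RE, ...), one row per model —
#' the "across data" rows of a multi-dataset comparison table.
#'
#' @param summaries `data.frame` with a `dataset` column, a `model`
#'   column and numeric summary columns.
#' @return `data.frame` with one row per model.
#' @export
aggregateAcrossDatasets <- function(summaries) {
  if (!all(c("dataset", "model") %in% colnames(summaries))) {
    stop("summaries must have 'dataset' and 'model' columns")
  }
  datasets <- unique(summaries$dataset)
  tab <- table(summaries$model, summaries$dataset)
  if (any(tab != 1)) {
    bad <- which(tab == 0, arr.ind = TRUE)
    if (nrow(bad)) {
      stop("model ", rownames(tab)[bad[1, 1]], " missing from dataset ",
           colnames(tab)[bad[1, 2]])
    }
    stop("duplicated (model, dataset) summary rows")
  }
  num_cols <- setdiff(colnames(summaries)[vapply(summaries, is.numeric,
                                                 logical(1))], "dataset")
  out <- do.call(rbind, lapply(split(summaries, summaries$model),
    function(g) {
      row <- data.frame(model = g$model[1], stringsAsFactors = FALSE)
      for (cc in num_cols) row[[cc]] <- mean(g[[cc]])
      row
    }))
  rownames(out) <- NULL
  out
}

# fit one predictor on one fold and score the held-out environment
fitFold <- function(modelId, dataset, trait, fold, mcmc, seed,
                    borutaIter = 60L, borutaTrees = 200L) {
  sel <- selectForModel(modelId, dataset, trait, fold$trainRows,
                        seed = seed, borutaIter = borutaIter,
                        borutaTrees = borutaTrees)
  spec <- suppressWarnings(
    assembleModelSpec(modelId, dataset, trait, fold$trainRows, sel,
                      mcmc = mcmc))
  fit <- fitKernelModel(spec)
  yObs <- observations(dataset)[[trait]][fold$testRows]
  list(nrmse = nrmse(yObs, predict(fit, fold$testRows)),
       selection = sel, fit = fit)
}

#' Run a leave-one-environment-out prediction study
#'
#' The full pipeline, per data set x trait x fold x model: select
#' covariates on the training rows, engineer the covariate blocks,
#' build the kernels, fit the Bayesian multi-kernel model, predict the
#' left-out environment and score it with NRMSE. Results are collected
#' into a [CvReport-class] with per-model summaries, RE against the
#' worst model, RE against M0 (when present) and win counts.
#'
#' @param datasets named list of [MetDataset-class] objects (a single
#'   dataset may be passed bare).
#' @param modelIds predictor ids to evaluate.
#' @param traits traits to evaluate (default: all in the first
#'   dataset).
#' @param mcmc MCMC settings forwarded to the sampler.
#' @param seed study seed; fold- and model-level seeds derive from it.
#' @param borutaIter,borutaTrees Boruta settings for the
#'   Boruta-selecting predictors.
#' @param normalizer NRMSE normalizer.
#' @return a [CvReport-class].
#' @export
runStudy <- function(datasets, modelIds = c("M0", "M6"), traits = NULL,
                     mcmc = list(), seed = 1L,
                     borutaIter = 60L, borutaTrees = 200L,
                     normalizer = "mean") {
  if (is(datasets, "MetDataset")) datasets <- list(dataset1 = datasets)
  if (is.null(names(datasets))) {
    names(datasets) <- paste0("dataset", seq_along(datasets))
  }
  if (is.null(traits)) traits <- traitNames(datasets[[1]])
  mcmc <- utils::modifyList(list(nIter = 2000L, burnIn = 500L, thin = 2L),
                            mcmc)
  cells <- list()
  for (ds_name in names(datasets)) {
    ds <- datasets[[ds_name]]
    folds <- loeoFolds(ds)
    for (trait in traits) {
      for (f in seq_along(folds)) {
        for (m in modelIds) {
          sub_seed <- (seed * 1009L + f * 101L +
                         match(m, modelIds) * 13L +
                         match(trait, traits)) %% 2147483647L
          mcmc$seed <- sub_seed
          res <- fitFold(m, ds, trait, folds[[f]], mcmc, sub_seed,
                         borutaIter, borutaTrees)
          cells[[length(cells) + 1L]] <- data.frame(
            dataset = ds_name, trait = trait,
            environment = folds[[f]]$testEnv, model = m,
            nrmse = res$nrmse, stringsAsFactors = FALSE)
        }
      }
    }
  }
  cells <- do.call(rbind, cells)
  summarizeCells(cells, seed = seed)
}

#' Summarize a table of NRMSE cells into a CvReport
#'
#' Computes per-model mean NRMSE, RE against the worst model, RE
#' against M0 when present, and the win-count tables. Useful for
#' re-summarizing saved cell tables.
#'
#' @param cells `data.frame` with columns `dataset`, `trait`,
#'   `environment`, `model`, `nrmse`.
#' @param seed recorded seed (metadata only).
#' @return a [CvReport-class].
#' @export
summarizeCells <- function(cells, seed = NA_integer_) {
  mean_nrmse <- tapply(cells$nrmse, cells$model, mean)
  worst <- max(mean_nrmse)
  summ <- data.frame(model = names(mean_nrmse),
                     nrmse = as.numeric(mean_nrmse),
                     stringsAsFactors = FALSE)
  summ$re <- relativeEfficiency(summ$nrmse, worst)
  if ("M0" %in% summ$model) {
    m0 <- summ$nrmse[summ$model == "M0"]
    summ$reM0 <- relativeEfficiency(summ$nrmse, m0)
  }
  wc <- lapply(split(cells, cells$dataset), winCounts)
  byEnv <- do.call(rbind, Map(function(w, nm) {
    w$byEnv$dataset <- nm
    w$byEnv
  }, wc, names(wc)))
  byTrait <- do.call(rbind, Map(function(w, nm) {
    w$byTrait$dataset <- nm
    w$byTrait
  }, wc, names(wc)))
  rownames(byEnv) <- rownames(byTrait) <- NULL
  rownames(summ) <- NULL
  new("CvReport", cells = cells, summary = summ,
      winEnv = byEnv, winTrait = byTrait,
      seed = as.integer(if (is.na(seed)) NA_integer_ else seed))
}
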