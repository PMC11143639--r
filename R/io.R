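#' @include AllClasses.R
NULL

#' Write a MET data set as plain CSV tables
#'
#' Writes `observations.csv` (long: env, line, traits),
#' `markers.csv` (wide: line x SNP), `env_covariates.csv` (wide:
#' env x covariate) and `indices.csv` (env, line, three index
#' columns) into `dir`. For simulated data the ground truth is
#' written as a `truth.json` sidecar.
#'
#' @param dataset a [MetDataset-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeMetDataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  obs <- observations(dataset)
  utils::write.csv(obs, file.path(dir, "observations.csv"),
                   row.names = FALSE)
  mk <- data.frame(line = rownames(markers(dataset)),
                   markers(dataset), check.names = FALSE)
  utils::write.csv(mk, file.path(dir, "markers.csv"), row.names = FALSE)
  ec <- data.frame(env = rownames(envCovariates(dataset)),
                   envCovariates(dataset), check.names = FALSE)
  utils::write.csv(ec, file.path(dir, "env_covariates.csv"),
                   row.names = FALSE)
  ix <- data.frame(env = obs$env, line = obs$line, msIndices(dataset),
                   check.names = FALSE)
  utils::write.csv(ix, file.path(dir, "indices.csv"), row.names = FALSE)
  truth <- datasetTruth(dataset)
  if (!is.null(truth)) {
    truth$config <- unclass(truth$config)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a MET data set from CSV tables
#'
#' Reads the four tables written by [writeMetDataset()] (or prepared
#' externally in the same layout) and cross-references them:
#' observations referencing unknown lines or environments are an
#' error naming the offenders; environmental covariate columns that
#' are constant across all environments are dropped with a warning;
#' missing marker entries are imputed by the marker's column mean
#' (with a message stating how many).
#'
#' @param dir directory containing `observations.csv`, `markers.csv`,
#'   `env_covariates.csv` and `indices.csv`.
#' @return a [MetDataset-class] (`datasetTruth()` is `NULL`; the
#'   truth sidecar, when present, is left for the caller).
#' @export
readMetDataset <- function(dir) {
  path <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop("missing input table: ", p)
    p
  }
  obs <- utils::read.csv(path("observations.csv"), check.names = FALSE,
                         stringsAsFactors = FALSE)
  if (!all(c("env", "line") %in% colnames(obs))) {
    stop("observations.csv must have 'env' and 'line' columns")
  }
  obs$env <- as.character(obs$env)
  obs$line <- as.character(obs$line)
  if (anyDuplicated(obs[, c("env", "line")])) {
    stop("duplicated (env, line) rows in observations.csv")
  }
  traits <- setdiff(colnames(obs), c("env", "line"))
  for (tr in traits) {
    if (!is.numeric(obs[[tr]])) stop("non-numeric trait column: ", tr)
  }

  mk <- utils::read.csv(path("markers.csv"), check.names = FALSE,
                        stringsAsFactors = FALSE)
  if (!"line" %in% colnames(mk)) stop("markers.csv must have a 'line' column")
  mk_lines <- as.character(mk$line)
  M <- as.matrix(mk[, setdiff(colnames(mk), "line"), drop = FALSE])
  if (!is.numeric(M)) stop("non-numeric genotype entries in markers.csv")
  rownames(M) <- mk_lines
  n_missing <- sum(is.na(M))
  if (n_missing > 0) {
    for (k in which(colSums(is.na(M)) > 0)) {
      M[is.na(M[, k]), k] <- mean(M[, k], na.rm = TRUE)
    }
    message("imputed ", n_missing, " missing marker entries by column mean")
  }

  ec <- utils::read.csv(path("env_covariates.csv"), check.names = FALSE,
                        stringsAsFactors = FALSE)
  if (!"env" %in% colnames(ec)) {
    stop("env_covariates.csv must have an 'env' column")
  }
  X <- as.matrix(ec[, setdiff(colnames(ec), "env"), drop = FALSE])
  rownames(X) <- as.character(ec$env)
  const <- apply(X, 2, function(v) stats::sd(v) == 0)
  if (any(const)) {
    warning("dropping ", sum(const),
            " environmental covariates constant across environments")
    X <- X[, !const, drop = FALSE]
  }

  ix <- utils::read.csv(path("indices.csv"), check.names = FALSE,
                        stringsAsFactors = FALSE)
  idx_cols <- setdiff(colnames(ix), c("env", "line"))
  if (length(idx_cols) != 3L) stop("indices.csv must have 3 index columns")
  key <- function(e, l) paste(e, l, sep = "\r")
  m <- match(key(obs$env, obs$line), key(ix$env, ix$line))
  if (anyNA(m)) stop("indices.csv missing rows for some observations")
  I3 <- as.matrix(ix[m, idx_cols, drop = FALSE])
  rownames(I3) <- NULL

  bad_line <- setdiff(unique(obs$line), rownames(M))
  if (length(bad_line)) {
    stop("observations reference unknown lines: ",
         paste(bad_line, collapse = ", "))
  }
  bad_env <- setdiff(unique(obs$env), rownames(X))
  if (length(bad_env)) {
    stop("observations reference unknown environments: ",
         paste(bad_env, collapse = ", "))
  }

  new("MetDataset", observations = obs, markers = M, envCovariates = X,
      indices = I3, traits = traits, truth = NULL)
}

#' Write a CvReport as CSV tables
#'
#' @param report a [CvReport-class].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
writeCvReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cvCells(report), file.path(dir, "cells.csv"),
                   row.names = FALSE)
  utils::write.csv(cvSummary(report), file.path(dir, "summary.csv"),
                   row.names = FALSE)
  utils::write.csv(report@winEnv, file.path(dir, "wins_by_env.csv"),
                   row.names = FALSE)
  utils::write.csv(report@winTrait, file.path(dir, "wins_by_trait.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Example per-dataset model comparison summary
#'
#' Per-dataset win counts, win percentages, mean NRMSE and relative
#' efficiency for two predictors (M3: selected covariates entered
#' individually; M6: the single sign-aligned average covariate)
#' across four winter-wheat multi-environment data sets, as reported
#' in a published comparison. Shipped as a worked input for
#' [aggregateAcrossDatasets()].
#'
#' @return `data.frame` with columns `dataset`, `model`, `wonEnv`,
#'   `wonEnvPct`, `wonTrait`, `wonTraitPct`, `nrmse`, `re`.
#' @export
exampleModelSummary <- function() {
  utils::read.csv(system.file("extdata", "example_model_summary.csv",
                              package = "enviroGP"),
                  stringsAsFactors = FALSE)
}
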