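#' @include AllClasses.R kernels.R
NULL

#' Expand an environment-level matrix to observation level
#'
#' Replicates each environment's row to every observation in that
#' environment, so environment-level covariates and line-level
#' responses share an index.
#'
#' @param envMat I x q matrix with environment ids as rownames.
#' @param envLabels character vector of observation environment labels.
#' @return length(envLabels) x q matrix.
#' @examples
#' m <- matrix(c(10, 20), 2, 1, dimnames = list(c("A", "B"), "x"))
#' expandEnvToObs(m, c("A", "B", "A"))  # rows 10, 20, 10
#' @export
expandEnvToObs <- function(envMat, envLabels) {
  envMat <- as.matrix(envMat)
  if (is.null(rownames(envMat))) stop("envMat must have environment rownames")
  idx <- match(as.character(envLabels), rownames(envMat))
  if (anyNA(idx)) {
    stop("unknown environments: ",
         paste(unique(envLabels[is.na(idx)]), collapse = ", "))
  }
  out <- envMat[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sign-aligned average covariate
#'
#' Collapses the selected (standardized) environmental covariates into
#' a single column: the training-set correlation of each column with
#' the response determines its sign; negatively correlated columns are
#' multiplied by -1 so every column correlates non-negatively with the
#' response on the training rows; the row mean of the sign-aligned
#' matrix is the average covariate. Because environmental covariates
#' are constant within an environment, the row mean at observation
#' level equals the environment-level average expanded to observations.
#'
#' Columns with exactly zero training correlation keep sign +1
#' (deterministic tie-break).
#'
#' @param X observation-level standardized selected covariates (n x q,
#'   q >= 1).
#' @param y full response vector (only `trainRows` entries are used).
#' @param trainRows training row indices.
#' @return a [CovariateBlock-class] with `kind = "averaged"` (n x 1).
#' @export
signedAverage <- function(X, y, trainRows) {
  X <- as.matrix(X)
  if (ncol(X) < 1L) stop("empty selection: drop the average-covariate term")
  if (!length(trainRows)) stop("trainRows must be non-empty")
  if (is.null(colnames(X))) colnames(X) <- paste0("c", seq_len(ncol(X)))
  cors <- suppressWarnings(
    stats::cor(X[trainRows, , drop = FALSE], y[trainRows]))[, 1]
  sgn <- ifelse(is.na(cors) | cors >= 0, 1, -1)
  flipped <- sweep(X, 2, sgn, "*")
  avg <- matrix(rowMeans(flipped), ncol = 1,
                dimnames = list(NULL, "X_e.avg"))
  new("CovariateBlock", values = avg, kind = "averaged",
      sourceColumns = colnames(X), fitRows = as.integer(trainRows))
}

#' Square-augmented covariate block
#'
#' Concatenates each column of the input with its elementwise square:
#' q input columns become 2q output columns. When `fitRows` is given,
#' the squared columns are re-standardized with statistics from those
#' rows (the originals are assumed already standardized); without
#' `fitRows` the raw concatenation is returned.
#'
#' @param X observation-level covariate matrix (n x q, q >= 1).
#' @param fitRows optional training rows for re-standardizing the
#'   squared columns.
#' @return a [CovariateBlock-class] with `kind = "squared_augmented"`.
#' @export
squareAugment <- function(X, fitRows = NULL) {
  X <- as.matrix(X)
  if (ncol(X) < 1L) stop("empty input")
  if (is.null(colnames(X))) colnames(X) <- paste0("c", seq_len(ncol(X)))
  sq <- X^2
  colnames(sq) <- paste0(colnames(X), "_sq")
  if (!is.null(fitRows)) {
    sq <- standardizeMatrix(sq, fitRows)@values
  }
  new("CovariateBlock", values = cbind(X, sq), kind = "squared_augmented",
      sourceColumns = colnames(X),
      fitRows = if (is.null(fitRows)) integer() else as.integer(fitRows))
}
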