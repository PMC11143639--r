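#' @include AllClasses.R
NULL

#' Standardize a matrix with statistics from designated rows
#'
#' Centers and scales every column using the mean and sample standard
#' deviation (n - 1 denominator) computed on `fitRows` only, then
#' applies that transform to all rows. Columns with zero variance on
#' the fitting rows are dropped and recorded in the result, so the
#' caller can see what was removed. This is the leakage-safe primitive
#' behind every kernel and covariate block: statistics always come from
#' the training rows of the current fold.
#'
#' @param x numeric matrix.
#' @param fitRows integer row indices to compute statistics on
#'   (default: all rows).
#' @return a [StandardizedMatrix-class].
#' @examples
#' s <- standardizeMatrix(cbind(a = c(1, 2, 3)))
#' s@values  # [-1, 0, 1]
#' @export
standardizeMatrix <- function(x, fitRows = seq_len(nrow(x))) {
  x <- as.matrix(x)
  fitRows <- as.integer(fitRows)
  if (!length(fitRows)) stop("fitRows must be non-empty")
  if (is.null(colnames(x))) colnames(x) <- paste0("c", seq_len(ncol(x)))
  mu <- colMeans(x[fitRows, , drop = FALSE])
  sdv <- apply(x[fitRows, , drop = FALSE], 2, stats::sd)
  keep <- is.finite(sdv) & sdv > 0
  if (!any(keep)) stop("all columns have zero variance on the fitting rows")
  z <- sweep(x[, keep, drop = FALSE], 2, mu[keep], "-")
  z <- sweep(z, 2, sdv[keep], "/")
  new("StandardizedMatrix",
      values = z,
      columnMeans = mu[keep],
      columnScales = sdv[keep],
      dropped = colnames(x)[!keep],
      fitRows = fitRows)
}

std_values <- function(x) {
  if (is(x, "StandardizedMatrix")) x@values else as.matrix(x)
}

#' Incidence (design) matrices for environments and genotypes
#'
#' Builds the 0/1 incidence matrix mapping observations to environment
#' (`envDesign`) or line (`genoDesign`) levels. Column order is the
#' sorted level order, so the matrix is invariant to observation input
#' order up to row permutation.
#'
#' @param labels character vector, one label per observation.
#' @param levels the full label set; defaults to the sorted distinct
#'   labels. An observation label outside `levels` is an error.
#' @return n x length(levels) 0/1 matrix with one 1 per row.
#' @examples
#' envDesign(c("A", "B", "A"))
#' @export
envDesign <- function(labels, levels = sort(unique(labels))) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), levels)
  if (length(bad)) {
    stop("unknown labels: ", paste(bad, collapse = ", "))
  }
  levels <- sort(levels)
  z <- matrix(0, length(labels), length(levels),
              dimnames = list(NULL, levels))
  z[cbind(seq_along(labels), match(labels, levels))] <- 1
  z
}

#' @rdname envDesign
#' @export
genoDesign <- function(labels, levels = sort(unique(labels))) {
  envDesign(labels, levels)
}

#' Environmental relationship matrix from standardized covariates
#'
#' Computes `H_e = X_e X_e^T / r_s` from the standardized
#' environment-by-covariate matrix, the enviromic analogue of a genomic
#' relationship matrix. The divisor is the *current* column count, so
#' after covariate selection it is the number of selected columns.
#'
#' @param XeStd a [StandardizedMatrix-class] or plain standardized
#'   matrix, environments x covariates.
#' @return I x I symmetric matrix.
#' @export
envRelationship <- function(XeStd) {
  x <- std_values(XeStd)
  if (ncol(x) < 1L) {
    stop("no covariate columns: fall back to a configuration without H_e")
  }
  tcrossprod(x) / ncol(x)
}

#' Baseline environment kernel from the incidence matrix
#'
#' `K_e = Z_e Z_e^T / I`: entry (a, b) is 1/I when observations a and b
#' share an environment and 0 otherwise.
#'
#' @param Ze environment incidence matrix (n x I).
#' @return n x n matrix.
#' @export
baselineEnvKernel <- function(Ze) {
  tcrossprod(Ze) / ncol(Ze)
}

#' Genomic relationship matrix
#'
#' `K_g = M_e M_e^T / p` from the standardized line-by-marker matrix,
#' the classical marker-based relationship matrix under
#' per-marker unit-variance scaling.
#'
#' @param MeStd a [StandardizedMatrix-class] or standardized matrix,
#'   lines x markers.
#' @return J x J symmetric PSD matrix.
#' @export
genomicKernel <- function(MeStd) {
  m <- std_values(MeStd)
  if (ncol(m) < 1L) stop("no marker columns")
  tcrossprod(m) / ncol(m)
}

#' Covariate-informed environment kernel at observation level
#'
#' `K_ec = Z_e H_e Z_e^T`: spreads the environment relationship matrix
#' to observations, so entry (a, b) is `H_e[env(a), env(b)]`.
#'
#' @param Ze environment incidence matrix (n x I).
#' @param He environment relationship matrix (I x I).
#' @return n x n matrix.
#' @export
expandedEnvKernel <- function(Ze, He) {
  if (ncol(Ze) != nrow(He)) stop("Ze and He dimensions do not match")
  Ze %*% He %*% t(Ze)
}

#' Genotype-by-environment interaction kernel
#'
#' Hadamard product `K_env ⊙ Z_g K_g Z_g^T`, giving `K_ge` when the
#' environmental factor is `K_e` and `K_gec` when it is `K_ec`. PSD of
#' both factors implies PSD of the product (Schur product theorem).
#'
#' @param KenvObs observation-level environmental kernel (n x n).
#' @param Zg genotype incidence matrix (n x J).
#' @param Kg genomic relationship matrix (J x J).
#' @return n x n matrix.
#' @export
interactionKernel <- function(KenvObs, Zg, Kg) {
  if (nrow(KenvObs) != nrow(Zg)) stop("kernel/design dimension mismatch")
  if (ncol(Zg) != nrow(Kg)) stop("Zg and Kg dimensions do not match")
  KenvObs * (Zg %*% Kg %*% t(Zg))
}

# Symmetry + near-PSD check; adds 1e-8 ridge when the smallest
# eigenvalue sits below 1e-10, errors when genuinely indefinite.
ensurePSD <- function(k, label = "kernel", tol = 1e-8) {
  if (max(abs(k - t(k))) > 1e-10) stop(label, " is not symmetric")
  ev <- eigen((k + t(k)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol) stop(label, " is not PSD (min eigenvalue ", min(ev), ")")
  if (min(ev) < 1e-10) k <- k + diag(tol, nrow(k))
  k
}
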