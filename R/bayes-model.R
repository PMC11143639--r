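#' @include AllClasses.R kernels.R
NULL

#' Specify a Bayesian multi-kernel model
#'
#' Assembles the pieces of the mixed kernel/ridge model
#' `y = mu + sum_t u_t + sum_b X_b beta_b + eps`, where each RKHS term
#' `u_t ~ N(0, sigma2_t K_t)` is a random effect with a relationship
#' kernel as covariance and each ridge block's coefficients get an
#' i.i.d. normal prior (Bayesian ridge regression). Every variance has
#' a scaled-inverse-chi-square prior.
#'
#' Prior scales default to a variance budget: the prior mode assigns a
#' fraction `R2` (default 0.5) of the training response variance split
#' equally across the model terms, with the remainder going to the
#' residual. Each scale can be overridden through `priors$scale`.
#'
#' @param rkhsTerms named list of n x n symmetric PSD kernels.
#' @param ridgeTerms named list of n x q covariate matrices.
#' @param y length-n response; entries at non-training rows may be `NA`.
#' @param trainRows rows entering the likelihood. Test rows never
#'   contribute to any full conditional.
#' @param priors list: `df` (default 5), `R2` (default 0.5), optional
#'   named `scale`.
#' @param mcmc list: `nIter` (default 10000), `burnIn` (2000),
#'   `thin` (5), `seed` (1).
#' @param fixedVariances named numeric of variances to hold fixed
#'   rather than sample (term names, or `"residual"`); used for
#'   conjugate closed-form checks.
#' @return a [KernelModelSpec-class].
#' @export
kernelModelSpec <- function(rkhsTerms = list(), ridgeTerms = list(),
                            y, trainRows,
                            priors = list(),
                            mcmc = list(),
                            fixedVariances = numeric()) {
  priors <- utils::modifyList(list(df = 5, R2 = 0.5, scale = NULL), priors)
  mcmc <- utils::modifyList(
    list(nIter = 10000L, burnIn = 2000L, thin = 5L, seed = 1L), mcmc)
  new("KernelModelSpec",
      rkhsTerms = rkhsTerms, ridgeTerms = ridgeTerms,
      y = as.numeric(y), trainRows = as.integer(trainRows),
      priors = priors, mcmc = mcmc,
      fixedVariances = fixedVariances)
}

# lag-1 autocorrelation-adjusted Monte-Carlo standard error
mcse <- function(x) {
  n <- length(x)
  if (n < 10 || stats::sd(x) == 0) return(stats::sd(x) / sqrt(max(n, 1)))
  rho <- suppressWarnings(stats::cor(x[-1], x[-n]))
  if (!is.finite(rho)) rho <- 0
  rho <- min(max(rho, 0), 0.99)
  stats::sd(x) / sqrt(n * (1 - rho) / (1 + rho))
}

#' Fit the multi-kernel model by Gibbs sampling
#'
#' Runs a blocked Gibbs sampler. Each RKHS term is handled in the
#' eigenbasis of its kernel restricted to the training rows
#' (`K[train, train] = U D U'`): with `u_train = U D^{1/2} delta` and
#' `delta ~ N(0, sigma2_t I)`, the orthogonality of `U` makes the full
#' conditional of `delta` diagonal, so the whole block is drawn in one
#' vectorized step. Effects at held-out rows are the Gaussian
#' conditional mean `K[test, train] K[train, train]^+ u_train`, which
#' gives the same posterior means as sampling the full-kernel
#' eigenbasis because the likelihood only touches training rows.
#' Ridge blocks are drawn through the thin SVD of the training design
#' (rotated coordinates have a diagonal full conditional; the null
#' space, which the likelihood cannot see, is drawn from its prior so
#' variance updates remain exact). Eigen/singular values below 1e-10
#' (relative) are truncated.
#'
#' Update order per sweep: intercept, each RKHS block, each ridge
#' block, each term variance, residual variance.
#'
#' @param spec a [KernelModelSpec-class].
#' @return a [KernelModelFit-class]; `predictions()` gives the
#'   posterior-predictive mean for all n rows.
#' @export
fitKernelModel <- function(spec) {
  stopifnot(is(spec, "KernelModelSpec"))
  validObject(spec)
  mc <- spec@mcmc
  set.seed(mc$seed)
  tr <- spec@trainRows
  y_tr <- spec@y[tr]
  n_tr <- length(tr)
  n <- length(spec@y)
  df0 <- spec@priors$df
  R2 <- spec@priors$R2
  vy <- stats::var(y_tr)
  if (!is.finite(vy) || vy <= 0) vy <- 1

  rk_names <- names(spec@rkhsTerms)
  rg_names <- names(spec@ridgeTerms)
  n_terms <- length(rk_names) + length(rg_names)
  budget <- if (n_terms > 0) R2 * vy / n_terms else 0

  # --- precompute per-term structures -------------------------------
  rk <- lapply(rk_names, function(nm) {
    K <- ensurePSD(spec@rkhsTerms[[nm]], nm)
    Ktt <- K[tr, tr, drop = FALSE]
    eg <- eigen((Ktt + t(Ktt)) / 2, symmetric = TRUE)
    keep <- eg$values > max(eg$values, 0) * 1e-10 & eg$values > 1e-10
    if (!any(keep)) stop("kernel '", nm, "' has no usable eigenvalues")
    d <- eg$values[keep]
    U <- eg$vectors[, keep, drop = FALSE]
    # A[tr, ] equals the design U D^{1/2}; other rows extend the effect
    A <- K[, tr, drop = FALSE] %*% U %*% diag(1 / sqrt(d), length(d))
    mode_v <- budget / max(mean(diag(Ktt)), 1e-12)
    list(name = nm, d = d, W = A[tr, , drop = FALSE], A = A,
         m = length(d), S0 = mode_v * (df0 + 2) / df0)
  })
  names(rk) <- rk_names

  rg <- lapply(rg_names, function(nm) {
    X <- as.matrix(spec@ridgeTerms[[nm]])
    Xtr <- X[tr, , drop = FALSE]
    sv <- svd(Xtr)
    keep <- sv$d > max(sv$d, 0) * 1e-10 & sv$d > 1e-10
    d <- sv$d[keep]
    U <- sv$u[, keep, drop = FALSE]
    V <- sv$v[, keep, drop = FALSE]
    msx <- sum(apply(Xtr, 2, stats::var))
    mode_v <- budget / max(msx, 1e-12)
    list(name = nm, X = X, Xtr = Xtr, d = d, U = U, V = V,
         q = ncol(X), m = length(d), S0 = mode_v * (df0 + 2) / df0)
  })
  names(rg) <- rg_names

  S0_e <- max((1 - R2) * vy, 1e-12) * (df0 + 2) / df0
  user_scale <- spec@priors$scale
  if (!is.null(user_scale)) {
    for (nm in intersect(names(user_scale), rk_names)) rk[[nm]]$S0 <- user_scale[[nm]]
    for (nm in intersect(names(user_scale), rg_names)) rg[[nm]]$S0 <- user_scale[[nm]]
    if ("residual" %in% names(user_scale)) S0_e <- user_scale[["residual"]]
  }

  fixed <- spec@fixedVariances
  is_fixed <- function(nm) nm %in% names(fixed)

  # --- state --------------------------------------------------------
  mu <- mean(y_tr)
  delta <- lapply(rk, function(t) numeric(t$m))
  fit_rk <- lapply(rk, function(t) numeric(n_tr))
  beta <- lapply(rg, function(t) numeric(t$q))
  fit_rg <- lapply(rg, function(t) numeric(n_tr))
  v_rk <- vapply(rk, function(t)
    if (is_fixed(t$name)) fixed[[t$name]] else t$S0 * df0 / (df0 + 2),
    numeric(1))
  v_rg <- vapply(rg, function(t)
    if (is_fixed(t$name)) fixed[[t$name]] else t$S0 * df0 / (df0 + 2),
    numeric(1))
  v_e <- if (is_fixed("residual")) fixed[["residual"]] else
    S0_e * df0 / (df0 + 2)

  resid <- y_tr - mu

  n_iter <- mc$nIter; burn <- mc$burnIn; thin <- mc$thin
  saved <- 0L
  mu_sum <- 0
  delta_sum <- lapply(rk, function(t) numeric(t$m))
  beta_sum <- lapply(rg, function(t) numeric(t$q))
  v_sum <- numeric(length(rk) + length(rg) + 1)
  pred_sum <- numeric(n); pred_ssq <- numeric(n)
  int_draws <- numeric(0)
  beta_draws <- lapply(rg, function(t)
    matrix(0, 0, t$q))
  keep_beta_draws <- vapply(rg, function(t) t$q <= 200, logical(1))

  for (it in seq_len(n_iter)) {
    # intercept (flat prior)
    resid <- resid + mu
    mu <- stats::rnorm(1, mean(resid), sqrt(v_e / n_tr))
    resid <- resid - mu

    # RKHS blocks: diagonal full conditional in the kernel eigenbasis
    for (k in seq_along(rk)) {
      t <- rk[[k]]
      resid <- resid + fit_rk[[k]]
      prec <- t$d / v_e + 1 / v_rk[k]
      mn <- (crossprod(t$W, resid) / v_e) / prec
      delta[[k]] <- drop(mn) + stats::rnorm(t$m) / sqrt(prec)
      fit_rk[[k]] <- drop(t$W %*% delta[[k]])
      resid <- resid - fit_rk[[k]]
    }

    # ridge blocks via thin SVD; null-space coefficients from prior
    for (k in seq_along(rg)) {
      t <- rg[[k]]
      resid <- resid + fit_rg[[k]]
      prec <- t$d^2 / v_e + 1 / v_rg[k]
      utr <- crossprod(t$U, resid)
      alpha <- drop((t$d * utr / v_e) / prec) + stats::rnorm(t$m) / sqrt(prec)
      b <- drop(t$V %*% alpha)
      if (t$q > t$m) {
        z <- stats::rnorm(t$q) * sqrt(v_rg[k])
        b <- b + z - drop(t$V %*% crossprod(t$V, z))
      }
      beta[[k]] <- b
      fit_rg[[k]] <- drop(t$U %*% (t$d * alpha))
      resid <- resid - fit_rg[[k]]
    }

    # variances
    for (k in seq_along(rk)) {
      if (!is_fixed(rk[[k]]$name)) {
        ss <- sum(delta[[k]]^2)
        v_rk[k] <- (df0 * rk[[k]]$S0 + ss) /
          stats::rchisq(1, df0 + rk[[k]]$m)
      }
    }
    for (k in seq_along(rg)) {
      if (!is_fixed(rg[[k]]$name)) {
        ss <- sum(beta[[k]]^2)
        v_rg[k] <- (df0 * rg[[k]]$S0 + ss) /
          stats::rchisq(1, df0 + rg[[k]]$q)
      }
    }
    if (!is_fixed("residual")) {
      v_e <- (df0 * S0_e + sum(resid^2)) / stats::rchisq(1, df0 + n_tr)
    }

    if (it > burn && (it - burn) %% thin == 0L) {
      saved <- saved + 1L
      mu_sum <- mu_sum + mu
      int_draws <- c(int_draws, mu)
      pred <- rep(mu, n)
      for (k in seq_along(rk)) {
        delta_sum[[k]] <- delta_sum[[k]] + delta[[k]]
        pred <- pred + drop(rk[[k]]$A %*% delta[[k]])
      }
      for (k in seq_along(rg)) {
        beta_sum[[k]] <- beta_sum[[k]] + beta[[k]]
        if (keep_beta_draws[k]) {
          beta_draws[[k]] <- rbind(beta_draws[[k]], beta[[k]])
        }
        pred <- pred + drop(rg[[k]]$X %*% beta[[k]])
      }
      pred_sum <- pred_sum + pred
      pred_ssq <- pred_ssq + pred^2
      v_sum <- v_sum + c(v_rk, v_rg, v_e)
    }
  }
  if (saved == 0L) stop("no post-burn-in draws saved; check nIter/burnIn/thin")

  effects <- lapply(seq_along(rk), function(k)
    drop(rk[[k]]$A %*% (delta_sum[[k]] / saved)))
  names(effects) <- rk_names
  coefs <- lapply(seq_along(rg), function(k) {
    b <- beta_sum[[k]] / saved
    names(b) <- colnames(rg[[k]]$X)
    b
  })
  names(coefs) <- rg_names
  variances <- v_sum / saved
  names(variances) <- c(rk_names, rg_names, "residual")
  predictions <- pred_sum / saved
  pred_sd <- sqrt(pmax(pred_ssq / saved - predictions^2, 0))

  coef_mcse <- lapply(seq_along(rg), function(k) {
    if (keep_beta_draws[k] && nrow(beta_draws[[k]]) > 1) {
      apply(beta_draws[[k]], 2, mcse)
    } else NULL
  })
  names(coef_mcse) <- rg_names

  new("KernelModelFit",
      posteriorMeans = list(
        intercept = mu_sum / saved,
        effects = effects,
        coefficients = coefs,
        variances = variances),
      predictions = predictions,
      diagnostics = list(
        nDraws = saved,
        interceptMCSE = mcse(int_draws),
        coefficientMCSE = coef_mcse,
        predictionSd = pred_sd,
        predictionMCSE = pred_sd / sqrt(saved)),
      seed = as.integer(mc$seed))
}

#' Posterior-mean predictions at selected rows
#'
#' @param object a [KernelModelFit-class].
#' @param rows row indices (default: all).
#' @param ... ignored.
#' @return numeric vector of posterior-predictive means.
#' @export
setMethod("predict", "KernelModelFit", function(object, rows = NULL, ...) {
  p <- object@predictions
  if (is.null(rows)) p else p[rows]
})
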