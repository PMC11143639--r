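# Small deterministic fixtures, built in code.

# A hand-sized MET dataset: 3 environments, 4 lines, unbalanced.
tinyDataset <- function(seed = 1) {
  set.seed(seed)
  envs <- c("E1", "E2", "E3")
  lines <- c("L1", "L2", "L3", "L4")
  obs <- data.frame(
    env = c("E1", "E1", "E1", "E2", "E2", "E3", "E3", "E3"),
    line = c("L1", "L2", "L3", "L1", "L4", "L2", "L3", "L4"),
    stringsAsFactors = FALSE)
  obs$trait1 <- round(rnorm(nrow(obs), 10), 3)
  obs$trait2 <- round(rnorm(nrow(obs), 5), 3)
  M <- matrix(sample(0:2, 4 * 6, replace = TRUE), 4, 6,
              dimnames = list(lines, paste0("snp", 1:6)))
  M[, 1] <- c(0, 1, 2, 1)  # guarantee polymorphism
  X <- matrix(rnorm(3 * 8), 3, 8,
              dimnames = list(envs, paste0("var01_d00", 1:8)))
  idx <- matrix(rnorm(nrow(obs) * 3), ncol = 3,
                dimnames = list(NULL, paste0("index", 1:3)))
  new("MetDataset", observations = obs, markers = M, envCovariates = X,
      indices = idx, traits = c("trait1", "trait2"), truth = NULL)
}

# Construct a column whose sample correlation with y is exactly rho.
makeCorrCol <- function(y, rho, seed = 1) {
  set.seed(seed)
  n <- length(y)
  z <- drop(scale(y))
  w <- rnorm(n)
  w <- w - z * sum(w * z) / sum(z * z)   # orthogonal to z
  w <- drop(scale(w))
  rho * z + sqrt(1 - rho^2) * w
}

# Default fast MCMC settings for unit tests.
fastMcmc <- function(seed = 1) {
  list(nIter = 1200L, burnIn = 400L, thin = 2L, seed = seed)
}
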