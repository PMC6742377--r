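# Shared fixture builders. Everything is generated in code at test time.

# Data whose *sample* correlation matrix equals R exactly: whiten an
# arbitrary full-rank draw, then colour by chol(R).
exact_cor_data <- function(R, n, seed = 1) {
  set.seed(seed)
  p <- ncol(R)
  X <- matrix(rnorm(n * p), n, p)
  Xc <- scale(X, scale = FALSE)
  Z <- Xc %*% solve(chol(cov(Xc)))
  Y <- Z %*% chol(R)
  colnames(Y) <- colnames(R)
  as.data.frame(Y)
}

# Implied covariance of the chain x -> m -> y with unit total variances.
chain_cov <- function(a, b) {
  m <- matrix(c(1, a, a * b,
                a, 1, b,
                a * b, b, 1), 3, 3,
              dimnames = rep(list(c("x", "m", "y")), 2))
  m
}

# Simulate raw data from the standardized chain x -> m -> y.
chain_data <- function(n, a, b) {
  x <- rnorm(n)
  m <- a * x + sqrt(1 - a^2) * rnorm(n)
  y <- b * m + sqrt(1 - b^2) * rnorm(n)
  data.frame(x = x, m = m, y = y)
}

chain_spec_paths <- function() data.frame(from = c("x", "m"), to = c("m", "y"))

# Direct Newton-Raphson solve of the logistic score equations; an oracle
# independent of glm.fit's IRLS.
newton_logistic <- function(X, y, tol = 1e-12, maxit = 100) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    score <- drop(t(X) %*% (y - mu))
    H <- t(X) %*% (X * (mu * (1 - mu)))
    step <- solve(H, score)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  list(beta = beta, vcov = solve(H))
}

# One-factor genotype block with per-SNP latent loadings: SNP j's latent
# normal is loading[j] * shared + sqrt(1 - loading^2) * unique, thresholded
# at the HWE quantiles. A small loading plants a low-communality member.
loaded_genotypes <- function(loadings, maf, n) {
  shared <- rnorm(n)
  sapply(loadings, function(l) {
    z <- l * shared + sqrt(1 - l^2) * rnorm(n)
    (z > qnorm((1 - maf)^2)) + (z > qnorm(1 - maf^2))
  })
}

# Normalized varimax criterion (Kaiser row-normalized), for grid oracles.
varimax_criterion <- function(L) {
  h <- sqrt(rowSums(L^2))
  W <- L / h
  sum(apply(W^2, 2, function(x) mean(x^2) - mean(x)^2))
}

published_effects <- function() {
  tibble::tribble(
    ~source, ~target, ~component, ~value,
    "SUB", "BMI", "direct", 0.632,
    "SUB", "WC",  "direct", 0.041,
    "BMI", "WC",  "direct", 0.797,
    "SUB", "T2D", "direct", 0.085,
    "WC",  "T2D", "direct", 0.097,
    "BMI", "HTN", "direct", 0.140,
    "WC",  "HTN", "direct", 0.052,
    "SUB", "T2D", "total",  0.123,
    "BMI", "HTN", "total",  0.186
  )
}
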