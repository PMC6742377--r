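# Standardized direct/indirect/total effect decomposition with delta-method
# standard errors, and the bootstrap alternative for indirect effects.

# Effects from a standardized path matrix B (B[i, j] = effect of j on i):
# total = (I - B)^-1 - I, direct = B, indirect = total - direct.
decompose_matrix <- function(B) {
  nv <- ncol(B)
  total <- solve(diag(nv) - B) - diag(nv)
  dimnames(total) <- dimnames(B)
  list(direct = B, indirect = total - B, total = total)
}

# Recompute the standardized-effect vector for given cells at parameter
# vector theta; used both at the estimate and inside the delta-method
# Jacobian.
effect_vector <- function(ram, theta, cells) {
  Sig <- implied_covariance(ram, theta)
  Sigma_all <- attr(Sig, "Sigma_all")
  sds <- sqrt(pmax(diag(Sigma_all), .Machine$double.eps))
  m <- ram_matrices(ram, theta)
  A_std <- m$A * outer(1 / sds, sds)
  dec <- decompose_matrix(A_std)
  unlist(lapply(seq_len(nrow(cells)), function(r) {
    i <- cells$ti[r]; j <- cells$si[r]
    c(dec$direct[i, j], dec$indirect[i, j], dec$total[i, j])
  }))
}

#' Standardized direct, indirect, and total effects
#'
#' Decomposes the fitted standardized path matrix over all variables (latent
#' and observed) into direct effects, indirect effects (the sum over all
#' mediated path products), and total effects, for every (source,
#' endogenous target) pair with a nonzero total effect. The identity
#' total = direct + indirect holds exactly. Standard errors come from the
#' delta method using the fitted parameter covariance; `statistic` is
#' estimate/SE with significance stars * p<.10, ** p<.05, *** p<.01.
#'
#' @param fit A converged [fit_ml()] result.
#' @return A tibble of class `effect_table`: `source`, `target`, then
#'   `direct`, `indirect`, `total`, each with `_se`, `_z`, and `_stars`
#'   companions.
#' @export
effect_decomposition <- function(fit) {
  if (!inherits(fit, "sem_fit")) abort("`fit` must be a sem_fit")
  if (!fit$convergence$converged)
    abort("refusing to decompose effects of a non-converged fit")
  vars <- fit$ram$variables
  dec <- decompose_matrix(fit$A_std)
  endo <- fit$spec$endogenous
  cells <- tidyr::expand_grid(target = endo, source = vars) |>
    filter(.data$source != .data$target) |>
    mutate(ti = match(.data$target, vars), si = match(.data$source, vars)) |>
    filter(abs(dec$total[cbind(.data$ti, .data$si)]) > 1e-12)
  est <- effect_vector(fit$ram, fit$theta, cells)
  se <- rep(NA_real_, length(est))
  if (!is.null(fit$acov) && all(is.finite(fit$acov))) {
    J <- numeric_jacobian(function(th) effect_vector(fit$ram, th, cells),
                          fit$theta)
    V <- J %*% fit$acov %*% t(J)
    se <- sqrt(pmax(diag(V), 0))
  }
  idx <- function(k) seq(k, by = 3, length.out = nrow(cells))
  out <- cells |>
    select("source", "target") |>
    mutate(
      direct = est[idx(1)], direct_se = se[idx(1)],
      indirect = est[idx(2)], indirect_se = se[idx(2)],
      total = est[idx(3)], total_se = se[idx(3)]
    ) |>
    mutate(
      direct_z = .data$direct / .data$direct_se,
      indirect_z = .data$indirect / .data$indirect_se,
      total_z = .data$total / .data$total_se,
      direct_stars = effect_stars(2 * pnorm(abs(.data$direct_z), lower.tail = FALSE)),
      indirect_stars = effect_stars(2 * pnorm(abs(.data$indirect_z), lower.tail = FALSE)),
      total_stars = effect_stars(2 * pnorm(abs(.data$total_z), lower.tail = FALSE))
    )
  class(out) <- c("effect_table", class(out))
  attr(out, "n") <- fit$n
  out
}

numeric_jacobian <- function(f, x, h = 1e-6) {
  f0 <- f(x)
  J <- matrix(0, length(f0), length(x))
  for (i in seq_along(x)) {
    hi <- h * max(1, abs(x[i]))
    xp <- x; xp[i] <- xp[i] + hi
    xm <- x; xm[i] <- xm[i] - hi
    J[, i] <- (f(xp) - f(xm)) / (2 * hi)
  }
  J
}

#' Bootstrap percentile intervals for indirect effects
#'
#' Nonparametric case resampling: rows of the spec's raw data are resampled
#' with replacement, the model is refitted to each resample's covariance
#' matrix (warm-started at the full-sample solution), and percentile
#' intervals are formed for every standardized indirect effect that is
#' nonzero in the full-sample fit. Reproducible under a fixed seed. Matrix
#' input mode is not supported — the empirical distribution requires raw
#' rows.
#'
#' @param spec A [sem_spec()] built with `data`.
#' @param B Number of bootstrap replicates (at least 200).
#' @param seed Integer seed.
#' @param level Confidence level (default 0.95).
#' @return A tibble: `source`, `target`, `estimate`, `lower`, `upper`,
#'   `B_used` (replicates that converged).
#' @export
bootstrap_indirect <- function(spec, B = 500, seed = 1, level = 0.95) {
  if (!inherits(spec, "sem_spec")) abort("`spec` must be a sem_spec")
  if (is.null(spec$data))
    abort("bootstrap requires raw-data input; matrix mode is unsupported")
  if (B < 200) abort("`B` must be at least 200")
  set.seed(as.integer(seed))
  full <- fit_ml(spec)
  eff <- effect_decomposition(full)
  cells <- filter(eff, abs(.data$indirect) > 1e-12)
  if (nrow(cells) == 0)
    abort("the fitted model has no indirect effects to bootstrap")
  vars <- full$ram$variables
  cells_idx <- tibble(source = cells$source, target = cells$target,
                      si = match(cells$source, vars),
                      ti = match(cells$target, vars))
  d <- spec$data[, spec$observed, drop = FALSE]
  d <- d[complete.cases(d), , drop = FALSE]
  nobs <- nrow(d)
  dm <- as.matrix(d)
  draws <- matrix(NA_real_, B, nrow(cells_idx))
  obj_theta0 <- full$theta
  for (b in seq_len(B)) {
    idx <- sample.int(nobs, nobs, replace = TRUE)
    Sb <- cov(dm[idx, , drop = FALSE])
    ramb <- full$ram
    ramb$par$start[ramb$par$free] <- obj_theta0
    obj <- sem_objective_env(ramb, Sb)
    opt <- tryCatch(optim(obj_theta0, obj$fn, obj$gr, method = "BFGS",
                          control = list(maxit = 500, reltol = 1e-12)),
                    error = function(e) NULL)
    if (is.null(opt)) next
    vals <- effect_vector(full$ram, opt$par, cells_idx)
    draws[b, ] <- vals[seq(2, by = 3, length.out = nrow(cells_idx))]
  }
  a <- (1 - level) / 2
  tibble(
    source = cells_idx$source, target = cells_idx$target,
    estimate = cells$indirect,
    lower = apply(draws, 2, quantile, probs = a, na.rm = TRUE, names = FALSE),
    upper = apply(draws, 2, quantile, probs = 1 - a, na.rm = TRUE, names = FALSE),
    B_used = apply(draws, 2, function(x) sum(!is.na(x)))
  )
}
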