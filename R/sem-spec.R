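# Step 4 (part 1): declarative structural model and its RAM
# parameterization. A model is a set of directed paths over observed and
# latent variables, free variances/covariances of exogenous terms, and
# optional correlated-residual pairs. The implied covariance is
# F (I - A)^-1 S (I - A)^-T F^T.

#' Declare a structural equation model
#'
#' @param paths Data frame with columns `from`, `to`, and optionally `value`
#'   (a number to fix the path at; `NA` or absent means free). Latent-to-
#'   observed paths are measurement loadings. The directed edge set must be
#'   acyclic (recursive structural part).
#' @param latent Character vector of latent variable names. Each latent
#'   variable's (residual) variance is fixed at 1 for scale identification;
#'   fix a loading instead by giving it a `value` and keeping the others
#'   free.
#' @param covariances `"exogenous"` (default: free covariances among all
#'   exogenous variables), `"none"`, or a data frame `var1`/`var2` of pairs
#'   to free.
#' @param residual_covariances Optional data frame `var1`/`var2` of
#'   endogenous pairs whose residuals (measurement errors) are allowed to
#'   correlate.
#' @param data Raw data frame holding the observed variables (one input mode),
#'   or
#' @param sample_cov Labelled covariance/correlation matrix with `n` (matrix
#'   input mode).
#' @param n Sample size, required with `sample_cov`.
#' @param variables Optional extra variable names not appearing in any path
#'   (e.g. to declare an independence model with no paths at all).
#' @return An object of class `sem_spec`.
#' @seealso [fit_ml()]
#' @export
sem_spec <- function(paths, latent = character(0), covariances = "exogenous",
                     residual_covariances = NULL, data = NULL,
                     sample_cov = NULL, n = NULL, variables = NULL) {
  paths <- as_tibble(paths)
  if (nrow(paths) == 0 && !all(c("from", "to") %in% names(paths)))
    paths <- tibble(from = character(0), to = character(0))
  if (!all(c("from", "to") %in% names(paths)))
    abort("`paths` needs columns `from` and `to`")
  if (!"value" %in% names(paths)) paths$value <- NA_real_
  vars <- unique(c(paths$from, paths$to, latent, variables))
  if (length(vars) == 0) abort("the model declares no variables")
  ts <- topo_sort(vars, paths)
  if (is.null(ts$order))
    abort(sprintf("structural paths contain a cycle through: %s",
                  paste(ts$cycle, collapse = ", ")))
  ord <- ts$order
  observed <- setdiff(ord, latent)
  if (!is.null(data)) {
    missing <- setdiff(observed, names(data))
    if (length(missing) > 0)
      abort(sprintf("data lacks observed variables: %s",
                    paste(missing, collapse = ", ")))
  } else if (!is.null(sample_cov)) {
    check_square_named(sample_cov, "sample_cov")
    missing <- setdiff(observed, rownames(sample_cov))
    if (length(missing) > 0)
      abort(sprintf("sample_cov lacks observed variables: %s",
                    paste(missing, collapse = ", ")))
    if (is.null(n)) abort("`n` must be supplied with `sample_cov`")
  }
  endo <- unique(paths$to)
  exo <- setdiff(ord, endo)
  free_cov <- if (is.data.frame(covariances)) {
    as_tibble(covariances)[, c("var1", "var2")]
  } else if (identical(covariances, "exogenous")) {
    if (length(exo) >= 2) {
      cmb <- utils::combn(exo, 2)
      tibble(var1 = cmb[1, ], var2 = cmb[2, ])
    } else tibble(var1 = character(0), var2 = character(0))
  } else if (identical(covariances, "none")) {
    tibble(var1 = character(0), var2 = character(0))
  } else abort("`covariances` must be \"exogenous\", \"none\", or a var1/var2 data frame")
  if (!is.null(residual_covariances))
    free_cov <- dplyr::distinct(bind_rows(
      free_cov, as_tibble(residual_covariances)[, c("var1", "var2")]))
  structure(
    list(paths = paths, variables = ord, latent = latent,
         observed = observed, endogenous = intersect(ord, endo),
         exogenous = exo, free_covariances = free_cov,
         data = data, sample_cov = sample_cov, n = n),
    class = "sem_spec"
  )
}

# Parameter table + start values. Rows: one per free or fixed nonzero entry
# of A (directed paths) and S (variances/covariances). Start values for
# paths come from per-equation least squares on the sample covariance where
# the parents are observed.
build_ram <- function(spec, S_obs) {
  vars <- spec$variables
  nv <- length(vars)
  obs <- spec$observed
  par <- list()
  add <- function(mat, i, j, free, value, start, from, to, type) {
    par[[length(par) + 1]] <<- tibble(
      matrix = mat, row = i, col = j, free = free, value = value,
      start = start, from = from, to = to, type = type)
  }
  sdiag <- setNames(rep(1, nv), vars)
  sdiag[obs] <- diag(S_obs)[obs]

  # A entries: A[child, parent]
  for (r in seq_len(nrow(spec$paths))) {
    pfrom <- spec$paths$from[r]; pto <- spec$paths$to[r]
    fixedv <- spec$paths$value[r]
    start <- 0.3 * sqrt(sdiag[[pto]] / sdiag[[pfrom]])
    add("A", match(pto, vars), match(pfrom, vars), is.na(fixedv),
        ifelse(is.na(fixedv), NA_real_, fixedv), start, pfrom, pto, "path")
  }
  # refine starts by least squares where every parent is observed
  partab <- list_rbind(par)
  resid_start <- sdiag
  for (y in spec$endogenous) {
    parents <- spec$paths$from[spec$paths$to == y]
    if (y %in% obs && all(parents %in% obs)) {
      beta <- tryCatch(solve(S_obs[parents, parents, drop = FALSE],
                             S_obs[parents, y]),
                       error = function(e) NULL)
      if (!is.null(beta)) {
        for (k in seq_along(parents)) {
          idx <- which(partab$matrix == "A" & partab$to == y &
                         partab$from == parents[k])
          if (partab$free[idx]) partab$start[idx] <- beta[k]
        }
        rv <- S_obs[y, y] - sum(beta * S_obs[parents, y])
        resid_start[y] <- max(rv, 0.05 * S_obs[y, y])
      }
    }
  }
  par <- list(partab)

  # S diagonal
  for (v in vars) {
    lat <- v %in% spec$latent
    add("S", match(v, vars), match(v, vars), !lat,
        ifelse(lat, 1, NA_real_), resid_start[[v]], v, v,
        ifelse(v %in% spec$endogenous, "residual_variance", "variance"))
  }
  # S off-diagonal (free covariances / correlated residuals)
  fc <- spec$free_covariances
  for (r in seq_len(nrow(fc))) {
    v1 <- fc$var1[r]; v2 <- fc$var2[r]
    start <- if (v1 %in% obs && v2 %in% obs &&
                 !(v1 %in% spec$endogenous) && !(v2 %in% spec$endogenous))
      S_obs[v1, v2] else 0
    add("S", match(v1, vars), match(v2, vars), TRUE, NA_real_, start,
        v1, v2, "covariance")
  }
  partab <- list_rbind(par)
  partab$param_id <- ifelse(partab$free, cumsum(partab$free), NA_integer_)
  list(variables = vars, observed = obs, par = partab,
       n_free = sum(partab$free))
}

ram_matrices <- function(ram, theta) {
  nv <- length(ram$variables)
  A <- matrix(0, nv, nv, dimnames = list(ram$variables, ram$variables))
  S <- matrix(0, nv, nv, dimnames = list(ram$variables, ram$variables))
  p <- ram$par
  vals <- ifelse(p$free, theta[p$param_id], p$value)
  for (r in seq_len(nrow(p))) {
    if (p$matrix[r] == "A") {
      A[p$row[r], p$col[r]] <- vals[r]
    } else {
      S[p$row[r], p$col[r]] <- vals[r]
      S[p$col[r], p$row[r]] <- vals[r]
    }
  }
  list(A = A, S = S)
}

#' Model-implied covariance matrix of a RAM parameterization
#'
#' Evaluates `F (I - A)^-1 S (I - A)^-T F^T` over the observed variables,
#' where `A` holds the directed-path coefficients and `S` the covariances of
#' exogenous terms and residuals.
#'
#' @param ram A RAM structure as stored in a fitted model (`fit$ram`), or
#'   any list with `variables`, `observed`, and a parameter table `par`.
#' @param theta Free-parameter vector.
#' @return Implied covariance matrix over the observed variables, with
#'   attribute `Sigma_all` (covariance over all variables, latent included).
#' @export
implied_covariance <- function(ram, theta) {
  m <- ram_matrices(ram, theta)
  IA <- diag(length(ram$variables)) - m$A
  E <- tryCatch(solve(IA), error = function(e)
    abort("(I - A) is singular: structural coefficients imply a non-recursive or degenerate system"))
  Sigma_all <- E %*% m$S %*% t(E)
  dimnames(Sigma_all) <- list(ram$variables, ram$variables)
  out <- Sigma_all[ram$observed, ram$observed, drop = FALSE]
  attr(out, "Sigma_all") <- Sigma_all
  out
}
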