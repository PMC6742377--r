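# Step 3b: recursive path analysis that fixes the mediation ordering among
# the intermediate phenotypes and diseases.

#' Declare a recursive (acyclic) path model
#'
#' @param edges Tibble/data frame with columns `from` and `to`, one directed
#'   edge per row. The edge set must be acyclic.
#' @param variables Optional variable ordering; defaults to order of first
#'   appearance. The stored order is topological.
#' @return An object of class `path_spec` with `edges` and the topologically
#'   ordered `variables`.
#' @export
path_spec <- function(edges, variables = NULL) {
  edges <- as_tibble(edges)[, c("from", "to")]
  vars <- variables %||% unique(c(edges$from, edges$to))
  missing <- setdiff(unique(c(edges$from, edges$to)), vars)
  if (length(missing) > 0)
    abort(sprintf("edge variables not declared: %s", paste(missing, collapse = ", ")))
  ts <- topo_sort(vars, edges)
  if (is.null(ts$order))
    abort(sprintf("the edge set contains a cycle through: %s",
                  paste(ts$cycle, collapse = ", ")))
  structure(list(edges = edges, variables = ts$order), class = "path_spec")
}

#' The published mediation ordering among phenotypes and diseases
#'
#' The recursive ordering established for the KARE phenotypes on clinical
#' grounds: subcutaneous adiposity drives overall adiposity, both drive
#' abdominal adiposity, the three adiposity traits drive T2D, and all four
#' drive hypertension (T2D is a risk factor for hypertension). Ten directed
#' edges; topological order SUB, BMI, WC, T2D, HTN.
#'
#' @return A `path_spec` with 10 edges over SUB, BMI, WC, T2D, HTN.
#' @export
default_disease_paths <- function() {
  edges <- tibble(
    from = c("SUB", "SUB", "BMI", "SUB", "BMI", "WC", "SUB", "BMI", "WC", "T2D"),
    to   = c("BMI", "WC",  "WC",  "T2D", "T2D", "T2D", "HTN", "HTN", "HTN", "HTN")
  )
  path_spec(edges, variables = c("SUB", "BMI", "WC", "T2D", "HTN"))
}

#' Fit a recursive path model by standardized least squares
#'
#' For a recursive (acyclic) system, the standardized coefficients of each
#' endogenous variable on its parents solve the normal equations on the
#' correlation matrix; the fit is therefore identical whether computed from
#' raw data or from the data's correlation matrix. Standard errors use the
#' standardized OLS formula with `n - k - 1` degrees of freedom per
#' equation.
#'
#' @param spec A [path_spec()].
#' @param data Raw data frame (used if `cor_matrix` is `NULL`); covariates,
#'   if given, are partialled out via [partial_correlation()].
#' @param cor_matrix Labelled correlation (or covariance) matrix covering the
#'   spec variables; must be positive semi-definite and accompanied by `n`.
#' @param n Sample size for matrix input.
#' @param covariates Covariate columns to adjust for in raw-data mode.
#' @return An object of class `path_fit`: `estimates` tibble (`from`, `to`,
#'   `estimate`, `std_error`, `statistic`, `p_value`), the correlation
#'   matrix used, `n`, and the spec.
#' @examples
#' fit <- path_fit(default_disease_paths(),
#'                 cor_matrix = kare_phenotype_correlations(), n = 8792)
#' tidy(fit)
#' @export
path_fit <- function(spec, data = NULL, cor_matrix = NULL, n = NULL,
                     covariates = character(0)) {
  if (!inherits(spec, "path_spec")) abort("`spec` must be a path_spec")
  vars <- spec$variables
  if (is.null(cor_matrix)) {
    if (is.null(data)) abort("either `data` or `cor_matrix` must be supplied")
    pc <- partial_correlation(data, vars, covariates)
    R <- pc$r
    n <- pc$n - length(covariates)
  } else {
    check_square_named(cor_matrix, "cor_matrix")
    if (is.null(n)) abort("`n` must be supplied with matrix input")
    missing <- setdiff(vars, rownames(cor_matrix))
    if (length(missing) > 0)
      abort(sprintf("cor_matrix lacks variables: %s", paste(missing, collapse = ", ")))
    R <- stats::cov2cor(cor_matrix[vars, vars])
    if (!is_psd(R)) abort("`cor_matrix` must be positive semi-definite")
  }
  endo <- unique(spec$edges$to)
  rows <- map(endo, function(y) {
    x <- spec$edges$from[spec$edges$to == y]
    Rxx <- R[x, x, drop = FALSE]
    beta <- drop(solve(Rxx, R[x, y]))
    r2 <- sum(beta * R[x, y])
    k <- length(x)
    df <- n - k - 1
    se <- sqrt(pmax(1 - r2, 0) / df * diag(solve(Rxx)))
    stat <- beta / se
    tibble(from = x, to = y, estimate = unname(beta),
           std_error = unname(se), statistic = unname(stat),
           p_value = unname(2 * pt(abs(stat), df, lower.tail = FALSE)))
  })
  structure(list(estimates = list_rbind(rows), R = R, n = n, spec = spec),
            class = "path_fit")
}

#' @export
print.path_fit <- function(x, ...) {
  cat(sprintf("<path_fit> %d edges over %d variables (n = %d)\n",
              nrow(x$estimates), length(x$spec$variables), x$n))
  print(as.data.frame(mutate(x$estimates,
                             across(c("estimate", "std_error", "statistic"),
                                    ~ round(.x, 3)))), row.names = FALSE)
  invisible(x)
}

#' @rdname path_fit
#' @param x A `path_fit`.
#' @param ... Unused.
#' @export
tidy.path_fit <- function(x, ...) x$estimates

# Coefficient matrix B with B[child, parent] = standardized coefficient.
path_coef_matrix <- function(fit) {
  vars <- fit$spec$variables
  B <- matrix(0, length(vars), length(vars), dimnames = list(vars, vars))
  for (i in seq_len(nrow(fit$estimates)))
    B[fit$estimates$to[i], fit$estimates$from[i]] <- fit$estimates$estimate[i]
  B
}

#' Model-implied correlation matrix of a fitted recursive path model
#'
#' Residual variances are `1 - R^2` per equation; exogenous variables keep
#' their observed correlations. A saturated recursive model (every ordered
#' pair connected) reproduces the observed correlation matrix exactly.
#'
#' @param fit A [path_fit()] result.
#' @return The implied correlation matrix over the spec variables.
#' @export
path_implied_correlation <- function(fit) {
  vars <- fit$spec$variables
  B <- path_coef_matrix(fit)
  endo <- unique(fit$spec$edges$to)
  exo <- setdiff(vars, endo)
  Psi <- matrix(0, length(vars), length(vars), dimnames = list(vars, vars))
  Psi[exo, exo] <- fit$R[exo, exo]
  for (y in endo) {
    x <- fit$spec$edges$from[fit$spec$edges$to == y]
    r2 <- sum(B[y, x] * fit$R[x, y])
    Psi[y, y] <- 1 - r2
  }
  IA <- solve(diag(length(vars)) - B)
  out <- IA %*% Psi %*% t(IA)
  dimnames(out) <- list(vars, vars)
  out
}
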