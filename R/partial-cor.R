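# Step 3a: covariate-adjusted partial correlations among phenotypes and
# diseases. Binary disease indicators enter as numeric 0/1.

#' Covariate-adjusted partial correlation matrix
#'
#' Regresses each variable on the covariates by least squares and returns
#' the Pearson correlations of the residuals, with p-values from the t
#' distribution on `n - n_covariates - 2` degrees of freedom. With an empty
#' conditioning set this is the plain Pearson correlation matrix.
#'
#' @param data Data frame (complete cases over the used columns are taken).
#' @param variables Character vector of at least two numeric column names.
#' @param covariates Character vector of covariate column names (may be
#'   empty).
#' @return An object of class `partial_cor`: `r` (symmetric matrix),
#'   `p_values`, `n` (complete cases), `df`, `variables`, `covariates`.
#' @examples
#' d <- as.data.frame(MASS::mvrnorm(200, rep(0, 3), diag(3) * 0.5 + 0.5))
#' names(d) <- c("x", "y", "z")
#' partial_correlation(d, c("y", "z"), covariates = "x")
#' @export
partial_correlation <- function(data, variables, covariates = character(0)) {
  if (length(variables) < 2) abort("at least two variables are required")
  cols <- c(variables, covariates)
  cc <- complete.cases(data[, cols, drop = FALSE])
  d <- data[cc, cols, drop = FALSE]
  n <- nrow(d)
  if (n <= length(covariates) + 2)
    abort("too few complete cases for the requested conditioning set")
  for (v in cols) {
    if (!is.numeric(d[[v]])) abort(sprintf("column `%s` must be numeric", v))
    if (stats::sd(d[[v]]) == 0) abort(sprintf("column `%s` is constant", v))
  }
  Y <- as.matrix(d[, variables, drop = FALSE])
  if (length(covariates) > 0) {
    X <- model.matrix(~., data = d[, covariates, drop = FALSE])
    res <- Y - X %*% qr.coef(qr(X), Y)
  } else {
    res <- scale(Y, scale = FALSE)
  }
  r <- cor(res)
  df <- n - length(covariates) - 2
  tstat <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  diag(p) <- NA_real_
  structure(list(r = r, p_values = p, n = n, df = df,
                 variables = variables, covariates = covariates),
            class = "partial_cor")
}

#' @export
print.partial_cor <- function(x, ...) {
  cat(sprintf("<partial_cor> %d variables given {%s}, n = %d\n",
              length(x$variables),
              paste(x$covariates, collapse = ", "), x$n))
  print(round(x$r, 3))
  invisible(x)
}

#' @rdname partial_correlation
#' @param x A `partial_cor` object.
#' @param ... Unused.
#' @export
tidy.partial_cor <- function(x, ...) {
  pairs <- which(upper.tri(x$r), arr.ind = TRUE)
  tibble(var1 = rownames(x$r)[pairs[, 1]],
         var2 = colnames(x$r)[pairs[, 2]],
         estimate = x$r[pairs],
         p_value = x$p_values[pairs],
         n = x$n)
}
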