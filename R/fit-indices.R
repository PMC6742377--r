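# Goodness-of-fit indices for a fitted structural model and the published
# cutoff battery: NFI >= 0.95, CFI >= 0.95, GFI >= 0.95, AGFI >= 0.90,
# RMSEA <= 0.07.

#' Fit indices of a structural equation model
#'
#' Computes chi-square-based and residual-based fit indices against the
#' independence baseline:
#' \itemize{
#'   \item NFI = (chi2_b - chi2_m) / chi2_b
#'   \item CFI = 1 - max(chi2_m - df_m, 0) / max(chi2_b - df_b, chi2_m - df_m, 0)
#'   \item GFI = 1 - tr\[(Sigma^-1 S - I)^2\] / tr\[(Sigma^-1 S)^2\]
#'   \item AGFI = 1 - \[p(p+1) / (2 df)\] (1 - GFI)
#'   \item RMSEA = sqrt(max(chi2 - df, 0) / (df (n - 1)))
#' }
#' For a saturated model (df = 0) AGFI and RMSEA are undefined and reported
#' as `NA` with a note.
#'
#' @param fit A [fit_ml()] result.
#' @param baseline Optional baseline with `chi_square` and `df`; defaults to
#'   the closed-form [independence_fit()] on the same sample covariance.
#' @return An object of class `fit_indices`: `chi_square`, `df`, `nfi`,
#'   `cfi`, `gfi`, `agfi`, `rmsea`, the baseline, and the cutoff table from
#'   [check_fit_cutoffs()].
#' @export
fit_indices <- function(fit, baseline = NULL) {
  if (!inherits(fit, "sem_fit")) abort("`fit` must be a sem_fit")
  if (is.null(baseline)) baseline <- independence_fit(fit$S, fit$n)
  chi_m <- fit$chi_square; df_m <- fit$df
  chi_b <- baseline$chi_square; df_b <- baseline$df
  nfi <- if (chi_b > 0) (chi_b - chi_m) / chi_b else NA_real_
  denom <- max(chi_b - df_b, chi_m - df_m, 0)
  cfi <- if (denom > 0) 1 - max(chi_m - df_m, 0) / denom else 1
  Si <- solve(fit$Sigma_hat)
  M <- Si %*% fit$S
  p <- ncol(fit$S)
  gfi <- 1 - sum(diag((M - diag(p)) %*% (M - diag(p)))) / sum(diag(M %*% M))
  saturated <- df_m == 0
  agfi <- if (saturated) NA_real_ else 1 - (p * (p + 1) / (2 * df_m)) * (1 - gfi)
  rmsea <- if (saturated) NA_real_ else sqrt(max(chi_m - df_m, 0) / (df_m * (fit$n - 1)))
  out <- structure(
    list(chi_square = chi_m, df = df_m, nfi = nfi, cfi = cfi, gfi = gfi,
         agfi = agfi, rmsea = rmsea, baseline = baseline,
         note = if (saturated) "saturated model: AGFI and RMSEA undefined" else NULL),
    class = "fit_indices")
  out$cutoffs <- check_fit_cutoffs(out)
  out
}

#' @export
print.fit_indices <- function(x, ...) {
  cat(sprintf("chi-square %.3f on %d df | NFI %.3f  CFI %.3f  GFI %.3f  AGFI %s  RMSEA %s\n",
              x$chi_square, x$df, x$nfi, x$cfi, x$gfi,
              ifelse(is.na(x$agfi), "NA", sprintf("%.3f", x$agfi)),
              ifelse(is.na(x$rmsea), "NA", sprintf("%.3f", x$rmsea))))
  if (!is.null(x$note)) cat(" ", x$note, "\n")
  print(as.data.frame(x$cutoffs), row.names = FALSE)
  invisible(x)
}

#' Check fit indices against the published adequacy cutoffs
#'
#' Applies the cutoff battery NFI >= 0.95, CFI >= 0.95, GFI >= 0.95,
#' AGFI >= 0.90, RMSEA <= 0.07 to a set of indices. Accepts a
#' [fit_indices()] object or a named list/vector (`nfi`, `cfi`, `gfi`,
#' `agfi`, `rmsea`; a `chi_square` entry is echoed but carries no cutoff).
#'
#' @param indices Indices to check.
#' @return A tibble with `index`, `value`, `rule`, `pass`, plus attribute
#'   `all_pass`.
#' @examples
#' check_fit_cutoffs(kare_reported_fit_indices())
#' @export
check_fit_cutoffs <- function(indices) {
  v <- if (inherits(indices, "fit_indices")) {
    list(nfi = indices$nfi, cfi = indices$cfi, gfi = indices$gfi,
         agfi = indices$agfi, rmsea = indices$rmsea)
  } else as.list(indices)
  names(v) <- tolower(names(v))
  rules <- tibble(
    index = c("nfi", "cfi", "gfi", "agfi", "rmsea"),
    rule = c(">= 0.95", ">= 0.95", ">= 0.95", ">= 0.90", "<= 0.07"),
    cutoff = c(0.95, 0.95, 0.95, 0.90, 0.07),
    ge = c(TRUE, TRUE, TRUE, TRUE, FALSE)
  )
  out <- rules |>
    mutate(value = map_dbl(.data$index, ~ v[[.x]] %||% NA_real_),
           pass = ifelse(is.na(.data$value), NA,
                         ifelse(.data$ge, .data$value >= .data$cutoff,
                                .data$value <= .data$cutoff))) |>
    select("index", "value", "rule", "pass")
  attr(out, "all_pass") <- all(out$pass[!is.na(out$pass)]) && !all(is.na(out$pass))
  out
}
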