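# Step 1: single-SNP association scans (linear / logistic, with covariates)
# and construction of per-trait SNP blocks.

scan_design <- function(data, covariates) {
  if (length(covariates) == 0) {
    matrix(1, nrow(data), 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    model.matrix(~., data = data[, covariates, drop = FALSE])
  }
}

#' Single-SNP linear association scan
#'
#' Regresses a continuous trait on each SNP's additive dosage (minor-allele
#' count, 0/1/2) plus the given covariates, one SNP at a time, and reports
#' the per-allele Wald estimate, standard error, t statistic, and two-sided
#' p-value from the t distribution on the residual degrees of freedom.
#' Complete cases per SNP; monomorphic SNPs (fewer than two distinct dosages)
#' are flagged with `p_value = NA` and are never retained by
#' [select_blocks()].
#'
#' @param data Data frame with the trait, dosage, and covariate columns.
#' @param trait Name of the numeric trait column.
#' @param snps Character vector of dosage column names.
#' @param covariates Character vector of covariate column names (may be
#'   empty).
#' @return A tibble with one row per SNP: `snp_id`, `trait`, `model`,
#'   `estimate`, `std_error`, `statistic`, `p_value`, `n`, `note`.
#' @examples
#' d <- data.frame(g = c(0, 1, 2, 0, 1, 2), y = c(0.1, 1.1, 2, 0, 0.9, 2.1))
#' linear_scan(d, "y", "g")
#' @export
linear_scan <- function(data, trait, snps, covariates = character(0)) {
  if (!is.numeric(data[[trait]])) abort(sprintf("trait `%s` must be numeric", trait))
  rows <- map(snps, function(s) {
    cols <- c(trait, s, covariates)
    cc <- complete.cases(data[, cols, drop = FALSE])
    d <- data[cc, , drop = FALSE]
    g <- d[[s]]
    if (length(unique(g)) < 2) {
      return(tibble(snp_id = s, trait = trait, model = "linear",
                    estimate = NA_real_, std_error = NA_real_,
                    statistic = NA_real_, p_value = NA_real_,
                    n = nrow(d), note = "monomorphic"))
    }
    X <- cbind(scan_design(d, covariates), dosage = g)
    fit <- lm.fit(X, d[[trait]])
    df <- nrow(X) - ncol(X)
    rss <- sum(fit$residuals^2)
    xtx_inv <- chol2inv(fit$qr$qr[seq_len(ncol(X)), , drop = FALSE])
    k <- ncol(X)
    est <- fit$coefficients[["dosage"]]
    if (rss <= .Machine$double.eps * sum(d[[trait]]^2) || df <= 0) {
      # perfect fit: slope is exact, no residual variation to test against
      se <- 0
      stat <- if (est == 0) 0 else sign(est) * Inf
      p <- if (est == 0) 1 else 0
    } else {
      se <- sqrt(rss / df * xtx_inv[k, k])
      stat <- est / se
      p <- 2 * pt(abs(stat), df, lower.tail = FALSE)
    }
    tibble(snp_id = s, trait = trait, model = "linear", estimate = est,
           std_error = se, statistic = stat, p_value = p, n = nrow(d),
           note = "")
  })
  list_rbind(rows)
}

#' Single-SNP logistic association scan
#'
#' Logistic regression of a binary disease indicator on each SNP's additive
#' dosage plus covariates, fitted by iteratively reweighted least squares
#' (convergence tolerance 1e-8, at most 50 iterations). Reports the Wald
#' log-odds estimate per allele. Non-converged fits (e.g. under perfect
#' separation) are flagged with `note = "non_converged"` and `p_value = NA`
#' so that [select_blocks()] drops them with a warning.
#'
#' @inheritParams linear_scan
#' @param disease Name of the 0/1 disease column; both classes must be
#'   present.
#' @return A tibble in the same layout as [linear_scan()], with
#'   `model = "logistic"` and `estimate` the per-allele log-odds ratio.
#' @export
logistic_scan <- function(data, disease, snps, covariates = character(0)) {
  y_all <- data[[disease]]
  if (!all(stats::na.omit(y_all) %in% c(0, 1)))
    abort(sprintf("disease `%s` must be coded 0/1", disease))
  if (length(unique(stats::na.omit(y_all))) < 2)
    abort(sprintf("disease `%s` has a single class; both cases and controls are required", disease))
  rows <- map(snps, function(s) {
    cols <- c(disease, s, covariates)
    cc <- complete.cases(data[, cols, drop = FALSE])
    d <- data[cc, , drop = FALSE]
    g <- d[[s]]
    base <- tibble(snp_id = s, trait = disease, model = "logistic",
                   estimate = NA_real_, std_error = NA_real_,
                   statistic = NA_real_, p_value = NA_real_,
                   n = nrow(d), note = "")
    if (length(unique(g)) < 2) return(mutate(base, note = "monomorphic"))
    X <- cbind(scan_design(d, covariates), dosage = g)
    fit <- suppressWarnings(
      glm.fit(X, d[[disease]], family = binomial(),
              control = list(epsilon = 1e-8, maxit = 50))
    )
    if (!fit$converged || fit$boundary)
      return(mutate(base, note = "non_converged"))
    w <- fit$weights
    info <- crossprod(X * sqrt(w))
    cov_beta <- tryCatch(solve(info), error = function(e) NULL)
    if (is.null(cov_beta)) return(mutate(base, note = "non_converged"))
    k <- ncol(X)
    est <- fit$coefficients[["dosage"]]
    se <- sqrt(cov_beta[k, k])
    if (!is.finite(se) || se > 50) return(mutate(base, note = "non_converged"))
    stat <- est / se
    mutate(base, estimate = est, std_error = se, statistic = stat,
           p_value = 2 * pnorm(abs(stat), lower.tail = FALSE))
  })
  list_rbind(rows)
}

#' Scan all SNPs against all traits and diseases
#'
#' Convenience wrapper running [linear_scan()] for each continuous trait and
#' [logistic_scan()] for each binary disease, returning one combined result
#' tibble.
#'
#' @inheritParams linear_scan
#' @param traits Continuous trait column names.
#' @param diseases Binary disease column names.
#' @return A tibble of per-SNP association results across all outcomes.
#' @export
snp_scan <- function(data, snps, traits = character(0), diseases = character(0),
                     covariates = character(0)) {
  bind_rows(
    list_rbind(map(traits, function(tr) linear_scan(data, tr, snps, covariates))),
    list_rbind(map(diseases, function(dz) logistic_scan(data, dz, snps, covariates)))
  )
}

#' Build per-trait SNP blocks from scan results
#'
#' Retains, for each outcome, exactly the SNPs with `p_value < alpha`
#' (default 1e-5, the genome-wide screening threshold used for the KARE
#' analysis), ordered by ascending p-value. Flagged results (monomorphic or
#' non-converged, `p_value = NA`) are dropped with a warning. Outcomes with
#' no significant SNP yield an empty block, recorded in the `empty_traits`
#' attribute.
#'
#' @param results Scan results tibble from [snp_scan()] / [linear_scan()] /
#'   [logistic_scan()].
#' @param alpha Significance threshold in (0, 1).
#' @return A tibble with `block_id`, `trait`, `snp_id`, `p_value`, ordered by
#'   block then p-value, with attribute `empty_traits`.
#' @export
select_blocks <- function(results, alpha = 1e-5) {
  stopifnot_scalar_prob(alpha, "alpha")
  flagged <- filter(results, .data$note != "")
  if (nrow(flagged) > 0)
    warn(sprintf("%d flagged scan results (%s) excluded from blocks",
                 nrow(flagged), paste(unique(flagged$note), collapse = ", ")))
  traits <- unique(results$trait)
  kept <- results |>
    filter(.data$note == "", !is.na(.data$p_value), .data$p_value < alpha) |>
    mutate(trait = factor(.data$trait, levels = traits)) |>
    arrange(.data$trait, .data$p_value) |>
    mutate(block_id = as.integer(.data$trait), trait = as.character(.data$trait)) |>
    select("block_id", "trait", "snp_id", "p_value")
  empty <- setdiff(traits, kept$trait)
  attr(kept, "empty_traits") <- empty
  attr(kept, "alpha") <- alpha
  kept
}

#' Greedy LD pruning in significance order
#'
#' Walks the SNPs in the given order (most significant first) and keeps a SNP
#' only if its squared Pearson correlation with every already-kept SNP is
#' below `r2_threshold`. Off by default in the pipeline; provided for cohorts
#' with strong local linkage disequilibrium.
#'
#' @param X Numeric matrix or data frame of dosages with SNP column names.
#' @param snp_order Character vector of SNP ids, most significant first.
#' @param r2_threshold Squared-correlation threshold in (0, 1].
#' @return Character vector of retained SNP ids, in input order.
#' @export
ld_prune <- function(X, snp_order = colnames(X), r2_threshold = 0.8) {
  if (r2_threshold <= 0 || r2_threshold > 1)
    abort("`r2_threshold` must lie in (0, 1]")
  X <- as.matrix(X)
  kept <- character(0)
  for (s in snp_order) {
    ok <- TRUE
    for (k in kept) {
      r2 <- suppressWarnings(cor(X[, s], X[, k]))^2
      if (is.finite(r2) && r2 >= r2_threshold) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, s)
  }
  kept
}
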