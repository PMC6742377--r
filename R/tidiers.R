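# broom-style tidiers for the remaining result types.

#' Tidy a fitted factor model
#'
#' One row per retained SNP with its rotated loadings on each factor and its
#' communality, mirroring the per-block loading-table layout.
#'
#' @param x A `factor_model` from [fit_factor_block()].
#' @param ... Unused.
#' @return A tibble: `snp_id`, `factor1..k`, `communality`.
#' @export
tidy.factor_model <- function(x, ...) {
  dplyr::bind_cols(
    tibble(snp_id = rownames(x$loadings)),
    as_tibble(x$loadings),
    tibble(communality = unname(x$communalities))
  )
}

#' @rdname tidy.factor_model
#' @export
glance.factor_model <- function(x, ...) {
  tibble(block_id = x$block_id, n_snps = length(x$snp_ids),
         n_factors = x$k, variance_explained = x$variance_explained,
         n_excluded = nrow(x$excluded))
}

#' @rdname path_fit
#' @export
glance.path_fit <- function(x, ...) {
  tibble(n_edges = nrow(x$estimates),
         n_variables = length(x$spec$variables), n = x$n)
}
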