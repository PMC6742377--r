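#' Published KARE phenotype partial-correlation matrix
#'
#' The covariate-adjusted (area, sex, age) partial correlations among the
#' three obesity-related intermediate phenotypes and the two diseases in the
#' Korea Association Resource (KARE) cohort, as published: subscapular skin
#' fold thickness (`SUB`, subcutaneous adiposity), body mass index (`BMI`,
#' overall adiposity), waist circumference (`WC`, abdominal adiposity), type 2
#' diabetes (`T2D`), and hypertension (`HTN`). The raw cohort data are under
#' restricted access, but this matrix together with its complete-case sample
#' size (n = 8792) is sufficient to fit the recursive phenotype path model in
#' matrix mode and reproduce the published phenotype-level effect
#' decomposition.
#'
#' @return A 5x5 labelled correlation matrix with attribute `n` (the
#'   complete-case sample size, 8792).
#' @examples
#' R <- kare_phenotype_correlations()
#' attr(R, "n")
#' @export
kare_phenotype_correlations <- function() {
  pairs <- tibble(
    var1  = c("SUB", "SUB", "SUB", "SUB", "BMI", "BMI", "BMI", "WC", "WC", "T2D"),
    var2  = c("BMI", "WC", "T2D", "HTN", "WC", "T2D", "HTN", "T2D", "HTN", "HTN"),
    value = c(0.634, 0.547, 0.121, 0.135, 0.824, 0.107, 0.194, 0.122, 0.180, 0.102)
  )
  m <- build_corr_matrix(c("SUB", "BMI", "WC", "T2D", "HTN"), pairs)
  attr(m, "n") <- 8792L
  m
}

#' Published fit indices of the final KARE structural model
#'
#' The goodness-of-fit measures reported for the final KARE structural
#' equation model (fitted on the restricted raw data, hence not recomputable
#' here). Useful as input to [check_fit_cutoffs()].
#'
#' @return A named list with `chi_square`, `nfi`, `cfi`, `gfi`, `agfi`,
#'   `rmsea`.
#' @export
kare_reported_fit_indices <- function() {
  list(chi_square = 536.52, nfi = 0.997, cfi = 0.998, gfi = 0.995,
       agfi = 0.993, rmsea = 0.012)
}
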