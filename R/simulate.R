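# Synthetic cohort generator: Hardy-Weinberg genotypes in correlated SNP
# groups, latent genetic factors, a standardized adiposity cascade
# (SUB -> BMI -> WC), and liability-threshold diseases (T2D, HTN).

#' Simulation configuration
#'
#' Builds the configuration object for [simulate_cohort()]. The defaults
#' emulate the KARE study conditions: 8,842 subjects, five SNP groups sized
#' like the published per-trait SNP blocks after communality filtering
#' (4/6/6/1/4 markers), disease prevalences of 9.45% (T2D) and 27.06%
#' (hypertension), covariates sex and area with the cohort's observed
#' proportions, and age uniform on 39-70 years. Cascade coefficients default
#' to the published standardized direct effects among the phenotypes and
#' diseases.
#'
#' All generating coefficients are on the standardized scale: each continuous
#' trait's systematic part plus residual has unit population variance before
#' covariate effects are added, and disease liabilities are standardized the
#' same way before thresholding at the configured prevalence.
#'
#' @param n_subjects Number of subjects (positive integer).
#' @param seed Integer seed; regeneration with an identical config is
#'   bit-identical.
#' @param snp_groups List of groups, each a list with `group_id`, `n_snps`,
#'   `maf_range` (pair in (0, 0.5]), and `within_group_r` (latent Gaussian
#'   correlation in \[0, 1)).
#' @param factor_effects Named list mapping `group_id` to
#'   `list(target = <trait>, effect = <standardized coefficient>)`.
#' @param cascade Named list of standardized path coefficients:
#'   `sub_to_bmi`, `sub_to_wc`, `bmi_to_wc`, `sub_to_t2d`, `bmi_to_t2d`,
#'   `wc_to_t2d`, `sub_to_htn`, `bmi_to_htn`, `wc_to_htn`, `t2d_to_htn`.
#' @param prevalences Named list with `t2d` and `htn` in (0, 1).
#' @param covariate_effects Named list mapping each of SUB/BMI/WC/T2D/HTN to
#'   a numeric vector of coefficients `c(sex, area, age)` applied to the
#'   centred covariates (age is standardized by its population SD).
#' @param covariate_props Named list with the Bernoulli proportions for `sex`
#'   and `area`.
#'
#' @return A list of class `sim_config`.
#' @seealso [simulate_cohort()], [simulate_genotypes()]
#' @export
sim_config <- function(n_subjects = 8842L,
                       seed = 1L,
                       snp_groups = default_snp_groups(),
                       factor_effects = default_factor_effects(),
                       cascade = default_cascade(),
                       prevalences = list(t2d = 0.0945, htn = 0.2706),
                       covariate_effects = default_covariate_effects(),
                       covariate_props = list(sex = 0.4731, area = 0.4756)) {
  if (!is.numeric(n_subjects) || length(n_subjects) != 1 || n_subjects < 1)
    abort("`n_subjects` must be a positive integer")
  stopifnot_scalar_prob(prevalences$t2d, "prevalences$t2d")
  stopifnot_scalar_prob(prevalences$htn, "prevalences$htn")
  for (g in snp_groups) {
    rng <- g$maf_range
    if (any(rng <= 0) || any(rng > 0.5))
      abort(sprintf("maf_range for group '%s' must lie in (0, 0.5]", g$group_id))
    if (g$within_group_r < 0 || g$within_group_r >= 1)
      abort(sprintf("within_group_r for group '%s' must lie in [0, 1)", g$group_id))
  }
  cascade <- modifyList(default_cascade(), cascade)
  structure(
    list(n_subjects = as.integer(n_subjects), seed = as.integer(seed),
         snp_groups = snp_groups, factor_effects = factor_effects,
         cascade = cascade, prevalences = prevalences,
         covariate_effects = covariate_effects,
         covariate_props = covariate_props),
    class = "sim_config"
  )
}

#' @rdname sim_config
#' @export
default_snp_groups <- function() {
  list(
    list(group_id = "g1_sub", n_snps = 4L, maf_range = c(0.10, 0.45), within_group_r = 0.6),
    list(group_id = "g2_bmi", n_snps = 6L, maf_range = c(0.10, 0.45), within_group_r = 0.6),
    list(group_id = "g3_wc",  n_snps = 6L, maf_range = c(0.10, 0.45), within_group_r = 0.6),
    list(group_id = "g4_t2d", n_snps = 1L, maf_range = c(0.10, 0.45), within_group_r = 0.0),
    list(group_id = "g5_htn", n_snps = 4L, maf_range = c(0.10, 0.45), within_group_r = 0.6)
  )
}

#' @rdname sim_config
#' @export
default_factor_effects <- function() {
  list(
    g1_sub = list(target = "SUB", effect = 0.05),
    g2_bmi = list(target = "BMI", effect = 0.05),
    g3_wc  = list(target = "WC",  effect = 0.02),
    g4_t2d = list(target = "T2D", effect = 0.05),
    g5_htn = list(target = "HTN", effect = 0.04)
  )
}

#' @rdname sim_config
#' @export
default_cascade <- function() {
  list(sub_to_bmi = 0.632, sub_to_wc = 0.041, bmi_to_wc = 0.797,
       sub_to_t2d = 0.085, bmi_to_t2d = -0.024, wc_to_t2d = 0.097,
       sub_to_htn = 0.005, bmi_to_htn = 0.140, wc_to_htn = 0.052,
       t2d_to_htn = 0.079)
}

#' @rdname sim_config
#' @export
default_covariate_effects <- function() {
  # c(sex, area, age) on the standardized-trait scale; small nonzero values
  # so covariate adjustment is exercised downstream.
  list(SUB = c(0.10, 0.05, 0.10), BMI = c(0.05, 0.05, 0.10),
       WC  = c(0.10, 0.05, 0.10), T2D = c(0.05, 0.02, 0.15),
       HTN = c(0.05, 0.02, 0.20))
}

#' Simulate Hardy-Weinberg genotypes with within-group correlation
#'
#' Generates an `n x m` matrix of minor-allele counts. Each SNP marginally
#' follows Hardy-Weinberg proportions at its minor-allele frequency; within
#' the group, SNPs are positively correlated at approximately
#' `within_group_r` via a Gaussian copula: an equicorrelated latent normal is
#' thresholded at the HWE quantiles.
#'
#' @param mafs Numeric vector of minor-allele frequencies in (0, 0.5].
#' @param n Number of subjects.
#' @param within_group_r Latent equicorrelation in \[0, 1).
#' @param seed Optional integer seed (`NULL` to use the current RNG state).
#' @return An `n x length(mafs)` integer matrix with entries in `{0, 1, 2}`.
#' @examples
#' g <- simulate_genotypes(c(0.3, 0.3), n = 100, within_group_r = 0.5, seed = 1)
#' table(g[, 1])
#' @export
simulate_genotypes <- function(mafs, n, within_group_r = 0, seed = NULL) {
  if (any(mafs <= 0) || any(mafs > 0.5))
    abort("minor-allele frequencies must lie in (0, 0.5]")
  if (n < 1) abort("`n` must be at least 1")
  if (!is.null(seed)) set.seed(as.integer(seed))
  m <- length(mafs)
  r <- within_group_r
  # Equicorrelated latent normals: sqrt(r) * shared + sqrt(1-r) * unique.
  shared <- rnorm(n)
  z <- sqrt(r) * matrix(shared, n, m) + sqrt(1 - r) * matrix(rnorm(n * m), n, m)
  geno <- matrix(0L, n, m)
  for (j in seq_len(m)) {
    p <- mafs[j]
    # HWE cumulative cut points: P(0)=(1-p)^2, P(0 or 1)=1-p^2.
    c1 <- qnorm((1 - p)^2)
    c2 <- qnorm(1 - p^2)
    geno[, j] <- (z[, j] > c1) + (z[, j] > c2)
  }
  geno
}

#' Simulate a full synthetic cohort
#'
#' Generates genotypes, covariates, latent genetic factors, the continuous
#' adiposity cascade, and liability-threshold diseases from a [sim_config()].
#' Latent factors are standardized equal-weight sums of their SNP group's
#' standardized dosages. Each continuous trait is a linear combination of its
#' cascade parents and genetic factors plus an independent normal residual
#' scaled so the standardized core has unit population variance; covariate
#' effects are then added on the centred covariates. Disease liabilities are
#' built the same way (with the binary T2D indicator, standardized, feeding
#' the hypertension liability) and dichotomized at the empirical quantile
#' matching the configured prevalence.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_cohort` with elements
#'   \describe{
#'     \item{data}{tibble: `subject_id`, covariates `SEX`/`AREA`/`AGE`, one
#'       column per SNP, then `SUB`, `BMI`, `WC`, `T2D`, `HTN`.}
#'     \item{snp_groups}{tibble mapping `snp_id` to `group_id`.}
#'     \item{truth}{record of every generating parameter: per-SNP MAFs,
#'       cascade and factor coefficients, covariate effects, residual SDs,
#'       and liability thresholds.}
#'     \item{config}{the input configuration.}
#'   }
#' @examples
#' cohort <- simulate_cohort(sim_config(n_subjects = 500, seed = 7))
#' dplyr::count(cohort$data, T2D)
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) abort("`config` must be a sim_config")
  set.seed(config$seed)
  n <- config$n_subjects
  traits <- c("SUB", "BMI", "WC")
  diseases <- c("T2D", "HTN")

  # Covariates. Age centred/scaled by its population moments (uniform on
  # [39, 70]: mean 54.5, sd 31/sqrt(12)).
  sex <- rbinom(n, 1L, config$covariate_props$sex)
  area <- rbinom(n, 1L, config$covariate_props$area)
  age <- runif(n, 39, 70)
  cov_centred <- cbind(sex = sex - config$covariate_props$sex,
                       area = area - config$covariate_props$area,
                       age = (age - 54.5) / (31 / sqrt(12)))

  # Genotypes and per-group standardized factors.
  geno_cols <- list()
  snp_map <- list()
  mafs_all <- list()
  factors <- list()
  for (g in config$snp_groups) {
    mafs <- runif(g$n_snps, g$maf_range[1], g$maf_range[2])
    gm <- simulate_genotypes(mafs, n, g$within_group_r, seed = NULL)
    ids <- paste0(g$group_id, "_s", seq_len(g$n_snps))
    colnames(gm) <- ids
    geno_cols[[g$group_id]] <- gm
    snp_map[[g$group_id]] <- tibble(snp_id = ids, group_id = g$group_id)
    mafs_all[[g$group_id]] <- setNames(mafs, ids)
    fs <- rowSums(scale(gm))
    factors[[g$group_id]] <- as.numeric(scale(fs))
  }
  geno <- do.call(cbind, geno_cols)
  fmat <- do.call(cbind, factors)
  colnames(fmat) <- names(factors)

  # Standardized trait cores via the implied-covariance recursion: factors
  # are mutually independent with unit variance; each trait gets residual
  # variance 1 - var(systematic part).
  cz <- lapply(config$cascade, as.numeric)
  parent_sets <- list(
    SUB = numeric(0),
    BMI = c(SUB = cz$sub_to_bmi),
    WC  = c(SUB = cz$sub_to_wc, BMI = cz$bmi_to_wc)
  )
  fac_ids <- names(factors)
  vars_all <- c(fac_ids, traits)
  C <- diag(length(vars_all))
  dimnames(C) <- list(vars_all, vars_all)
  C[traits, ] <- 0; C[, traits] <- 0
  core <- matrix(0, n, length(traits), dimnames = list(NULL, traits))
  resid_sd <- c()
  for (tr in traits) {
    w <- setNames(numeric(length(vars_all)), vars_all)
    pv <- parent_sets[[tr]]
    w[names(pv)] <- pv
    for (gid in fac_ids) {
      fe <- config$factor_effects[[gid]]
      if (!is.null(fe) && identical(fe$target, tr)) w[gid] <- fe$effect
    }
    var_sys <- drop(t(w) %*% C %*% w)
    if (var_sys >= 1)
      abort(sprintf("inadmissible configuration: systematic variance of %s is %.3f >= 1 (implied residual variance non-positive)", tr, var_sys))
    lin <- fmat %*% w[fac_ids] + core %*% w[traits]
    e_sd <- sqrt(1 - var_sys)
    core[, tr] <- lin + e_sd * rnorm(n)
    resid_sd[tr] <- e_sd
    cw <- C %*% w
    C[tr, ] <- cw; C[, tr] <- cw
    C[tr, tr] <- 1
  }

  observed <- core
  for (tr in traits)
    observed[, tr] <- core[, tr] + drop(cov_centred %*% config$covariate_effects[[tr]])

  # Disease liabilities: linear in trait cores (+ factors + covariates), with
  # residual variance topping the empirical systematic variance up to 1, then
  # thresholded at the empirical quantile matching the configured prevalence.
  liab_part <- function(disease, extra = NULL) {
    w_tr <- if (disease == "T2D") {
      c(SUB = cz$sub_to_t2d, BMI = cz$bmi_to_t2d, WC = cz$wc_to_t2d)
    } else {
      c(SUB = cz$sub_to_htn, BMI = cz$bmi_to_htn, WC = cz$wc_to_htn)
    }
    lin <- core %*% w_tr
    for (gid in fac_ids) {
      fe <- config$factor_effects[[gid]]
      if (!is.null(fe) && identical(fe$target, disease)) lin <- lin + fe$effect * fmat[, gid]
    }
    lin <- lin + drop(cov_centred %*% config$covariate_effects[[disease]])
    if (!is.null(extra)) lin <- lin + extra
    lin
  }
  thresholds <- c()
  disease_mat <- matrix(0L, n, 2, dimnames = list(NULL, diseases))
  lin_t2d <- liab_part("T2D")
  v <- var(drop(lin_t2d))
  if (v >= 1) abort("inadmissible configuration: T2D liability systematic variance >= 1")
  liab_t2d <- drop(lin_t2d) + sqrt(1 - v) * rnorm(n)
  thresholds["T2D"] <- quantile(liab_t2d, 1 - config$prevalences$t2d, names = FALSE)
  disease_mat[, "T2D"] <- as.integer(liab_t2d > thresholds["T2D"])

  p_t2d <- config$prevalences$t2d
  t2d_std <- (disease_mat[, "T2D"] - p_t2d) / sqrt(p_t2d * (1 - p_t2d))
  lin_htn <- liab_part("HTN", extra = config$cascade$t2d_to_htn * t2d_std)
  v <- var(drop(lin_htn))
  if (v >= 1) abort("inadmissible configuration: HTN liability systematic variance >= 1")
  liab_htn <- drop(lin_htn) + sqrt(1 - v) * rnorm(n)
  thresholds["HTN"] <- quantile(liab_htn, 1 - config$prevalences$htn, names = FALSE)
  disease_mat[, "HTN"] <- as.integer(liab_htn > thresholds["HTN"])

  data <- dplyr::bind_cols(
    tibble(subject_id = sprintf("S%05d", seq_len(n)),
           SEX = sex, AREA = area, AGE = age),
    as_tibble(geno),
    as_tibble(observed),
    as_tibble(disease_mat)
  )
  truth <- list(
    mafs = unlist(unname(mafs_all)),
    factor_effects = config$factor_effects,
    cascade = config$cascade,
    covariate_effects = config$covariate_effects,
    trait_residual_sd = resid_sd,
    liability_thresholds = thresholds,
    prevalences = config$prevalences
  )
  structure(list(data = data,
                 snp_groups = purrr::list_rbind(unname(snp_map)),
                 truth = truth, config = config),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("<sim_cohort> %d subjects, %d SNPs in %d groups\n",
              nrow(x$data), nrow(x$snp_groups),
              length(unique(x$snp_groups$group_id))))
  cat(sprintf("  observed prevalence: T2D %.4f, HTN %.4f\n",
              mean(x$data$T2D), mean(x$data$HTN)))
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Writes `genotypes.csv` (first column `subject_id`, then one column per
#' SNP), `phenotypes.csv` (`subject_id`, SUB, BMI, WC, T2D, HTN, SEX, AREA,
#' AGE), and `truth.json` under `dir`.
#'
#' @param cohort A `sim_cohort`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  snps <- cohort$snp_groups$snp_id
  paths <- c(
    genotypes = file.path(dir, "genotypes.csv"),
    phenotypes = file.path(dir, "phenotypes.csv"),
    truth = file.path(dir, "truth.json")
  )
  readr::write_csv(dplyr::select(cohort$data, "subject_id", all_of(snps)),
                   paths[["genotypes"]])
  readr::write_csv(
    dplyr::select(cohort$data, "subject_id", "SUB", "BMI", "WC",
                  "T2D", "HTN", "SEX", "AREA", "AGE"),
    paths[["phenotypes"]])
  jsonlite::write_json(cohort$truth, paths[["truth"]],
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
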