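# Orchestration of the four analysis steps from a single configuration:
# scan -> blocks -> factors -> phenotype network -> structural model,
# writing every artifact under one output directory.

#' Pipeline configuration
#'
#' Exactly one input mode must be used: raw (genotypes + phenotypes, all
#' four steps) or matrix (a labelled correlation matrix + n; steps 1-2 are
#' skipped and the phenotype path model and SEM are fitted directly, which
#' makes the published in-print correlation matrix runnable without any
#' genotype data).
#'
#' @param genotypes Path to a genotype table (see [read_genotypes()]) or a
#'   data frame with `subject_id` first.
#' @param phenotypes Path to a phenotype CSV or a data frame.
#' @param cor_matrix Path to a labelled correlation CSV (see
#'   [read_corr_matrix()]) or a labelled matrix; matrix input mode.
#' @param n Sample size for matrix mode (taken from the matrix's `n`
#'   attribute when present).
#' @param traits,diseases,covariates Column-name vectors.
#' @param alpha Scan significance threshold (default 1e-5).
#' @param communality_threshold Factor-analysis exclusion threshold
#'   (default 0.3).
#' @param k_override Named list trait -> fixed factor count.
#' @param ld_prune_r2 Optional squared-correlation threshold for greedy LD
#'   pruning within each block (`NULL`, the default, disables pruning).
#' @param path_edges A [path_spec()], a `from`/`to` data frame, or `NULL`
#'   for [default_disease_paths()].
#' @param residual_covariances Optional `var1`/`var2` data frame of
#'   correlated-residual pairs for the SEM.
#' @param seed Integer seed recorded in the run log (the analysis itself is
#'   deterministic).
#' @param out_dir Output directory for artifacts.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(genotypes = NULL, phenotypes = NULL,
                            cor_matrix = NULL, n = NULL,
                            traits = c("SUB", "BMI", "WC"),
                            diseases = c("T2D", "HTN"),
                            covariates = c("SEX", "AREA", "AGE"),
                            alpha = 1e-5, communality_threshold = 0.3,
                            k_override = list(), ld_prune_r2 = NULL,
                            path_edges = NULL, residual_covariances = NULL,
                            seed = 1L, out_dir = tempfile("sempath_run_")) {
  matrix_mode <- !is.null(cor_matrix)
  raw_mode <- !is.null(genotypes) || !is.null(phenotypes)
  if (matrix_mode && raw_mode)
    abort("supply either raw inputs (genotypes + phenotypes) or a correlation matrix, not both")
  if (!matrix_mode && (is.null(genotypes) || is.null(phenotypes)))
    abort("raw mode needs both `genotypes` and `phenotypes`")
  structure(
    list(genotypes = genotypes, phenotypes = phenotypes,
         cor_matrix = cor_matrix, n = n, traits = traits,
         diseases = diseases, covariates = covariates, alpha = alpha,
         communality_threshold = communality_threshold,
         k_override = k_override, ld_prune_r2 = ld_prune_r2,
         path_edges = path_edges,
         residual_covariances = residual_covariances,
         seed = as.integer(seed), out_dir = out_dir,
         matrix_mode = matrix_mode),
    class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' Only file-path inputs are serializable; a config holding in-memory data
#' frames or matrices cannot be written. Parsing a written config yields an
#' equal configuration (round-trip safe).
#'
#' @param path YAML file path.
#' @return `read_pipeline_config()`: a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$residual_covariances))
    y$residual_covariances <- as_tibble(y$residual_covariances)
  if (!is.null(y$seed)) y$seed <- as.integer(y$seed)
  do.call(pipeline_config, y)
}

#' @rdname read_pipeline_config
#' @param config A [pipeline_config()] whose inputs are file paths.
#' @export
write_pipeline_config <- function(config, path) {
  if (!is.character(config$genotypes %||% "x") ||
      !is.character(config$phenotypes %||% "x") ||
      !is.character(config$cor_matrix %||% "x"))
    abort("only configs with file-path inputs can be serialized")
  fields <- config[c("genotypes", "phenotypes", "cor_matrix", "n", "traits",
                     "diseases", "covariates", "alpha",
                     "communality_threshold", "k_override", "ld_prune_r2",
                     "residual_covariances", "seed", "out_dir")]
  if (!is.null(fields$residual_covariances))
    fields$residual_covariances <- as.list(fields$residual_covariances)
  fields <- fields[!map_lgl(fields, is.null)]
  yaml::write_yaml(fields, path)
  invisible(path)
}

#' Residualize columns on covariates
#'
#' Least-squares residuals of each variable after regression on the
#' covariates (with intercept). Used to carry covariate adjustment into the
#' covariance matrix handed to the SEM, so matrix-mode and raw-mode fits are
#' consistent.
#'
#' @param data Data frame.
#' @param variables Columns to residualize.
#' @param covariates Covariate columns (empty: variables are centred only).
#' @return A tibble of residualized variables.
#' @export
residualize <- function(data, variables, covariates = character(0)) {
  cc <- complete.cases(data[, c(variables, covariates), drop = FALSE])
  d <- data[cc, , drop = FALSE]
  Y <- as.matrix(d[, variables, drop = FALSE])
  if (length(covariates) == 0) return(as_tibble(scale(Y, scale = FALSE)))
  X <- model.matrix(~., data = d[, covariates, drop = FALSE])
  as_tibble(Y - X %*% qr.coef(qr(X), Y))
}

step_banner <- function(msg) message(sprintf("== %s", msg))

# Overlapping SNP blocks can make factor scores of different blocks (near-)
# collinear, which breaks ML covariance fitting. Greedily drop any score
# explained almost perfectly (R^2 >= r2_max) by the scores kept so far,
# preferring to keep earlier blocks' factors.
drop_collinear_scores <- function(scores, r2_max = 0.99) {
  keep <- character(0)
  dropped <- character(0)
  for (v in names(scores)) {
    if (length(keep) == 0) { keep <- v; next }
    X <- as.matrix(scores[, keep, drop = FALSE])
    y <- scores[[v]]
    r2 <- summary(stats::lm(y ~ X))$r.squared
    if (r2 >= r2_max) dropped <- c(dropped, v) else keep <- c(keep, v)
  }
  if (length(dropped) > 0)
    warn(sprintf("factor scores collinear with earlier blocks dropped from the SEM: %s",
                 paste(dropped, collapse = ", ")))
  scores[, keep, drop = FALSE]
}

#' Run the full four-step pipeline
#'
#' Executes scan, factor construction, phenotype-network analysis, and the
#' structural model from one [pipeline_config()], writing artifacts with
#' fixed names under `out_dir`: `scan.tsv`, `blocks.json`,
#' `loadings_<trait>.tsv`, `factor_scores.csv`,
#' `partial_correlations.csv`, `path_fit.tsv`, `sem_fit.json`,
#' `effects.tsv`, `diagram.dot`, and `run_log.json`. Re-running with the
#' same config and inputs reproduces numerically identical outputs. If no
#' SNP block survives the threshold the pipeline continues with a
#' phenotype-only structural model and logs a warning.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_report`: fitted objects (`scan`,
#'   `blocks`, `factors`, `partial_cor`, `path_fit`, `sem_fit`, `indices`,
#'   `effects`) and the artifact path list.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) abort("`config` must be a pipeline_config")
  set.seed(config$seed)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  artifacts <- list()
  report <- list()

  pspec <- if (is.null(config$path_edges)) default_disease_paths()
           else if (inherits(config$path_edges, "path_spec")) config$path_edges
           else path_spec(config$path_edges)

  if (config$matrix_mode) {
    step_banner("matrix mode: steps 1-2 skipped")
    R <- if (is.character(config$cor_matrix)) read_corr_matrix(config$cor_matrix)
         else config$cor_matrix
    n <- config$n %||% attr(R, "n")
    if (is.null(n)) abort("matrix mode needs `n` (argument or matrix attribute)")
    pcor_r <- stats::cov2cor(R)
    factor_targets <- NULL
    sem_data <- NULL
  } else {
    geno <- if (is.character(config$genotypes)) read_genotypes(config$genotypes)
            else as_tibble(config$genotypes)
    pheno <- if (is.character(config$phenotypes)) read_phenotypes(config$phenotypes)
             else as_tibble(config$phenotypes)
    snps <- setdiff(names(geno), "subject_id")
    data <- dplyr::inner_join(pheno, geno, by = "subject_id")
    if (nrow(data) == 0) abort("no subjects shared between genotype and phenotype tables")

    step_banner(sprintf("step 1: single-SNP scan (%d SNPs, alpha = %g)",
                        length(snps), config$alpha))
    scan <- snp_scan(data, snps, config$traits, config$diseases, config$covariates)
    readr::write_tsv(scan, out("scan.tsv"))
    artifacts$scan <- out("scan.tsv")
    blocks <- select_blocks(scan, alpha = config$alpha)
    if (!is.null(config$ld_prune_r2) && nrow(blocks) > 0) {
      blocks <- blocks |>
        group_by(.data$block_id) |>
        filter(.data$snp_id %in% ld_prune(data[, .data$snp_id, drop = FALSE],
                                          .data$snp_id, config$ld_prune_r2)) |>
        ungroup()
    }
    jsonlite::write_json(split(blocks$snp_id, blocks$trait), out("blocks.json"),
                         auto_unbox = FALSE)
    artifacts$blocks <- out("blocks.json")
    report$scan <- scan; report$blocks <- blocks

    if (nrow(blocks) == 0) {
      warn("no SNP reached the significance threshold; continuing with a phenotype-only model")
      factor_targets <- NULL
      scores <- NULL
    } else {
      step_banner(sprintf("step 2: factor analysis of %d block(s)",
                          length(unique(blocks$block_id))))
      fa <- snp_factor_analysis(data, blocks,
                                threshold = config$communality_threshold,
                                k_override = config$k_override)
      for (tr in names(fa$models)) {
        readr::write_tsv(tidy(fa$models[[tr]]),
                         out(sprintf("loadings_%s.tsv", tr)))
        artifacts[[paste0("loadings_", tr)]] <- out(sprintf("loadings_%s.tsv", tr))
      }
      scores <- dplyr::bind_cols(tibble(subject_id = data$subject_id), fa$scores)
      readr::write_csv(scores, out("factor_scores.csv"))
      artifacts$factor_scores <- out("factor_scores.csv")
      factor_targets <- fa$factor_targets
      report$factors <- fa
    }

    step_banner("step 3: phenotype network")
    pcor <- partial_correlation(data, c(config$traits, config$diseases),
                                config$covariates)
    R <- pcor$r
    attr(R, "n") <- pcor$n
    write_corr_matrix(R, out("partial_correlations.csv"))
    artifacts$partial_correlations <- out("partial_correlations.csv")
    report$partial_cor <- pcor
    pcor_r <- R
    n <- pcor$n

    sem_vars <- c(config$traits, config$diseases)
    score_resid <- NULL
    if (!is.null(scores)) {
      score_resid <- drop_collinear_scores(residualize(
        dplyr::bind_cols(data[, config$covariates, drop = FALSE], fa$scores),
        names(fa$scores), config$covariates))
      factor_targets <- filter(factor_targets, .data$factor %in% names(score_resid))
    }
    sem_data <- dplyr::bind_cols(residualize(data, sem_vars, config$covariates),
                                 score_resid)
  }

  pfit <- path_fit(pspec, cor_matrix = pcor_r, n = n)
  readr::write_tsv(tidy(pfit), out("path_fit.tsv"))
  artifacts$path_fit <- out("path_fit.tsv")
  report$path_fit <- pfit

  step_banner("step 4: structural equation model")
  sem_paths <- mutate(pspec$edges, value = NA_real_)
  if (!is.null(factor_targets) && nrow(factor_targets) > 0)
    sem_paths <- bind_rows(
      tibble(from = factor_targets$factor, to = factor_targets$trait,
             value = NA_real_),
      sem_paths)
  spec <- if (is.null(sem_data)) {
    sem_spec(sem_paths, residual_covariances = config$residual_covariances,
             sample_cov = pcor_r[pspec$variables, pspec$variables], n = n)
  } else {
    sem_spec(sem_paths, residual_covariances = config$residual_covariances,
             data = sem_data)
  }
  fit <- fit_ml(spec)
  indices <- fit_indices(fit)
  effects <- effect_decomposition(fit)
  readr::write_tsv(effects, out("effects.tsv"))
  jsonlite::write_json(
    list(parameters = tidy(fit), chi_square = fit$chi_square, df = fit$df,
         n = fit$n,
         indices = list(nfi = indices$nfi, cfi = indices$cfi,
                        gfi = indices$gfi, agfi = indices$agfi,
                        rmsea = indices$rmsea),
         convergence = fit$convergence),
    out("sem_fit.json"), auto_unbox = TRUE, digits = NA)
  writeLines(export_dot(fit), out("diagram.dot"))
  artifacts$effects <- out("effects.tsv")
  artifacts$sem_fit <- out("sem_fit.json")
  artifacts$diagram <- out("diagram.dot")
  report$sem_fit <- fit; report$indices <- indices; report$effects <- effects

  jsonlite::write_json(
    list(seed = config$seed, mode = if (config$matrix_mode) "matrix" else "raw",
         alpha = config$alpha,
         communality_threshold = config$communality_threshold,
         r_version = paste(R.version$major, R.version$minor, sep = "."),
         artifacts = lapply(artifacts, basename)),
    out("run_log.json"), auto_unbox = TRUE)
  artifacts$run_log <- out("run_log.json")
  report$artifacts <- artifacts
  report$config <- config
  structure(report, class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n  artifacts:\n")
  for (a in names(x$artifacts)) cat(sprintf("   - %s\n", x$artifacts[[a]]))
  if (!is.null(x$indices)) print(x$indices)
  invisible(x)
}

#' Export a fitted model as a Graphviz DOT diagram
#'
#' Nodes for every model variable (latent factors as ellipses, observed
#' variables as boxes); directed edges labelled with the standardized
#' estimates to three decimals. Edges whose p-value is at or above 0.05 are
#' drawn dashed, the convention for statistically insignificant paths.
#'
#' @param fit A [fit_ml()] result.
#' @return The DOT source as a character vector of lines.
#' @export
export_dot <- function(fit) {
  if (!inherits(fit, "sem_fit")) abort("`fit` must be a sem_fit")
  paths <- filter(fit$parameters, .data$type == "path")
  nodes <- fit$ram$variables
  node_lines <- map_chr(nodes, function(v)
    sprintf("  \"%s\" [shape=%s];", v,
            if (v %in% fit$spec$latent) "ellipse" else "box"))
  edge_lines <- map_chr(seq_len(nrow(paths)), function(i) {
    p <- paths$p_value[i]
    dashed <- is.na(p) || p >= 0.05
    sprintf("  \"%s\" -> \"%s\" [label=\"%.3f\"%s];",
            paths$from[i], paths$to[i], paths$std_estimate[i],
            if (dashed) ", style=dashed" else "")
  })
  c("digraph sem {", "  rankdir=LR;", node_lines, edge_lines, "}")
}
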