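# Step 2: per-block exploratory factor analysis of significant SNPs —
# principal-component extraction, varimax rotation, communality filtering,
# and standardized factor scores (the FACTORij latent variables).

#' Principal-component factor extraction
#'
#' Extracts unrotated loadings from a SNP correlation matrix: column j is
#' `sqrt(lambda_j) * v_j` for the j-th eigenpair. The number of factors
#' defaults to the Kaiser rule (eigenvalues strictly greater than 1). Column
#' signs are fixed so each column's largest-magnitude entry is positive,
#' which makes the decomposition deterministic.
#'
#' @param R Symmetric correlation matrix with unit diagonal and SNP
#'   row/column names.
#' @param k Optional factor count override; `NULL` for the Kaiser rule.
#' @return An m x k loading matrix with attribute `eigenvalues`.
#' @examples
#' R <- matrix(c(1, .8, .8, 1), 2, dimnames = rep(list(c("a", "b")), 2))
#' extract_factors(R)
#' @export
extract_factors <- function(R, k = NULL) {
  check_square_named(R, "R")
  if (max(abs(diag(R) - 1)) > 1e-8) abort("`R` must have a unit diagonal")
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < -1e-8 * max(ev$values))
    abort("`R` must be positive semi-definite")
  if (is.null(k)) k <- sum(ev$values > 1)
  if (k < 1)
    abort("no common factor: the Kaiser rule retains zero factors for this correlation matrix")
  if (k > ncol(R)) abort("`k` cannot exceed the number of SNPs")
  L <- ev$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pmax(ev$values[seq_len(k)], 0)), k)
  L <- fix_column_signs(L)
  dimnames(L) <- list(rownames(R), paste0("factor", seq_len(k)))
  attr(L, "eigenvalues") <- ev$values
  attr(L, "eigenvectors") <- ev$vectors[, seq_len(k), drop = FALSE]
  L
}

fix_column_signs <- function(L) {
  for (j in seq_len(ncol(L))) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) L[, j] <- -L[, j]
  }
  L
}

#' Varimax rotation of a loading matrix
#'
#' Orthogonal rotation maximizing the Kaiser-normalized varimax criterion by
#' cyclic pairwise planar rotations, each pair rotated by its closed-form
#' optimal angle, iterated until the criterion improves by less than 1e-9.
#' The closed-form angle steps off saddle points (e.g. perfectly balanced
#' two-factor loadings) where gradient-style updates stall. Row
#' communalities are invariant under the rotation. With a single factor the
#' loadings are returned unchanged.
#'
#' @param loadings m x k loading matrix.
#' @param normalize Kaiser-normalize rows (divide by the square root of the
#'   communality) before rotating; default `TRUE`.
#' @param eps Criterion-change convergence tolerance.
#' @return A list with `loadings` (rotated, column signs fixed) and
#'   `rotation` (the k x k orthogonal matrix, loadings %*% rotation =
#'   rotated).
#' @export
varimax_rotate <- function(loadings, normalize = TRUE, eps = 1e-9) {
  k <- ncol(loadings)
  if (k < 1) abort("at least one factor is required")
  if (k == 1) {
    return(list(loadings = fix_column_signs(loadings), rotation = diag(1)))
  }
  L <- as.matrix(loadings)
  m <- nrow(L)
  h <- if (normalize) sqrt(pmax(rowSums(L^2), .Machine$double.eps)) else rep(1, m)
  W <- L / h
  rot <- diag(k)
  crit <- function(X) sum(apply(X^2, 2, function(x) sum(x^2) / m - (sum(x) / m)^2))
  old <- crit(W)
  for (iter in 1:100) {
    for (pq in utils::combn(k, 2, simplify = FALSE)) {
      p <- pq[1]; q <- pq[2]
      u <- W[, p]^2 - W[, q]^2
      v <- 2 * W[, p] * W[, q]
      A <- sum(u); Bv <- sum(v)
      C <- sum(u^2 - v^2); D <- sum(2 * u * v)
      num <- D - 2 * A * Bv / m
      den <- C - (A^2 - Bv^2) / m
      phi <- atan2(num, den) / 4
      if (abs(phi) < 1e-13) next
      G <- matrix(c(cos(phi), -sin(phi), sin(phi), cos(phi)), 2, 2)
      W[, c(p, q)] <- W[, c(p, q)] %*% G
      rot[, c(p, q)] <- rot[, c(p, q)] %*% G
    }
    new <- crit(W)
    if (new - old < eps) break
    old <- new
  }
  L <- (W * h)
  # fix column signs, carrying the flip into the rotation matrix
  for (j in seq_len(k)) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) { L[, j] <- -L[, j]; rot[, j] <- -rot[, j] }
  }
  dimnames(L) <- dimnames(loadings)
  list(loadings = L, rotation = rot)
}

#' Fit a rotated factor model to one SNP block, filtering low communalities
#'
#' Computes the Pearson correlation matrix of the block's dosages, extracts
#' principal-component factors (Kaiser rule unless `k` is given), applies
#' varimax rotation, and iteratively drops the SNP with the lowest
#' communality below `threshold` — re-extracting and re-rotating after each
#' exclusion — until every retained communality reaches the threshold.
#'
#' @param data Data frame holding the dosage columns.
#' @param snps Character vector of the block's SNP column names.
#' @param block_id Identifier carried into the result.
#' @param threshold Communality threshold in (0, 1); default 0.3, the
#'   published exclusion rule.
#' @param k Optional factor-count override (applied at every pass, capped at
#'   the retained block size).
#' @return An object of class `factor_model`: retained `snp_ids`, rotated
#'   `loadings`, `communalities`, `variance_explained`, `rotation`,
#'   `score_coefficients`, `excluded` (tibble of dropped SNPs with their
#'   final communality), `k`, and the correlation matrix `R`.
#' @export
fit_factor_block <- function(data, snps, block_id = "block", threshold = 0.3,
                             k = NULL) {
  if (threshold <= 0 || threshold >= 1) abort("`threshold` must lie in (0, 1)")
  retained <- snps
  excluded <- tibble(snp_id = character(0), communality = numeric(0))
  repeat {
    if (length(retained) == 0)
      abort(sprintf("block '%s' is empty: every SNP fell below the communality threshold %.2f",
                    block_id, threshold))
    X <- as.matrix(data[, retained, drop = FALSE])
    if (length(retained) == 1) {
      R <- matrix(1, 1, 1, dimnames = list(retained, retained))
      L <- matrix(1, 1, 1, dimnames = list(retained, "factor1"))
      attr(L, "eigenvalues") <- 1
      attr(L, "eigenvectors") <- matrix(1, 1, 1)
      rot <- list(loadings = L, rotation = diag(1))
      comm <- setNames(1, retained)
      break
    }
    R <- cor(X)
    kk <- if (is.null(k)) NULL else min(k, length(retained))
    L <- extract_factors(R, k = kk)
    rot <- varimax_rotate(L)
    comm <- rowSums(rot$loadings^2)
    low <- which(comm < threshold)
    if (length(low) == 0) break
    drop_i <- names(which.min(comm[low]))
    excluded <- bind_rows(excluded,
                          tibble(snp_id = drop_i, communality = comm[[drop_i]]))
    retained <- setdiff(retained, drop_i)
  }
  kfit <- ncol(rot$loadings)
  eigvals <- attr(L, "eigenvalues")
  # score coefficients: standardized PC scores carried through the rotation
  V <- attr(L, "eigenvectors")
  W <- V %*% diag(1 / sqrt(eigvals[seq_len(kfit)]), kfit) %*% rot$rotation
  dimnames(W) <- dimnames(rot$loadings)
  structure(
    list(block_id = block_id, snp_ids = retained, loadings = rot$loadings,
         rotation = rot$rotation, communalities = comm,
         variance_explained = sum(rot$loadings^2) / length(retained),
         score_coefficients = W, excluded = excluded, k = kfit, R = R,
         threshold = threshold),
    class = "factor_model"
  )
}

#' @export
print.factor_model <- function(x, ...) {
  cat(sprintf("<factor_model> block '%s': %d SNPs, %d factor(s), %.1f%% variance explained\n",
              x$block_id, length(x$snp_ids), x$k, 100 * x$variance_explained))
  if (nrow(x$excluded) > 0)
    cat(sprintf("  excluded (communality < %.2f): %s\n", x$threshold,
                paste(sprintf("%s (%.3f)", x$excluded$snp_id,
                              x$excluded$communality), collapse = ", ")))
  print(round(x$loadings, 4))
  invisible(x)
}

#' Standardized factor scores for a fitted block
#'
#' Projects standardized dosages onto the rotated principal-component score
#' coefficients. In sample, every factor score has mean 0 and variance 1
#' exactly, and scores of different factors within a block are exactly
#' uncorrelated.
#'
#' @param data Data frame containing the model's SNP columns.
#' @param model A [fit_factor_block()] result.
#' @param prefix Column-name prefix for the score columns (default the
#'   block id).
#' @return A tibble of `k` score columns named `<prefix>_1 .. <prefix>_k`
#'   (or the factor names when `prefix = NULL`).
#' @export
factor_scores <- function(data, model, prefix = model$block_id) {
  missing <- setdiff(model$snp_ids, names(data))
  if (length(missing) > 0)
    abort(sprintf("genotype columns missing for block '%s': %s",
                  model$block_id, paste(missing, collapse = ", ")))
  Z <- scale(as.matrix(data[, model$snp_ids, drop = FALSE]))
  S <- Z %*% model$score_coefficients
  colnames(S) <- if (is.null(prefix)) colnames(model$loadings)
                 else paste0(prefix, "_", seq_len(model$k))
  as_tibble(S)
}

#' Assign each SNP to its dominant factor
#'
#' Each SNP is assigned to the factor holding its maximum absolute loading;
#' the signed loading is retained so opposite-direction members of a factor
#' remain visible. Exact ties go to the lower-indexed factor, with a message.
#'
#' @param model A `factor_model`.
#' @return A tibble with `snp_id`, `factor`, `loading`, `communality`.
#' @export
assign_snps <- function(model) {
  L <- model$loadings
  rows <- map(rownames(L), function(s) {
    a <- abs(L[s, ])
    j <- which(a == max(a))
    if (length(j) > 1) {
      rlang::inform(sprintf("loading tie for %s between factors %s; assigned to factor %d",
                            s, paste(j, collapse = "/"), min(j)))
      j <- min(j)
    }
    tibble(snp_id = s, factor = colnames(L)[j], loading = L[s, j],
           communality = model$communalities[[s]])
  })
  list_rbind(rows)
}

#' Factor-analyse every SNP block and build the FACTORij score table
#'
#' Runs [fit_factor_block()] on each block from [select_blocks()] and
#' assembles the per-subject factor scores. Score columns follow the
#' FACTORij naming convention: `FACTOR<block><j>` is the j-th latent
#' variable of the i-th block.
#'
#' @param data Data frame with all dosage columns.
#' @param blocks Block tibble from [select_blocks()].
#' @param threshold Communality threshold passed to [fit_factor_block()].
#' @param k_override Named list mapping trait name to a fixed factor count.
#' @return A list with `models` (named by trait), `scores` (tibble of all
#'   FACTORij columns), and `factor_targets` (tibble `factor`, `trait`).
#' @export
snp_factor_analysis <- function(data, blocks, threshold = 0.3,
                                k_override = list()) {
  ids <- sort(unique(blocks$block_id))
  models <- list()
  score_list <- list()
  targets <- list()
  for (b in ids) {
    bi <- filter(blocks, .data$block_id == b)
    trait <- bi$trait[1]
    model <- fit_factor_block(data, bi$snp_id, block_id = trait,
                              threshold = threshold,
                              k = k_override[[trait]])
    sc <- factor_scores(data, model, prefix = NULL)
    names(sc) <- paste0("FACTOR", b, seq_len(model$k))
    models[[trait]] <- model
    score_list[[trait]] <- sc
    targets[[trait]] <- tibble(factor = names(sc), trait = trait)
  }
  list(models = models,
       scores = dplyr::bind_cols(score_list),
       factor_targets = list_rbind(unname(targets)))
}
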