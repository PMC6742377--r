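# Step 2: principal-component extraction, varimax, communality filtering,
# and factor scores.

test_that("extraction matches the 2x2 eigendecomposition closed form", {
  R <- matrix(c(1, 0.8, 0.8, 1), 2, dimnames = rep(list(c("a", "b")), 2))
  L <- extract_factors(R)
  expect_equal(ncol(L), 1)
  expect_equal(unname(L[, 1]), rep(sqrt(1.8) * sqrt(0.5), 2), tolerance = 1e-6)
  expect_equal(unname(L[, 1]), c(0.9487, 0.9487), tolerance = 1e-4)
})

test_that("identity correlation yields the no-common-factor error", {
  R <- diag(4); dimnames(R) <- rep(list(paste0("s", 1:4)), 2)
  expect_error(extract_factors(R), "no common factor")
})

test_that("block-diagonal structure gives one factor per block with known loadings", {
  R <- diag(4)
  R[1, 2] <- R[2, 1] <- 0.7
  R[3, 4] <- R[4, 3] <- 0.7
  dimnames(R) <- rep(list(paste0("s", 1:4)), 2)
  L <- varimax_rotate(extract_factors(R))$loadings
  expect_equal(ncol(L), 2)
  # per-pair eigenvalues 1.7/0.3; loading sqrt(1.7)*sqrt(0.5) = 0.9220
  onf <- apply(abs(L), 1, max)
  off <- apply(abs(L), 1, min)
  expect_equal(unname(onf), rep(0.92195, 4), tolerance = 1e-4)
  expect_true(all(off < 1e-8))
  # the planted pairs are recovered
  grouping <- assign_snps(list(loadings = L, communalities = rowSums(L^2)))
  expect_equal(grouping$factor[1], grouping$factor[2])
  expect_equal(grouping$factor[3], grouping$factor[4])
  expect_false(grouping$factor[1] == grouping$factor[3])
})

test_that("varimax fixes perfect simple structure and matches a grid-search oracle", {
  # simple structure is a fixed point (up to sign/permutation)
  L0 <- diag(2)
  r0 <- varimax_rotate(L0)
  expect_equal(abs(r0$loadings), diag(2), tolerance = 1e-9)

  # planar grid oracle at 0.1 degree resolution
  L <- matrix(c(0.707, 0.707, 0.707, -0.707), 2, 2)
  r <- varimax_rotate(L)
  got <- varimax_criterion(r$loadings)
  grid <- seq(0, pi / 2, by = 0.1 * pi / 180)
  best <- max(sapply(grid, function(th) {
    G <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
    varimax_criterion(L %*% G)
  }))
  expect_gte(got, best - 1e-6)

  # rotation is orthogonal; communalities invariant
  expect_equal(crossprod(r$rotation), diag(2), tolerance = 1e-10)
  expect_true(max(abs(rowSums(r$loadings^2) - rowSums(L^2))) < 1e-12)
})

test_that("communality filter excludes exactly the planted weak member per block", {
  set.seed(14)
  n <- 3000
  # three blocks, each: 4 strongly loading SNPs plus one weak member whose
  # communality falls below 0.3, mirroring one exclusion per published block
  for (b in 1:3) {
    d <- as.data.frame(loaded_genotypes(c(rep(0.8, 4), 0.3), maf = 0.3, n = n))
    names(d) <- c(paste0("b", b, "_s", 1:4), paste0("b", b, "_weak"))
    fm <- fit_factor_block(d, names(d), block_id = paste0("b", b))
    expect_equal(fm$excluded$snp_id, paste0("b", b, "_weak"))
    expect_true(all(fm$communalities >= 0.3))
    expect_true(fm$excluded$communality < 0.3)
    # recompute communalities by hand from the rotated loadings
    expect_equal(unname(fm$communalities),
                 unname(rowSums(fm$loadings^2)), tolerance = 1e-10)
  }
})

test_that("a block with all communalities above threshold passes untouched", {
  set.seed(15)
  d <- as.data.frame(simulate_genotypes(rep(0.3, 4), 2000, within_group_r = 0.6))
  names(d) <- paste0("s", 1:4)
  fm <- fit_factor_block(d, names(d))
  expect_equal(nrow(fm$excluded), 0)
  expect_equal(fm$snp_ids, names(d))
})

test_that("a structureless block degrades to a single trivially loading SNP", {
  set.seed(16)
  d <- as.data.frame(matrix(sample(0:2, 200 * 3, TRUE), 200, 3))
  names(d) <- paste0("s", 1:3)
  # with a demanding threshold, independent SNPs are shed one by one until a
  # single SNP (communality exactly 1) remains
  fm <- fit_factor_block(d, names(d), threshold = 0.99)
  expect_equal(length(fm$snp_ids), 1)
  expect_equal(nrow(fm$excluded), 2)
  expect_equal(unname(fm$communalities), 1)
})

test_that("factor scores are standardized, orthogonal, and exact for single-SNP blocks", {
  set.seed(17)
  d <- as.data.frame(simulate_genotypes(rep(0.25, 4), 1500, within_group_r = 0.5))
  names(d) <- paste0("s", 1:4)
  d$solo <- as.vector(simulate_genotypes(0.4, 1500))
  fm <- fit_factor_block(d, paste0("s", 1:4), k = 2)
  sc <- factor_scores(d, fm, prefix = NULL)
  expect_equal(colMeans(as.matrix(sc)), c(factor1 = 0, factor2 = 0),
               tolerance = 1e-10)
  expect_equal(apply(as.matrix(sc), 2, var), c(factor1 = 1, factor2 = 1),
               tolerance = 1e-10)
  expect_lt(abs(cor(sc[[1]], sc[[2]])), 1e-8)

  fm1 <- fit_factor_block(d, "solo", block_id = "solo")
  expect_equal(unname(fm1$loadings[1, 1]), 1.0)
  sc1 <- factor_scores(d, fm1)
  expect_equal(sc1[[1]], as.numeric(scale(d$solo)), tolerance = 1e-12)

  expect_error(factor_scores(d[, "solo", drop = FALSE], fm), "missing")
})

test_that("variance explained equals the eigenvalue share and survives rotation", {
  set.seed(18)
  d <- as.data.frame(simulate_genotypes(rep(0.3, 5), 2500, within_group_r = 0.55))
  names(d) <- paste0("s", 1:5)
  fm <- fit_factor_block(d, names(d))
  ev <- eigen(fm$R, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(fm$variance_explained, sum(ev[seq_len(fm$k)]) / length(fm$snp_ids),
               tolerance = 1e-10)
  # determinism
  fm2 <- fit_factor_block(d, names(d))
  expect_identical(fm$loadings, fm2$loadings)
})

test_that("tie-broken assignment goes to the lower-indexed factor", {
  fake <- list(loadings = matrix(c(0.5, 0.01, 0.5, 0.86), 2, 2,
                                 dimnames = list(c("s1", "s2"), c("factor1", "factor2"))),
               communalities = c(s1 = 0.5, s2 = 0.74))
  expect_message(a <- assign_snps(fake), "tie")
  expect_equal(a$factor[a$snp_id == "s1"], "factor1")
  expect_equal(a$factor[a$snp_id == "s2"], "factor2")
})

test_that("the Kaiser rule recovers planted group structure across seeds", {
  hits <- 0L
  for (seed in 1:100) {
    set.seed(seed)
    g1 <- simulate_genotypes(rep(0.3, 3), 5000, within_group_r = 0.55)
    g2 <- simulate_genotypes(rep(0.3, 3), 5000, within_group_r = 0.55)
    d <- as.data.frame(cbind(g1, g2))
    names(d) <- c(paste0("a", 1:3), paste0("b", 1:3))
    fm <- try(fit_factor_block(d, names(d)), silent = TRUE)
    if (inherits(fm, "try-error") || fm$k != 2) next
    asg <- assign_snps(fm)
    fa <- asg$factor[match(paste0("a", 1:3), asg$snp_id)]
    fb <- asg$factor[match(paste0("b", 1:3), asg$snp_id)]
    if (length(unique(fa)) == 1 && length(unique(fb)) == 1 &&
        fa[1] != fb[1]) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})
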