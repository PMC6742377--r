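# Step 1: single-SNP scans, Wald consistency, block selection, LD pruning.

test_that("linear scan matches closed-form least squares", {
  d <- data.frame(g = c(0, 1, 2, 0, 1, 2),
                  y = c(0.1, 1.1, 2.0, 0.0, 0.9, 2.1))
  res <- linear_scan(d, "y", "g")
  expect_equal(res$estimate, 1.0, tolerance = 1e-12) # Sxy = Sxx = 4.0
  expect_equal(res$model, "linear")

  # perfect fit: exact slope, degenerate p handled without division error
  d2 <- data.frame(g = c(0, 1, 2, 0, 1, 2))
  d2$y <- d2$g
  res2 <- linear_scan(d2, "y", "g")
  expect_equal(res2$estimate, 1.0)
  expect_equal(res2$p_value, 0)

  # monomorphic SNP flagged, never an error
  d3 <- data.frame(g = rep(1, 10), y = rnorm(10))
  res3 <- linear_scan(d3, "y", "g")
  expect_true(is.na(res3$p_value))
  expect_equal(res3$note, "monomorphic")
})

test_that("Wald statistic equals estimate/se for every emitted result", {
  co <- simulate_cohort(sim_config(n_subjects = 600, seed = 4))
  res <- snp_scan(co$data, co$snp_groups$snp_id, c("SUB", "BMI"), "HTN",
                  c("SEX", "AREA", "AGE"))
  ok <- dplyr::filter(res, note == "")
  expect_gt(nrow(ok), 0)
  expect_true(all(abs(ok$statistic - ok$estimate / ok$std_error) < 1e-10))
  expect_true(all(ok$p_value >= 0 & ok$p_value <= 1))
})

test_that("a covariate orthogonal to dosage and trait leaves the estimate unchanged", {
  set.seed(31)
  n <- 200
  d <- data.frame(g = sample(0:2, n, TRUE), y = rnorm(n))
  z <- rnorm(n)
  d$z <- resid(lm(z ~ g + y, data = d)) # orthogonal by construction
  b0 <- linear_scan(d, "y", "g")$estimate
  b1 <- linear_scan(d, "y", "g", covariates = "z")$estimate
  expect_lt(abs(b1 - b0), 1e-8)
})

test_that("logistic scan agrees with a direct Newton solve of the score equations", {
  cases <- c(5, 10, 20); controls <- c(20, 10, 5)
  g <- rep(rep(0:2, 2), c(cases, controls))
  y <- rep(c(1, 0), c(sum(cases), sum(controls)))
  d <- data.frame(g = g, y = y)
  res <- logistic_scan(d, "y", "g")
  oracle <- newton_logistic(cbind(1, g), y)
  expect_equal(res$estimate, unname(oracle$beta[2]), tolerance = 1e-7)
  expect_equal(res$std_error, sqrt(oracle$vcov[2, 2]), tolerance = 1e-6)

  # balanced null table: log-OR 0, p ~ 1
  d0 <- data.frame(g = rep(rep(0:2, 2), rep(10, 6)),
                   y = rep(c(1, 0), c(30, 30)))
  res0 <- logistic_scan(d0, "y", "g")
  expect_equal(res0$estimate, 0, tolerance = 1e-8)
  expect_gt(res0$p_value, 0.99)

  expect_error(logistic_scan(data.frame(g = 0:2, y = c(0, 0, 0)), "y", "g"),
               "single class")
})

test_that("perfect separation is flagged as non-converged, not fatal", {
  d <- data.frame(g = c(0, 0, 0, 2, 2, 2), y = c(0, 0, 0, 1, 1, 1))
  res <- logistic_scan(d, "y", "g")
  expect_equal(res$note, "non_converged")
  expect_true(is.na(res$p_value))
  expect_warning(select_blocks(res, alpha = 0.5), "flagged")
})

test_that("null-scan p-values are uniform and type-I error is controlled", {
  set.seed(6)
  n <- 500; m <- 200
  ks_crit <- 1.628 / sqrt(m) # alpha = 0.01 asymptotic critical value
  ks_pass <- 0L
  all_p <- numeric(0)
  for (rep in 1:100) {
    G <- matrix(sample(0:2, n * m, TRUE, prob = c(0.49, 0.42, 0.09)), n, m)
    colnames(G) <- paste0("s", 1:m)
    d <- data.frame(y = rnorm(n))
    d <- cbind(d, as.data.frame(G))
    res <- linear_scan(d, "y", colnames(G))
    p <- sort(res$p_value)
    D <- max(pmax(abs(p - (seq_len(m) - 1) / m), abs(p - seq_len(m) / m)))
    if (D < ks_crit) ks_pass <- ks_pass + 1L
    all_p <- c(all_p, res$p_value)
  }
  expect_gte(ks_pass, 95L)
  rate <- mean(all_p < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / length(all_p)))
})

test_that("select_blocks retains exactly the sub-threshold SNPs per trait", {
  # boundary logic at the published threshold
  res <- tibble::tibble(
    snp_id = c("rsA", "rsB"), trait = "SUB", model = "linear",
    estimate = 1, std_error = 1, statistic = 1,
    p_value = c(1.92e-7, 2.0e-5), n = 100, note = "")
  blk <- select_blocks(res, alpha = 1e-5)
  expect_equal(blk$snp_id, "rsA")

  # planted per-trait counts (5/7/7/1/4) equal brute-force counting
  set.seed(9)
  counts <- c(SUB = 5, BMI = 7, WC = 7, T2D = 1, HTN = 4)
  rows <- purrr::imap(counts, function(k, tr) {
    m <- k + 10
    tibble::tibble(snp_id = paste0(tr, "_", seq_len(m)), trait = tr,
                   model = "linear", estimate = 0, std_error = 1, statistic = 0,
                   p_value = c(runif(k, 1e-9, 9e-6), runif(m - k, 1e-4, 1)),
                   n = 100, note = "")
  })
  res2 <- dplyr::bind_rows(rows)
  blk2 <- select_blocks(res2, alpha = 1e-5)
  got <- table(blk2$trait)[names(counts)]
  brute <- sapply(names(counts), function(tr)
    sum(res2$p_value[res2$trait == tr] < 1e-5))
  expect_equal(as.integer(got), as.integer(brute))
  expect_equal(as.integer(got), as.integer(counts))
  # ordered by ascending p within block
  expect_true(all(diff(order(blk2$block_id, blk2$p_value)) > 0))
})

test_that("empty blocks are allowed and reported", {
  res <- tibble::tibble(snp_id = "rs1", trait = "SUB", model = "linear",
                        estimate = 0, std_error = 1, statistic = 0,
                        p_value = 0.5, n = 10, note = "")
  blk <- select_blocks(res, alpha = 1e-5)
  expect_equal(nrow(blk), 0)
  expect_equal(attr(blk, "empty_traits"), "SUB")
})

test_that("greedy LD pruning matches an exhaustive oracle", {
  # duplicate columns: only the more significant one survives
  set.seed(10)
  g <- sample(0:2, 100, TRUE)
  X <- cbind(a = g, b = g)
  expect_equal(ld_prune(X, c("a", "b"), 0.8), "a")

  # independent SNPs: all kept
  Xi <- sapply(1:4, function(i) sample(0:2, 200, TRUE))
  colnames(Xi) <- paste0("s", 1:4)
  expect_equal(ld_prune(Xi, colnames(Xi), 0.5), colnames(Xi))

  # 5 SNPs with a known dependence structure spanning both sides of the
  # threshold: compare against a brute-force greedy pass
  set.seed(11)
  s1 <- rnorm(400)
  d <- data.frame(s1 = s1,
                  s2 = 0.97 * s1 + sqrt(1 - 0.97^2) * rnorm(400),
                  s3 = 0.75 * s1 + sqrt(1 - 0.75^2) * rnorm(400))
  d$s4 <- 0.96 * d$s3 + sqrt(1 - 0.96^2) * rnorm(400)
  d$s5 <- 0.5 * d$s4 + sqrt(0.75) * rnorm(400)
  thr <- 0.8
  greedy_oracle <- function(cols) {
    kept <- character(0)
    for (s in cols) {
      if (all(sapply(kept, function(k) cor(d[[s]], d[[k]])^2 < thr)))
        kept <- c(kept, s)
    }
    kept
  }
  expect_equal(ld_prune(d, names(d), thr), greedy_oracle(names(d)))
  expect_error(ld_prune(d, names(d), 0), "0, 1")
})
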