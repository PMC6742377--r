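# Synthetic-cohort generator: Hardy-Weinberg margins, copula correlation,
# the standardized cascade, and liability-threshold diseases.

test_that("genotype margins follow Hardy-Weinberg proportions", {
  n <- 10000
  g <- simulate_genotypes(0.3, n = n, within_group_r = 0, seed = 42)
  freq <- tabulate(g + 1L, nbins = 3) / n
  hwe <- c(0.49, 0.42, 0.09)
  for (k in 1:3) {
    band <- 3 * sqrt(hwe[k] * (1 - hwe[k]) / n)
    expect_lt(abs(freq[k] - hwe[k]), band)
  }
  expect_true(all(simulate_genotypes(0.5, 4, 0, seed = 9) %in% 0:2))
  expect_error(simulate_genotypes(0.6, 10), "0, 0.5")
  expect_error(simulate_genotypes(0, 10), "0, 0.5")
})

test_that("HWE goodness-of-fit is non-rejected at close to the nominal rate", {
  set.seed(1)
  n <- 2000
  rejections <- 0L
  for (i in 1:100) {
    maf <- runif(1, 0.05, 0.5)
    g <- simulate_genotypes(maf, n, within_group_r = 0)
    obs <- tabulate(g + 1L, nbins = 3)
    expd <- n * c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
    stat <- sum((obs - expd)^2 / expd)
    if (stat > qchisq(0.95, df = 2)) rejections <- rejections + 1L
  }
  expect_gte(100L - rejections, 94L)
})

test_that("within-group copula correlation is close to its target", {
  g <- simulate_genotypes(rep(0.3, 4), n = 20000, within_group_r = 0.6, seed = 5)
  offdiag <- cor(g)[upper.tri(diag(4))]
  expect_true(all(offdiag > 0.4 & offdiag < 0.7))
})

test_that("identical configs regenerate bit-identical cohorts", {
  cfg <- sim_config(n_subjects = 300, seed = 77)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$data, c2$data)
  expect_identical(c1$truth, c2$truth)
  snps <- c1$snp_groups$snp_id
  expect_true(all(as.matrix(c1$data[, snps]) %in% 0:2))
})

test_that("observed disease prevalences match the configured KARE rates", {
  co <- simulate_cohort(sim_config(n_subjects = 8842, seed = 3))
  targets <- c(T2D = 0.0945, HTN = 0.2706)
  for (dz in names(targets)) {
    pi <- targets[[dz]]
    band <- 3 * sqrt(pi * (1 - pi) / 8842)
    expect_lt(abs(mean(co$data[[dz]]) - pi), band)
  }
  # calibration tightens (or stays exact) as n grows
  small <- simulate_cohort(sim_config(n_subjects = 1000, seed = 3))
  big <- simulate_cohort(sim_config(n_subjects = 100000, seed = 3))
  err_small <- abs(mean(small$data$T2D) - 0.0945)
  err_big <- abs(mean(big$data$T2D) - 0.0945)
  expect_lte(err_big, max(err_small, 1 / 1000))
})

test_that("null configuration yields uncorrelated traits", {
  zero_cov <- lapply(default_covariate_effects(), function(x) x * 0)
  zero_fac <- lapply(default_factor_effects(), function(f) {
    f$effect <- 0; f
  })
  cz <- lapply(default_cascade(), function(x) 0)
  co <- simulate_cohort(sim_config(n_subjects = 20000, seed = 8,
                                   cascade = cz, factor_effects = zero_fac,
                                   covariate_effects = zero_cov))
  r <- cor(co$data[, c("SUB", "BMI", "WC")])
  expect_true(all(abs(r[upper.tri(r)]) < 3 / sqrt(20000)))
})

test_that("per-equation least squares recovers the generating cascade", {
  cz <- modifyList(lapply(default_cascade(), function(x) 0),
                   list(sub_to_bmi = 0.63, bmi_to_wc = 0.80, sub_to_wc = 0.04))
  zero_cov <- lapply(default_covariate_effects(), function(x) x * 0)
  zero_fac <- lapply(default_factor_effects(), function(f) {
    f$effect <- 0; f
  })
  co <- simulate_cohort(sim_config(n_subjects = 20000, seed = 12, cascade = cz,
                                   factor_effects = zero_fac,
                                   covariate_effects = zero_cov))
  d <- co$data
  expect_lt(abs(coef(lm(BMI ~ SUB, d))[["SUB"]] - 0.63), 0.02)
  fit_wc <- coef(lm(WC ~ SUB + BMI, d))
  expect_lt(abs(fit_wc[["SUB"]] - 0.04), 0.02)
  expect_lt(abs(fit_wc[["BMI"]] - 0.80), 0.02)
})

test_that("strengthening sub_to_bmi strengthens corr(SUB, BMI)", {
  cors <- sapply(c(0.2, 0.4, 0.6), function(b) {
    cz <- modifyList(lapply(default_cascade(), function(x) 0),
                     list(sub_to_bmi = b))
    co <- simulate_cohort(sim_config(n_subjects = 20000, seed = 21, cascade = cz))
    cor(co$data$SUB, co$data$BMI)
  })
  expect_true(all(diff(cors) > 0))
})

test_that("inadmissible configurations are rejected with a diagnostic", {
  bad <- modifyList(default_cascade(), list(sub_to_bmi = 1.2))
  expect_error(simulate_cohort(sim_config(n_subjects = 100, cascade = bad)),
               "inadmissible")
  expect_error(sim_config(prevalences = list(t2d = 0, htn = 0.3)), "0,1")
  expect_error(sim_config(snp_groups = list(
    list(group_id = "g", n_snps = 2L, maf_range = c(0, 0.4),
         within_group_r = 0.5))), "maf_range")
})

test_that("cohort files round-trip through the writers and readers", {
  co <- simulate_cohort(sim_config(n_subjects = 60, seed = 2))
  dir <- withr::local_tempdir()
  paths <- write_cohort(co, dir)
  g <- read_genotypes(paths[["genotypes"]])
  p <- read_phenotypes(paths[["phenotypes"]])
  expect_equal(names(g)[-1], co$snp_groups$snp_id)
  expect_equal(g$subject_id, co$data$subject_id)
  expect_equal(p$BMI, co$data$BMI, tolerance = 1e-9)
})
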