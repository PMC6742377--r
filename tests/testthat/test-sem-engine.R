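# Step 4: RAM implied covariance, ML estimation, and fit indices.

test_that("implied covariance matches hand computations", {
  # A = 0, S = I -> identity
  spec0 <- sem_spec(data.frame(from = character(0), to = character(0)),
                    variables = c("x", "y"), covariances = "none",
                    sample_cov = diag(2) |> `dimnames<-`(rep(list(c("x", "y")), 2)),
                    n = 50)
  f0 <- fit_ml(spec0)
  ram <- f0$ram
  Sig <- implied_covariance(ram, c(1, 1))
  expect_equal(unclass(Sig), diag(2), ignore_attr = TRUE)

  # single path a = 0.5, unit x variance, residual 0.75
  spec1 <- sem_spec(data.frame(from = "x", to = "y"),
                    sample_cov = matrix(c(1, .5, .5, 1), 2,
                                        dimnames = rep(list(c("x", "y")), 2)),
                    n = 101)
  f1 <- fit_ml(spec1)
  Sig1 <- implied_covariance(f1$ram, c(0.5, 1, 0.75))
  expect_equal(unclass(Sig1), matrix(c(1, .5, .5, 1), 2), ignore_attr = TRUE,
               tolerance = 1e-12)

  # chain: cov(x, y) = a * b
  spec2 <- sem_spec(chain_spec_paths(), sample_cov = chain_cov(0.5, 0.4), n = 200)
  f2 <- fit_ml(spec2)
  Sig2 <- implied_covariance(f2$ram, f2$theta)
  expect_equal(Sig2["x", "y"], 0.2, tolerance = 1e-6)
})

test_that("singular structural systems are rejected", {
  spec <- sem_spec(data.frame(from = "x", to = "y"),
                   sample_cov = matrix(c(1, .5, .5, 1), 2,
                                       dimnames = rep(list(c("x", "y")), 2)),
                   n = 101)
  ram <- fit_ml(spec)$ram
  ram$par$value[ram$par$matrix == "A"] <- NA
  bad_ram <- ram
  # force A entry y<-y via a hacked parameter row to create (I - A) singular
  bad_ram$par <- rbind(bad_ram$par,
                       tibble::tibble(matrix = "A", row = 2, col = 2,
                                      free = FALSE, value = 1, start = 1,
                                      from = "y", to = "y", type = "path",
                                      param_id = NA_integer_))
  expect_error(implied_covariance(bad_ram, c(0.5, 1, 0.75)), "singular")
})

test_that("the two-variable regression model has the closed-form ML solution", {
  S <- matrix(c(1, .5, .5, 1), 2, dimnames = rep(list(c("x", "y")), 2))
  fit <- fit_ml(sem_spec(data.frame(from = "x", to = "y"),
                         sample_cov = S, n = 101))
  est <- tidy(fit)
  expect_equal(est$estimate[est$type == "path"], 0.5, tolerance = 1e-8)
  expect_equal(est$estimate[est$to == "y" & est$type == "residual_variance"],
               0.75, tolerance = 1e-8)
  expect_equal(fit$chi_square, 0, tolerance = 1e-8)
})

test_that("a saturated model attains zero discrepancy and reproduces S", {
  set.seed(30)
  d <- as.data.frame(MASS::mvrnorm(400, rep(0, 4), diag(4) * 0.5 + 0.5))
  names(d) <- c("a", "b", "c", "e")
  paths <- data.frame(from = c("a", "a", "b", "a", "b", "c"),
                      to = c("b", "c", "c", "e", "e", "e"))
  fit <- fit_ml(sem_spec(paths, data = d))
  expect_equal(fit$df, 0)
  expect_lt(fit$F_ml, 1e-10)
  expect_lt(max(abs(fit$Sigma_hat - fit$S)), 1e-8)
  fi <- fit_indices(fit)
  expect_equal(fi$gfi, 1, tolerance = 1e-8)
  expect_equal(fi$cfi, 1)
  expect_true(is.na(fi$rmsea))
})

test_that("ML estimates equal per-equation OLS for recursive observed models", {
  co <- simulate_cohort(sim_config(n_subjects = 2500, seed = 31))
  d <- co$data
  spec <- default_disease_paths()
  S <- cov(d[, spec$variables])
  fit <- fit_ml(sem_spec(spec$edges, sample_cov = S, n = nrow(d)))
  est <- dplyr::filter(tidy(fit), type == "path")
  for (y in unique(spec$edges$to)) {
    x <- spec$edges$from[spec$edges$to == y]
    ols <- solve(S[x, x], S[x, y])
    ml <- est$estimate[match(paste(x, y), paste(est$from, est$to))]
    expect_equal(ml, unname(ols), tolerance = 1e-6)
  }
})

test_that("standardized solutions are scale equivariant", {
  co <- simulate_cohort(sim_config(n_subjects = 1500, seed = 32))
  spec_edges <- default_disease_paths()$edges
  d <- co$data
  S <- cov(d[, c("SUB", "BMI", "WC", "T2D", "HTN")])
  # rescale to a covariance with wildly different units
  D <- diag(c(10, 0.2, 3, 1, 0.5))
  dimnames(D) <- NULL
  S2 <- D %*% S %*% D
  dimnames(S2) <- dimnames(S)
  f1 <- fit_ml(sem_spec(spec_edges, sample_cov = S, n = 1500))
  f2 <- fit_ml(sem_spec(spec_edges, sample_cov = S2, n = 1500))
  expect_equal(tidy(f1)$std_estimate, tidy(f2)$std_estimate, tolerance = 1e-6)
})

test_that("the independence model fitted as target matches the closed form", {
  S <- matrix(c(1, .5, .5, 1), 2, dimnames = rep(list(c("x", "y")), 2))
  fit <- fit_ml(sem_spec(data.frame(from = character(0), to = character(0)),
                         variables = c("x", "y"), covariances = "none",
                         sample_cov = S, n = 101))
  expect_equal(fit$df, 1)
  expect_equal(fit$chi_square, -100 * log(0.75), tolerance = 1e-6)
  fi <- fit_indices(fit)
  expect_equal(fi$rmsea, sqrt((fit$chi_square - 1) / 100), tolerance = 1e-6)
  expect_equal(fi$rmsea, 0.527, tolerance = 1e-3)
  # closed-form helper agrees
  expect_equal(independence_fit(S, 101)$chi_square, fit$chi_square,
               tolerance = 1e-6)
})

test_that("latent-variable measurement models are estimable", {
  set.seed(33)
  n <- 2000
  eta <- rnorm(n)
  d <- data.frame(i1 = 0.8 * eta + 0.6 * rnorm(n),
                  i2 = 0.7 * eta + sqrt(1 - 0.49) * rnorm(n),
                  i3 = 0.6 * eta + 0.8 * rnorm(n))
  spec <- sem_spec(data.frame(from = "eta", to = c("i1", "i2", "i3")),
                   latent = "eta", data = d)
  fit <- fit_ml(spec)
  expect_true(fit$convergence$converged)
  est <- dplyr::filter(tidy(fit), type == "path")
  expect_equal(est$estimate, c(0.8, 0.7, 0.6), tolerance = 0.1)
  expect_equal(fit$df, 0)
})

test_that("the model chi-square is calibrated for a correctly specified model", {
  set.seed(34)
  rejections <- 0L
  for (i in 1:500) {
    d <- chain_data(500, 0.5, 0.4)
    fit <- fit_ml(sem_spec(chain_spec_paths(), data = d))
    if (fit$chi_square > qchisq(0.95, 1)) rejections <- rejections + 1L
  }
  rate <- rejections / 500
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 500))
})

test_that("non-PSD input matrices are rejected before optimization", {
  bad <- matrix(c(1, 2, 2, 1), 2, dimnames = rep(list(c("x", "y")), 2))
  expect_error(fit_ml(sem_spec(data.frame(from = "x", to = "y"),
                               sample_cov = bad, n = 50)),
               "positive semi-definite")
})

test_that("the cutoff battery applies the published adequacy rules", {
  chk <- check_fit_cutoffs(kare_reported_fit_indices())
  expect_true(attr(chk, "all_pass"))
  chk2 <- check_fit_cutoffs(list(nfi = 0.99, cfi = 0.99, gfi = 0.99,
                                 agfi = 0.99, rmsea = 0.10))
  expect_false(attr(chk2, "all_pass"))
  expect_equal(chk2$pass, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  # boundary values pass (cutoffs are inclusive)
  chk3 <- check_fit_cutoffs(list(nfi = 0.95, cfi = 0.95, gfi = 0.95,
                                 agfi = 0.90, rmsea = 0.07))
  expect_true(attr(chk3, "all_pass"))
})
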