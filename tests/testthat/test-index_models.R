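test_that("least squares reproduces exact and algebraic solutions", {
  x <- 1:10
  y <- 1 + 2 * x
  f <- fit_ols(y, cbind(constant = 1, x = x))
  expect_equal(unname(f$coefficients), c(1, 2), tolerance = 1e-12)
  expect_equal(f$r_squared, 1)
  set.seed(15)
  X <- cbind(constant = 1, a = rnorm(30), b = runif(30))
  yy <- rnorm(30)
  f2 <- fit_ols(yy, X)
  oracle <- drop(solve(crossprod(X), crossprod(X, yy)))
  expect_equal(unname(f2$coefficients), unname(oracle), tolerance = 1e-10)
  # classical SE identity
  res <- yy - drop(X %*% oracle)
  s2 <- sum(res^2) / (30 - 3)
  expect_equal(unname(f2$se), unname(sqrt(diag(s2 * solve(crossprod(X))))),
               tolerance = 1e-10)
  expect_error(fit_ols(yy, cbind(X, a2 = X[, "a"])), "a2")
})

make_index_pheno <- function(n = 180, seed = 1) {
  ph <- scan_ready_pheno(generator_config(n_samples = n, seed = seed))
  ph
}

test_that("moderated index regression exposes the full covariate model", {
  ph <- make_index_pheno(seed = 51)
  set.seed(51)
  y <- 0.5 * ph$smoking_status - 0.2 * ph$mmthfr +
    0.4 * ph$smoking_status * ph$mmthfr + rnorm(180, 0, 0.5)
  m1 <- moderated_index_regression(y, ph, "status", with_interaction = FALSE)
  m2 <- moderated_index_regression(y, ph, "status", with_interaction = TRUE)
  expect_setequal(m1$terms, c("smoking", "mmthfr", "male", "age", "diet",
                              "cd8t", "cd4t", "nk", "bcell", "mono", "constant"))
  expect_true("smoking:mmthfr" %in% m2$terms)
  expect_gte(m2$r_squared, m1$r_squared)   # nesting
  expect_true(all(glance(m2)$r_squared <= 1))
  # consumption substitutes for status in the identical design
  mc <- moderated_index_regression(y, ph, "consumption", TRUE)
  expect_identical(mc$terms, m2$terms)
  # degenerate covariate errors
  ph_bad <- ph
  ph_bad$diet <- 2L
  expect_error(moderated_index_regression(y, ph_bad, "status"), "diet")
})

test_that("index interaction coefficients recover generator signs", {
  hits <- sapply(1:60, function(s) {
    cfg <- generator_config(n_samples = 180, n_hyper = 15, n_hypo = 30,
                            n_null = 0, seed = 6000 + s)
    coh <- simulate_cohort(cfg)
    ph <- coh$phenotypes
    ph$mmthfr <- build_index(coh$betas, coh$mmthfr_probes)$index
    tr <- coh$truth$loci
    cls <- tibble::tibble(
      probe_id = tr$probe_id,
      direction = tr$class,
      sign = ifelse(tr$class == "hypo", "+", "-")
    )
    hypo <- build_outcome_index(coh$betas, cls, "hypo")
    hyper <- build_outcome_index(coh$betas, cls, "hyper")
    f_hypo <- moderated_index_regression(hypo, ph, "status", TRUE)
    f_hyper <- moderated_index_regression(hyper, ph, "status", TRUE)
    f_hypo$coefficients[["smoking:mmthfr"]] > 0 &&
      f_hyper$coefficients[["smoking:mmthfr"]] < 0
  })
  expect_gte(mean(hits), 0.95)
})

test_that("simple slopes follow the linear formula and reparameterization", {
  ph <- make_index_pheno(seed = 52)
  set.seed(52)
  y <- 1 + 0.6 * ph$smoking_status + 0.3 * ph$mmthfr -
    0.5 * ph$smoking_status * ph$mmthfr + rnorm(180, 0, 0.3)
  fit <- moderated_index_regression(y, ph, "status", TRUE)
  ss <- simple_slopes(fit, moderator_sd = 1)
  b <- fit$coefficients
  expect_equal(ss$slope, unname(b["smoking"] + b["smoking:mmthfr"] * c(-1, 1)))
  # no moderation -> equal slopes
  fit0 <- fit
  fit0$coefficients["smoking:mmthfr"] <- 0
  ss0 <- simple_slopes(fit0)
  expect_equal(ss0$slope[1], ss0$slope[2])
  # hand-forced values
  fit1 <- fit
  fit1$coefficients[c("smoking", "smoking:mmthfr")] <- c(1, 0.5)
  expect_equal(simple_slopes(fit1, 1)$slope, c(0.5, 1.5))
  # reparameterization oracle: shifting the moderator by -/+ sd makes the
  # smoking main effect equal the conditional slope
  sdm <- 1.3
  for (i in 1:2) {
    shift <- c(-1, 1)[i] * sdm
    ph_s <- ph
    ph_s$mmthfr <- ph$mmthfr - shift
    fit_s <- moderated_index_regression(y, ph_s, "status", TRUE)
    expect_equal(simple_slopes(fit, sdm)$slope[i],
                 unname(fit_s$coefficients["smoking"]), tolerance = 1e-8)
  }
  fit_no <- moderated_index_regression(y, ph, "status", FALSE)
  expect_error(simple_slopes(fit_no), "smoking:mmthfr")
})

test_that("affine rescaling of age leaves t statistics unchanged", {
  ph <- make_index_pheno(seed = 53)
  set.seed(53)
  y <- 0.3 * ph$smoking_status + 0.01 * ph$age + rnorm(180, 0, 0.4)
  f1 <- moderated_index_regression(y, ph, "status", TRUE)
  ph2 <- ph
  ph2$age <- (ph$age - 50) / 10
  f2 <- moderated_index_regression(y, ph2, "status", TRUE)
  keep <- setdiff(f1$terms, "constant")   # the intercept absorbs the shift
  expect_equal(f1$t[keep], f2$t[keep], tolerance = 1e-8)
  expect_equal(f1$coefficients[["age"]], f2$coefficients[["age"]] / 10,
               tolerance = 1e-8)
})
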