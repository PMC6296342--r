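test_that("phenotype moments match the configured cohort at large n", {
  cfg <- generator_config(n_samples = 10000, seed = 11)
  ph <- simulate_phenotypes(cfg)
  se_prev <- sqrt(0.483 * (1 - 0.483) / 10000)
  expect_lt(abs(mean(ph$smoking_status) - 0.483), 3 * se_prev)
  expect_lt(abs(mean(ph$age) - 48.861), 3 * 8.586 / sqrt(10000))
  expect_lt(abs(mean(ph$male) - 0.372), 3 * sqrt(0.372 * 0.628 / 10000))
  # latent moderator: standard normal with the configured sex correlation
  expect_lt(abs(mean(ph$latent_mmthfr)), 0.05)
  expect_lt(abs(sd(ph$latent_mmthfr) - 1), 0.05)
  expect_lt(abs(cor(ph$latent_mmthfr, ph$male) - 0.412), 0.05)
  # cell fractions average near their Dirichlet means
  means <- colMeans(ph[c("cd8t", "cd4t", "nk", "bcell", "mono")])
  expect_lt(max(abs(means - c(0.137, 0.284, 0.071, 0.165, 0.144))), 0.02)
  # consumption is monotone in smoking and lives on [0, 6]
  expect_true(all(ph$consumption >= 0 & ph$consumption <= 6))
  expect_gt(mean(ph$consumption[ph$smoking_status == 1]),
            mean(ph$consumption[ph$smoking_status == 0]))
})

test_that("generator is deterministic and handles n = 0", {
  cfg <- generator_config(n_samples = 25, seed = 42)
  expect_identical(simulate_phenotypes(cfg), simulate_phenotypes(cfg))
  coh1 <- simulate_cohort(cfg)
  coh2 <- simulate_cohort(cfg)
  expect_identical(coh1$betas, coh2$betas)
  expect_identical(coh1$truth, coh2$truth)
  empty <- simulate_phenotypes(generator_config(n_samples = 0))
  expect_s3_class(empty, "tbl_df")
  expect_identical(nrow(empty), 0L)
})

test_that("invalid configuration errors name the offending field", {
  expect_error(generator_config(precision_phi = -1), "precision_phi")
  expect_error(generator_config(smoking_prevalence = 1.2), "smoking_prevalence")
  expect_error(generator_config(n_hyper = -3), "n_hyper")
  expect_error(generator_config(mmthfr_sex_corr = 1), "mmthfr_sex_corr")
  expect_error(
    generator_config(cell_fraction_means = c(a = 0.5, b = 0.6, c = 0.1,
                                             d = 0.1, e = 0.1)),
    "cell_fraction_means")
})

test_that("cell reference is deterministic with discriminating columns", {
  expect_identical(simulate_cell_reference(50, 5, seed = 9),
                   simulate_cell_reference(50, 5, seed = 9))
  one <- simulate_cell_reference(30, 1, seed = 1)
  expect_identical(ncol(one), 2L)  # probe_id + single cell type
  w <- estimate_cell_fractions(as.matrix(one[-1])[, 1], one)
  expect_equal(w[[2]], 1, tolerance = 1e-8)
  ref <- simulate_cell_reference(100, 5, seed = 3)
  R <- as.matrix(ref[-1])
  pairs <- utils::combn(5, 2)
  dists <- apply(pairs, 2, function(ij) sqrt(sum((R[, ij[1]] - R[, ij[2]])^2)))
  expect_true(all(dists > 0))
  expect_error(simulate_cell_reference(10, 0), "n_celltypes")
})

test_that("noiseless methylation equals the inverse-logit linear predictor", {
  cfg <- generator_config(n_samples = 40, n_hyper = 3, n_hypo = 3, n_null = 2,
                          n_background = 4, seed = 5)
  ph <- simulate_phenotypes(cfg)
  meth <- simulate_methylation(cfg, ph, noise = FALSE)
  tr <- meth$truth$loci
  cells <- c("cd8t", "cd4t", "nk", "bcell", "mono")
  W <- as.matrix(ph[cells])
  W_c <- sweep(W, 2, colMeans(W))
  m <- as.matrix(meth$betas[-1])
  for (j in seq_len(nrow(tr))) {
    eta <- tr$b0[j] + tr$beta_smoking[j] * ph$smoking_status +
      tr$beta_mmthfr[j] * ph$latent_mmthfr +
      tr$beta_interaction[j] * ph$smoking_status * ph$latent_mmthfr +
      tr$beta_male[j] * ph$male + tr$beta_age[j] * (ph$age - mean(ph$age)) +
      drop(W_c %*% unlist(tr[j, paste0("gamma_", cells)]))
    expect_equal(unname(m[cfg$n_mmthfr_probes + j, ]), plogis(eta),
                 tolerance = 1e-12)
  }
})

test_that("locus beta values have the configured mean and beta-law spread", {
  # single interaction-null locus, no covariate effects: mu is constant
  cfg <- generator_config(n_samples = 20000, n_hyper = 0, n_hypo = 0,
                          n_null = 1, n_background = 0,
                          beta_smoking = 0, precision_phi = 50,
                          cell_effect_sd = 0, mmthfr_main_sd = 0,
                          male_effect_sd = 0, age_effect_sd = 0, seed = 21)
  ph <- simulate_phenotypes(cfg)
  meth <- simulate_methylation(cfg, ph)
  mu <- plogis(meth$truth$loci$b0[1])
  y <- as.numeric(as.matrix(meth$betas[-1])[cfg$n_mmthfr_probes + 1, ])
  se <- sqrt(mu * (1 - mu) / (1 + 50)) / sqrt(20000)
  expect_lt(abs(mean(y) - mu), 3 * se)
  expect_true(all(y > 0 & y < 1))
})

test_that("interaction effects obey the difference-in-differences identity", {
  # binary moderator by hand; all nuisance effects off; large n
  cfg <- generator_config(n_samples = 20000, n_hyper = 0, n_hypo = 1,
                          n_null = 0, n_background = 0,
                          beta_smoking = 0, beta_interaction = 0.5,
                          precision_phi = 200, cell_effect_sd = 0,
                          mmthfr_main_sd = 0, male_effect_sd = 0,
                          age_effect_sd = 0, seed = 8)
  ph <- simulate_phenotypes(cfg)
  ph$latent_mmthfr <- rep(c(-1, 1), length.out = nrow(ph))
  meth <- simulate_methylation(cfg, ph)
  bSM <- meth$truth$loci$beta_interaction[1]
  y <- as.numeric(as.matrix(meth$betas[-1])[cfg$n_mmthfr_probes + 1, ])
  gm <- function(s, m) {
    qlogis(mean(y[ph$smoking_status == s & ph$latent_mmthfr == m]))
  }
  did <- (gm(1, 1) - gm(0, 1)) - (gm(1, -1) - gm(0, -1))
  expect_equal(did, 2 * bSM, tolerance = 0.08)
})

test_that("locus classes carry the dominant sign pattern by construction", {
  coh <- simulate_cohort(generator_config(n_samples = 10, seed = 2))
  tr <- coh$truth$loci
  expect_true(all(tr$beta_smoking[tr$class == "hyper"] > 0))
  expect_true(all(tr$beta_interaction[tr$class == "hyper"] < 0))
  expect_true(all(tr$beta_smoking[tr$class == "hypo"] < 0))
  expect_true(all(tr$beta_interaction[tr$class == "hypo"] > 0))
  expect_true(all(tr$beta_interaction[tr$class == "null"] == 0))
  expect_true(all(as.matrix(coh$betas[-1]) > 0 & as.matrix(coh$betas[-1]) < 1))
})
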