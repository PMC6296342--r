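test_that("sample filter drops samples exceeding the failed-probe fraction", {
  set.seed(1)
  nb <- toy_betas(matrix(runif(100 * 3, 0.2, 0.8), 100, 3))
  dp <- toy_betas(matrix(0, 100, 3), probe_ids = nb$probe_id)
  # sample S2: 2 of 100 probes fail at p = 0.2 (2% > 1%) -> removed
  dp$S2[1:2] <- 0.2
  # sample S3: exactly 1% failing -> retained (strict inequality)
  dp$S3[1] <- 0.2
  out <- filter_samples(nb, dp)
  expect_identical(sort(c("S1", "S3")), sort(setdiff(names(out), "probe_id")))
  rep <- qc_report(out)
  expect_identical(rep$removals$id, "S2")
  expect_identical(rep$counts$after[rep$counts$dimension == "samples"], 2L)
  # clean input: nothing removed
  clean <- filter_samples(nb, toy_betas(matrix(0, 100, 3), nb$probe_id))
  expect_identical(names(clean), names(nb))
  expect_error(filter_samples(nb, NULL), "detection p-value")
})

test_that("probe filter applies beadcount and detection rules with >=", {
  set.seed(2)
  nb <- toy_betas(matrix(runif(3 * 20, 0.2, 0.8), 3, 20))
  bc <- toy_betas(matrix(10, 3, 20), nb$probe_id)
  bc[1, 2] <- 2          # beadcount < 3 in 1/20 samples = 5% -> removed
  out <- filter_probes(nb, beadcounts = bc)
  expect_identical(out$probe_id, c("p2", "p3"))
  expect_match(qc_report(out)$removals$reason, "beadcount")

  nb200 <- toy_betas(matrix(runif(2 * 200, 0.2, 0.8), 2, 200))
  dp <- toy_betas(matrix(0, 2, 200), nb200$probe_id)
  dp[1, 2:3] <- 0.06     # 2/200 = 1% -> removed
  dp[2, 2] <- 0.06       # 1/200 = 0.5% -> retained
  out2 <- filter_probes(nb200, detection_p = dp)
  expect_identical(out2$probe_id, "p2")

  # clean matrices remove nothing, and surviving values are untouched
  clean <- filter_probes(nb, beadcounts = toy_betas(matrix(10, 3, 20), nb$probe_id),
                         detection_p = toy_betas(matrix(0, 3, 20), nb$probe_id))
  expect_identical(clean$probe_id, nb$probe_id)
  expect_equal(as.matrix(clean[-1]), as.matrix(nb[-1]))
  expect_error(filter_probes(nb), "neither")
})

test_that("quantile normalization matches the hand-worked reference", {
  nb <- toy_betas(cbind(A = c(0.1, 0.2, 0.3), B = c(0.2, 0.4, 0.6)))
  names(nb) <- c("probe_id", "A", "B")
  out <- quantile_normalize(nb)
  expect_equal(out$A, c(0.15, 0.30, 0.45))
  expect_equal(out$B, c(0.15, 0.30, 0.45))
  # identical columns are a fixed point
  same <- toy_betas(cbind(c(0.2, 0.5, 0.7), c(0.2, 0.5, 0.7)))
  expect_equal(as.matrix(quantile_normalize(same)[-1]), as.matrix(same[-1]))
  # single sample unchanged
  one <- toy_betas(matrix(c(0.3, 0.9, 0.1), 3, 1))
  expect_equal(quantile_normalize(one)$S1, one$S1)
})

test_that("quantile normalization is idempotent and aligns distributions", {
  set.seed(3)
  nb <- toy_betas(matrix(runif(200 * 6), 200, 6))
  once <- quantile_normalize(nb)
  twice <- quantile_normalize(once)
  expect_equal(as.matrix(once[-1]), as.matrix(twice[-1]), tolerance = 1e-12)
  sorted <- apply(as.matrix(once[-1]), 2, sort)
  expect_true(all(abs(sorted - sorted[, 1]) < 1e-12))
  expect_true(all(as.matrix(once[-1]) >= 0 & as.matrix(once[-1]) <= 1))
})

test_that("ties receive the mean of their tied reference values", {
  nb <- toy_betas(cbind(c(0.2, 0.2, 0.8), c(0.1, 0.5, 0.9)))
  out <- quantile_normalize(nb)
  ref <- rowMeans(cbind(sort(nb$S1), sort(nb$S2)))
  expect_equal(out$S1, c(mean(ref[1:2]), mean(ref[1:2]), ref[3]))
})

test_that("stratified normalization works per design type and warns on tiny strata", {
  set.seed(4)
  nb <- toy_betas(matrix(runif(5 * 3), 5, 3))
  ann <- tibble::tibble(probe_id = nb$probe_id,
                        design_type = c("I", "I", "II", "II", "lonely"))
  expect_warning(out <- quantile_normalize(nb, ann), "lonely")
  # the lonely stratum passes through unchanged
  expect_equal(unlist(out[5, -1]), unlist(nb[5, -1]))
  # within the I stratum columns share sorted values
  mI <- as.matrix(out[1:2, -1])
  expect_equal(sort(mI[, 1]), sort(mI[, 2]))
})

test_that("squeeze transform fixes boundaries, midpoint and order", {
  expect_equal(squeeze_unit_interval(0, 100), 0.005)
  expect_equal(squeeze_unit_interval(1, 100), 0.995)
  expect_equal(squeeze_unit_interval(0.5, 17), 0.5)
  y <- c(0, 0.1, 0.5, 0.77, 1)
  z <- squeeze_unit_interval(y, 180)
  expect_true(all(z > 0 & z < 1))
  expect_identical(order(z), order(y))
  expect_error(squeeze_unit_interval(0.5, 0), "n")
  expect_error(squeeze_unit_interval(c(-0.1, 0.5), 10), "0,1")
})
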