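#' Configuration for the synthetic cohort generator
#'
#' Bundles and validates every knob of the simulator. Defaults describe a
#' middle-aged cohort assayed on a 450K-style array: 180 samples; smoking
#' prevalence 0.483; age 48.9 (SD 8.6) years; 37.2% male; a latent moderator
#' (the mMTHFR analogue) correlated 0.412 with male sex; five PBMC cell types
#' with mean fractions (0.137, 0.284, 0.071, 0.165, 0.144) drawn from a
#' Dirichlet with concentration 50; and 300 scanned loci split into 24
#' hyper-methylating, 73 hypo-methylating and 203 interaction-null loci,
#' mirroring the composition of a smoking-associated locus panel in which
#' roughly a third of loci carry a genuine moderation effect.
#'
#' Hyper loci receive a positive smoking main effect and a negative
#' smoking-by-moderator interaction on the logit scale; hypo loci the mirror
#' image; null loci a random-signed main effect and a zero interaction.
#'
#' @param n_samples Number of samples.
#' @param n_hyper,n_hypo,n_null Scanned-locus counts per class.
#' @param n_background Count of additional effect-free background probes.
#'   These emulate the bulk of the array: between-sample normalization is
#'   only meaningful when the systematically exposure-responsive panel is a
#'   small minority of the probes it sees, as on the real platform.
#' @param beta_smoking Logit-scale smoking main-effect magnitude.
#' @param beta_interaction Logit-scale interaction magnitude (applied with
#'   sign opposite to the main effect).
#' @param precision_phi Beta-distribution precision of locus values (> 0).
#' @param smoking_prevalence Bernoulli probability of being a smoker.
#' @param age_mean,age_sd Age distribution in years.
#' @param male_fraction Probability of male sex.
#' @param mmthfr_sex_corr Target correlation between the latent moderator and
#'   the male indicator, in (-1, 1).
#' @param cell_fraction_means Named 5-vector of mean cell fractions,
#'   nonnegative, summing to at most 1.
#' @param cell_concentration Dirichlet concentration of cell fractions (> 0).
#' @param cell_mmthfr_tilt Strength of the moderator-driven tilt of cell
#'   fractions (0 removes cell-composition confounding).
#' @param cell_effect_sd SD of per-locus cell-composition effects on the
#'   logit scale.
#' @param mmthfr_main_sd SD of per-locus moderator main effects.
#' @param male_effect_sd,age_effect_sd SDs of per-locus sex and (per-year)
#'   age effects.
#' @param n_mmthfr_probes Number of probes emitted for the moderator index.
#' @param mmthfr_probe_slope Logit-scale slope of each moderator probe on the
#'   latent moderator.
#' @param mmthfr_probe_phi Beta precision of the moderator probes.
#' @param seed Integer seed; every generator draw derives from it.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(n_samples = 180,
                             n_hyper = 24, n_hypo = 73, n_null = 203,
                             n_background = 2000,
                             beta_smoking = 0.4,
                             beta_interaction = 0.6,
                             precision_phi = 50,
                             smoking_prevalence = 0.483,
                             age_mean = 48.861, age_sd = 8.586,
                             male_fraction = 0.372,
                             mmthfr_sex_corr = 0.412,
                             cell_fraction_means = c(cd8t = 0.137, cd4t = 0.284,
                                                     nk = 0.071, bcell = 0.165,
                                                     mono = 0.144),
                             cell_concentration = 50,
                             cell_mmthfr_tilt = 1,
                             cell_effect_sd = 1,
                             mmthfr_main_sd = 0.1,
                             male_effect_sd = 0.05,
                             age_effect_sd = 0.004,
                             n_mmthfr_probes = 7,
                             mmthfr_probe_slope = 0.4,
                             mmthfr_probe_phi = 300,
                             seed = 1L) {
  cfg <- list(
    n_samples = n_samples, n_hyper = n_hyper, n_hypo = n_hypo, n_null = n_null,
    n_background = n_background,
    beta_smoking = beta_smoking, beta_interaction = beta_interaction,
    precision_phi = precision_phi, smoking_prevalence = smoking_prevalence,
    age_mean = age_mean, age_sd = age_sd, male_fraction = male_fraction,
    mmthfr_sex_corr = mmthfr_sex_corr,
    cell_fraction_means = cell_fraction_means,
    cell_concentration = cell_concentration,
    cell_mmthfr_tilt = cell_mmthfr_tilt, cell_effect_sd = cell_effect_sd,
    mmthfr_main_sd = mmthfr_main_sd, male_effect_sd = male_effect_sd,
    age_effect_sd = age_effect_sd,
    n_mmthfr_probes = n_mmthfr_probes,
    mmthfr_probe_slope = mmthfr_probe_slope,
    mmthfr_probe_phi = mmthfr_probe_phi,
    seed = as.integer(seed)
  )
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  bad <- function(field, why) {
    abort(sprintf("Invalid generator configuration: `%s` %s.", field, why))
  }
  count_fields <- c("n_samples", "n_hyper", "n_hypo", "n_null", "n_background")
  for (f in count_fields) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v != round(v)) {
      bad(f, "must be a nonnegative integer")
    }
  }
  for (f in c("smoking_prevalence", "male_fraction")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      bad(f, "must lie in [0,1]")
    }
  }
  for (f in c("precision_phi", "cell_concentration", "mmthfr_probe_phi")) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || cfg[[f]] <= 0) {
      bad(f, "must be a positive number")
    }
  }
  if (abs(cfg$mmthfr_sex_corr) >= 1) bad("mmthfr_sex_corr", "must lie in (-1,1)")
  if (cfg$age_sd < 0) bad("age_sd", "must be nonnegative")
  cfm <- cfg$cell_fraction_means
  if (length(cfm) != 5 || any(cfm < 0) || sum(cfm) > 1) {
    bad("cell_fraction_means", "must be 5 nonnegative fractions summing to <= 1")
  }
  if (cfg$n_mmthfr_probes < 1) bad("n_mmthfr_probes", "must be at least 1")
  invisible(cfg)
}

cell_type_names <- function(cfg) {
  names(cfg$cell_fraction_means) %||% c("cd8t", "cd4t", "nk", "bcell", "mono")
}

# logit-scale tilt of per-sample Dirichlet means by the latent moderator,
# calibrated (at tilt = 1, concentration 50) so the simulated moderator/cell
# correlations reproduce the observed cohort pattern: about -0.20 (CD8T),
# -0.30 (CD4T), +0.03..0.08 (NK), +0.16..0.18 (B, Mono); the compositional
# constraint keeps the small positive components from going lower
CELL_TILT_DIRECTION <- c(-0.108, -0.113, 0.000, 0.014, 0.020)

#' Simulate a phenotype table
#'
#' Draws smoking status, average consumption, sex, age, diet, a latent
#' moderator, and Dirichlet cell fractions whose per-sample means are tilted
#' by the moderator (so that cell composition genuinely confounds
#' moderator-adjusted analyses). Consumption is a noisy monotone function of
#' smoking status, truncated into \[0, 6\].
#'
#' @param config A [generator_config()].
#' @return A tibble with columns `sample_id`, `smoking_status`, `consumption`,
#'   `male`, `age`, `diet`, `latent_mmthfr`, and one column per cell type.
#' @export
simulate_phenotypes <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_samples
  cells <- cell_type_names(config)
  if (n == 0L) {
    out <- tibble(sample_id = character(), smoking_status = integer(),
                  consumption = numeric(), male = integer(), age = numeric(),
                  diet = integer(), latent_mmthfr = numeric())
    for (ct in cells) out[[ct]] <- numeric()
    return(out)
  }
  set.seed(config$seed)
  smoking <- rbinom(n, 1L, config$smoking_prevalence)
  age <- rnorm(n, config$age_mean, config$age_sd)
  male <- rbinom(n, 1L, config$male_fraction)
  diet <- sample.int(4L, n, replace = TRUE)
  consumption <- pmin(6, pmax(0, ifelse(
    smoking == 1L, rnorm(n, 2.7, 1.2), abs(rnorm(n, 0.1, 0.25)))))
  p <- config$male_fraction
  male_c <- if (p > 0 && p < 1) (male - p) / sqrt(p * (1 - p)) else rep(0, n)
  r <- config$mmthfr_sex_corr
  latent <- r * male_c + sqrt(1 - r^2) * rnorm(n)

  base <- c(config$cell_fraction_means, other = 1 - sum(config$cell_fraction_means))
  tilt <- config$cell_mmthfr_tilt * c(CELL_TILT_DIRECTION, 0)
  frac <- matrix(0, n, length(base))
  for (i in seq_len(n)) {
    m_i <- exp(log(pmax(base, 1e-8)) + tilt * latent[i])
    m_i <- m_i / sum(m_i)
    g <- rgamma(length(base), shape = config$cell_concentration * m_i)
    frac[i, ] <- g / sum(g)
  }
  out <- tibble(
    sample_id = sprintf("S%03d", seq_len(n)),
    smoking_status = smoking,
    consumption = consumption,
    male = male,
    age = age,
    diet = diet,
    latent_mmthfr = latent
  )
  for (j in seq_along(cells)) out[[cells[j]]] <- frac[, j]
  out
}

#' Simulate a cell-type reference panel
#'
#' Generates a probe-by-cell-type matrix of reference beta values with
#' distinct, discriminating column profiles (each entry uniform on
#' (0.05, 0.95)).
#'
#' @param n_probes Number of reference probes (>= 1).
#' @param n_celltypes Number of cell types (>= 1).
#' @param seed Integer seed.
#' @return A tibble with `probe_id` and one column per cell type; the default
#'   five types are named `cd8t`, `cd4t`, `nk`, `bcell`, `mono`.
#' @export
simulate_cell_reference <- function(n_probes = 100, n_celltypes = 5, seed = 1L) {
  if (n_celltypes < 1) abort("`n_celltypes` must be at least 1.")
  if (n_probes < 1) abort("`n_probes` must be at least 1.")
  set.seed(as.integer(seed))
  m <- matrix(runif(n_probes * n_celltypes, 0.05, 0.95), n_probes, n_celltypes)
  labels <- if (n_celltypes == 5) {
    c("cd8t", "cd4t", "nk", "bcell", "mono")
  } else {
    sprintf("celltype_%d", seq_len(n_celltypes))
  }
  colnames(m) <- labels
  dplyr::bind_cols(tibble(probe_id = sprintf("ref_%04d", seq_len(n_probes))),
                   as_tibble(m))
}

#' Simulate locus methylation with known ground truth
#'
#' For each locus the logit-scale linear predictor is
#' `b0 + bS*S + bM*M + bSM*S*M + b_male*male + b_age*(age - mean) +
#' gamma' (w - mean(w))`, with `S` smoking status, `M` the latent moderator
#' and `w` the cell fractions; the emitted value is Beta(mu*phi, (1-mu)*phi)
#' with `mu` the inverse logit. Moderator probes are noisy monotone (logit
#' linear) transforms of `M`. With `noise = FALSE` the expected value `mu` is
#' emitted exactly.
#'
#' @param config A [generator_config()].
#' @param pheno A phenotype tibble from [simulate_phenotypes()] (must carry
#'   `latent_mmthfr` and the cell-fraction columns).
#' @param noise Draw Beta noise (`TRUE`, default) or emit the mean exactly.
#' @return A list with `betas` (tibble: `probe_id` + samples, moderator
#'   probes first) and `truth` (list: `loci` coefficient tibble with one row
#'   per generated locus, `latent` per-sample moderator tibble).
#' @export
simulate_methylation <- function(config, pheno, noise = TRUE) {
  stopifnot(inherits(config, "generator_config"))
  if (config$precision_phi <= 0) abort("`precision_phi` must be positive.")
  needed <- c("sample_id", "smoking_status", "age", "male", "latent_mmthfr",
              cell_type_names(config))
  if (!all(needed %in% names(pheno))) {
    abort(sprintf("`pheno` lacks required columns: %s.",
                  paste(setdiff(needed, names(pheno)), collapse = ", ")))
  }
  if (nrow(pheno) != config$n_samples) {
    abort("`pheno` does not match `config$n_samples`.")
  }
  set.seed(config$seed + 1L)
  n <- nrow(pheno)
  cells <- cell_type_names(config)
  classes <- rep(c("hyper", "hypo", "null"),
                 c(config$n_hyper, config$n_hypo, config$n_null))
  J <- length(classes)
  jit <- function(m) runif(m, 0.7, 1.3)
  b0 <- logit(runif(J, 0.2, 0.8))
  bS <- numeric(J); bSM <- numeric(J)
  bS[classes == "hyper"] <- config$beta_smoking * jit(sum(classes == "hyper"))
  bSM[classes == "hyper"] <- -config$beta_interaction * jit(sum(classes == "hyper"))
  bS[classes == "hypo"] <- -config$beta_smoking * jit(sum(classes == "hypo"))
  bSM[classes == "hypo"] <- config$beta_interaction * jit(sum(classes == "hypo"))
  nn <- sum(classes == "null")
  bS[classes == "null"] <- sample(c(-1, 1), nn, replace = TRUE) *
    config$beta_smoking * jit(nn)
  bM <- rnorm(J, 0, config$mmthfr_main_sd)
  b_male <- rnorm(J, 0, config$male_effect_sd)
  b_age <- rnorm(J, 0, config$age_effect_sd)
  gamma <- matrix(rnorm(J * length(cells), 0, config$cell_effect_sd), J)
  colnames(gamma) <- cells

  S <- pheno$smoking_status
  M <- pheno$latent_mmthfr
  age_c <- pheno$age - mean(pheno$age)
  W <- as.matrix(pheno[cells])
  W_c <- sweep(W, 2, colMeans(W))

  locus_ids <- sprintf("locus_%s_%04d", classes, seq_len(J))
  eta <- outer(b0, rep(1, n)) + outer(bS, S) + outer(bM, M) +
    outer(bSM, S * M) + outer(b_male, pheno$male) + outer(b_age, age_c) +
    gamma %*% t(W_c)
  mu <- inv_logit(eta)
  phi <- config$precision_phi
  vals <- if (noise) {
    matrix(rbeta(J * n, mu * phi, (1 - mu) * phi), J, n)
  } else {
    mu
  }

  # moderator probes: logit-linear in the latent moderator
  K <- config$n_mmthfr_probes
  a_k <- logit(runif(K, 0.3, 0.5))
  eta_m <- outer(a_k, rep(1, n)) + config$mmthfr_probe_slope * outer(rep(1, K), M)
  mu_m <- inv_logit(eta_m)
  pphi <- config$mmthfr_probe_phi
  vals_m <- if (noise) {
    matrix(rbeta(K * n, mu_m * pphi, (1 - mu_m) * pphi), K, n)
  } else {
    mu_m
  }
  mm_ids <- sprintf("mmthfr_%02d", seq_len(K))

  # effect-free background probes (constant mean per probe)
  B <- config$n_background
  if (B > 0) {
    b0_bg <- logit(runif(B, 0.1, 0.9))
    mu_bg <- inv_logit(outer(b0_bg, rep(1, n)))
    vals_bg <- if (noise) {
      matrix(rbeta(B * n, mu_bg * phi, (1 - mu_bg) * phi), B, n)
    } else {
      mu_bg
    }
    bg_ids <- sprintf("bg_%05d", seq_len(B))
  } else {
    vals_bg <- matrix(numeric(), 0, n)
    bg_ids <- character()
  }

  m_all <- rbind(vals_m, vals, vals_bg)
  colnames(m_all) <- pheno$sample_id
  betas <- dplyr::bind_cols(tibble(probe_id = c(mm_ids, locus_ids, bg_ids)),
                            as_tibble(m_all))
  loci <- tibble(
    probe_id = locus_ids, class = classes, b0 = b0,
    beta_smoking = bS, beta_mmthfr = bM, beta_interaction = bSM,
    beta_male = b_male, beta_age = b_age
  )
  for (ct in cells) loci[[paste0("gamma_", ct)]] <- gamma[, ct]
  list(
    betas = betas,
    truth = list(
      loci = loci,
      latent = tibble(sample_id = pheno$sample_id, latent_mmthfr = M)
    )
  )
}

#' Simulate a complete synthetic cohort
#'
#' Convenience wrapper chaining [simulate_phenotypes()],
#' [simulate_cell_reference()] and [simulate_methylation()], and adding clean
#' detection p-value and beadcount matrices plus a probe annotation with
#' random design-type strata.
#'
#' @param config A [generator_config()].
#' @param noise Passed to [simulate_methylation()].
#' @return A list: `betas`, `detection_p`, `beadcounts`, `phenotypes`,
#'   `annotation`, `reference`, `truth`, `locus_list` (scanned locus ids),
#'   `mmthfr_probes` (moderator probe ids), `config`.
#' @export
simulate_cohort <- function(config = generator_config(), noise = TRUE) {
  pheno <- simulate_phenotypes(config)
  meth <- simulate_methylation(config, pheno, noise = noise)
  reference <- simulate_cell_reference(n_probes = 100,
                                       n_celltypes = length(cell_type_names(config)),
                                       seed = config$seed + 2L)
  set.seed(config$seed + 3L)
  nP <- nrow(meth$betas); nS <- config$n_samples
  dp <- matrix(runif(nP * nS, 0, 0.01), nP, nS,
               dimnames = list(NULL, pheno$sample_id))
  bc <- matrix(3L + rpois(nP * nS, 11), nP, nS,
               dimnames = list(NULL, pheno$sample_id))
  annotation <- tibble(
    probe_id = meth$betas$probe_id,
    gene = ifelse(grepl("^mmthfr", meth$betas$probe_id), "MTHFR", ""),
    design_type = sample(c("I", "II"), nP, replace = TRUE, prob = c(0.3, 0.7))
  )
  list(
    betas = meth$betas,
    detection_p = dplyr::bind_cols(tibble(probe_id = meth$betas$probe_id), as_tibble(dp)),
    beadcounts = dplyr::bind_cols(tibble(probe_id = meth$betas$probe_id), as_tibble(bc)),
    phenotypes = pheno,
    annotation = annotation,
    reference = reference,
    truth = meth$truth,
    locus_list = meth$truth$loci$probe_id,
    mmthfr_probes = grep("^mmthfr_", meth$betas$probe_id, value = TRUE),
    config = config
  )
}
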