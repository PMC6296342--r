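#' Fit the two per-locus moderation models at one locus
#'
#' Model 1 regresses a locus's beta values on smoking, the moderator index,
#' sex and age by beta regression; Model 2 adds the smoking-by-moderator
#' interaction. The locus's direction class (hyper/hypo) is the sign of the
#' Model 1 smoking coefficient; the interaction sign comes from Model 2.
#'
#' @param y Locus beta values, strictly inside (0,1) (see
#'   [squeeze_unit_interval()]).
#' @param pheno Phenotype tibble with columns `mmthfr`, `male`, `age` and the
#'   smoking measure (`smoking_status` or `consumption`).
#' @param smoking_measure `"status"` (binary) or `"consumption"` (0-6 scale).
#' @param probe_id Identifier recorded in the result.
#' @return A one-row tibble: Model 1/Model 2 coefficients and p-values for
#'   smoking and moderator terms, interaction estimate/p, `direction`
#'   (`"hyper"`/`"hypo"`), `sign` (`"+"`/`"-"`, `NA` unless Model 2
#'   converged), and convergence flags. Non-convergence is flagged, never
#'   thrown.
#' @export
fit_locus_pair <- function(y, pheno, smoking_measure = c("status", "consumption"),
                           probe_id = "locus") {
  smoking_measure <- match.arg(smoking_measure)
  smo_col <- if (smoking_measure == "status") "smoking_status" else "consumption"
  needed <- c(smo_col, "mmthfr", "male", "age")
  if (!all(needed %in% names(pheno))) {
    abort(sprintf("`pheno` lacks required columns: %s.",
                  paste(setdiff(needed, names(pheno)), collapse = ", ")))
  }
  ok <- complete.cases(pheno[needed]) & is.finite(y)
  y <- y[ok]
  ph <- pheno[ok, , drop = FALSE]
  X1 <- cbind(constant = 1, smoking = ph[[smo_col]], mmthfr = ph$mmthfr,
              male = ph$male, age = ph$age)
  X2 <- cbind(X1, `smoking:mmthfr` = ph[[smo_col]] * ph$mmthfr)
  safe_fit <- function(X) {
    tryCatch(fit_betareg(y, X), error = function(e) NULL)
  }
  f1 <- safe_fit(X1)
  f2 <- safe_fit(X2)
  c1 <- !is.null(f1) && isTRUE(f1$converged)
  c2 <- !is.null(f2) && isTRUE(f2$converged)
  g <- function(fit, term, what) {
    if (is.null(fit)) return(NA_real_)
    unname(fit[[what]][[match(term, fit$terms)]])
  }
  int_b <- if (c2) g(f2, "smoking:mmthfr", "coefficients") else NA_real_
  tibble(
    probe_id = probe_id,
    model1_smo_b = if (c1) g(f1, "smoking", "coefficients") else NA_real_,
    model1_smo_p = if (c1) g(f1, "smoking", "p") else NA_real_,
    model1_mmthfr_b = if (c1) g(f1, "mmthfr", "coefficients") else NA_real_,
    model1_mmthfr_p = if (c1) g(f1, "mmthfr", "p") else NA_real_,
    model2_smo_b = if (c2) g(f2, "smoking", "coefficients") else NA_real_,
    model2_smo_p = if (c2) g(f2, "smoking", "p") else NA_real_,
    model2_mmthfr_b = if (c2) g(f2, "mmthfr", "coefficients") else NA_real_,
    model2_mmthfr_p = if (c2) g(f2, "mmthfr", "p") else NA_real_,
    int_b = int_b,
    int_p = if (c2) g(f2, "smoking:mmthfr", "p") else NA_real_,
    direction = if (c1) {
      if (g(f1, "smoking", "coefficients") > 0) "hyper" else "hypo"
    } else NA_character_,
    sign = if (c2 && !is.na(int_b)) (if (int_b > 0) "+" else "-") else NA_character_,
    model1_converged = c1,
    model2_converged = c2
  )
}

#' Scan a locus panel for smoking-by-moderator interactions
#'
#' Runs [fit_locus_pair()] at every locus of the panel (in input order) and
#' appends Bonferroni- and Benjamini-Hochberg-adjusted interaction p-values.
#' The Bonferroni denominator is the number of loci scanned.
#'
#' @param betas Beta tibble (`probe_id` + samples), values strictly in (0,1).
#' @param pheno Phenotype tibble with one row per sample column of `betas`,
#'   in the same order, carrying `mmthfr`, `male`, `age` and the smoking
#'   measure.
#' @param locus_list Probe identifiers to scan; must all be present in
#'   `betas`. `NULL` scans every probe.
#' @inheritParams fit_locus_pair
#' @param alpha Nominal significance level recorded on the result.
#' @return An `ewas_scan` tibble with one row per locus (see
#'   [fit_locus_pair()]), plus `int_p_bonf` and `int_p_bh`.
#' @export
scan_loci <- function(betas, pheno, locus_list = NULL,
                      smoking_measure = c("status", "consumption"),
                      alpha = 0.05) {
  smoking_measure <- match.arg(smoking_measure)
  assert_beta_tbl(betas)
  locus_list <- locus_list %||% betas$probe_id
  missing <- setdiff(locus_list, betas$probe_id)
  if (length(missing)) {
    abort(sprintf("locus_list contains %d probes absent from `betas` (e.g. %s).",
                  length(missing), missing[1]))
  }
  samples <- sample_cols(betas)
  if (nrow(pheno) != length(samples)) {
    abort("`pheno` must have one row per sample column of `betas`.")
  }
  m <- beta_values(betas)[locus_list, , drop = FALSE]
  records <- purrr::map_dfr(seq_along(locus_list), function(j) {
    fit_locus_pair(m[j, ], pheno, smoking_measure, probe_id = locus_list[j])
  })
  if (nrow(records)) {
    records$int_p_bonf <- ifelse(is.na(records$int_p), NA_real_,
                                 pmin(1, nrow(records) * records$int_p))
    ok <- !is.na(records$int_p)
    bh <- rep(NA_real_, nrow(records))
    if (any(ok)) bh[ok] <- adjust_pvalues(records$int_p[ok], "bh")
    records$int_p_bh <- bh
  } else {
    records$int_p_bonf <- numeric()
    records$int_p_bh <- numeric()
  }
  structure(records, class = c("ewas_scan", class(records)),
            alpha = alpha, smoking_measure = smoking_measure)
}

#' Multiple-testing adjustment of p-values
#'
#' Bonferroni (`min(1, m * p)`) or Benjamini-Hochberg step-up adjusted
#' values.
#'
#' @param p Vector of p-values in \[0,1\].
#' @param method `"bonferroni"` or `"bh"`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "bh")) {
  method <- match.arg(method)
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    abort("All p-values must lie in [0,1].")
  }
  m <- length(p)
  if (m == 0L) return(numeric())
  if (method == "bonferroni") {
    pmin(1, m * p)
  } else {
    o <- order(p, decreasing = TRUE)
    adj <- pmin(1, cummin(m / (m:1) * p[o]))
    adj[order(o)]
  }
}

#' Classify significant interactions by direction and sign
#'
#' Keeps loci whose interaction p-value at the chosen tier falls below
#' `alpha` and both models converged, and cross-classifies them by direction
#' class (hyper/hypo, from the Model 1 smoking coefficient) and interaction
#' sign.
#'
#' @param scan An [scan_loci()] result.
#' @param alpha Significance level.
#' @param tier `"nominal"`, `"bonferroni"` or `"bh"` interaction p-value.
#' @return An `interaction_classification` tibble (`probe_id`, `direction`,
#'   `sign`, `int_b`, interaction p columns) with attributes `counts` (named
#'   vector hyper_pos/hyper_neg/hypo_pos/hypo_neg), `n_scanned`,
#'   `n_excluded`, `alpha`, `tier`.
#' @export
classify_interactions <- function(scan, alpha = 0.05,
                                  tier = c("nominal", "bonferroni", "bh")) {
  tier <- match.arg(tier)
  pcol <- switch(tier, nominal = "int_p", bonferroni = "int_p_bonf",
                 bh = "int_p_bh")
  keep <- !is.na(scan[[pcol]]) & scan[[pcol]] < alpha &
    scan$model1_converged & scan$model2_converged &
    !is.na(scan$direction) & !is.na(scan$sign)
  cls <- as_tibble(scan)[keep, c("probe_id", "direction", "sign",
                                 "int_b", "int_p", "int_p_bonf", "int_p_bh")]
  counts <- c(
    hyper_pos = sum(cls$direction == "hyper" & cls$sign == "+"),
    hyper_neg = sum(cls$direction == "hyper" & cls$sign == "-"),
    hypo_pos = sum(cls$direction == "hypo" & cls$sign == "+"),
    hypo_neg = sum(cls$direction == "hypo" & cls$sign == "-")
  )
  structure(cls, class = c("interaction_classification", class(cls)),
            counts = counts, n_scanned = nrow(scan),
            n_excluded = nrow(scan) - nrow(cls), alpha = alpha, tier = tier)
}
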