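#' Remove samples with too many failed detection p-values
#'
#' A sample is dropped when the fraction of its probes with detection
#' p-value above `p_threshold` strictly exceeds `max_failed_fraction`
#' (default: more than 1% of probes failing at p > 0.05).
#'
#' @param betas Beta-value tibble: `probe_id` plus one column per sample.
#' @param detection_p Detection p-value tibble with the same layout.
#' @param p_threshold Per-probe detection p-value above which a probe counts
#'   as failed in that sample.
#' @param max_failed_fraction Largest tolerated failed-probe fraction.
#' @return The filtered beta tibble with a `qc_report` attribute (see
#'   [qc_report()]).
#' @export
filter_samples <- function(betas, detection_p, p_threshold = 0.05,
                           max_failed_fraction = 0.01) {
  assert_beta_tbl(betas)
  if (is.null(detection_p)) {
    abort("Sample filtering needs a detection p-value matrix; none supplied.")
  }
  assert_beta_tbl(detection_p, "detection_p")
  samples <- sample_cols(betas)
  if (!setequal(samples, sample_cols(detection_p))) {
    abort("`betas` and `detection_p` must cover the same samples.")
  }
  dp <- beta_values(detection_p)[betas$probe_id, samples, drop = FALSE]
  frac_failed <- colMeans(dp > p_threshold)
  drop <- names(frac_failed)[frac_failed > max_failed_fraction]
  out <- betas[c("probe_id", setdiff(samples, drop))]
  report <- tibble(
    entity = rep("sample", length(drop)),
    id = drop,
    reason = sprintf("detection p > %g in %.2f%% of probes (limit %g%%)",
                     p_threshold, 100 * frac_failed[drop],
                     100 * max_failed_fraction)
  )
  attr(out, "qc_report") <- new_qc_report(report,
    n_samples_in = length(samples), n_samples_out = length(samples) - length(drop),
    n_probes_in = nrow(betas), n_probes_out = nrow(betas))
  out
}

#' Remove unreliable probes by beadcount and detection p-value
#'
#' A probe is dropped when its beadcount is below `beadcount_min` in at least
#' `beadcount_fail_fraction` of samples, or its detection p-value exceeds
#' `p_threshold` in at least `p_fail_fraction` of samples. Either auxiliary
#' matrix may be omitted, in which case the corresponding sub-filter is
#' skipped; omitting both is an error.
#'
#' @inheritParams filter_samples
#' @param beadcounts Beadcount tibble (`probe_id` + samples), or `NULL`.
#' @param detection_p Detection p-value tibble, or `NULL`.
#' @param beadcount_min Minimum acceptable beadcount.
#' @param beadcount_fail_fraction Fraction of samples at which low beadcount
#'   removes the probe (inclusive).
#' @param p_fail_fraction Fraction of samples at which detection failure
#'   removes the probe (inclusive).
#' @return The filtered beta tibble with a `qc_report` attribute.
#' @export
filter_probes <- function(betas, beadcounts = NULL, detection_p = NULL,
                          beadcount_min = 3, beadcount_fail_fraction = 0.05,
                          p_threshold = 0.05, p_fail_fraction = 0.01) {
  assert_beta_tbl(betas)
  if (is.null(beadcounts) && is.null(detection_p)) {
    abort("Probe filtering needs beadcounts and/or detection p-values; neither supplied.")
  }
  samples <- sample_cols(betas)
  reasons <- character(0)
  ids <- character(0)
  if (!is.null(beadcounts)) {
    assert_beta_tbl(beadcounts, "beadcounts")
    bc <- beta_values(beadcounts)[betas$probe_id, samples, drop = FALSE]
    frac <- rowMeans(bc < beadcount_min)
    bad <- frac >= beadcount_fail_fraction
    ids <- c(ids, betas$probe_id[bad])
    reasons <- c(reasons, sprintf(
      "beadcount < %g in %.2f%% of samples (limit %g%%)",
      beadcount_min, 100 * frac[bad], 100 * beadcount_fail_fraction))
  }
  if (!is.null(detection_p)) {
    assert_beta_tbl(detection_p, "detection_p")
    dp <- beta_values(detection_p)[betas$probe_id, samples, drop = FALSE]
    frac <- rowMeans(dp > p_threshold)
    bad <- frac >= p_fail_fraction
    ids <- c(ids, betas$probe_id[bad])
    reasons <- c(reasons, sprintf(
      "detection p > %g in %.2f%% of samples (limit %g%%)",
      p_threshold, 100 * frac[bad], 100 * p_fail_fraction))
  }
  keep <- !duplicated(ids)
  report <- tibble(entity = rep("probe", sum(keep)),
                   id = ids[keep], reason = reasons[keep])
  out <- betas[!betas$probe_id %in% ids, , drop = FALSE]
  attr(out, "qc_report") <- new_qc_report(report,
    n_samples_in = length(samples), n_samples_out = length(samples),
    n_probes_in = nrow(betas), n_probes_out = nrow(out))
  out
}

new_qc_report <- function(removals, n_samples_in, n_samples_out,
                          n_probes_in, n_probes_out) {
  structure(list(
    removals = removals,
    counts = tibble(
      dimension = c("samples", "probes"),
      before = c(n_samples_in, n_probes_in),
      after = c(n_samples_out, n_probes_out)
    )
  ), class = "qc_report")
}

#' Retrieve the QC report attached by a filtering step
#'
#' @param x A beta tibble returned by [filter_samples()] or [filter_probes()].
#' @return A `qc_report`: list with `removals` (entity, id, reason) and
#'   `counts` (before/after per dimension), or `NULL` if none is attached.
#' @export
qc_report <- function(x) attr(x, "qc_report")

#' @export
print.qc_report <- function(x, ...) {
  print(x$counts)
  if (nrow(x$removals)) print(x$removals) else cat("No removals.\n")
  invisible(x)
}

#' Between-sample quantile normalization of beta values
#'
#' Forces every sample (column) to share the same empirical distribution: the
#' across-sample mean of order statistics, assigned back by within-sample
#' rank. Ties receive the mean of their tied reference quantiles. When a
#' probe annotation with a `design_type` column is supplied, normalization is
#' carried out separately within each design-type stratum, in the spirit of
#' Type I/II-aware normalization of 450K data.
#'
#' @param betas Beta-value tibble (`probe_id` + samples), no missing values.
#' @param annotation Optional tibble with `probe_id` and `design_type`;
#'   `NULL` treats all probes as one stratum.
#' @return A beta tibble of the same shape, probes in the input order.
#' @export
quantile_normalize <- function(betas, annotation = NULL) {
  assert_beta_tbl(betas)
  m <- beta_values(betas)
  if (anyNA(m)) abort("Quantile normalization requires complete values.")
  if (is.null(annotation)) {
    strata <- rep("all", nrow(m))
  } else {
    if (!all(c("probe_id", "design_type") %in% names(annotation))) {
      abort("`annotation` must have columns probe_id and design_type.")
    }
    strata <- annotation$design_type[match(betas$probe_id, annotation$probe_id)]
    strata[is.na(strata)] <- "unannotated"
  }
  for (s in unique(strata)) {
    idx <- which(strata == s)
    if (length(idx) < 2L) {
      warn(sprintf("Stratum '%s' has fewer than 2 probes; passed through unchanged.", s))
      next
    }
    m[idx, ] <- qn_stratum(m[idx, , drop = FALSE])
  }
  out <- matrix_to_beta_tbl(m)
  out$probe_id <- betas$probe_id
  out
}

qn_stratum <- function(m) {
  if (ncol(m) < 2L) return(m)
  ref <- rowMeans(apply(m, 2, sort, method = "radix"))
  apply(m, 2, function(col) {
    v <- ref[rank(col, ties.method = "first")]
    # ties share the mean of their tied reference quantiles
    stats::ave(v, factor(col), FUN = mean)
  })
}

#' Squeeze unit-interval values off the boundary
#'
#' Applies the compression `(y * (n - 1) + 0.5) / n` so that exact 0s and 1s
#' move strictly inside (0,1), as the beta likelihood requires. The transform
#' is order-preserving and fixes the midpoint 0.5.
#'
#' @param y Numeric vector in \[0,1\].
#' @param n Effective count (conventionally the number of samples); must be
#'   at least 1.
#' @return The squeezed vector, strictly inside (0,1) whenever `n > 1`.
#' @export
squeeze_unit_interval <- function(y, n) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    abort("`n` must be a single number >= 1.")
  }
  if (any(y < 0 | y > 1, na.rm = TRUE)) abort("`y` must lie in [0,1].")
  (y * (n - 1) + 0.5) / n
}
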