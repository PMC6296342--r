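#' Standardize a probe's values across samples
#'
#' Centers and scales to sample mean 0 and standard deviation 1 (n - 1
#' denominator).
#'
#' @param x Numeric vector of per-sample values (length >= 2, nonzero
#'   variance).
#' @param probe Optional probe identifier used in error messages.
#' @return The z-scored vector.
#' @export
zscore <- function(x, probe = NULL) {
  lbl <- if (is.null(probe)) "input" else sprintf("probe '%s'", probe)
  if (length(x) < 2L) abort(sprintf("Cannot z-score %s: fewer than 2 values.", lbl))
  s <- sd(x)
  if (!is.finite(s) || s == 0) {
    abort(sprintf("Cannot z-score %s: zero variance.", lbl))
  }
  (x - mean(x)) / s
}

#' Build a composite methylation index
#'
#' The per-sample mean of per-probe z-scores over the probes of the
#' definition, computed on the full sample. This is how a composite moderator
#' index (e.g. a 7-probe promoter-methylation index) or an outcome index is
#' constructed.
#'
#' @param betas Beta tibble (`probe_id` + samples).
#' @param probes Character vector of probe ids making up the index (non-empty;
#'   all present in `betas`).
#' @param name Column name for the index values.
#' @return A tibble with `sample_id` and the index column, one row per
#'   sample.
#' @export
build_index <- function(betas, probes, name = "index") {
  assert_beta_tbl(betas)
  probes <- unique(probes)
  if (length(probes) == 0L) abort("Index definition has no probes.")
  missing <- setdiff(probes, betas$probe_id)
  if (length(missing)) {
    abort(sprintf("Index probes missing from `betas`: %s.",
                  paste(missing, collapse = ", ")))
  }
  m <- beta_values(betas)[probes, , drop = FALSE]
  z <- t(apply(m, 1, zscore))
  if (length(probes) == 1L) z <- matrix(zscore(m[1, ]), nrow = 1)
  out <- tibble(sample_id = colnames(m))
  out[[name]] <- unname(colMeans(z))
  out
}

#' Build one sign-concordant outcome index
#'
#' The hypo-methylation index averages standardized values over
#' hypo-direction loci with a positive interaction sign; the hyper index over
#' hyper-direction loci with a negative sign.
#'
#' @param betas Beta tibble.
#' @param classification An [classify_interactions()] result.
#' @param which `"hypo"` or `"hyper"`.
#' @return A tibble (`sample_id`, index column named `hypo_index` or
#'   `hyper_index`) with attribute `probes` (the definition). Errors if the
#'   sign-concordant class is empty.
#' @export
build_outcome_index <- function(betas, classification, which = c("hypo", "hyper")) {
  which <- match.arg(which)
  want_sign <- if (which == "hypo") "+" else "-"
  probes <- classification$probe_id[classification$direction == which &
                                      classification$sign == want_sign]
  if (length(probes) == 0L) {
    abort(sprintf(
      "No %s-direction loci with %s interaction sign; cannot build the %s index.",
      which, if (want_sign == "+") "positive" else "negative", which))
  }
  out <- build_index(betas, probes, name = paste0(which, "_index"))
  attr(out, "probes") <- probes
  out
}

#' Build both outcome indices from a classification
#'
#' Convenience wrapper over [build_outcome_index()]. An index whose
#' sign-concordant class is empty is returned as `NULL` with a warning; the
#' other index is still built.
#'
#' @inheritParams build_outcome_index
#' @return A list with `hypo`, `hyper` (tibbles or `NULL`) and `definitions`
#'   (list of probe vectors).
#' @export
build_outcome_indices <- function(betas, classification) {
  grab <- function(which) {
    tryCatch(build_outcome_index(betas, classification, which),
             error = function(e) {
               warn(conditionMessage(e))
               NULL
             })
  }
  hypo <- grab("hypo")
  hyper <- grab("hyper")
  list(
    hypo = hypo,
    hyper = hyper,
    definitions = list(
      hypo = if (is.null(hypo)) character() else attr(hypo, "probes"),
      hyper = if (is.null(hyper)) character() else attr(hyper, "probes")
    )
  )
}
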