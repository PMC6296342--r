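#' Construct a direction-by-sign contingency table
#'
#' @param hyper_pos,hyper_neg,hypo_pos,hypo_neg Nonnegative integer counts of
#'   loci by direction class (rows) and interaction sign (columns).
#' @return A `contingency_2x2` object: the 2x2 count matrix (rows hyper/hypo,
#'   columns positive/negative) with row, column and grand totals available
#'   via [tidy()].
#' @export
contingency_table <- function(hyper_pos, hyper_neg, hypo_pos, hypo_neg) {
  counts <- c(hyper_pos, hyper_neg, hypo_pos, hypo_neg)
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts))) {
    abort("Contingency counts must be nonnegative integers.")
  }
  m <- matrix(counts, nrow = 2, byrow = TRUE,
              dimnames = list(direction = c("hyper", "hypo"),
                              sign = c("positive", "negative")))
  structure(m, class = "contingency_2x2")
}

#' Contingency table of an interaction classification
#'
#' @param classification An [classify_interactions()] result.
#' @return A [contingency_table()] of its counts.
#' @export
contingency_from_classification <- function(classification) {
  ct <- attr(classification, "counts")
  if (is.null(ct)) abort("`classification` carries no counts attribute.")
  contingency_table(ct[["hyper_pos"]], ct[["hyper_neg"]],
                    ct[["hypo_pos"]], ct[["hypo_neg"]])
}

#' Pearson chi-square test of sign consistency
#'
#' The uncorrected Pearson statistic `sum((O - E)^2 / E)` on the 2x2
#' direction-by-sign table, with expected counts from the row and column
#' margins and no continuity correction. The upper-tail p-value is evaluated
#' in log space, so values far below 1e-300 remain representable through the
#' `log10_p` column.
#'
#' @param table A `contingency_2x2` (see [contingency_table()]).
#' @return A one-row tibble: `statistic`, `df` (= 1), `p_value`, `log10_p`.
#' @export
pearson_chi2 <- function(table) {
  stopifnot(inherits(table, "contingency_2x2"))
  O <- unclass(table)
  n <- sum(O)
  if (n <= 0) abort("Contingency table is empty.")
  E <- outer(rowSums(O), colSums(O)) / n
  if (any(E == 0)) abort("A margin of the contingency table is zero.")
  stat <- sum((O - E)^2 / E)
  log_p <- pchisq(stat, df = 1, lower.tail = FALSE, log.p = TRUE)
  tibble(statistic = stat, df = 1L,
         p_value = exp(log_p), log10_p = log_p / log(10))
}

#' Row-wise sign percentages of a contingency table
#'
#' @param table A `contingency_2x2`.
#' @return A tibble with `direction`, `positive_pct`, `negative_pct`
#'   (percentages to one decimal place; `NA` with a warning for a zero row
#'   total).
#' @export
row_proportions <- function(table) {
  stopifnot(inherits(table, "contingency_2x2"))
  O <- unclass(table)
  tot <- rowSums(O)
  if (any(tot == 0)) {
    warn(sprintf("Row total is zero for: %s; proportions undefined.",
                 paste(rownames(O)[tot == 0], collapse = ", ")))
  }
  pct <- sweep(O, 1, tot, "/") * 100
  pct[tot == 0, ] <- NA_real_
  tibble(direction = rownames(O),
         positive_pct = unname(round(pct[, "positive"], 1)),
         negative_pct = unname(round(pct[, "negative"], 1)))
}

#' @export
#' @method tidy contingency_2x2
tidy.contingency_2x2 <- function(x, ...) {
  O <- unclass(x)
  tibble(
    direction = rep(rownames(O), each = 2),
    sign = rep(colnames(O), 2),
    count = as.integer(t(O))
  )
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  O <- unclass(x)
  out <- cbind(O, total = rowSums(O))
  out <- rbind(out, total = colSums(out))
  print(out)
  invisible(x)
}
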