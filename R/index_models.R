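#' Ordinary least squares with classical inference
#'
#' QR-based least squares with classical standard errors, t statistics,
#' two-sided t-distribution p-values and R-squared.
#'
#' @param y Outcome vector.
#' @param X Design matrix (including the intercept column), full column rank,
#'   more rows than columns.
#' @param term_names Optional term labels; defaults to `colnames(X)`.
#' @return An `ols_fit` object: `coefficients`, `se`, `t`, `p`, `vcov`,
#'   `r_squared`, `sigma`, `df_residual`, `n`, `terms`, `x_means`. [tidy()]
#'   and [glance()] give broom-style views.
#' @export
fit_ols <- function(y, X, term_names = NULL) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) abort("`y` and `X` have different numbers of rows.")
  term_names <- term_names %||% colnames(X) %||% paste0("x", seq_len(ncol(X)))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- term_names[qx$pivot[(qx$rank + 1):ncol(X)]]
    abort(sprintf("Design matrix is rank deficient; collinear terms: %s.",
                  paste(dropped, collapse = ", ")))
  }
  if (nrow(X) <= ncol(X)) abort("Need more observations than terms.")
  fit <- lm.fit(X, y)
  res <- fit$residuals
  df <- length(y) - ncol(X)
  s2 <- sum(res^2) / df
  vc <- s2 * solve(crossprod(X))
  se <- sqrt(diag(vc))
  b <- fit$coefficients
  tval <- b / se
  has_intercept <- any(apply(X, 2, function(col) all(col == col[1]) && col[1] != 0))
  tss <- if (has_intercept) sum((y - mean(y))^2) else sum(y^2)
  structure(list(
    coefficients = setNames(unname(b), term_names),
    se = setNames(unname(se), term_names),
    t = setNames(unname(tval), term_names),
    p = setNames(unname(2 * pt(-abs(tval), df)), term_names),
    vcov = vc,
    r_squared = 1 - sum(res^2) / tss,
    sigma = sqrt(s2),
    df_residual = df,
    n = length(y),
    terms = term_names,
    x_means = setNames(colMeans(X), term_names)
  ), class = "ols_fit")
}

#' @export
#' @method tidy ols_fit
tidy.ols_fit <- function(x, ...) {
  tibble(term = x$terms, estimate = unname(x$coefficients),
         std_error = unname(x$se), statistic = unname(x$t),
         p_value = unname(x$p))
}

#' @export
#' @method glance ols_fit
glance.ols_fit <- function(x, ...) {
  tibble(r_squared = x$r_squared, sigma = x$sigma, n = x$n,
         df_residual = x$df_residual)
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf("OLS fit, n = %d, R-squared = %.3f\n", x$n, x$r_squared))
  print(tidy(x))
  invisible(x)
}

#' Covariate-adjusted regression of an index or single locus
#'
#' The index-level model: the outcome is regressed on smoking, the moderator
#' index, sex, age, diet and the five cell fractions (Model 1), optionally
#' adding the smoking-by-moderator interaction (Model 2), by ordinary least
#' squares on complete cases.
#'
#' @param outcome Numeric outcome vector aligned with `pheno` rows, or a
#'   tibble with `sample_id` and one value column (joined on `sample_id`).
#' @param pheno Phenotype tibble with columns `mmthfr`, `male`, `age`,
#'   `diet`, `cd8t`, `cd4t`, `nk`, `bcell`, `mono` and the smoking measure.
#' @inheritParams fit_locus_pair
#' @param with_interaction Add the smoking-by-moderator term (Model 2)?
#' @return An [fit_ols()] object.
#' @export
moderated_index_regression <- function(outcome, pheno,
                                       smoking_measure = c("status", "consumption"),
                                       with_interaction = FALSE) {
  smoking_measure <- match.arg(smoking_measure)
  smo_col <- if (smoking_measure == "status") "smoking_status" else "consumption"
  cells <- c("cd8t", "cd4t", "nk", "bcell", "mono")
  needed <- c(smo_col, "mmthfr", "male", "age", "diet", cells)
  if (!all(needed %in% names(pheno))) {
    abort(sprintf("`pheno` lacks required columns: %s.",
                  paste(setdiff(needed, names(pheno)), collapse = ", ")))
  }
  if (is.data.frame(outcome)) {
    if (!"sample_id" %in% names(outcome) || ncol(outcome) != 2L) {
      abort("A data-frame `outcome` must have columns sample_id and one value column.")
    }
    val_col <- setdiff(names(outcome), "sample_id")
    y <- outcome[[val_col]][match(pheno$sample_id, outcome$sample_id)]
  } else {
    if (length(outcome) != nrow(pheno)) {
      abort("`outcome` must have one value per row of `pheno`.")
    }
    y <- outcome
  }
  ok <- complete.cases(pheno[needed]) & is.finite(y)
  ph <- pheno[ok, , drop = FALSE]
  y <- y[ok]
  for (v in needed) {
    if (var(ph[[v]]) == 0) {
      abort(sprintf("Covariate '%s' has zero variance on the analysis sample.", v))
    }
  }
  X <- cbind(smoking = ph[[smo_col]], mmthfr = ph$mmthfr, male = ph$male,
             age = ph$age, diet = ph$diet,
             as.matrix(ph[cells]))
  if (with_interaction) {
    X <- cbind(X, `smoking:mmthfr` = ph[[smo_col]] * ph$mmthfr)
  }
  X <- cbind(X, constant = 1)
  fit_ols(y, X)
}

#' Simple slopes of smoking at low and high moderator values
#'
#' Evaluates the conditional smoking slope `b_smoking + b_interaction * m` at
#' moderator values one SD below and above its (centered) mean, the standard
#' explication of a fitted interaction. Plot-ready intercepts evaluate all
#' remaining covariates at their fitted means.
#'
#' @param fit An [fit_ols()] (or [fit_betareg()]) object whose terms include
#'   `smoking`, `mmthfr` and `smoking:mmthfr`.
#' @param moderator_sd Standard deviation of the moderator (default 1, i.e.
#'   an index already standardized).
#' @return A `simple_slopes` tibble: `moderator_level` (`"-1 SD"`,
#'   `"+1 SD"`), `moderator_value`, `slope`, `intercept`.
#' @export
simple_slopes <- function(fit, moderator_sd = 1) {
  need <- c("smoking", "mmthfr", "smoking:mmthfr")
  if (!all(need %in% fit$terms)) {
    abort(sprintf("Fit lacks required terms: %s.",
                  paste(setdiff(need, fit$terms), collapse = ", ")))
  }
  b <- fit$coefficients
  m_vals <- c(-1, 1) * moderator_sd
  slope <- unname(b["smoking"] + b["smoking:mmthfr"] * m_vals)
  other <- setdiff(fit$terms, need)
  base <- if (length(other)) {
    sum(b[other] * fit$x_means[other])
  } else 0
  intercept <- unname(base + b["mmthfr"] * m_vals)
  structure(
    tibble(moderator_level = c("-1 SD", "+1 SD"),
           moderator_value = m_vals, slope = slope, intercept = intercept),
    class = c("simple_slopes", class(tibble())))
}
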