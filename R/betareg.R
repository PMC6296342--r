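#' Beta-regression log-likelihood
#'
#' Log-likelihood of the beta regression model in the mean-precision
#' parameterization: the response `y` in (0,1) is Beta(mu*phi, (1-mu)*phi)
#' with mean `mu = plogis(X %*% b)` and a single constant precision `phi`.
#'
#' @param params Numeric vector `c(b, log_phi)`: mean-model coefficients on
#'   the logit scale followed by the log precision.
#' @param y Response vector, strictly inside (0,1).
#' @param X Design matrix with `length(params) - 1` columns, full column rank.
#' @return The log-likelihood (a scalar).
#' @export
beta_loglik <- function(params, y, X) {
  X <- as.matrix(X)
  if (length(params) != ncol(X) + 1L) {
    abort("`params` must hold one coefficient per design column plus log(phi).")
  }
  check_unit_open(y)
  b <- params[-length(params)]
  phi <- exp(params[length(params)])
  mu <- inv_logit(drop(X %*% b))
  sum(lgamma(phi) - lgamma(mu * phi) - lgamma((1 - mu) * phi) +
        (mu * phi - 1) * log(y) + ((1 - mu) * phi - 1) * log1p(-y))
}

check_unit_open <- function(y) {
  if (any(!is.finite(y)) || any(y <= 0) || any(y >= 1)) {
    abort(paste(
      "All responses must lie strictly inside (0,1);",
      "apply squeeze_unit_interval() to boundary values first."
    ))
  }
  invisible(y)
}

# analytic score of beta_loglik, same parameter layout
beta_score <- function(params, y, X) {
  b <- params[-length(params)]
  phi <- exp(params[length(params)])
  eta <- drop(X %*% b)
  mu <- inv_logit(eta)
  ystar <- log(y) - log1p(-y)
  mustar <- digamma(mu * phi) - digamma((1 - mu) * phi)
  dmu <- mu * (1 - mu)                       # d mu / d eta for the logit link
  grad_b <- drop(crossprod(X, phi * (ystar - mustar) * dmu))
  dl_dphi <- sum(digamma(phi) - mu * digamma(mu * phi) -
                   (1 - mu) * digamma((1 - mu) * phi) +
                   mu * log(y) + (1 - mu) * log1p(-y))
  c(grad_b, dl_dphi * phi)                   # chain rule for log(phi)
}

# observed information (negative Hessian) by central finite differences of the
# analytic score; step 1e-5 * max(1, |theta_j|)
observed_information <- function(params, y, X) {
  k <- length(params)
  H <- matrix(0, k, k)
  for (j in seq_len(k)) {
    h <- 1e-5 * max(1, abs(params[j]))
    up <- params; up[j] <- up[j] + h
    dn <- params; dn[j] <- dn[j] - h
    H[, j] <- (beta_score(up, y, X) - beta_score(dn, y, X)) / (2 * h)
  }
  -(H + t(H)) / 2
}

starting_values <- function(y, X) {
  z <- logit(y)
  ls <- lm.fit(X, z)
  b0 <- ls$coefficients
  b0[is.na(b0)] <- 0
  mu0 <- inv_logit(drop(X %*% b0))
  # method-of-moments precision from the response-scale residual variance
  e <- y - mu0
  s2 <- max(var(e), 1e-8)
  phi0 <- max(mean(mu0 * (1 - mu0)) / s2 - 1, 1)
  c(b0, log(phi0))
}

#' Fit a beta regression by maximum likelihood
#'
#' Maximizes [beta_loglik()] by quasi-Newton (BFGS) iteration with an analytic
#' score, started from an OLS fit of `logit(y)` and a method-of-moments
#' precision, followed by Newton polishing when the gradient has not vanished.
#' Standard errors come from the inverse of the observed information evaluated
#' by central finite differences of the score.
#'
#' @param y Response vector strictly in (0,1).
#' @param X Design matrix (including the intercept column), full column rank.
#' @param term_names Optional term labels; defaults to `colnames(X)`.
#' @return An object of class `betareg_fit`: a list with elements
#'   `coefficients`, `phi`, `log_phi`, `vcov` (all parameters, log-phi last),
#'   `se`, `z`, `p`, `loglik`, `converged`, `iterations`, `n`, `terms`.
#'   [tidy()] returns the per-term table, [glance()] the fit summary.
#' @export
fit_betareg <- function(y, X, term_names = NULL) {
  X <- as.matrix(X)
  check_unit_open(y)
  if (nrow(X) != length(y)) abort("`y` and `X` have different numbers of rows.")
  if (qr(X)$rank < ncol(X)) abort("Design matrix `X` is rank deficient.")
  if (length(y) <= ncol(X)) {
    abort("Need more observations than mean-model parameters to fit the model.")
  }
  term_names <- term_names %||% colnames(X) %||%
    paste0("x", seq_len(ncol(X)))

  nll <- function(p) -beta_loglik(p, y, X)
  ngr <- function(p) -beta_score(p, y, X)

  start <- starting_values(y, X)
  opt <- tryCatch(
    optim(start, nll, ngr, method = "BFGS",
          control = list(maxit = 500, reltol = 1e-14)),
    error = function(e) NULL
  )
  theta <- if (is.null(opt)) start else opt$par
  iter <- if (is.null(opt)) 0L else opt$counts[["function"]]

  # Newton polish until the score vanishes (or the information degenerates)
  for (i in 1:25) {
    g <- beta_score(theta, y, X)
    if (max(abs(g)) <= 1e-9) break
    info <- observed_information(theta, y, X)
    step <- tryCatch(solve(info, g), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    cand <- theta + step
    damp <- 1
    while (damp > 1e-4 && (!is.finite(nll(cand)) || nll(cand) > nll(theta) + 1e-9)) {
      damp <- damp / 2
      cand <- theta + damp * step
    }
    if (damp <= 1e-4) break
    theta <- cand
    iter <- iter + 1L
  }

  g <- beta_score(theta, y, X)
  converged <- is.finite(max(abs(g))) && max(abs(g)) <= 1e-5
  info <- observed_information(theta, y, X)
  vc <- tryCatch(solve(info), error = function(e) NULL)
  if (is.null(vc) || any(!is.finite(diag(vc))) || any(diag(vc) < 0)) {
    vc <- matrix(NA_real_, length(theta), length(theta))
    converged <- FALSE
  }
  k <- ncol(X)
  se <- sqrt(diag(vc))[seq_len(k)]
  b <- theta[seq_len(k)]
  z <- b / se
  structure(list(
    coefficients = setNames(b, term_names),
    phi = exp(theta[k + 1L]),
    log_phi = theta[k + 1L],
    vcov = vc,
    se = setNames(se, term_names),
    z = setNames(z, term_names),
    p = setNames(2 * pnorm(-abs(z)), term_names),
    loglik = beta_loglik(theta, y, X),
    converged = converged,
    iterations = as.integer(iter),
    n = length(y),
    terms = term_names
  ), class = "betareg_fit")
}

#' Wald tests for a fitted beta regression
#'
#' @param fit A converged [fit_betareg()] object.
#' @return A tibble with one row per mean-model term: `term`, `estimate`,
#'   `std_error`, `statistic` (Wald z), `p_value` (two-sided normal).
#' @export
wald_pvalues <- function(fit) {
  stopifnot(inherits(fit, "betareg_fit"))
  if (!isTRUE(fit$converged)) {
    abort("Wald tests require a converged fit; this fit did not converge.")
  }
  tibble(
    term = fit$terms,
    estimate = unname(fit$coefficients),
    std_error = unname(fit$se),
    statistic = unname(fit$z),
    p_value = unname(fit$p)
  )
}

#' @export
#' @method tidy betareg_fit
tidy.betareg_fit <- function(x, ...) {
  tibble(
    term = x$terms,
    estimate = unname(x$coefficients),
    std_error = unname(x$se),
    statistic = unname(x$z),
    p_value = unname(x$p)
  )
}

#' @export
#' @method glance betareg_fit
glance.betareg_fit <- function(x, ...) {
  tibble(
    log_lik = x$loglik,
    phi = x$phi,
    n = x$n,
    converged = x$converged,
    iterations = x$iterations
  )
}

#' @export
print.betareg_fit <- function(x, ...) {
  cat(sprintf("Beta regression (logit link), n = %d, phi = %.3f, logLik = %.3f%s\n",
              x$n, x$phi, x$loglik,
              if (x$converged) "" else " [NOT CONVERGED]"))
  print(tidy(x))
  invisible(x)
}
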