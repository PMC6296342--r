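# Independent oracles used across tests. These deliberately avoid the code
# paths they check.

# Grid-search maximum likelihood for beta regression with an intercept, one
# covariate and log-precision: coarse bracketing followed by iterative grid
# refinement down to the requested step. Evaluates the log-density through
# stats::dbeta, not the package likelihood.
grid_mle_betareg <- function(y, x, step = 1e-3) {
  ll <- function(b0, b1, lphi) {
    mu <- plogis(b0 + b1 * x)
    phi <- exp(lphi)
    sum(dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE))
  }
  centers <- c(0, 0, 2)
  widths <- c(3, 3, 3)
  repeat {
    grids <- lapply(1:3, function(j) {
      seq(centers[j] - widths[j], centers[j] + widths[j], length.out = 13)
    })
    best <- -Inf
    arg <- centers
    for (b0 in grids[[1]]) for (b1 in grids[[2]]) for (lphi in grids[[3]]) {
      v <- ll(b0, b1, lphi)
      if (is.finite(v) && v > best) {
        best <- v
        arg <- c(b0, b1, lphi)
      }
    }
    centers <- arg
    if (all(widths / 6 <= step / 2)) break
    widths <- widths / 4
  }
  list(par = centers, loglik = best)
}

# Dense simplex grid search for the constrained projection with three cell
# types: every (w1, w2, w3) on a step-0.01 grid with w >= 0, sum(w) <= 1.
grid_fractions_oracle <- function(y, R, step = 0.01) {
  g <- seq(0, 1, by = step)
  W <- as.matrix(expand.grid(w1 = g, w2 = g, w3 = g))
  W <- W[rowSums(W) <= 1 + 1e-12, , drop = FALSE]
  resid2 <- colSums((y - R %*% t(W))^2)
  i <- which.min(resid2)
  list(w = W[i, ], objective = resid2[i])
}

# A tiny beta tibble fixture: values chosen by hand, two samples by default.
toy_betas <- function(values, probe_ids = NULL) {
  m <- as.matrix(values)
  colnames(m) <- paste0("S", seq_len(ncol(m)))
  probe_ids <- probe_ids %||% paste0("p", seq_len(nrow(m)))
  dplyr::bind_cols(tibble::tibble(probe_id = probe_ids),
                   tibble::as_tibble(m))
}

# Phenotypes with an attached moderator column, ready for scans.
scan_ready_pheno <- function(config) {
  ph <- simulate_phenotypes(config)
  ph$mmthfr <- ph$latent_mmthfr
  ph
}

`%||%` <- function(a, b) if (is.null(a)) b else a
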