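#' Reference-based cell-fraction estimation by constrained projection
#'
#' Estimates leukocyte-subtype fractions for each sample by projecting its
#' methylation profile onto reference cell-type profiles: the fractions
#' minimize `||y - R w||^2` subject to `w >= 0` and `sum(w) <= 1`. The sum is
#' allowed to fall below 1 because a PBMC reference panel does not span all
#' circulating cell types. The quadratic program is solved exactly by
#' enumerating KKT active sets (feasible for the small panels used here).
#'
#' @param x Either a beta tibble (`probe_id` + one column per sample) or a
#'   single numeric profile over the reference probes, in reference order.
#' @param reference Cell reference tibble: `probe_id` plus one column of beta
#'   values per cell type, at least as many probes as cell types, full column
#'   rank.
#' @return A tibble with `sample_id` and one fraction column per cell type.
#' @export
estimate_cell_fractions <- function(x, reference) {
  assert_beta_tbl(reference, "reference")
  R <- beta_values(reference)
  if (nrow(R) < ncol(R)) abort("Reference needs at least as many probes as cell types.")
  if (qr(R)$rank < ncol(R)) abort("Reference matrix is rank deficient.")
  if (is.numeric(x) && is.null(dim(x))) {
    Y <- matrix(x, ncol = 1, dimnames = list(NULL, "sample_1"))
    if (nrow(Y) != nrow(R)) {
      abort(sprintf("Profile has %d probes but the reference has %d.",
                    nrow(Y), nrow(R)))
    }
  } else {
    assert_beta_tbl(x)
    missing <- setdiff(reference$probe_id, x$probe_id)
    if (length(missing)) {
      abort(sprintf("Profiles lack %d reference probes (e.g. %s).",
                    length(missing), missing[1]))
    }
    Y <- beta_values(x)[reference$probe_id, , drop = FALSE]
  }
  W <- apply(Y, 2, project_fractions, R = R)
  out <- as_tibble(t(W))
  names(out) <- colnames(R)
  dplyr::bind_cols(tibble(sample_id = colnames(Y)), out)
}

# exact solution of min ||y - R w||^2 s.t. w >= 0, sum(w) <= 1 by
# enumeration of active sets (2^(k+1) tiny equality-constrained solves)
project_fractions <- function(y, R) {
  k <- ncol(R)
  if (k > 15L) abort("Active-set enumeration supports at most 15 cell types.")
  RtR <- crossprod(R)
  Rty <- drop(crossprod(R, y))
  tol <- 1e-9
  best <- NULL
  best_obj <- Inf
  for (code in 0:(2^k - 1)) {
    free <- which(bitwAnd(code, 2^(0:(k - 1))) == 0)
    for (sum_active in c(FALSE, TRUE)) {
      w <- numeric(k)
      if (length(free) == 0L) {
        if (sum_active) next
      } else if (!sum_active) {
        sol <- tryCatch(solve(RtR[free, free, drop = FALSE], Rty[free]),
                        error = function(e) NULL)
        if (is.null(sol)) next
        w[free] <- sol
      } else {
        nf <- length(free)
        A <- rbind(cbind(RtR[free, free, drop = FALSE], rep(1, nf)),
                   c(rep(1, nf), 0))
        sol <- tryCatch(solve(A, c(Rty[free], 1)), error = function(e) NULL)
        if (is.null(sol)) next
        w[free] <- sol[seq_len(nf)]
      }
      if (any(w < -tol) || sum(w) > 1 + tol) next
      w <- pmax(w, 0)
      obj <- sum((y - drop(R %*% w))^2)
      if (obj < best_obj - 1e-15) {
        best_obj <- obj
        best <- w
      }
    }
  }
  setNames(best, colnames(R))
}
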