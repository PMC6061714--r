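#' Moore-Penrose pseudo-inverse via SVD
#'
#' Singular values below `max(dim(A)) * eps * max(sv)` are treated as zero,
#' which keeps the normal-equations solution stable when quadratic design
#' columns are nearly collinear.
#'
#' @param A numeric matrix.
#' @param tol relative singular-value cutoff; default
#'   `max(dim(A)) * .Machine$double.eps`.
#' @return the pseudo-inverse of `A`.
#' @export
pinv <- function(A, tol = NULL) {
  A <- as.matrix(A)
  s <- svd(A)
  if (is.null(tol)) tol <- max(dim(A)) * .Machine$double.eps
  keep <- s$d > tol * max(s$d, 0)
  if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

# Coerce retention/design inputs to plain matrices.
as_response_matrix <- function(X) {
  if (inherits(X, "rt_matrix")) X <- X$values
  as.matrix(X)
}

as_design_values <- function(D) {
  if (inherits(D, "design_matrix")) D$values else as.matrix(D)
}

#' Fit design-of-experiments coefficients by multiple linear regression
#'
#' Solves `X = D B` in the least-squares sense, `Bhat = pinv(D) X`, one
#' column of coefficients per compound. The pseudo-inverse is computed by
#' SVD rather than from the normal equations.
#'
#' @param X runs x compounds retention-time matrix (minutes), or an
#'   `rt_matrix`.
#' @param D design matrix (a [build_design()] result or a plain runs x terms
#'   matrix).
#' @return object of class `mlr_fit`: list with `coefficients` (terms x
#'   compounds), `fitted`, `residuals`, `method = "MLR"`, `term_labels`.
#' @examples
#' D <- build_design(hsa_design_spec())
#' B <- matrix(rnorm(6 * 4), 6, 4)
#' fit <- fit_mlr(D$values %*% B, D)
#' max(abs(fit$coefficients - B))  # ~ 1e-14
#' @export
fit_mlr <- function(X, D) {
  Dv <- as_design_values(D)
  Xv <- as_response_matrix(X)
  if (nrow(Xv) != nrow(Dv)) {
    stop(sprintf("X has %d rows but D has %d", nrow(Xv), nrow(Dv)),
         call. = FALSE)
  }
  qrD <- qr(Dv)
  if (qrD$rank < ncol(Dv)) {
    bad <- colnames(Dv)[qrD$pivot[-seq_len(qrD$rank)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  B <- pinv(Dv) %*% Xv
  dimnames(B) <- list(colnames(Dv), colnames(Xv))
  fitted <- Dv %*% B
  structure(
    list(coefficients = B, fitted = fitted, residuals = Xv - fitted,
         method = "MLR",
         term_labels = colnames(Dv) %||% paste0("term", seq_len(ncol(Dv)))),
    class = "mlr_fit"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.mlr_fit <- function(x, ...) {
  cat(sprintf("%s fit: %d terms x %d compounds\n", x$method,
              nrow(x$coefficients), ncol(x$coefficients)))
  invisible(x)
}

#' Pure-error confidence-interval halfwidths from replicate runs
#'
#' The replicated center points estimate the run-to-run repeatability of
#' each compound's retention time. The halfwidth is
#' `t(1 - (1-level)/2, n-1) * sd / sqrt(n)` per compound.
#'
#' @param replicate_rts replicates x compounds matrix of retention times.
#' @param level confidence level (default 0.95).
#' @return numeric vector of halfwidths (minutes), one per compound.
#' @export
replicate_ci <- function(replicate_rts, level = 0.95) {
  R <- as_response_matrix(replicate_rts)
  n <- nrow(R)
  if (n < 2L) stop("at least 2 replicate rows are required", call. = FALSE)
  stopifnot(level > 0, level < 1)
  sds <- apply(R, 2L, stats::sd)
  stats::qt(1 - (1 - level) / 2, df = n - 1L) * sds / sqrt(n)
}

#' Coefficient-level confidence intervals from pure error
#'
#' Propagates the replicate (pure-error) standard deviation through the
#' least-squares geometry: for term j the halfwidth is
#' `t(1-(1-level)/2, n_rep - 1) * s_pure * sqrt([(D'D)^-1]_jj)`, per
#' compound. This puts an interval on every coefficient using only the
#' center-point repeatability, without assuming the regression residuals
#' are pure noise.
#'
#' @param fit an [fit_mlr()] result.
#' @param D the design matrix used for the fit (a [build_design()] result;
#'   its `is_replicate` flag identifies the replicate rows), or a plain
#'   matrix together with `is_replicate`.
#' @param X the retention matrix the fit was computed from.
#' @param is_replicate logical per-run flag; defaults to `D$is_replicate`.
#' @param level confidence level.
#' @return terms x compounds matrix of CI halfwidths.
#' @export
coefficient_ci <- function(fit, D, X, is_replicate = NULL, level = 0.95) {
  Dv <- as_design_values(D)
  Xv <- as_response_matrix(X)
  if (is.null(is_replicate)) {
    if (!inherits(D, "design_matrix")) {
      stop("'is_replicate' must be given when D is a plain matrix",
           call. = FALSE)
    }
    is_replicate <- D$is_replicate
  }
  n_rep <- sum(is_replicate)
  if (n_rep < 2L) stop("at least 2 replicate runs are required", call. = FALSE)
  s_pure <- apply(Xv[is_replicate, , drop = FALSE], 2L, stats::sd)
  g <- diag(pinv(crossprod(Dv)))           # [(D'D)^-1]_jj
  tq <- stats::qt(1 - (1 - level) / 2, df = n_rep - 1L)
  hw <- outer(sqrt(pmax(g, 0)), s_pure) * tq
  dimnames(hw) <- dimnames(fit$coefficients)
  hw
}

#' Relative residual variance per compound
#'
#' For each compound, the residual sum of squares of a prediction divided
#' by the centered sum of squares of the observations: 0 for a perfect
#' prediction, 1 for predicting the column mean. Set `center = FALSE` to
#' normalize by the raw (uncentered) sum of squares instead.
#'
#' @param X observed runs x compounds matrix.
#' @param X_hat predicted matrix, same shape.
#' @param center normalize by centered (default) or raw sum of squares.
#' @return numeric vector of fractions, one per compound.
#' @export
relative_residual_variance <- function(X, X_hat, center = TRUE) {
  Xv <- as_response_matrix(X)
  Hv <- as_response_matrix(X_hat)
  if (!all(dim(Xv) == dim(Hv))) stop("shape mismatch", call. = FALSE)
  ss_res <- colSums((Xv - Hv)^2)
  denom <- if (center) {
    colSums(scale(Xv, center = TRUE, scale = FALSE)^2)
  } else {
    colSums(Xv^2)
  }
  if (any(denom == 0)) {
    stop("zero-variance compound column; relative residual variance ",
         "is undefined", call. = FALSE)
  }
  ss_res / denom
}
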