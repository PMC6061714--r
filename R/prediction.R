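#' Calibrant selection with overlap exclusion
#'
#' A calibrant compound is excluded from a target's calibration block iff
#' in any run its retention time comes within `rt_window` minutes of the
#' target's. This keeps isotopes, adducts, fragments, or genuinely
#' co-eluting species out of the predictor block, so the calibration rests
#' on information from other analytes only.
#'
#' @param X runs x compounds retention matrix or `rt_matrix`.
#' @param target compound label or column index.
#' @param rt_window exclusion half-width, minutes (default 0.2).
#' @return character vector of calibrant labels, in column order.
#' @export
exclude_overlapping <- function(X, target, rt_window = 0.2) {
  Xv <- as_response_matrix(X)
  if (rt_window < 0) stop("rt_window must be non-negative", call. = FALSE)
  labels <- colnames(Xv) %||% as.character(seq_len(ncol(Xv)))
  colnames(Xv) <- labels
  ti <- resolve_compound(target, labels)
  near <- apply(abs(Xv - Xv[, ti]) < rt_window, 2L, any)
  near[ti] <- TRUE
  labels[!near]
}

resolve_compound <- function(target, labels) {
  ti <- if (is.character(target)) match(target, labels) else as.integer(target)
  if (is.na(ti) || ti < 1L || ti > length(labels)) {
    stop("target compound not found in matrix", call. = FALSE)
  }
  ti
}

#' Principal component regression of one compound on the others
#'
#' Centers the calibrant block and the target column, takes the leading
#' principal components of the calibrant block, and regresses the target
#' on the scores. Reports auto-prediction and (optionally) leave-one-run-
#' out cross-validated predictions with their relative residual variances
#' (residual sum of squares over centered sum of squares of the target).
#'
#' @param X runs x compounds retention matrix or `rt_matrix`.
#' @param target compound label or index.
#' @param calibrants calibrant labels/indices (e.g. from
#'   [exclude_overlapping()]); must not contain the target.
#' @param n_components number of components (default 6).
#' @param cv run leave-one-run-out cross-validation (default TRUE).
#' @return object of class `pcr_model`: `target`, `calibrants`,
#'   `n_components`, `regression_vector` (per calibrant),
#'   `centering` (calibrant means and target mean), `fitted`, `cv_pred`,
#'   `rrv_auto`, `rrv_cv`, `method`.
#' @export
fit_pcr <- function(X, target, calibrants, n_components = 6L, cv = TRUE) {
  fit_latent_calibration(X, target, calibrants, n_components, cv,
                         engine = pcr_engine, method = "PCR")
}

#' Partial least squares (PLS1) regression of one compound on the others
#'
#' NIPALS PLS1 with the same interface and metric surface as [fit_pcr()]:
#' latent components are extracted to maximize covariance with the target
#' rather than variance of the calibrant block alone.
#'
#' @inheritParams fit_pcr
#' @return a `pcr_model` with `method = "PLS"`.
#' @export
fit_pls <- function(X, target, calibrants, n_components = 6L, cv = TRUE) {
  fit_latent_calibration(X, target, calibrants, n_components, cv,
                         engine = pls_engine, method = "PLS")
}

fit_latent_calibration <- function(X, target, calibrants, n_components, cv,
                                   engine, method) {
  Xv <- as_response_matrix(X)
  labels <- colnames(Xv) %||% as.character(seq_len(ncol(Xv)))
  colnames(Xv) <- labels
  ti <- resolve_compound(target, labels)
  ci <- vapply(calibrants, resolve_compound, integer(1), labels = labels)
  if (length(ci) == 0L) stop("empty calibrant set", call. = FALSE)
  if (ti %in% ci) stop("target must not be among the calibrants",
                       call. = FALSE)
  k <- as.integer(n_components)
  n <- nrow(Xv)
  if (k < 1L) stop("n_components must be at least 1", call. = FALSE)
  if (k > min(n - 1L, length(ci))) {
    stop(sprintf("n_components = %d exceeds what %d runs x %d calibrants support",
                 k, n, length(ci)), call. = FALSE)
  }
  y <- Xv[, ti]
  Xc <- Xv[, ci, drop = FALSE]
  fit <- engine(Xc, y, k)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) stop("zero-variance target column", call. = FALSE)
  rrv_auto <- sum((y - fit$fitted)^2) / ss_tot
  cv_pred <- rep(NA_real_, n)
  rrv_cv <- NA_real_
  if (cv) {
    for (i in seq_len(n)) {
      f <- engine(Xc[-i, , drop = FALSE], y[-i], k)
      cv_pred[i] <- f$predict(Xc[i, ])
    }
    rrv_cv <- sum((y - cv_pred)^2) / ss_tot
  }
  structure(
    list(target = labels[ti], calibrants = labels[ci], n_components = k,
         regression_vector = fit$b,
         centering = list(calibrants = fit$mx, target = fit$my),
         fitted = fit$fitted, cv_pred = cv_pred,
         rrv_auto = rrv_auto, rrv_cv = rrv_cv, method = method),
    class = "pcr_model"
  )
}

#' @export
print.pcr_model <- function(x, ...) {
  cat(sprintf("%s model for %s: %d calibrants, %d component(s); RRV auto %.3g%s\n",
              x$method, x$target, length(x$calibrants), x$n_components,
              x$rrv_auto,
              if (is.na(x$rrv_cv)) "" else sprintf(", cv %.3g", x$rrv_cv)))
  invisible(x)
}

# PCR engine: regression of centered y on the first k PC scores of
# centered Xc. Errors if k exceeds the effective rank.
pcr_engine <- function(Xc, y, k) {
  mx <- colMeans(Xc)
  my <- mean(y)
  Xs <- sweep(Xc, 2L, mx)
  s <- svd(Xs)
  rank <- sum(s$d > max(dim(Xs)) * .Machine$double.eps * max(s$d, 0))
  if (k > rank) {
    stop(sprintf("n_components = %d exceeds the rank (%d) of the calibrant block",
                 k, rank), call. = FALSE)
  }
  q <- crossprod(s$u[, seq_len(k), drop = FALSE], y - my) / s$d[seq_len(k)]
  b <- s$v[, seq_len(k), drop = FALSE] %*% q
  list(b = as.vector(b), mx = mx, my = my,
       fitted = as.vector(Xs %*% b) + my,
       predict = function(xnew) sum((xnew - mx) * b) + my)
}

# NIPALS PLS1 engine: same contract as pcr_engine.
pls_engine <- function(Xc, y, k) {
  mx <- colMeans(Xc)
  my <- mean(y)
  Xs <- sweep(Xc, 2L, mx)
  ys <- y - my
  p <- ncol(Xs)
  W <- matrix(0, p, k); P <- matrix(0, p, k); qv <- numeric(k)
  Xd <- Xs; yd <- ys
  a_used <- 0L
  for (a in seq_len(k)) {
    w <- crossprod(Xd, yd)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-14 * (1 + sqrt(sum(Xs^2)))) break
    w <- w / nw
    t <- Xd %*% w
    tt <- sum(t^2)
    if (tt < .Machine$double.eps) break
    pl <- crossprod(Xd, t) / tt
    qa <- sum(yd * t) / tt
    Xd <- Xd - t %*% t(pl)
    yd <- yd - t * qa
    W[, a] <- w; P[, a] <- pl; qv[a] <- qa
    a_used <- a
  }
  if (a_used == 0L) {
    b <- rep(0, p)
  } else {
    Wk <- W[, seq_len(a_used), drop = FALSE]
    Pk <- P[, seq_len(a_used), drop = FALSE]
    b <- as.vector(Wk %*% solve(crossprod(Pk, Wk), qv[seq_len(a_used)]))
  }
  list(b = b, mx = mx, my = my,
       fitted = as.vector(Xs %*% b) + my,
       predict = function(xnew) sum((xnew - mx) * b) + my)
}

#' Predict the design levels from the retention data
#'
#' For each non-intercept model term, regresses the term's design column
#' on the leading PCA scores of the (centered) retention matrix, for every
#' component count in `component_range`. Reports the root-mean-square
#' error of calibration (RMSEC), the leave-one-run-out cross-validated
#' RMSE (RMSECV), and the explained variance of auto-prediction. A term
#' whose coefficients are too small to leave a trace in the retention data
#' stays near its own column SD at every component count; a well-expressed
#' term drops to a small fraction of it.
#'
#' @param X runs x compounds retention matrix or `rt_matrix`.
#' @param D design matrix ([build_design()] result or plain matrix).
#' @param component_range integer vector of component counts (default 1:8).
#' @param cv run leave-one-run-out cross-validation (default TRUE).
#' @return object of class `level_prediction`: matrices `rmsec`, `rmsecv`,
#'   `explained_variance` (terms x component counts), `term_sd` (SD of
#'   each design column), `component_range`, and `cv_pred` (per-term list
#'   of per-run CV predictions at each component count).
#' @export
predict_design_levels <- function(X, D, component_range = 1:8, cv = TRUE) {
  Xv <- as_response_matrix(X)
  Dc <- design_columns_centered(D)
  terms <- colnames(Dc)
  n <- nrow(Xv)
  kmax <- max(component_range)
  if (kmax > min(n - 1L, ncol(Xv))) {
    stop("component_range exceeds the rank the data can support",
         call. = FALSE)
  }
  mu <- colMeans(Xv)
  Xs <- sweep(Xv, 2L, mu)
  s <- svd(Xs)
  scores <- s$u[, seq_len(kmax), drop = FALSE] *
    rep(s$d[seq_len(kmax)], each = n)
  nk <- length(component_range)
  rmsec <- rmsecv <- ev <- matrix(
    NA_real_, length(terms), nk,
    dimnames = list(terms, paste0("k", component_range)))
  cv_store <- lapply(terms, function(.) matrix(NA_real_, n, nk))
  names(cv_store) <- terms
  # calibration errors
  for (ik in seq_len(nk)) {
    k <- component_range[ik]
    Tk <- scores[, seq_len(k), drop = FALSE]
    H <- cbind(1, Tk)
    beta <- pinv(H) %*% Dc
    res <- Dc - H %*% beta
    rmsec[, ik] <- sqrt(colMeans(res^2))
    ss_tot <- colSums(Dc^2)          # Dc is centered
    ev[, ik] <- 1 - colSums(res^2) / ss_tot
  }
  if (cv) {
    for (i in seq_len(n)) {
      mu_tr <- colMeans(Xv[-i, , drop = FALSE])
      Xtr <- sweep(Xv[-i, , drop = FALSE], 2L, mu_tr)
      st <- svd(Xtr)
      Ttr_full <- st$u[, seq_len(kmax), drop = FALSE] *
        rep(st$d[seq_len(kmax)], each = n - 1L)
      t_new_full <- as.vector((Xv[i, ] - mu_tr) %*%
                                st$v[, seq_len(kmax), drop = FALSE])
      for (ik in seq_len(nk)) {
        k <- component_range[ik]
        H <- cbind(1, Ttr_full[, seq_len(k), drop = FALSE])
        beta <- pinv(H) %*% Dc[-i, , drop = FALSE]
        pred <- as.vector(c(1, t_new_full[seq_len(k)]) %*% beta)
        for (j in seq_along(terms)) cv_store[[j]][i, ik] <- pred[j]
      }
    }
    for (j in seq_along(terms)) {
      rmsecv[j, ] <- sqrt(colMeans((cv_store[[j]] - Dc[, j])^2))
    }
  }
  structure(
    list(rmsec = rmsec, rmsecv = rmsecv, explained_variance = ev,
         term_sd = apply(Dc, 2L, stats::sd), component_range = component_range,
         cv_pred = cv_store),
    class = "level_prediction"
  )
}

#' @export
print.level_prediction <- function(x, ...) {
  cat("Design-level prediction RMSEC (terms x components):\n")
  print(round(x$rmsec, 4))
  if (!all(is.na(x$rmsecv))) {
    cat("RMSECV:\n")
    print(round(x$rmsecv, 4))
  }
  invisible(x)
}

#' Per-compound residual-variance comparison of MLR and PCR
#'
#' Fits the design-based MLR model and, for every compound, a PCR
#' calibration on the overlap-excluded remaining compounds, and tabulates
#' the relative residual variances side by side: MLR auto-prediction, PCR
#' auto-prediction, and PCR leave-one-run-out cross-validation.
#'
#' @param X runs x compounds retention matrix or `rt_matrix`.
#' @param D design matrix.
#' @param n_components PCR components (default 6).
#' @param rt_window overlap-exclusion window, minutes.
#' @param cv include the cross-validated column (default TRUE).
#' @param compounds subset of compound labels/indices (default all).
#' @return data frame with columns `compound`, `mlr_auto`, `pcr_auto`,
#'   `pcr_cv` (NA when `cv = FALSE`), and `n_calibrants`.
#' @export
residual_variance_comparison <- function(X, D, n_components = 6L,
                                         rt_window = 0.2, cv = TRUE,
                                         compounds = NULL) {
  Xv <- as_response_matrix(X)
  labels <- colnames(Xv) %||% as.character(seq_len(ncol(Xv)))
  colnames(Xv) <- labels
  mlr <- fit_mlr(Xv, D)
  mlr_rrv <- relative_residual_variance(Xv, mlr$fitted)
  if (is.null(compounds)) compounds <- labels
  idx <- vapply(compounds, resolve_compound, integer(1), labels = labels)
  out <- data.frame(compound = labels[idx],
                    mlr_auto = unname(mlr_rrv[idx]),
                    pcr_auto = NA_real_, pcr_cv = NA_real_,
                    n_calibrants = NA_integer_,
                    stringsAsFactors = FALSE)
  for (r in seq_along(idx)) {
    cal <- exclude_overlapping(Xv, idx[r], rt_window)
    if (length(cal) == 0L) next
    k <- min(n_components, length(cal), nrow(Xv) - 1L)
    m <- fit_pcr(Xv, idx[r], cal, n_components = k, cv = cv)
    out$pcr_auto[r] <- m$rrv_auto
    out$pcr_cv[r] <- m$rrv_cv
    out$n_calibrants[r] <- length(cal)
  }
  out
}
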