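#' Principal component analysis of a retention matrix
#'
#' SVD-based decomposition `X = T P' + E` (after optional column mean
#' centering). Components are ordered by decreasing variance and the sign
#' of each component is fixed so that its largest-magnitude loading entry
#' is positive, making scores reproducible across SVD implementations.
#'
#' @param X runs x compounds matrix or `rt_matrix`.
#' @param n_components number of components to retain.
#' @param center subtract column means before decomposing (default TRUE).
#'   Uncentered PCA devotes the first component to the mean retention
#'   times themselves, which is rarely what a shift analysis wants.
#' @return object of class `pca_fit`: `scores` (runs x k), `loadings`
#'   (compounds x k, orthonormal columns), `residual`,
#'   `explained_variance` (fractions of total variance, all components of
#'   the matrix counted in the denominator), `centering` (per-compound
#'   offsets), `singular_values`.
#' @export
fit_pca <- function(X, n_components, center = TRUE) {
  Xv <- as_response_matrix(X)
  k <- as.integer(n_components)
  if (k < 1L || k > min(dim(Xv))) {
    stop(sprintf("n_components must be in 1..%d", min(dim(Xv))),
         call. = FALSE)
  }
  mu <- if (center) colMeans(Xv) else rep(0, ncol(Xv))
  Xc <- sweep(Xv, 2L, mu)
  s <- svd(Xc)
  flip <- vapply(seq_len(k), function(j) {
    v <- s$v[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  flip[flip == 0] <- 1
  scores <- sweep(s$u[, seq_len(k), drop = FALSE] %*%
                    diag(s$d[seq_len(k)], k, k), 2L, flip, "*")
  loadings <- sweep(s$v[, seq_len(k), drop = FALSE], 2L, flip, "*")
  comp_labels <- paste0("PC", seq_len(k))
  dimnames(scores) <- list(rownames(Xv), comp_labels)
  dimnames(loadings) <- list(colnames(Xv), comp_labels)
  structure(
    list(scores = scores, loadings = loadings,
         residual = Xc - scores %*% t(loadings),
         explained_variance = if (sum(s$d^2) > 0)
           s$d[seq_len(k)]^2 / sum(s$d^2) else rep(0, k),
         centering = mu, singular_values = s$d[seq_len(k)],
         centered = center),
    class = "pca_fit"
  )
}

#' @export
print.pca_fit <- function(x, ...) {
  cat(sprintf("PCA: %d component(s), %.1f%% of variance\n",
              ncol(x$scores), 100 * sum(x$explained_variance)))
  invisible(x)
}

#' Least-squares conversion factor between scores and design
#'
#' Fits `D = T C + E_C` by the pseudo-inverse,
#' `Chat = (T'T)^-1 T' D`. The conversion factor maps PCA scores onto the
#' design matrix (and back), bridging the abstract latent structure and
#' the designed factors.
#'
#' @param scores runs x components score matrix (or a `pca_fit`).
#' @param D runs x terms design-column matrix. When the scores come from a
#'   centered PCA, pass the centered non-intercept design columns (see
#'   [design_columns_centered()]); [pca_coefficients()] does this for you.
#' @return object of class `conversion_fit`: `matrix` (components x
#'   terms, Chat), `residual` (`D - T Chat`), `r_squared` per term.
#' @export
fit_conversion <- function(scores, D) {
  if (inherits(scores, "pca_fit")) scores <- scores$scores
  Tm <- as.matrix(scores)
  Dm <- as_design_values(D)
  if (nrow(Tm) != nrow(Dm)) stop("row counts differ", call. = FALSE)
  cnorm <- sqrt(colMeans(Tm^2))
  if (any(cnorm <= max(cnorm) * 1e-12)) {
    stop("degenerate scores: zero-variance component(s) ",
         paste(which(cnorm <= max(cnorm) * 1e-12), collapse = ", "),
         call. = FALSE)
  }
  C <- pinv(Tm) %*% Dm
  res <- Dm - Tm %*% C
  ss_tot <- colSums(scale(Dm, center = TRUE, scale = FALSE)^2)
  r2 <- ifelse(ss_tot > 0, 1 - colSums(res^2) / ss_tot, NA_real_)
  dimnames(C) <- list(colnames(Tm), colnames(Dm))
  structure(list(matrix = C, residual = res, r_squared = r2),
            class = "conversion_fit")
}

#' @export
print.conversion_fit <- function(x, ...) {
  cat(sprintf("Conversion factor: %d component(s) -> %d term(s)\n",
              nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' Design coefficients from PCA loadings and the conversion factor
#'
#' Implements the loading-route coefficient recovery
#' `Bhat_PCA = (Chat' Chat)^-1 Chat' P'`: since `X ~ T P'` and
#' `D ~ T Chat`, substituting gives `P' ~ Chat B`, so the design
#' coefficients live in the loadings once the conversion factor is known.
#'
#' @param conv a [fit_conversion()] result.
#' @param loadings compounds x components loading matrix (or `pca_fit`).
#' @return terms x compounds coefficient matrix.
#' @export
coefficients_from_loadings <- function(conv, loadings) {
  stopifnot(inherits(conv, "conversion_fit"))
  if (inherits(loadings, "pca_fit")) loadings <- loadings$loadings
  P <- as.matrix(loadings)
  C <- conv$matrix
  if (ncol(P) != nrow(C)) {
    stop("component counts of conversion fit and loadings differ",
         call. = FALSE)
  }
  sv <- svd(C, nu = 0L, nv = 0L)$d
  if (nrow(C) < ncol(C) || min(sv) <= max(sv) * 1e-10) {
    stop("Chat'Chat is singular: more design terms than effective ",
         "components", call. = FALSE)
  }
  B <- pinv(C) %*% t(P)
  rownames(B) <- colnames(C)
  B
}

#' Centered non-intercept design columns
#'
#' Column-centers the design matrix and drops the intercept. Because
#' centering is linear, the centered responses satisfy
#' `Xc = Dc B[-intercept]` with the same non-intercept coefficients, which
#' is the design-side counterpart of mean-centering X before PCA.
#'
#' @param D a [build_design()] result or plain matrix with an intercept
#'   column named `"1"` (or a first column of all ones).
#' @return centered runs x (terms-1) matrix.
#' @export
design_columns_centered <- function(D) {
  Dv <- as_design_values(D)
  icol <- which(colnames(Dv) == "1")
  if (length(icol) == 0L && all(Dv[, 1L] == 1)) icol <- 1L
  if (length(icol) > 0L) Dv <- Dv[, -icol, drop = FALSE]
  scale(Dv, center = TRUE, scale = FALSE)[, , drop = FALSE]
}

#' Design coefficients by the PCA route, end to end
#'
#' Convenience wrapper: centered PCA of X, conversion factor against the
#' centered non-intercept design columns, loading-route coefficients, and
#' an intercept row restored from the column means so the output aligns
#' term-for-term with [fit_mlr()].
#'
#' @param X retention matrix.
#' @param D design matrix ([build_design()] result).
#' @param n_components number of principal components (default 6).
#' @return list with `coefficients` (terms x compounds, intercept first),
#'   `pca`, `conversion`, `method = "PCA"`.
#' @export
pca_coefficients <- function(X, D, n_components = 6L) {
  Xv <- as_response_matrix(X)
  pca <- fit_pca(Xv, n_components, center = TRUE)
  Dc <- design_columns_centered(D)
  conv <- fit_conversion(pca$scores, Dc)
  B_non <- coefficients_from_loadings(conv, pca$loadings)
  Dv <- as_design_values(D)
  icol <- which(colnames(Dv) == "1")
  Dnon <- Dv[, setdiff(seq_len(ncol(Dv)), icol), drop = FALSE]
  b0 <- colMeans(Xv) - as.vector(colMeans(Dnon) %*% B_non)
  B <- rbind(`1` = b0, B_non)
  colnames(B) <- colnames(Xv)
  list(coefficients = B, pca = pca, conversion = conv, method = "PCA")
}

#' ANOVA-simultaneous component analysis
#'
#' Partitions the grand-centered response matrix into per-factor effect
#' matrices (each level's mean row broadcast to its member runs) plus a
#' residual, then runs a PCA on each effect matrix. Because the five
#' levels of each factor are summarized nonparametrically by level means,
#' within-factor curvature (quadratic structure) is captured without a
#' polynomial fit. Balanced designs make the effect matrices mutually
#' orthogonal; unbalanced input is refused unless `force = TRUE`.
#'
#' @param X runs x compounds matrix or `rt_matrix`.
#' @param levels runs x factors matrix/data frame of level assignments
#'   (e.g. the `coded` slot of a [build_design()] on its factorial rows).
#' @param n_components components per effect PCA; `NULL` keeps the
#'   effective rank of each effect matrix.
#' @param force proceed on unbalanced level assignments (effect matrices
#'   then overlap; type-I style means).
#' @return object of class `asca_fit`: `effects` (named list of runs x
#'   compounds effect matrices), `residual_matrix`, `decompositions`
#'   (per-effect `pca_fit`, with `projected_scores` = scores of
#'   effect + residual on the effect loadings), `explained_ss` (fraction
#'   of grand-centered sum of squares per effect and residual),
#'   `centering`, `levels`.
#' @export
fit_asca <- function(X, levels, n_components = NULL, force = FALSE) {
  Xv <- as_response_matrix(X)
  lv <- as.matrix(levels)
  if (nrow(lv) != nrow(Xv)) stop("level assignments/rows mismatch",
                                 call. = FALSE)
  fac_names <- colnames(lv) %||% paste0("factor", seq_len(ncol(lv)))
  combo <- apply(lv, 1L, paste, collapse = "|")
  if (length(unique(table(combo))) != 1L) {
    if (!force) {
      stop("unbalanced level assignments (unequal cell counts); ",
           "rerun on the balanced factorial rows or use force = TRUE",
           call. = FALSE)
    }
    warning("unbalanced design: effect matrices are type-I style level means")
  }
  mu <- colMeans(Xv)
  Xc <- sweep(Xv, 2L, mu)
  effects <- list()
  for (j in seq_len(ncol(lv))) {
    eff <- matrix(0, nrow(Xc), ncol(Xc), dimnames = dimnames(Xc))
    for (l in unique(lv[, j])) {
      rows <- lv[, j] == l
      eff[rows, ] <- rep(colMeans(Xc[rows, , drop = FALSE]),
                         each = sum(rows))
    }
    effects[[fac_names[j]]] <- eff
  }
  residual <- Xc - Reduce(`+`, effects)
  ss_tot <- sum(Xc^2)
  scale_ref <- sqrt(ss_tot)   # rank cutoffs are relative to the data scale,
                              # not to a possibly all-roundoff effect matrix
  decomp <- lapply(effects, function(eff) {
    asca_effect_pca(eff, residual, n_components, scale_ref)
  })
  structure(
    list(effects = effects, residual_matrix = residual,
         decompositions = decomp,
         explained_ss = c(vapply(effects, function(e) sum(e^2) / ss_tot,
                                 numeric(1)),
                          residual = sum(residual^2) / ss_tot),
         centering = mu, levels = lv, scale_ref = scale_ref),
    class = "asca_fit"
  )
}

# Effective rank against an absolute reference scale: singular values below
# 1e-10 of the data norm are treated as numerically zero effects (mean
# partitioning of O(10 min) retention values leaves roundoff near 1e-13).
rank_at_scale <- function(M, scale_ref) {
  d <- svd(M, nu = 0L, nv = 0L)$d
  sum(d > 1e-10 * max(scale_ref, d[1L], 0))
}

# PCA of one effect matrix; components limited to effective rank when
# n_components is NULL; held-out residual projected onto the loadings.
asca_effect_pca <- function(eff, residual, n_components, scale_ref) {
  rank <- rank_at_scale(eff, scale_ref)
  k <- if (is.null(n_components)) max(rank, 1L) else min(n_components,
                                                         min(dim(eff)))
  if (rank == 0L) k <- 1L
  fit <- fit_pca(eff, k, center = FALSE)
  fit$effective_rank <- rank
  fit$projected_scores <- (eff + residual) %*% fit$loadings
  fit
}

#' @export
print.asca_fit <- function(x, ...) {
  cat("ASCA partition; explained sum of squares:\n")
  print(round(x$explained_ss, 4))
  invisible(x)
}

#' Design coefficients by the ASCA route
#'
#' Concatenates the per-effect scores and loadings (and, by default, those
#' of the residual block, so that interaction structure a balanced
#' main-effect partition relegates to the residual remains recoverable),
#' fits the scores-to-design conversion factor on the concatenated scores,
#' and recovers coefficients from the concatenated loadings. The output is
#' aligned term-for-term with [fit_mlr()] for scatter comparison.
#'
#' @param asca an [fit_asca()] result.
#' @param D the design matrix of the same runs.
#' @param include_residual include the residual-block PCA in the
#'   concatenation (default TRUE).
#' @param n_components_effect cap on the components taken from each
#'   effect block (default 2, the usual two-component ASCA effect
#'   representation). Weak trailing effect components carry level-mean
#'   noise with near-zero conversion rows, which the pseudo-inverse would
#'   amplify into the coefficients; capping keeps the recovery stable.
#' @param n_components_residual components for the residual block; `NULL`
#'   keeps its effective rank, capped at the number of design terms.
#' @return list with `coefficients` (terms x compounds, intercept
#'   restored), `conversion`, `method = "ASCA"`.
#' @export
asca_coefficients <- function(asca, D, include_residual = TRUE,
                              n_components_effect = 2L,
                              n_components_residual = NULL) {
  stopifnot(inherits(asca, "asca_fit"))
  Dv <- as_design_values(D)
  if (nrow(Dv) != nrow(asca$residual_matrix)) {
    stop("design and ASCA fit have different run counts", call. = FALSE)
  }
  # keep only components up to each effect's effective rank; a factor with
  # no effect contributes nothing to the concatenation
  T_list <- list(); P_list <- list()
  for (nm in names(asca$decompositions)) {
    d <- asca$decompositions[[nm]]
    r <- min(d$effective_rank, ncol(d$scores), n_components_effect)
    if (r > 0L) {
      T_list[[nm]] <- d$scores[, seq_len(r), drop = FALSE]
      P_list[[nm]] <- d$loadings[, seq_len(r), drop = FALSE]
    }
  }
  if (include_residual) {
    R <- asca$residual_matrix
    rank <- rank_at_scale(R, asca$scale_ref)
    k <- if (is.null(n_components_residual)) {
      min(max(rank, 1L), ncol(Dv))
    } else {
      n_components_residual
    }
    if (rank > 0L) {
      rp <- fit_pca(R, min(k, rank), center = FALSE)
      T_list$residual <- rp$scores
      P_list$residual <- rp$loadings
    }
  }
  if (length(T_list) == 0L) {
    stop("all ASCA effects are numerically zero; nothing to convert",
         call. = FALSE)
  }
  T_all <- do.call(cbind, T_list)
  P_all <- do.call(cbind, P_list)
  Dc <- design_columns_centered(D)
  conv <- fit_conversion(T_all, Dc)
  B_non <- coefficients_from_loadings(conv, P_all)
  icol <- which(colnames(Dv) == "1")
  Dnon <- Dv[, setdiff(seq_len(ncol(Dv)), icol), drop = FALSE]
  b0 <- asca$centering - as.vector(colMeans(Dnon) %*% B_non)
  B <- rbind(`1` = b0, B_non)
  colnames(B) <- colnames(asca$residual_matrix)
  list(coefficients = B, conversion = conv, method = "ASCA")
}
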