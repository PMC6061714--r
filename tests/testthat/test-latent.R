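test_that("PCA reconstructs and keeps loadings orthonormal", {
  set.seed(7)
  X <- matrix(rnorm(30 * 12), 30, 12)
  p <- fit_pca(X, 5)
  expect_equal(crossprod(p$loadings), diag(5), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(sweep(p$scores %*% t(p$loadings) + p$residual, 2,
                     -p$centering),
               X, tolerance = 1e-10)
  expect_lt(max(abs(crossprod(p$scores) - diag(diag(crossprod(p$scores))))),
            1e-8)
  # sign convention: largest-magnitude loading entry positive
  for (j in 1:5) {
    v <- p$loadings[, j]
    expect_gt(v[which.max(abs(v))], 0)
  }
})

test_that("a rank-one matrix is explained by one component", {
  X <- outer(1:10, c(2, -1, 3))
  p <- fit_pca(X, 1, center = FALSE)
  expect_lt(max(abs(p$residual)), 1e-10)
  expect_equal(p$explained_variance, 1, tolerance = 1e-12)
})

test_that("explained variances match an independent eigendecomposition", {
  X <- matrix(c(1, 2, 3, 2, 1, 5), 3, 2)
  p <- fit_pca(X, 2)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  ev <- eigen(crossprod(Xc), symmetric = TRUE)$values
  expect_equal(p$explained_variance, ev / sum(ev), tolerance = 1e-12)
  expect_true(all(diff(p$explained_variance) <= 1e-15))
  expect_lte(sum(p$explained_variance), 1 + 1e-12)
  expect_error(fit_pca(X, 3), "n_components")
})

test_that("the conversion factor is identity when scores equal the design", {
  Dc <- design_columns_centered(ref_design())
  cv <- fit_conversion(Dc, Dc)
  expect_equal(cv$matrix, diag(ncol(Dc)), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_lt(max(abs(cv$residual)), 1e-10)
})

test_that("scores spanning the design column space convert with R squared one", {
  Dc <- design_columns_centered(ref_design())
  Tm <- qr.Q(qr(Dc))          # orthonormal basis of the design column space
  cv <- fit_conversion(Tm, Dc)
  expect_lt(max(abs(cv$residual)), 1e-10)
  expect_equal(unname(cv$r_squared), rep(1, ncol(Dc)), tolerance = 1e-10)
})

test_that("scores orthogonal to the design convert to near-zero entries", {
  D <- ref_design()
  Dc <- design_columns_centered(D)
  set.seed(3)
  raw <- matrix(rnorm(30 * 2), 30, 2)
  Tm <- raw - cbind(1, Dc) %*% (pinv(cbind(1, Dc)) %*% raw)
  cv <- fit_conversion(Tm, Dc)
  expect_lt(max(abs(cv$matrix)), 1e-8)
  expect_error(fit_conversion(cbind(Tm, 0), Dc), "degenerate")
})

test_that("identity conversion returns the loadings transposed", {
  set.seed(11)
  P <- qr.Q(qr(matrix(rnorm(20 * 4), 20, 4)))
  cv <- structure(list(matrix = diag(4),
                       residual = matrix(0, 10, 4),
                       r_squared = rep(1, 4)),
                  class = "conversion_fit")
  expect_equal(coefficients_from_loadings(cv, P), t(P), ignore_attr = TRUE)
})

test_that("the loading route reproduces MLR on noiseless designed data", {
  ds <- noiseless_dataset(n_compounds = 25L)
  mlr <- fit_mlr(ds$retention, ds$design)
  pr <- pca_coefficients(ds$retention, ds$design, n_components = 5)
  expect_lt(max(abs(pr$coefficients - mlr$coefficients)) /
              max(abs(mlr$coefficients)), 1e-8)
})

test_that("a singular conversion factor is refused", {
  ds <- noiseless_dataset(n_compounds = 25L)
  # 3 components cannot carry 5 design terms
  p <- fit_pca(ds$retention$values, 3)
  cv <- fit_conversion(p$scores, design_columns_centered(ds$design))
  expect_error(coefficients_from_loadings(cv, p$loadings), "singular")
})

test_that("the coefficient route is invariant to joint score/loading rotation", {
  ds <- noiseless_dataset(n_compounds = 25L)
  p <- fit_pca(ds$retention$values, 5)
  Dc <- design_columns_centered(ds$design)
  B0 <- coefficients_from_loadings(fit_conversion(p$scores, Dc), p$loadings)
  set.seed(99)
  for (i in 1:5) {
    R <- qr.Q(qr(matrix(rnorm(25), 5, 5)))
    Br <- coefficients_from_loadings(
      fit_conversion(p$scores %*% R, Dc), p$loadings %*% R)
    expect_equal(Br, B0, tolerance = 1e-8)
  }
})

test_that("latent contamination makes the PCA route diverge from MLR on small terms", {
  spec <- ref_spec()
  small <- c("temperature^2", "pH:temperature")
  # noiseless reference discrepancy
  tr0 <- ground_truth(spec, n_compounds = 40L, seed = 17L, noise_sd = 0,
                      n_latent = 0L)
  ds0 <- simulate_retention(spec, tr0)
  d0 <- max(abs(pca_coefficients(ds0$retention, ds0$design, 5)$coefficients[small, ] -
                  fit_mlr(ds0$retention, ds0$design)$coefficients[small, ]))
  # strong latent factor, 6 components
  tr1 <- ground_truth(spec, n_compounds = 40L, seed = 17L, noise_sd = 0.02,
                      n_latent = 1L, latent_loading_sd = 0.1)
  ds1 <- simulate_retention(spec, tr1)
  d1 <- max(abs(pca_coefficients(ds1$retention, ds1$design, 6)$coefficients[small, ] -
                  fit_mlr(ds1$retention, ds1$design)$coefficients[small, ]))
  expect_gt(d1, 10 * d0)
})

test_that("ASCA conserves the grand-centered matrix and separates effects", {
  ds <- noiseless_dataset(n_compounds = 18L)
  fac <- !ds$design$is_replicate
  X <- ds$retention$values[fac, ]
  af <- fit_asca(X, ds$design$coded[fac, ])
  Xc <- scale(X, center = TRUE, scale = FALSE)
  recon <- Reduce(`+`, af$effects) + af$residual_matrix
  expect_lt(max(abs(recon - Xc)), 1e-10)
  # balanced effects are mutually orthogonal
  expect_lt(abs(sum(af$effects$pH * af$effects$temperature)), 1e-10)
  expect_true(all(af$explained_ss >= 0))
  expect_equal(sum(af$explained_ss), 1, tolerance = 1e-10)
})

test_that("a factor simulated with zero effect yields a null effect matrix", {
  spec <- ref_spec()
  tr <- ground_truth(spec, n_compounds = 12L, seed = 23L, noise_sd = 0,
                     n_latent = 0L)
  tr$true_coefficients[c("temperature", "temperature^2", "pH:temperature"), ] <- 0
  ds <- simulate_retention(spec, tr)
  fac <- !ds$design$is_replicate
  af <- fit_asca(ds$retention$values[fac, ], ds$design$coded[fac, ])
  expect_lt(sqrt(sum(af$effects$temperature^2)), 1e-10)
})

test_that("unbalanced assignments are refused unless forced", {
  ds <- noiseless_dataset(n_compounds = 5L)
  # the five extra center runs unbalance the level counts
  expect_error(fit_asca(ds$retention$values, ds$design$coded), "unbalanced")
  expect_warning(fit_asca(ds$retention$values, ds$design$coded, force = TRUE),
                 "unbalanced")
})

test_that("ASCA-route coefficients match MLR on noiseless designed data", {
  ds <- noiseless_dataset(n_compounds = 25L)
  fac <- !ds$design$is_replicate
  mlr <- fit_mlr(ds$retention, ds$design)
  af <- fit_asca(ds$retention$values[fac, ], ds$design$coded[fac, ])
  ac <- asca_coefficients(af, ds$design$values[fac, ])
  expect_lt(max(abs(ac$coefficients - mlr$coefficients)), 1e-6)
})

test_that("a zero-effect factor gets near-zero ASCA-route coefficients", {
  spec <- ref_spec()
  tr <- ground_truth(spec, n_compounds = 15L, seed = 31L, noise_sd = 0.005,
                     n_latent = 0L)
  tr$true_coefficients[c("temperature", "temperature^2", "pH:temperature"), ] <- 0
  ds <- simulate_retention(spec, tr)
  fac <- !ds$design$is_replicate
  af <- fit_asca(ds$retention$values[fac, ], ds$design$coded[fac, ])
  ac <- asca_coefficients(af, ds$design$values[fac, ])
  expect_lt(max(abs(ac$coefficients["temperature", ])), 0.01)
})

test_that("large terms agree between ASCA and MLR under latent contamination", {
  ds <- default_dataset(n_compounds = 40L, seed = 19L)
  fac <- !ds$design$is_replicate
  mlr <- fit_mlr(ds$retention, ds$design)
  af <- fit_asca(ds$retention$values[fac, ], ds$design$coded[fac, ])
  ac <- asca_coefficients(af, ds$design$values[fac, ])
  for (term in c("pH", "temperature", "pH^2")) {
    truth_mag <- abs(ds$truth$true_coefficients[term, ])
    strong <- truth_mag > 5 * ds$truth$noise_sd
    if (sum(strong) >= 3) {
      expect_gt(cor(mlr$coefficients[term, strong],
                    ac$coefficients[term, strong]), 0.99)
    }
  }
})
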