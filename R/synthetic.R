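#' Default adduct mass-difference table
#'
#' Mass differences (Thomson, singly charged) of common positive-mode
#' adducts relative to the protonated species: sodium, ammonium, and
#' potassium.
#'
#' @return named numeric vector of m/z deltas.
#' @export
adduct_table_default <- function() {
  c("M+Na" = 21.98194, "M+NH4" = 17.02655, "M+K" = 37.95588)
}

# Mass of one neutron-equivalent isotope spacing (Th at z = 1).
ISOTOPE_SPACING <- 1.00335

#' Ground truth for the synthetic retention study
#'
#' Draws per-compound design coefficients with the effect structure the
#' retention study exhibits: linear temperature coefficients negative for
#' most compounds (about 10 in 98 positive), linear and quadratic pH
#' coefficients of both signs with non-negligible quadratic magnitude, and
#' temperature-quadratic and interaction terms far below the replicate
#' repeatability error. One or more latent uncontrolled factors enter as a
#' low-rank additive term. Units are minutes per coded unit.
#'
#' Compound m/z values (for the peak-list stage) are drawn with enforced
#' separation so that no pair of compounds mimics an isotope or adduct
#' mass relation within the classification tolerances: the species of the
#' digest are well resolved in m/z.
#'
#' @param spec a [design_spec()]; defaults to [hsa_design_spec()].
#' @param n_compounds number of monoisotopic species (default 98).
#' @param seed RNG seed recorded in the truth object.
#' @param noise_sd i.i.d. Gaussian measurement noise SD, minutes.
#' @param n_latent number of latent uncontrolled factors.
#' @param latent_loading_sd SD of per-compound latent loadings (minutes).
#' @param latent_scores_scale SD of per-run latent scores (unitless).
#' @param n_temp_positive number of compounds whose retention increases
#'   with temperature.
#' @param rt_range elution window (minutes) over which the mean retention
#'   times are spread.
#' @param coef_sd named numeric vector of coefficient scales
#'   (`ph_linear`, `ph_quad`, `temp_linear`, `temp_linear_pos`,
#'   `temp_quad`, `interaction`), minutes per coded unit.
#' @return object of class `ground_truth`: coefficients, latent structure,
#'   noise level, base retention times, m/z, charge, and the seed.
#' @export
ground_truth <- function(spec = hsa_design_spec(),
                         n_compounds = 98L,
                         seed = 1L,
                         noise_sd = 0.02,
                         n_latent = 1L,
                         latent_loading_sd = 0.03,
                         latent_scores_scale = 1,
                         n_temp_positive = 10L,
                         rt_range = c(5, 38),
                         coef_sd = c(ph_linear = 0.15, ph_quad = 0.05,
                                     temp_linear = 0.04, temp_linear_pos = 0.01,
                                     temp_quad = 0.001, interaction = 0.001)) {
  stopifnot(inherits(spec, "design_spec"), n_compounds >= 1L,
            noise_sd >= 0, n_latent >= 0L)
  nms <- vapply(spec$factors, `[[`, character(1), "name")
  if (length(nms) != 2L) {
    stop("the default ground truth assumes a two-factor design", call. = FALSE)
  }
  set.seed(seed)
  base_rts <- sort(stats::runif(n_compounds, rt_range[1L], rt_range[2L]))
  compound_labels <- sprintf("cmp%03d", seq_len(n_compounds))

  terms <- spec$model_terms
  B <- matrix(0, length(terms), n_compounds,
              dimnames = list(terms, compound_labels))
  B["1", ] <- base_rts
  lin_p <- nms[1L]; lin_t <- nms[2L]
  qp <- paste0(lin_p, "^2"); qt <- paste0(lin_t, "^2")
  inter <- paste0(lin_p, ":", lin_t)
  if (lin_p %in% terms) B[lin_p, ] <- stats::rnorm(n_compounds, 0, coef_sd[["ph_linear"]])
  if (qp %in% terms) B[qp, ] <- stats::rnorm(n_compounds, 0, coef_sd[["ph_quad"]])
  if (lin_t %in% terms) {
    b_t <- -abs(stats::rnorm(n_compounds, 0.10, coef_sd[["temp_linear"]]))
    pos <- sample.int(n_compounds, min(n_temp_positive, n_compounds))
    b_t[pos] <- abs(stats::rnorm(length(pos), 0.03, coef_sd[["temp_linear_pos"]]))
    B[lin_t, ] <- b_t
  }
  if (qt %in% terms) B[qt, ] <- stats::rnorm(n_compounds, 0, coef_sd[["temp_quad"]])
  if (inter %in% terms) B[inter, ] <- abs(stats::rnorm(n_compounds, 0, coef_sd[["interaction"]]))

  L <- if (n_latent > 0L) {
    matrix(stats::rnorm(n_latent * n_compounds, 0, latent_loading_sd),
           n_latent, n_compounds,
           dimnames = list(sprintf("latent%d", seq_len(n_latent)),
                           compound_labels))
  } else {
    matrix(0, 0L, n_compounds, dimnames = list(NULL, compound_labels))
  }

  charge <- sample(1:2, n_compounds, replace = TRUE)
  mz <- assign_separated_mz(n_compounds)

  structure(
    list(true_coefficients = B,
         latent_loadings = L,
         latent_scores_scale = latent_scores_scale,
         noise_sd = noise_sd,
         base_rts = base_rts,
         compound_labels = compound_labels,
         compound_mz = mz,
         charge = charge,
         seed = as.integer(seed)),
    class = "ground_truth"
  )
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "Ground truth: %d compounds, %d latent factor(s), noise SD %g min, seed %d\n",
    length(x$base_rts), nrow(x$latent_loadings), x$noise_sd, x$seed))
  invisible(x)
}

# Sequentially draw m/z values on a loose lattice, rejecting any candidate
# whose derived species (isotopes, adducts) would fall within `gap` Th of an
# isotope/adduct mass relation to any already-placed compound's species.
# Uses the current RNG stream.
assign_separated_mz <- function(n, gap = 0.02) {
  iso <- ISOTOPE_SPACING
  # species offsets a compound can emit (z in {1,2}; adducts at z = 1)
  offsets <- c(0, iso / 2, iso, 1.5 * iso, 2 * iso, adduct_table_default())
  # mass relations the classifier tests (isotope spacings for z 1..3, adducts)
  rels <- c(outer(1:2, 1:3, function(k, z) k * iso / z), adduct_table_default())
  sdiff <- unique(as.vector(outer(offsets, offsets, "-")))
  forbidden <- sort(unique(as.vector(outer(c(0, rels, -rels), sdiff, "-"))))
  near_forbidden <- function(d) {
    i <- findInterval(d, forbidden)
    lo <- ifelse(i >= 1L, d - forbidden[pmax(i, 1L)], Inf)
    hi <- ifelse(i < length(forbidden), forbidden[pmin(i + 1L, length(forbidden))] - d, Inf)
    pmin(abs(lo), abs(hi)) <= gap
  }
  mz <- numeric(n)
  reach <- max(abs(forbidden)) + 1
  for (i in seq_len(n)) {
    base <- 300 + 11 * (i - 1)
    for (try in 1:500) {
      cand <- base + stats::runif(1, 0, 8)
      close_idx <- which(abs(mz[seq_len(i - 1L)] - cand) < reach)
      ok <- length(close_idx) == 0L ||
        !any(near_forbidden(cand - mz[close_idx]))
      if (ok) break
    }
    if (!ok) stop("could not place a separated m/z value", call. = FALSE)
    mz[i] <- cand
  }
  mz
}

#' Simulate a factorial retention-time dataset
#'
#' Builds the design matrix for `spec` and generates
#' `X = D B_true + S L + E`: the designed polynomial effects, a low-rank
#' latent contribution from uncontrolled factors (per-run scores drawn
#' i.i.d. normal), and i.i.d. Gaussian measurement noise. Fully
#' reproducible from the seed.
#'
#' @param spec a [design_spec()].
#' @param truth a [ground_truth()]; its dimensions must match `spec`.
#' @param seed RNG seed for the run-level draws (latent scores and noise);
#'   defaults to `truth$seed`.
#' @return object of class `synthetic_dataset`: list with `design`
#'   (a `design_matrix`), `retention` (an `rt_matrix`), `truth`,
#'   `latent_scores`, and `peaks` (`NULL` until [generate_peak_lists()]).
#' @examples
#' tr <- ground_truth(n_compounds = 10, seed = 7)
#' ds <- simulate_retention(hsa_design_spec(), tr)
#' dim(ds$retention$values)  # 30 x 10
#' @export
simulate_retention <- function(spec, truth, seed = truth$seed) {
  stopifnot(inherits(spec, "design_spec"), inherits(truth, "ground_truth"))
  design <- build_design(spec)
  B <- truth$true_coefficients
  if (!identical(design$term_labels, rownames(B))) {
    stop("model terms of spec and truth differ", call. = FALSE)
  }
  n_runs <- nrow(design$values)
  n_cmp <- ncol(B)
  set.seed(seed)
  n_latent <- nrow(truth$latent_loadings)
  S <- matrix(stats::rnorm(n_runs * n_latent, 0, truth$latent_scores_scale),
              n_runs, n_latent)
  E <- matrix(stats::rnorm(n_runs * n_cmp, 0, truth$noise_sd), n_runs, n_cmp)
  X <- design$values %*% B + (if (n_latent > 0L) S %*% truth$latent_loadings else 0) + E
  dimnames(X) <- list(design$run_labels, truth$compound_labels)
  retention <- structure(
    list(values = X, run_labels = design$run_labels,
         compound_labels = truth$compound_labels,
         compound_mz = truth$compound_mz, charge = truth$charge),
    class = "rt_matrix"
  )
  structure(
    list(design = design, retention = retention, truth = truth,
         latent_scores = S, peaks = NULL, seed = as.integer(seed)),
    class = "synthetic_dataset"
  )
}

#' @export
print.rt_matrix <- function(x, ...) {
  cat(sprintf("Retention matrix: %d runs x %d compounds (minutes)\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  print(x$retention)
  print(x$truth)
  if (!is.null(x$peaks)) {
    cat(sprintf("Peak lists: %d peaks over %d runs\n", nrow(x$peaks),
                length(unique(x$peaks$run))))
  }
  invisible(x)
}

#' Peak-list generation settings
#'
#' @param n_isotopes number of isotope peaks per monoisotopic species
#'   (0 disables isotopes).
#' @param isotope_ratios intensity of each isotope peak relative to the
#'   monoisotopic peak; must be decreasing and below 1 so the monoisotopic
#'   peak stays the most intense of its envelope.
#' @param adducts named m/z-delta vector ([adduct_table_default()]); `NULL`
#'   or empty disables adducts.
#' @param adduct_fraction fraction of singly charged compounds that emit an
#'   adduct peak.
#' @param adduct_ratio adduct intensity relative to the monoisotopic peak.
#' @return list of settings for [generate_peak_lists()].
#' @export
isotope_config <- function(n_isotopes = 2L,
                           isotope_ratios = c(0.6, 0.25),
                           adducts = adduct_table_default(),
                           adduct_fraction = 0.3,
                           adduct_ratio = 0.3) {
  stopifnot(n_isotopes >= 0L, length(isotope_ratios) >= n_isotopes)
  if (n_isotopes > 0L) {
    r <- isotope_ratios[seq_len(n_isotopes)]
    stopifnot(all(r > 0), all(r < 1), !is.unsorted(rev(r)))
  }
  list(n_isotopes = as.integer(n_isotopes),
       isotope_ratios = isotope_ratios,
       adducts = adducts,
       adduct_fraction = adduct_fraction,
       adduct_ratio = adduct_ratio)
}

#' Generate per-run LC-MS peak lists from a simulated dataset
#'
#' Each compound contributes a monoisotopic peak at its (run-specific)
#' retention time, optionally accompanied by isotope peaks at spacings of
#' `1.00335/z` Th and, for singly charged compounds, an adduct peak at a
#' configured mass delta. Envelope members co-elute at the compound's
#' retention time. Ground-truth classes are recorded for recovery tests.
#'
#' @param dataset a [simulate_retention()] result whose truth carries m/z
#'   values.
#' @param config an [isotope_config()].
#' @param seed RNG seed for intensities and adduct assignment; defaults to
#'   the dataset seed.
#' @return the dataset with `$peaks` set: a data frame with columns
#'   `run`, `mz`, `rt`, `intensity`, `charge`, `compound`, `true_class`
#'   (`"monoisotopic"`, `"isotope"`, or `"adduct"`).
#' @export
generate_peak_lists <- function(dataset, config = isotope_config(),
                                seed = dataset$seed) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  rt <- dataset$retention
  if (is.null(rt$compound_mz)) stop("compound m/z values missing", call. = FALSE)
  set.seed(seed + 1L)
  n_cmp <- length(rt$compound_labels)
  base_int <- stats::rlnorm(n_cmp, meanlog = log(1e6), sdlog = 0.8)
  z1 <- which(dataset$truth$charge == 1L)
  has_adduct <- rep(FALSE, n_cmp)
  adduct_of <- rep(NA_character_, n_cmp)
  if (length(config$adducts) > 0L && config$adduct_fraction > 0 &&
      length(z1) > 0L) {
    chosen <- z1[stats::runif(length(z1)) < config$adduct_fraction]
    has_adduct[chosen] <- TRUE
    adduct_of[chosen] <- sample(names(config$adducts), length(chosen),
                                replace = TRUE)
  }
  runs <- rt$run_labels
  out <- vector("list", length(runs))
  for (r in seq_along(runs)) {
    jitter <- stats::rlnorm(n_cmp, 0, 0.1)
    rows <- vector("list", n_cmp)
    for (i in seq_len(n_cmp)) {
      z <- dataset$truth$charge[i]
      mz0 <- rt$compound_mz[i]
      rt0 <- rt$values[r, i]
      inten <- base_int[i] * jitter[i]
      mzs <- mz0
      ints <- inten
      cls <- "monoisotopic"
      if (config$n_isotopes > 0L) {
        k <- seq_len(config$n_isotopes)
        mzs <- c(mzs, mz0 + k * ISOTOPE_SPACING / z)
        ints <- c(ints, inten * config$isotope_ratios[k])
        cls <- c(cls, rep("isotope", config$n_isotopes))
      }
      if (has_adduct[i]) {
        mzs <- c(mzs, mz0 + config$adducts[[adduct_of[i]]])
        ints <- c(ints, inten * config$adduct_ratio)
        cls <- c(cls, "adduct")
      }
      rows[[i]] <- data.frame(
        run = runs[r], mz = mzs, rt = rt0, intensity = ints,
        charge = z, compound = rt$compound_labels[i], true_class = cls,
        stringsAsFactors = FALSE)
    }
    out[[r]] <- do.call(rbind, rows)
  }
  peaks <- do.call(rbind, out)
  rownames(peaks) <- NULL
  dataset$peaks <- peaks
  dataset
}

#' Write simulated outputs as plain-text files
#'
#' Writes `design.csv`, `retention.csv` (runs x compounds, first column the
#' run label), `peaks.csv` when peak lists are present, and `truth.json`
#' (coefficients, latent structure, noise level, seed).
#'
#' @param dataset a `synthetic_dataset`.
#' @param dir output directory, created if absent.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_design_csv(dataset$design, file.path(dir, "design.csv"))
  write_retention_csv(dataset$retention, file.path(dir, "retention.csv"))
  if (!is.null(dataset$peaks)) {
    utils::write.csv(dataset$peaks, file.path(dir, "peaks.csv"),
                     row.names = FALSE)
  }
  tr <- dataset$truth
  jsonlite::write_json(
    list(true_coefficients = tr$true_coefficients,
         term_labels = rownames(tr$true_coefficients),
         compound_labels = tr$compound_labels,
         latent_loadings = tr$latent_loadings,
         latent_scores_scale = tr$latent_scores_scale,
         noise_sd = tr$noise_sd, base_rts = tr$base_rts,
         compound_mz = tr$compound_mz, charge = tr$charge,
         seed = tr$seed, dataset_seed = dataset$seed),
    file.path(dir, "truth.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' Write / read a retention matrix as CSV
#'
#' First column `run`, one column per compound. m/z and charge metadata, if
#' present, go to a JSON sidecar `<path>.meta.json`.
#'
#' @param rt an `rt_matrix`.
#' @param path CSV path.
#' @export
write_retention_csv <- function(rt, path) {
  stopifnot(inherits(rt, "rt_matrix"))
  df <- data.frame(run = rt$run_labels, rt$values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(rt$compound_mz)) {
    jsonlite::write_json(
      list(compound_labels = rt$compound_labels,
           compound_mz = rt$compound_mz, charge = rt$charge),
      paste0(path, ".meta.json"), digits = NA, auto_unbox = TRUE)
  }
  invisible(path)
}

#' @rdname write_retention_csv
#' @export
read_retention_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"run" %in% names(df)) {
    stop("retention CSV lacks a 'run' column", call. = FALSE)
  }
  vals <- as.matrix(df[, setdiff(names(df), "run"), drop = FALSE])
  if (!is.numeric(vals) || anyNA(vals)) {
    bad <- colnames(vals)[apply(vals, 2L, function(v) anyNA(suppressWarnings(as.numeric(v))))]
    stop("non-numeric retention values in column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  rownames(vals) <- df$run
  mz <- charge <- NULL
  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::fromJSON(meta_path)
    mz <- meta$compound_mz
    charge <- meta$charge
  }
  structure(
    list(values = vals, run_labels = df$run, compound_labels = colnames(vals),
         compound_mz = mz, charge = charge),
    class = "rt_matrix"
  )
}
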