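#' Default run configuration
#'
#' One list describing the whole study: the two-factor five-level design
#' with five center replicates, the synthetic ground-truth parameters (98
#' compounds, measurement noise of 0.02 min, one latent uncontrolled
#' factor), the isotope/adduct filtering tolerances, and the analysis
#' settings (six principal components, 0.2 min overlap window).
#'
#' @param seed integer seed recorded in the config.
#' @return a named list accepted by [rt_simulate()], [rt_analyze()],
#'   [rt_recover()].
#' @export
default_run_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    design = list(
      factors = list(
        list(name = "pH", center = 3.75, step = 0.25),
        list(name = "temperature", center = 40.0, step = 2.5)
      ),
      center_replicates = 5L
    ),
    simulation = list(
      n_compounds = 98L,
      noise_sd = 0.02,
      n_latent = 1L,
      latent_loading_sd = 0.03,
      latent_scores_scale = 1,
      n_temp_positive = 10L
    ),
    filtering = list(
      mz_tolerance = 0.005,
      rt_tolerance = 0.1
    ),
    analysis = list(
      n_components = 6L,
      overlap_window = 0.2,
      component_range = 1:8
    )
  )
}

#' Validate a run configuration
#'
#' Checks the schema (sections, field types, ranges) and fills defaults
#' for missing optional fields. Errors name the offending field.
#'
#' @param config a list as produced by [default_run_config()] or read from
#'   YAML/JSON via [read_run_config()].
#' @return the normalized config.
#' @export
validate_run_config <- function(config) {
  def <- default_run_config()
  if (!is.list(config)) stop("config must be a list", call. = FALSE)
  for (sec in c("design", "simulation", "filtering", "analysis")) {
    if (is.null(config[[sec]])) config[[sec]] <- def[[sec]]
    config[[sec]] <- utils::modifyList(def[[sec]], config[[sec]])
  }
  if (is.null(config$seed)) config$seed <- def$seed
  config$seed <- as.integer(config$seed)
  # design section is validated by construction
  design_spec_from_list(config$design)
  sim <- config$simulation
  check_num <- function(x, name, min = 0) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min) {
      stop(sprintf("config field '%s' must be a number >= %g", name, min),
           call. = FALSE)
    }
  }
  check_num(sim$n_compounds, "simulation.n_compounds", 1)
  check_num(sim$noise_sd, "simulation.noise_sd", 0)
  check_num(sim$n_latent, "simulation.n_latent", 0)
  check_num(config$filtering$mz_tolerance, "filtering.mz_tolerance", 1e-6)
  check_num(config$filtering$rt_tolerance, "filtering.rt_tolerance", 1e-6)
  check_num(config$analysis$n_components, "analysis.n_components", 1)
  check_num(config$analysis$overlap_window, "analysis.overlap_window", 0)
  config
}

#' Read a run configuration from YAML or JSON
#'
#' @param path config file path (`.json` parsed as JSON, else YAML).
#' @return validated config list.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  validate_run_config(raw)
}

# Deterministic 31-bit polynomial hash of the serialized config, so every
# output can be traced back to the exact settings that produced it.
config_hash <- function(config) {
  s <- as.character(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA))
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

stage_log <- function(stage, t0, verbose) {
  if (verbose) {
    message(sprintf("[%s] done in %.2f s", stage,
                    as.numeric(Sys.time()) - t0))
  }
}

#' Simulate a dataset and write it to disk
#'
#' Builds the design from the config, draws the ground truth and the
#' retention matrix, generates the peak lists, and writes `design.csv`,
#' `retention.csv`, `peaks.csv`, `truth.json`, and `metadata.json`
#' (config, config hash, seed) into `out_dir`.
#'
#' @param config a run config (validated via [validate_run_config()]).
#' @param out_dir output directory.
#' @param seed overrides `config$seed` when given.
#' @param peaks also generate peak lists (default TRUE).
#' @param verbose log stage timings (default TRUE).
#' @return the `synthetic_dataset`, invisibly.
#' @export
rt_simulate <- function(config = default_run_config(), out_dir,
                        seed = NULL, peaks = TRUE, verbose = TRUE) {
  config <- validate_run_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  t0 <- as.numeric(Sys.time())
  spec <- design_spec_from_list(config$design)
  sim <- config$simulation
  truth <- ground_truth(
    spec, n_compounds = as.integer(sim$n_compounds), seed = config$seed,
    noise_sd = sim$noise_sd, n_latent = as.integer(sim$n_latent),
    latent_loading_sd = sim$latent_loading_sd,
    latent_scores_scale = sim$latent_scores_scale,
    n_temp_positive = as.integer(sim$n_temp_positive))
  ds <- simulate_retention(spec, truth)
  if (peaks) ds <- generate_peak_lists(ds)
  write_dataset(ds, out_dir)
  jsonlite::write_json(
    list(config = config, config_hash = config_hash(config),
         seed = config$seed),
    file.path(out_dir, "metadata.json"), auto_unbox = TRUE, digits = NA)
  stage_log("simulate", t0, verbose)
  invisible(ds)
}

#' Run the full analysis on a dataset directory
#'
#' Stages: isotope/adduct filtering (when `peaks.csv` is present, logged
#' and skipped otherwise), MLR with pure-error confidence intervals, PCA
#' and the scores-to-design conversion factor, PCA-route coefficients,
#' ASCA on the balanced factorial rows with ASCA-route coefficients,
#' per-compound PCR with overlap exclusion, and design-level prediction.
#' Each stage writes its table as CSV into `out_dir`; failures are
#' re-signalled with the stage name.
#'
#' @param config run config.
#' @param data_dir directory with `retention.csv` (and optionally
#'   `peaks.csv`), as written by [rt_simulate()].
#' @param out_dir report directory, created if absent.
#' @param cv run the cross-validated PCR columns (default TRUE).
#' @param verbose log stage timings.
#' @return a list of the in-memory results, invisibly.
#' @export
rt_analyze <- function(config, data_dir, out_dir, cv = TRUE, verbose = TRUE) {
  config <- validate_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  run_stage <- function(stage, expr) {
    t0 <- as.numeric(Sys.time())
    res <- tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
    stage_log(stage, t0, verbose)
    res
  }
  spec <- design_spec_from_list(config$design)
  design <- build_design(spec)

  rt_path <- file.path(data_dir, "retention.csv")
  if (!file.exists(rt_path)) {
    stop("stage 'load' failed: no retention.csv in ", data_dir, call. = FALSE)
  }
  retention <- run_stage("load", read_retention_csv(rt_path))
  if (nrow(retention$values) != nrow(design$values)) {
    stop(sprintf("stage 'load' failed: retention has %d runs, design %d",
                 nrow(retention$values), nrow(design$values)), call. = FALSE)
  }

  filtered <- NULL
  peaks_path <- file.path(data_dir, "peaks.csv")
  if (file.exists(peaks_path)) {
    filtered <- run_stage("filtering", {
      pk <- utils::read.csv(peaks_path)
      cls <- classify_peaks(pk,
                            mz_tolerance = config$filtering$mz_tolerance,
                            rt_tolerance = config$filtering$rt_tolerance)
      mono <- filter_monoisotopic(cls)
      utils::write.csv(mono, file.path(out_dir, "peaks_monoisotopic.csv"),
                       row.names = FALSE)
      if (verbose) {
        message(sprintf("[filtering] %d peaks -> %d monoisotopic",
                        nrow(cls), nrow(mono)))
      }
      mono
    })
  } else if (verbose) {
    message("[filtering] no peaks.csv; stage skipped")
  }

  mlr <- run_stage("mlr", {
    fit <- fit_mlr(retention, design)
    hw_rt <- replicate_ci(retention$values[design$is_replicate, , drop = FALSE])
    hw_coef <- coefficient_ci(fit, design, retention)
    write_coef_csv(fit$coefficients, file.path(out_dir, "coefficients_mlr.csv"))
    write_coef_csv(hw_coef, file.path(out_dir, "coefficients_ci.csv"))
    utils::write.csv(
      data.frame(compound = retention$compound_labels,
                 ci_halfwidth_rt = hw_rt),
      file.path(out_dir, "replicate_ci.csv"), row.names = FALSE)
    list(fit = fit, ci_rt = hw_rt, ci_coef = hw_coef)
  })

  k <- as.integer(config$analysis$n_components)
  pca_route <- run_stage("pca", {
    pr <- pca_coefficients(retention, design, n_components = k)
    utils::write.csv(data.frame(run = rownames(pr$pca$scores), pr$pca$scores),
                     file.path(out_dir, "scores.csv"), row.names = FALSE)
    utils::write.csv(data.frame(compound = rownames(pr$pca$loadings),
                                pr$pca$loadings),
                     file.path(out_dir, "loadings.csv"), row.names = FALSE)
    utils::write.csv(
      data.frame(component = paste0("PC", seq_along(pr$pca$explained_variance)),
                 explained_variance = pr$pca$explained_variance),
      file.path(out_dir, "explained_variance.csv"), row.names = FALSE)
    utils::write.csv(data.frame(component = rownames(pr$conversion$matrix),
                                pr$conversion$matrix, check.names = FALSE),
                     file.path(out_dir, "conversion.csv"), row.names = FALSE)
    write_coef_csv(pr$coefficients, file.path(out_dir, "coefficients_pca.csv"))
    pr
  })

  asca_route <- run_stage("asca", {
    fac_rows <- !design$is_replicate
    af <- fit_asca(retention$values[fac_rows, , drop = FALSE],
                   design$coded[fac_rows, , drop = FALSE])
    Dfac <- design$values[fac_rows, , drop = FALSE]
    ac <- asca_coefficients(af, Dfac)
    write_coef_csv(ac$coefficients, file.path(out_dir, "coefficients_asca.csv"))
    scatter <- data.frame(
      term = rep(rownames(mlr$fit$coefficients),
                 ncol(mlr$fit$coefficients)),
      compound = rep(colnames(mlr$fit$coefficients),
                     each = nrow(mlr$fit$coefficients)),
      mlr = as.vector(mlr$fit$coefficients),
      asca = as.vector(ac$coefficients[rownames(mlr$fit$coefficients), ]))
    utils::write.csv(scatter, file.path(out_dir, "asca_vs_mlr.csv"),
                     row.names = FALSE)
    list(asca = af, coef = ac)
  })

  rvc <- run_stage("pcr", {
    tab <- residual_variance_comparison(
      retention, design, n_components = k,
      rt_window = config$analysis$overlap_window, cv = cv)
    utils::write.csv(tab, file.path(out_dir, "residual_variance.csv"),
                     row.names = FALSE)
    tab
  })

  levels <- run_stage("levels", {
    lp <- predict_design_levels(retention, design,
                                component_range = config$analysis$component_range,
                                cv = cv)
    long <- data.frame(
      term = rep(rownames(lp$rmsec), length(lp$component_range)),
      n_components = rep(lp$component_range, each = nrow(lp$rmsec)),
      rmsec = as.vector(lp$rmsec),
      rmsecv = as.vector(lp$rmsecv),
      explained_variance = as.vector(lp$explained_variance))
    utils::write.csv(long, file.path(out_dir, "level_rmse.csv"),
                     row.names = FALSE)
    lp
  })

  jsonlite::write_json(
    list(config = config, config_hash = config_hash(config),
         seed = config$seed, n_runs = nrow(retention$values),
         n_compounds = ncol(retention$values)),
    file.path(out_dir, "metadata.json"), auto_unbox = TRUE, digits = NA)

  invisible(list(retention = retention, design = design, filtered = filtered,
                 mlr = mlr, pca = pca_route, asca = asca_route,
                 residual_variance = rvc, level_prediction = levels))
}

write_coef_csv <- function(B, path) {
  utils::write.csv(data.frame(term = rownames(B), B, check.names = FALSE),
                   path, row.names = FALSE)
  invisible(path)
}

#' Monte-Carlo recovery of the ground-truth coefficients
#'
#' Repeats simulate + MLR + coefficient CIs `n_repeats` times with fresh
#' noise and latent draws over a fixed ground truth, and summarizes how
#' well the true coefficients are recovered: per-term bias (averaged over
#' compounds and repeats), per-term RMSE, and the empirical coverage of
#' the nominal-level confidence intervals.
#'
#' @param config run config.
#' @param n_repeats number of Monte-Carlo repeats.
#' @param seed base seed; repeat r uses `seed + r`.
#' @param level CI confidence level (default 0.95).
#' @param out_dir optional directory for `recovery.csv`.
#' @param verbose log timing.
#' @return list with `summary` (data frame: term, bias, rmse, coverage),
#'   `coverage_overall`, `n_repeats`, `noise_sd`.
#' @export
rt_recover <- function(config = default_run_config(), n_repeats = 200L,
                       seed = NULL, level = 0.95, out_dir = NULL,
                       verbose = TRUE) {
  config <- validate_run_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  stopifnot(n_repeats >= 1L)
  t0 <- as.numeric(Sys.time())
  spec <- design_spec_from_list(config$design)
  sim <- config$simulation
  truth <- ground_truth(
    spec, n_compounds = as.integer(sim$n_compounds), seed = config$seed,
    noise_sd = sim$noise_sd, n_latent = as.integer(sim$n_latent),
    latent_loading_sd = sim$latent_loading_sd,
    latent_scores_scale = sim$latent_scores_scale,
    n_temp_positive = as.integer(sim$n_temp_positive))
  B_true <- truth$true_coefficients
  err_sum <- matrix(0, nrow(B_true), ncol(B_true))
  err_sq <- matrix(0, nrow(B_true), ncol(B_true))
  cover <- matrix(0, nrow(B_true), ncol(B_true))
  design <- build_design(spec)
  for (r in seq_len(n_repeats)) {
    ds <- simulate_retention(spec, truth, seed = (config$seed + r) %% 2147483647L)
    fit <- fit_mlr(ds$retention, design)
    hw <- coefficient_ci(fit, design, ds$retention, level = level)
    err <- fit$coefficients - B_true
    err_sum <- err_sum + err
    err_sq <- err_sq + err^2
    cover <- cover + (abs(err) <= hw)
  }
  bias <- err_sum / n_repeats
  rmse <- sqrt(err_sq / n_repeats)
  coverage <- cover / n_repeats
  summary <- data.frame(
    term = rownames(B_true),
    bias = rowMeans(bias),
    rmse = sqrt(rowMeans(rmse^2)),
    coverage = rowMeans(coverage))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(summary, file.path(out_dir, "recovery.csv"),
                     row.names = FALSE)
  }
  stage_log("recover", t0, verbose)
  list(summary = summary,
       coverage_overall = mean(coverage),
       n_repeats = n_repeats,
       noise_sd = truth$noise_sd)
}
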