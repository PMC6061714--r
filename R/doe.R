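#' Specify a design factor
#'
#' A factor is described on a coded integer scale (default -2..+2, i.e. a
#' five-level design) together with the affine map to real units:
#' `real = center + coded * step`.
#'
#' @param name factor name (e.g. `"pH"`).
#' @param center real value at coded level 0 (pH units, degrees Celsius, ...).
#' @param step real increment per coded unit; must be positive.
#' @param coded_levels strictly increasing integer vector of coded levels.
#'
#' @return An object of class `factor_spec`.
#' @examples
#' factor_spec("pH", center = 3.75, step = 0.25)
#' @export
factor_spec <- function(name, center, step, coded_levels = -2L:2L) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(step) || length(step) != 1L || step <= 0) {
    stop("'step' must be a single positive number", call. = FALSE)
  }
  coded_levels <- as.integer(coded_levels)
  if (anyNA(coded_levels) || is.unsorted(coded_levels, strictly = TRUE)) {
    stop("'coded_levels' must be strictly increasing integers", call. = FALSE)
  }
  structure(
    list(name = name, center = as.numeric(center), step = as.numeric(step),
         coded_levels = coded_levels),
    class = "factor_spec"
  )
}

#' @export
print.factor_spec <- function(x, ...) {
  cat(sprintf("Factor '%s': center %g, step %g, coded levels {%s}\n",
              x$name, x$center, x$step,
              paste(x$coded_levels, collapse = ", ")))
  invisible(x)
}

#' Specify a full factorial design
#'
#' Combines factors, replicated center points, and the model terms used for
#' regression. The default term set for two factors p and t is
#' `1, p, t, p^2, t^2, p:t` (intercept, linear, quadratic, interaction),
#' on the coded scale.
#'
#' @param factors list of [factor_spec()] objects.
#' @param center_replicates non-negative number of replicated center-point
#'   runs appended after the factorial block.
#' @param model_terms character vector of term labels. `"1"` is the
#'   intercept; a factor name is a linear term; `"<name>^2"` a quadratic
#'   term; `"<a>:<b>"` a pairwise interaction. The intercept must come
#'   first. `NULL` builds the full quadratic model.
#'
#' @return An object of class `design_spec`.
#' @seealso [build_design()], [hsa_design_spec()]
#' @export
design_spec <- function(factors, center_replicates = 0L, model_terms = NULL) {
  if (!is.list(factors) || length(factors) == 0L ||
      !all(vapply(factors, inherits, logical(1), "factor_spec"))) {
    stop("'factors' must be a non-empty list of factor_spec objects",
         call. = FALSE)
  }
  nms <- vapply(factors, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("duplicate factor names", call. = FALSE)
  center_replicates <- as.integer(center_replicates)
  stopifnot(length(center_replicates) == 1L, center_replicates >= 0L)
  if (center_replicates > 0L) {
    has_center <- vapply(factors, function(f) 0L %in% f$coded_levels,
                         logical(1))
    if (!all(has_center)) {
      stop("center replicates requested but 0 is not a coded level of ",
           "every factor", call. = FALSE)
    }
  }
  if (is.null(model_terms)) {
    model_terms <- c("1", nms, paste0(nms, "^2"),
                     if (length(nms) > 1L)
                       utils::combn(nms, 2L, paste, collapse = ":"))
  }
  if (anyDuplicated(model_terms)) {
    stop("duplicate model terms", call. = FALSE)
  }
  if (model_terms[1L] != "1") {
    stop("the intercept term \"1\" must come first", call. = FALSE)
  }
  # validate every term against the factor names
  for (tm in model_terms[-1L]) parse_term(tm, nms)
  structure(
    list(factors = factors, center_replicates = center_replicates,
         model_terms = model_terms),
    class = "design_spec"
  )
}

#' @export
print.design_spec <- function(x, ...) {
  cat(sprintf("Design spec: %d factor(s), %d center replicate(s)\n",
              length(x$factors), x$center_replicates))
  for (f in x$factors) print(f)
  cat("Model terms:", paste(x$model_terms, collapse = ", "), "\n")
  invisible(x)
}

# Parse a non-intercept term label into list(kind, factors).
parse_term <- function(term, factor_names) {
  if (term %in% factor_names) {
    return(list(kind = "linear", factors = term))
  }
  if (grepl("\\^2$", term)) {
    f <- sub("\\^2$", "", term)
    if (f %in% factor_names) return(list(kind = "quadratic", factors = f))
  }
  if (grepl(":", term, fixed = TRUE)) {
    fs <- strsplit(term, ":", fixed = TRUE)[[1L]]
    if (length(fs) == 2L && all(fs %in% factor_names)) {
      return(list(kind = "interaction", factors = fs))
    }
  }
  stop(sprintf("model term '%s' refers to no declared factor", term),
       call. = FALSE)
}

#' Map a coded level to real units
#'
#' @param coded coded level(s), each of which must belong to the factor's
#'   declared levels.
#' @param factor a [factor_spec()].
#' @return `factor$center + coded * factor$step`.
#' @examples
#' coded_to_real(2, factor_spec("pH", 3.75, 0.25))   # 4.25
#' @export
coded_to_real <- function(coded, factor) {
  stopifnot(inherits(factor, "factor_spec"))
  if (!all(coded %in% factor$coded_levels)) {
    stop(sprintf("coded level outside declared levels of '%s'", factor$name),
         call. = FALSE)
  }
  factor$center + coded * factor$step
}

#' Expand one run's coded levels into model-term values
#'
#' @param coded_row named (or positionally matched) numeric vector with one
#'   coded value per factor.
#' @param model_terms character vector of term labels (see [design_spec()]).
#' @param factor_names names of the factors, in declaration order.
#' @return numeric vector of term values, one per model term.
#' @examples
#' expand_terms(c(pH = -2, temperature = 1),
#'              c("1", "pH", "temperature", "pH^2", "temperature^2",
#'                "pH:temperature"),
#'              c("pH", "temperature"))
#' @export
expand_terms <- function(coded_row, model_terms, factor_names) {
  if (length(coded_row) != length(factor_names)) {
    stop("one coded value per factor is required", call. = FALSE)
  }
  names(coded_row) <- factor_names
  vapply(model_terms, function(tm) {
    if (tm == "1") return(1)
    p <- parse_term(tm, factor_names)
    switch(p$kind,
           linear = coded_row[[p$factors]],
           quadratic = coded_row[[p$factors]]^2,
           interaction = coded_row[[p$factors[1L]]] * coded_row[[p$factors[2L]]])
  }, numeric(1))
}

#' Build the design matrix of a full factorial
#'
#' Enumerates the full Cartesian product of coded levels in lexicographic
#' order (the first declared factor is the outer, slowest-varying loop),
#' appends the replicated center points last, and expands each run into the
#' model-term columns. Replicate rows are flagged, not deduplicated, since
#' they carry the pure-error information.
#'
#' @param spec a [design_spec()].
#' @return An object of class `design_matrix`: a list with
#'   \describe{
#'     \item{values}{runs x terms numeric matrix on the coded scale,
#'       intercept column all ones.}
#'     \item{coded}{runs x factors matrix of coded levels.}
#'     \item{run_labels, term_labels}{row/column identifiers.}
#'     \item{is_replicate}{logical flag per run.}
#'     \item{spec}{the input spec (carries the coded-to-real mapping).}
#'   }
#' @examples
#' D <- build_design(hsa_design_spec())
#' nrow(D$values)  # 30 = 5*5 factorial + 5 center replicates
#' @export
build_design <- function(spec) {
  stopifnot(inherits(spec, "design_spec"))
  nms <- vapply(spec$factors, `[[`, character(1), "name")
  levels_list <- lapply(spec$factors, `[[`, "coded_levels")
  # expand.grid varies its first argument fastest; reverse so the first
  # declared factor is the slowest (outer) loop
  grid <- expand.grid(rev(levels_list), KEEP.OUT.ATTRS = FALSE)
  grid <- as.matrix(grid[, rev(seq_along(levels_list)), drop = FALSE])
  colnames(grid) <- nms
  n_fact <- nrow(grid)
  if (spec$center_replicates > 0L) {
    center <- matrix(0L, spec$center_replicates, length(nms),
                     dimnames = list(NULL, nms))
    grid <- rbind(grid, center)
  }
  values <- t(apply(grid, 1L, expand_terms,
                    model_terms = spec$model_terms, factor_names = nms))
  colnames(values) <- spec$model_terms
  is_rep <- c(rep(FALSE, n_fact), rep(TRUE, spec$center_replicates))
  run_labels <- c(sprintf("run%02d", seq_len(n_fact)),
                  if (spec$center_replicates > 0L)
                    sprintf("rep%02d", seq_len(spec$center_replicates)))
  rownames(values) <- run_labels
  rownames(grid) <- run_labels
  structure(
    list(values = values, coded = grid, run_labels = run_labels,
         term_labels = spec$model_terms, is_replicate = is_rep, spec = spec),
    class = "design_matrix"
  )
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("Design matrix: %d runs (%d replicates) x %d terms [%s]\n",
              nrow(x$values), sum(x$is_replicate), ncol(x$values),
              paste(x$term_labels, collapse = ", ")))
  invisible(x)
}

#' @export
as.matrix.design_matrix <- function(x, ...) x$values

#' The reference two-factor five-level design
#'
#' Mobile-phase pH (3.25-4.25 in 0.25 steps, center 3.75) and column
#' temperature (35-45 degC in 2.5 steps, center 40), full 5x5 factorial
#' plus five replicated center points: the design used for the HSA tryptic
#' digest retention study this package models.
#'
#' @param center_replicates number of center-point replicates (default 5).
#' @return a [design_spec()].
#' @export
hsa_design_spec <- function(center_replicates = 5L) {
  design_spec(
    factors = list(
      factor_spec("pH", center = 3.75, step = 0.25),
      factor_spec("temperature", center = 40.0, step = 2.5)
    ),
    center_replicates = center_replicates
  )
}

#' Read a design spec from a YAML or JSON config file
#'
#' The schema is:
#' ```yaml
#' factors:
#'   - name: pH
#'     center: 3.75
#'     step: 0.25
#'     coded_levels: [-2, -1, 0, 1, 2]   # optional, default -2..2
#'   - name: temperature
#'     center: 40.0
#'     step: 2.5
#' center_replicates: 5
#' model_terms: ["1", "pH", "temperature", ...]   # optional
#' ```
#'
#' @param path file path; `.json` is parsed as JSON, anything else as YAML
#'   (JSON being a YAML subset, either parser accepts both dialects).
#' @return a [design_spec()].
#' @export
read_design_spec <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  design_spec_from_list(raw)
}

design_spec_from_list <- function(raw) {
  if (is.null(raw$factors)) stop("config lacks a 'factors' list", call. = FALSE)
  factors <- lapply(raw$factors, function(f) {
    for (fld in c("name", "center", "step")) {
      if (is.null(f[[fld]])) {
        stop(sprintf("factor entry lacks field '%s'", fld), call. = FALSE)
      }
    }
    factor_spec(f$name, f$center, f$step,
                coded_levels = if (is.null(f$coded_levels)) -2L:2L
                               else unlist(f$coded_levels))
  })
  design_spec(factors,
              center_replicates = if (is.null(raw$center_replicates)) 0L
                                  else raw$center_replicates,
              model_terms = if (is.null(raw$model_terms)) NULL
                            else unlist(raw$model_terms))
}

#' Write a design matrix as CSV
#'
#' First column holds the run label, then one column per model term, plus a
#' trailing `is_replicate` flag.
#'
#' @param design a [build_design()] result.
#' @param path output file path.
#' @export
write_design_csv <- function(design, path) {
  stopifnot(inherits(design, "design_matrix"))
  df <- data.frame(run = design$run_labels,
                   design$values, check.names = FALSE,
                   is_replicate = design$is_replicate)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
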