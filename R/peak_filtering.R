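#' Classify peaks as monoisotopic, isotope, or adduct
#'
#' Within each run, peaks are visited in decreasing intensity order and
#' tested against the peaks already classified as monoisotopic (the greedy
#' order resolves isotope-of-isotope chains deterministically):
#' \itemize{
#'   \item \emph{isotope}: a more intense monoisotopic peak exists at
#'     `mz - k * 1.00335 / z` (k = 1, 2) within both tolerances. The charge
#'     is taken from the `charge` column when present, otherwise candidate
#'     charges 1-3 are tried.
#'   \item \emph{adduct}: a monoisotopic peak exists at `mz - delta` within
#'     both tolerances for some entry of the adduct table.
#'   \item \emph{monoisotopic} otherwise.
#' }
#'
#' @param peaks data frame with columns `mz`, `rt`, `intensity`, optionally
#'   `charge` and `run` (classification is per run; a missing `run` column
#'   treats the whole list as one run).
#' @param mz_tolerance m/z matching tolerance, Th (default 0.005).
#' @param rt_tolerance co-elution tolerance, minutes (default 0.1).
#' @param adduct_table named vector of m/z deltas tested for adducts.
#' @param candidate_charges charges tried when `charge` is absent.
#' @return the input with a `class` column added
#'   (`"monoisotopic" | "isotope" | "adduct"`).
#' @export
classify_peaks <- function(peaks,
                           mz_tolerance = 0.005,
                           rt_tolerance = 0.1,
                           adduct_table = adduct_table_default(),
                           candidate_charges = 1:3) {
  if (mz_tolerance <= 0 || rt_tolerance <= 0) {
    stop("tolerances must be positive", call. = FALSE)
  }
  required <- c("mz", "rt", "intensity")
  if (!all(required %in% names(peaks))) {
    stop("peak list needs columns: ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  peaks$class <- character(nrow(peaks))
  if (nrow(peaks) == 0L) return(peaks)
  if (any(peaks$mz <= 0) || any(peaks$intensity < 0)) {
    stop("invalid peak list: m/z must be positive, intensity non-negative",
         call. = FALSE)
  }
  run_id <- if ("run" %in% names(peaks)) peaks$run else rep("all", nrow(peaks))
  for (r in unique(run_id)) {
    idx <- which(run_id == r)
    peaks$class[idx] <- classify_one_run(
      peaks[idx, , drop = FALSE], mz_tolerance, rt_tolerance,
      adduct_table, candidate_charges)
  }
  peaks
}

classify_one_run <- function(p, mz_tol, rt_tol, adducts, cand_z) {
  n <- nrow(p)
  ord <- order(-p$intensity)
  cls <- character(n)
  mono_idx <- integer(0)        # indices (into p) already called monoisotopic
  has_charge <- "charge" %in% names(p)
  for (i in ord) {
    verdict <- "monoisotopic"
    if (length(mono_idx) > 0L) {
      cand <- mono_idx[abs(p$rt[mono_idx] - p$rt[i]) <= rt_tol &
                         p$intensity[mono_idx] > p$intensity[i]]
      if (length(cand) > 0L) {
        zs <- if (has_charge && !is.na(p$charge[i])) p$charge[i] else cand_z
        deltas <- unique(as.vector(outer(1:2, zs, function(k, z) k * ISOTOPE_SPACING / z)))
        for (d in deltas) {
          if (any(abs(p$mz[cand] - (p$mz[i] - d)) <= mz_tol)) {
            verdict <- "isotope"
            break
          }
        }
        if (verdict == "monoisotopic" && length(adducts) > 0L) {
          # adduct reference: any co-eluting monoisotopic peak at mz - delta
          cand_a <- mono_idx[abs(p$rt[mono_idx] - p$rt[i]) <= rt_tol]
          for (d in adducts) {
            if (any(abs(p$mz[cand_a] - (p$mz[i] - d)) <= mz_tol)) {
              verdict <- "adduct"
              break
            }
          }
        }
      }
    }
    cls[i] <- verdict
    if (verdict == "monoisotopic") mono_idx <- c(mono_idx, i)
  }
  cls
}

#' Keep only monoisotopic peaks
#'
#' @param peaks a classified peak list (output of [classify_peaks()]).
#' @return the monoisotopic records, original order preserved.
#' @export
filter_monoisotopic <- function(peaks) {
  if (!"class" %in% names(peaks)) {
    stop("peak list is unclassified; run classify_peaks() first",
         call. = FALSE)
  }
  peaks[peaks$class == "monoisotopic", , drop = FALSE]
}

#' Assemble a retention matrix from filtered peak lists
#'
#' Groups monoisotopic peaks across runs by m/z (within `mz_tolerance` of
#' the per-group median) and builds the runs x compounds retention matrix,
#' columns ordered by mean elution time. Every run must contribute exactly
#' one peak per group; groups with missing runs are dropped with a warning.
#'
#' @param peaks monoisotopic peak list with `run`, `mz`, `rt` columns.
#' @param mz_tolerance grouping tolerance, Th.
#' @return an `rt_matrix`.
#' @export
peaks_to_retention <- function(peaks, mz_tolerance = 0.005) {
  stopifnot(all(c("run", "mz", "rt") %in% names(peaks)))
  runs <- unique(peaks$run)
  ord <- order(peaks$mz)
  gap <- c(Inf, diff(peaks$mz[ord]))
  grp <- cumsum(gap > mz_tolerance)
  group_id <- integer(nrow(peaks))
  group_id[ord] <- grp
  keep <- vapply(split(seq_len(nrow(peaks)), group_id), function(ii) {
    length(ii) == length(runs) && !anyDuplicated(peaks$run[ii])
  }, logical(1))
  if (!all(keep)) {
    warning(sum(!keep), " m/z group(s) incomplete across runs; dropped")
  }
  groups <- split(seq_len(nrow(peaks)), group_id)[keep]
  mz_med <- vapply(groups, function(ii) stats::median(peaks$mz[ii]), numeric(1))
  o <- order(vapply(groups, function(ii) mean(peaks$rt[ii]), numeric(1)))
  groups <- groups[o]; mz_med <- mz_med[o]
  vals <- vapply(groups, function(ii) {
    peaks$rt[ii][match(runs, peaks$run[ii])]
  }, numeric(length(runs)))
  vals <- matrix(vals, nrow = length(runs),
                 dimnames = list(runs, sprintf("mz%.4f", mz_med)))
  structure(
    list(values = vals, run_labels = runs, compound_labels = colnames(vals),
         compound_mz = unname(mz_med), charge = NULL),
    class = "rt_matrix"
  )
}
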