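#' Rescale raw intensities by run-day medians
#'
#' Corrects for daily drift of platform performance: each feature's raw value
#' is divided by the median of that feature's non-missing values within the
#' sample's acquisition day, so every feature has a per-run-day median of 1
#' wherever it was observed at all on that day.
#'
#' @param mat Samples x features matrix of raw intensities (`NA` = missing),
#'   rownames = sample ids.
#' @param run_day Character/factor vector of run-day labels, one per sample
#'   (row of `mat`).
#' @return The rescaled matrix. Cells of a (feature, run day) pair whose
#'   median is 0 or undefined are set missing (division impossible); a warning
#'   reports zero-median pairs.
#' @examples
#' m <- matrix(c(2, 4, 6), 3, 1, dimnames = list(paste0("s", 1:3), "f1"))
#' normalize_runday(m, rep("D1", 3))
#' @export
normalize_runday <- function(mat, run_day) {
  stopifnot(is.matrix(mat), length(run_day) == nrow(mat))
  out <- mat
  zero_median <- 0L
  for (day in unique(run_day)) {
    rows <- which(run_day == day)
    med <- apply(mat[rows, , drop = FALSE], 2, median, na.rm = TRUE)
    bad <- !is.na(med) & med == 0
    zero_median <- zero_median + sum(bad)
    med[bad] <- NA_real_
    out[rows, ] <- sweep(mat[rows, , drop = FALSE], 2, med, "/")
  }
  if (zero_median > 0) {
    warn(paste0(zero_median, " (feature, run day) pair(s) had median 0; ",
                "their cells were set missing."))
  }
  out
}

#' Filter features by missingness
#'
#' Keeps a feature only if its fraction of missing values across all samples
#' is strictly below `threshold`; with the default 0.40 a feature observed at
#' a median of three of five time points per subject survives.
#'
#' @param mat Samples x features matrix (`NA` = missing).
#' @param threshold Strict upper bound on the missing fraction, in (0, 1].
#' @return A list: `matrix` (kept columns only) and `summary`, a tibble with
#'   `feature_id`, `n_missing`, `prop_missing`, `kept` for every input feature.
#' @export
filter_missingness <- function(mat, threshold = 0.40) {
  stopifnot(is.matrix(mat), threshold > 0, threshold <= 1)
  if (ncol(mat) == 0 || nrow(mat) == 0) {
    warn("Empty intensity matrix; nothing to filter.")
    return(list(matrix = mat,
                summary = tibble::tibble(feature_id = character(),
                                         n_missing = integer(),
                                         prop_missing = double(),
                                         kept = logical())))
  }
  n_missing <- colSums(is.na(mat))
  prop <- n_missing / nrow(mat)
  kept <- prop < threshold
  list(
    matrix = mat[, kept, drop = FALSE],
    summary = tibble::tibble(
      feature_id = colnames(mat),
      n_missing = as.integer(n_missing),
      prop_missing = unname(prop),
      kept = unname(kept)
    )
  )
}

#' Log10-transform an intensity matrix
#'
#' @param mat Samples x features matrix on the raw scale.
#' @return The matrix of base-10 logarithms. Non-positive values cannot be
#'   log-transformed and become missing, with a warning reporting how many.
#' @export
transform_log10 <- function(mat) {
  stopifnot(is.matrix(mat))
  bad <- !is.na(mat) & mat <= 0
  if (any(bad)) {
    warn(paste0(sum(bad), " non-positive value(s) set missing before log10."))
    mat[bad] <- NA_real_
  }
  log10(mat)
}

#' Run the full preprocessing chain of one layer
#'
#' Run-day normalization (metabolome by default), strict missingness filter,
#' then log10 transformation — the order used throughout the pipeline.
#'
#' @param layer An `omics_layer` (or a list with `intensities` and `samples`).
#' @param threshold Missingness threshold for [filter_missingness()].
#' @param runday_normalize Whether to rescale by run-day medians. Defaults to
#'   `TRUE` for the metabolome only, the documented behaviour of the platform;
#'   set explicitly to extend to the proteome.
#' @return The layer with `intensities` replaced by the filtered log10 matrix,
#'   plus `filter_summary`.
#' @export
preprocess_layer <- function(layer, threshold = 0.40, runday_normalize = NULL) {
  mat <- layer$intensities
  is_metab <- !is.null(layer$config) && identical(layer$config$layer, "metabolite")
  runday_normalize <- runday_normalize %||% is_metab
  if (runday_normalize) mat <- normalize_runday(mat, layer$samples$run_day)
  flt <- filter_missingness(mat, threshold)
  layer$intensities <- transform_log10(flt$matrix)
  layer$filter_summary <- flt$summary
  layer
}
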