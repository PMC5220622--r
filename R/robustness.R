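#' Plan the leave-three-out participant subsets
#'
#' Draws `n_random` distinct exclusion triples of participants uniformly at
#' random (never repeating, never colliding with the fixed triple) and
#' appends one additional subset that excludes the fixed triple — by default
#' the flagged outlier participants — giving `n_random + 1` pairwise distinct
#' subsets. With 16 subjects and the defaults this is the 101-subset plan
#' (560 triples exist, so 101 distinct ones always do).
#'
#' @param subject_ids Character vector of participant ids (>= 5).
#' @param n_random Number of random exclusion triples (default 100).
#' @param fixed_exclusion Character vector of exactly 3 participant ids, or
#'   `NULL` for a purely random plan of length `n_random`.
#' @param seed Integer seed; the plan is deterministic given the seed.
#' @return A `subset_plan` tibble: `subset_id`, `excluded` (list-column of
#'   3-id vectors), `is_fixed`.
#' @examples
#' d <- design_study(seed = 1)
#' plan <- make_subsets(d$subjects$subject_id,
#'                      fixed_exclusion = d$outlier_subjects, seed = 1)
#' nrow(plan) # 101
#' @export
make_subsets <- function(subject_ids, n_random = 100,
                         fixed_exclusion = NULL, seed = 1L) {
  n <- length(subject_ids)
  if (n < 5) abort("Need at least 5 subjects for leave-three-out subsampling.",
                   class = "thyromics_config_error")
  if (!is.null(fixed_exclusion)) {
    if (length(fixed_exclusion) != 3 || !all(fixed_exclusion %in% subject_ids)) {
      abort("`fixed_exclusion` must name exactly 3 known subjects.",
            class = "thyromics_config_error")
    }
  }
  n_fixed <- as.integer(!is.null(fixed_exclusion))
  all_triples <- combn(sort(subject_ids), 3, simplify = FALSE)
  if (length(all_triples) < n_random + n_fixed) {
    abort(paste0("Only ", length(all_triples), " distinct triples exist; ",
                 "cannot draw ", n_random + n_fixed, " distinct subsets."),
          class = "thyromics_config_error")
  }
  key <- function(x) paste(sort(x), collapse = "|")
  pool <- all_triples
  if (!is.null(fixed_exclusion)) {
    pool <- pool[vapply(pool, key, "") != key(fixed_exclusion)]
  }
  set.seed(derive_seed(seed, "subsets"))
  drawn <- pool[sample.int(length(pool), n_random)]
  excluded <- c(drawn, if (!is.null(fixed_exclusion)) list(sort(fixed_exclusion)))
  tibble::tibble(
    subset_id = seq_along(excluded),
    excluded = excluded,
    is_fixed = c(rep(FALSE, n_random), rep(TRUE, n_fixed))
  )
}

#' Robust FT4 association via leave-three-out subsampling
#'
#' Re-runs the per-feature mixed-model screen of [associate_layer()] on every
#' subset of the plan (all samples of the excluded participants removed, FDR
#' re-adjusted within each subset), then averages estimates and FDR values
#' across subsets. A feature is called significant when its average FDR is
#' below `alpha` — the study's robust significance rule.
#'
#' @param mat Log10 intensity matrix or a preprocessed `omics_layer`.
#' @param samples Sample records aligned with the matrix rows.
#' @param plan A `subset_plan` from [make_subsets()].
#' @param layer `"metabolite"` or `"protein"`.
#' @param alpha Average-FDR significance level (default 0.05).
#' @param min_converged Minimum fraction of subsets in which a feature must
#'   converge to receive a significance call (default 0.8; guards against
#'   averages over a handful of subsets).
#' @return Tibble with one row per feature: `feature_id`, `mean_beta`,
#'   `sd_beta`, `mean_q`, `sd_q`, `n_subsets_converged`, `significant`.
#' @export
robust_associate <- function(mat, samples = NULL, plan = NULL,
                             layer = NULL, alpha = 0.05, min_converged = 0.8) {
  if (inherits(mat, "omics_layer")) {
    samples <- samples %||% mat$samples
    layer <- layer %||% mat$config$layer
    mat <- mat$intensities
  }
  stopifnot(is.matrix(mat), nrow(mat) == nrow(samples), !is.null(plan))
  per_subset <- purrr::map(seq_len(nrow(plan)), function(i) {
    keep <- !(samples$subject_id %in% plan$excluded[[i]])
    res <- associate_layer(mat[keep, , drop = FALSE], samples[keep, ], layer)
    dplyr::mutate(res, subset_id = plan$subset_id[i])
  })
  dplyr::bind_rows(per_subset) |>
    dplyr::filter(.data$converged) |>
    dplyr::group_by(.data$feature_id) |>
    dplyr::summarise(
      mean_beta = mean(.data$beta),
      sd_beta = sd(.data$beta),
      mean_q = mean(.data$q),
      sd_q = sd(.data$q),
      n_subsets_converged = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::right_join(tibble::tibble(feature_id = colnames(mat)),
                      by = "feature_id") |>
    dplyr::arrange(match(.data$feature_id, colnames(mat))) |>
    dplyr::mutate(
      n_subsets_converged = dplyr::coalesce(.data$n_subsets_converged, 0L),
      significant = !is.na(.data$mean_q) & .data$mean_q < alpha &
        .data$n_subsets_converged >= min_converged * nrow(plan)
    )
}
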