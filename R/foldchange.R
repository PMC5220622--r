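#' Mean log2 fold changes from baseline
#'
#' The heatmap quantity of the time-course figures: for every feature and
#' time point, each participant's ratio to their own baseline value is taken,
#' and the mean of the log2 ratios across participants is reported (mean of
#' log ratios, not log of the mean ratio). A participant contributes to a
#' cell only when both the baseline and the time-point value are present.
#'
#' @param mat Samples x features matrix on the raw (pre-log) scale.
#' @param samples Sample records aligned with the matrix rows (`subject_id`,
#'   `time_point`).
#' @param baseline Label of the baseline time point (default `"bas"`).
#' @return A `foldchange_tbl` tibble: `feature_id`, `time_point`,
#'   `mean_log2fc`, `n_subjects` (contributing participants; cells with none
#'   have `NA` fold change). The baseline column is identically 0 where
#'   defined.
#' @examples
#' d <- design_study(n_subjects = 4, seed = 1)
#' s <- simulate_hormones(d, seed = 1)
#' layer <- simulate_features(d, s, layer_config("metabolite", n_features = 5,
#'                                               missing_rate = 0), seed = 1)
#' fc <- mean_log2fc(layer$intensities, layer$samples)
#' autoplot(fc)
#' @export
mean_log2fc <- function(mat, samples, baseline = "bas") {
  stopifnot(is.matrix(mat), nrow(mat) == nrow(samples))
  tps <- if (is.factor(samples$time_point)) levels(samples$time_point) else
    unique(as.character(samples$time_point))
  if (!baseline %in% tps) {
    abort(paste0("Baseline time point '", baseline, "' not present."),
          class = "thyromics_config_error")
  }
  long <- tibble::tibble(
    subject_id = rep(samples$subject_id, ncol(mat)),
    time_point = rep(as.character(samples$time_point), ncol(mat)),
    feature_id = rep(colnames(mat), each = nrow(mat)),
    value = as.vector(mat)
  )
  base <- long |>
    dplyr::filter(.data$time_point == baseline, !is.na(.data$value)) |>
    dplyr::select("subject_id", "feature_id", base_value = "value")
  out <- long |>
    dplyr::inner_join(base, by = c("subject_id", "feature_id")) |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(.data$feature_id, .data$time_point) |>
    dplyr::summarise(
      mean_log2fc = mean(log2(.data$value / .data$base_value)),
      n_subjects = dplyr::n(),
      .groups = "drop"
    ) |>
    tidyr::complete(
      feature_id = colnames(mat),
      time_point = tps,
      fill = list(n_subjects = 0L)
    ) |>
    dplyr::mutate(
      time_point = factor(.data$time_point, levels = tps),
      feature_id = factor(.data$feature_id, levels = colnames(mat))
    ) |>
    dplyr::arrange(.data$feature_id, .data$time_point) |>
    dplyr::mutate(feature_id = as.character(.data$feature_id))
  class(out) <- c("foldchange_tbl", class(out))
  out
}

#' Heatmap of mean log2 fold changes
#'
#' @param object A `foldchange_tbl` from [mean_log2fc()].
#' @param ... Unused.
#' @return A ggplot: features x time points tiles, diverging fill centred at
#'   zero (orange = increase over baseline, blue = decrease).
#' @export
autoplot.foldchange_tbl <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$time_point, y = .data$feature_id,
                               fill = .data$mean_log2fc)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#E66101", midpoint = 0,
                                  na.value = "grey85",
                                  name = expression(log[2] ~ "FC")) +
    ggplot2::labs(x = "time point", y = NULL,
                  title = "Mean log2 fold change from baseline") +
    ggplot2::theme_minimal()
}
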