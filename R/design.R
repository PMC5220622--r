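#' Create a longitudinal study design with subject profiles
#'
#' Builds the sampling grid of an experimental-thyrotoxicosis study: a fixed
#' panel of subjects, each sampled at an ordered set of time points spanning
#' baseline, treatment and post-treatment phases. A configurable number of
#' subjects is flagged as "outliers" (mirroring participants whose liver
#' transaminase response differed strikingly); downstream robustness analyses
#' use this set as the fixed exclusion triple.
#'
#' @param n_subjects Number of subjects (default 16).
#' @param time_points Ordered character vector of time-point labels.
#' @param treated_points Subset of `time_points` sampled under treatment.
#' @param n_outliers Number of subjects flagged as outliers (default 3).
#' @param age_range,bmi_range Numeric length-2 ranges; ages and BMIs are drawn
#'   uniformly within them and held constant over time.
#' @param seed Integer seed; the design is deterministic given the seed.
#'
#' @return A `study_design` object: a list with `subjects` (a tibble with one
#'   row per subject: `subject_id`, `age`, `bmi`, `random_intercept` slot
#'   filled by the feature simulator, `is_outlier`), plus the design fields.
#' @examples
#' d <- design_study(seed = 1)
#' nrow(d$subjects) * length(d$time_points) # 80 sample slots
#' @export
design_study <- function(n_subjects = 16,
                         time_points = c("bas", "w4", "w8", "w12", "w16"),
                         treated_points = c("w4", "w8"),
                         n_outliers = 3,
                         age_range = c(22, 34),
                         bmi_range = c(21, 30),
                         seed = 1L) {
  if (n_subjects < 1) abort("`n_subjects` must be at least 1.", class = "thyromics_invalid_design")
  if (anyDuplicated(time_points)) abort("`time_points` must be unique.", class = "thyromics_invalid_design")
  if (!all(treated_points %in% time_points)) {
    abort("`treated_points` must be a subset of `time_points`.", class = "thyromics_invalid_design")
  }
  if (n_outliers > n_subjects) {
    abort("`n_outliers` cannot exceed `n_subjects`.", class = "thyromics_invalid_design")
  }
  set.seed(derive_seed(seed, "design"))
  ids <- sprintf("S%02d", seq_len(n_subjects))
  outliers <- sample(ids, n_outliers)
  subjects <- tibble::tibble(
    subject_id = ids,
    age = runif(n_subjects, age_range[1], age_range[2]),
    bmi = runif(n_subjects, bmi_range[1], bmi_range[2]),
    is_outlier = ids %in% outliers
  )
  structure(
    list(subjects = subjects, time_points = time_points,
         treated_points = treated_points,
         outlier_subjects = sort(outliers), seed = seed),
    class = "study_design"
  )
}

#' @export
print.study_design <- function(x, ...) {
  cat("<study_design> ", nrow(x$subjects), " subjects x ",
      length(x$time_points), " time points (",
      nrow(x$subjects) * length(x$time_points), " samples)\n", sep = "")
  cat("  time points: ", paste(x$time_points, collapse = ", "),
      " (treated: ", paste(x$treated_points, collapse = ", "), ")\n", sep = "")
  cat("  outlier subjects: ", paste(x$outlier_subjects, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Default hormone-trajectory parameters
#'
#' Per-time-point means and standard deviations of serum FT4 (pmol/L) and TSH
#' (mU/L) for a 250 ug/day levothyroxine challenge: FT4 roughly doubles under
#' treatment while TSH is suppressed to near zero, and both normalise within
#' four weeks of stopping.
#'
#' @return A tibble with columns `time_point`, `ft4_mean`, `ft4_sd`,
#'   `tsh_mean`, `tsh_sd`.
#' @export
hormone_defaults <- function() {
  tibble::tibble(
    time_point = c("bas", "w4", "w8", "w12", "w16"),
    ft4_mean = c(13.2, 28.6, 25.9, 11.5, 12.8),
    ft4_sd   = c(1.4, 6.5, 5.7, 1.5, 1.5),
    tsh_mean = c(2.104, 0.017, 0.007, 2.298, 2.177),
    tsh_sd   = c(1.017, 0.029, 0.007, 1.309, 0.897)
  )
}

#' Simulate hormone trajectories for every subject and time point
#'
#' Draws FT4 and TSH per subject/time point as independent normals truncated
#' at zero, using per-time-point means and SDs (defaults reproduce the
#' levothyroxine-challenge trajectory of [hormone_defaults()]).
#'
#' @param design A `study_design` from [design_study()].
#' @param params Tibble of trajectory parameters in the layout of
#'   [hormone_defaults()]; must cover every design time point.
#' @param seed Integer seed.
#'
#' @return A tibble of sample records: `sample_id`, `subject_id`,
#'   `time_point` (factor ordered as in the design), `ft4`, `tsh`, `age`,
#'   `bmi` — one row per (subject, time point).
#' @examples
#' d <- design_study(seed = 1)
#' samples <- simulate_hormones(d, seed = 1)
#' dplyr::summarise(dplyr::group_by(samples, time_point), ft4 = mean(ft4))
#' @export
simulate_hormones <- function(design, params = hormone_defaults(), seed = 1L) {
  stopifnot(inherits(design, "study_design"))
  missing_tp <- setdiff(design$time_points, params$time_point)
  if (length(missing_tp) > 0) {
    abort(paste0("`params` lacks time point(s): ", paste(missing_tp, collapse = ", ")),
          class = "thyromics_config_error")
  }
  if (any(params$ft4_sd < 0) || any(params$tsh_sd < 0)) {
    abort("Trajectory SDs must be non-negative.", class = "thyromics_config_error")
  }
  set.seed(derive_seed(seed, "hormones"))
  grid <- tidyr::expand_grid(subject_id = design$subjects$subject_id,
                             time_point = design$time_points) |>
    dplyr::left_join(params, by = "time_point") |>
    dplyr::left_join(design$subjects[, c("subject_id", "age", "bmi")],
                     by = "subject_id")
  grid$ft4 <- rtruncnorm_pos(nrow(grid), grid$ft4_mean, grid$ft4_sd)
  grid$tsh <- pmax(rtruncnorm_pos(nrow(grid), grid$tsh_mean, grid$tsh_sd), 0)
  grid |>
    dplyr::mutate(
      sample_id = paste(.data$subject_id, .data$time_point, sep = "_"),
      time_point = factor(.data$time_point, levels = design$time_points)
    ) |>
    dplyr::select("sample_id", "subject_id", "time_point",
                  "ft4", "tsh", "age", "bmi")
}

# Normal draw truncated at zero by inverse-CDF sampling; degenerates to the
# mean when sd == 0.
rtruncnorm_pos <- function(n, mean, sd) {
  out <- ifelse(sd == 0, mean, NA_real_)
  idx <- which(sd > 0)
  if (length(idx) > 0) {
    lo <- pnorm(0, mean[idx], sd[idx])
    u <- runif(length(idx), lo, 1)
    out[idx] <- qnorm(u, mean[idx], sd[idx])
  }
  out
}
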