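#' Configuration of a synthetic omics layer
#'
#' Describes the generative model of one feature layer (plasma metabolome or
#' proteome). On the log10 scale each feature follows
#' \deqn{\log_{10} I = \mu_j + \beta_j \mathrm{FT4} + \gamma_a \mathrm{age} +
#'   \gamma_b \mathrm{BMI} + b_{subject} + batch + \varepsilon,}
#' with a per-subject random intercept and, for the proteome, a batch shift;
#' the value is then multiplied by a run-day scale factor and returned on the
#' raw (positive) intensity scale. A configurable fraction of features carries
#' a nonzero FT4 effect `beta_j` of either sign; all others are null.
#'
#' Layer defaults mirror the observed panels: 349 metabolites with 19%
#' FT4-associated (45:20 positive:negative), 437 proteins with 14% associated
#' (47:16), batch effects on the proteome only.
#'
#' @param layer `"metabolite"` or `"protein"`.
#' @param n_features Number of features.
#' @param prop_assoc Fraction of features with a nonzero FT4 effect.
#' @param prop_positive Fraction of associated features with a positive sign.
#' @param beta_range Magnitudes of nonzero effects are drawn log-uniformly in
#'   this range (log10 intensity per pmol/L FT4).
#' @param mu_range Range of baseline log10 intensities (uniform).
#' @param gamma_age,gamma_bmi Fixed-effect slopes for age (per year) and BMI
#'   (per kg/m2) on the log10 scale.
#' @param subject_sd SD of the per-subject random intercept (log10 scale).
#' @param residual_sd Residual SD (log10 scale).
#' @param batch_sd SD of the batch shift (proteins; ignored for metabolites).
#' @param n_batches Number of experimental batches, assigned by subject.
#' @param runday_log_sd SD of log10 run-day scale factors (lognormal factors).
#' @param n_run_days Number of acquisition days, assigned by sample order.
#' @param missing_rate Upper bound of the per-feature missingness rate; must
#'   be < 1. Missingness is feature-concentrated, as on real LC-MS/shotgun
#'   platforms: a `missing_feature_frac` share of features is affected, each
#'   with its own rate drawn uniformly in (0, `missing_rate`), so some
#'   features straddle the 40% filter boundary while the rest are fully
#'   observed. Set `missing_rate = 0` for complete data.
#' @param missing_feature_frac Fraction of features carrying any missingness.
#' @param missing_mode `"mcar"` (cells of an affected feature missing
#'   completely at random) or `"censor"` (left-censoring of the affected
#'   feature's lowest intensities).
#' @param outlier_feature_frac Fraction of features receiving an extra
#'   idiosyncratic shift in the flagged outlier subjects.
#' @param outlier_shift_sd SD of that shift (log10 scale).
#'
#' @return A `layer_config` list.
#' @export
layer_config <- function(layer = c("metabolite", "protein"),
                         n_features = NULL,
                         prop_assoc = NULL,
                         prop_positive = NULL,
                         beta_range = c(0.005, 0.04),
                         mu_range = c(3, 6),
                         gamma_age = 0.002,
                         gamma_bmi = 0.004,
                         subject_sd = 0.20,
                         residual_sd = 0.15,
                         batch_sd = 0.10,
                         n_batches = 2,
                         runday_log_sd = 0.25,
                         n_run_days = 8,
                         missing_rate = 0.50,
                         missing_feature_frac = 0.50,
                         missing_mode = c("mcar", "censor"),
                         outlier_feature_frac = 0.05,
                         outlier_shift_sd = 0.30) {
  layer <- match.arg(layer)
  missing_mode <- match.arg(missing_mode)
  n_features <- n_features %||% if (layer == "metabolite") 349L else 437L
  prop_assoc <- prop_assoc %||% if (layer == "metabolite") 0.19 else 0.14
  prop_positive <- prop_positive %||% if (layer == "metabolite") 45 / 65 else 47 / 63
  if (missing_rate >= 1 || missing_rate < 0) {
    abort("`missing_rate` must be in [0, 1).", class = "thyromics_config_error")
  }
  if (prop_assoc < 0 || prop_assoc > 1) {
    abort("`prop_assoc` must be in [0, 1].", class = "thyromics_config_error")
  }
  structure(list(
    layer = layer, n_features = as.integer(n_features),
    prop_assoc = prop_assoc, prop_positive = prop_positive,
    beta_range = beta_range, mu_range = mu_range,
    gamma_age = gamma_age, gamma_bmi = gamma_bmi,
    subject_sd = subject_sd, residual_sd = residual_sd,
    batch_sd = batch_sd, n_batches = as.integer(n_batches),
    runday_log_sd = runday_log_sd, n_run_days = as.integer(n_run_days),
    missing_rate = missing_rate, missing_feature_frac = missing_feature_frac,
    missing_mode = missing_mode,
    outlier_feature_frac = outlier_feature_frac,
    outlier_shift_sd = outlier_shift_sd
  ), class = "layer_config")
}

#' Simulate a raw intensity matrix with planted FT4 effects
#'
#' Generates one omics layer for a study design and its hormone records,
#' following the generative model documented in [layer_config()]. The returned
#' feature catalog carries the planted ground truth (`true_beta`), which
#' downstream recovery and calibration tests rely on.
#'
#' @param design A `study_design`.
#' @param samples Sample records from [simulate_hormones()].
#' @param config A [layer_config()].
#' @param seed Integer seed.
#'
#' @return An `omics_layer` list with
#'   \describe{
#'     \item{intensities}{samples x features matrix of raw intensities
#'       (positive; `NA` = missing), rownames = sample ids.}
#'     \item{features}{tibble: `feature_id`, `layer`, `true_beta`, `class_tag`,
#'       `outlier_shifted`.}
#'     \item{samples}{the input records with `batch` and `run_day` added.}
#'     \item{config}{the configuration used.}
#'   }
#' @examples
#' d <- design_study(seed = 1)
#' s <- simulate_hormones(d, seed = 1)
#' layer <- simulate_features(d, s, layer_config("metabolite", n_features = 20), seed = 1)
#' dim(layer$intensities)
#' @export
simulate_features <- function(design, samples, config = layer_config(), seed = 1L) {
  stopifnot(inherits(design, "study_design"), inherits(config, "layer_config"))
  set.seed(derive_seed(seed, config$layer))
  n_s <- nrow(samples)
  n_f <- config$n_features

  # feature catalog with planted effects
  n_assoc <- round(config$prop_assoc * n_f)
  n_pos <- round(config$prop_positive * n_assoc)
  signs <- rep(0, n_f)
  if (n_assoc > 0) {
    assoc_idx <- sample.int(n_f, n_assoc)
    signs[assoc_idx] <- rep(c(1, -1), c(n_pos, n_assoc - n_pos))[sample.int(n_assoc)]
  }
  mag <- 10^runif(n_f, log10(config$beta_range[1]), log10(config$beta_range[2]))
  prefix <- if (config$layer == "metabolite") "M" else "P"
  features <- tibble::tibble(
    feature_id = sprintf("%s%04d", prefix, seq_len(n_f)),
    layer = config$layer,
    true_beta = signs * mag,
    class_tag = ifelse(signs > 0, "up", ifelse(signs < 0, "down", "null")),
    outlier_shifted = seq_len(n_f) %in%
      sample.int(n_f, round(config$outlier_feature_frac * n_f))
  )

  # technical structure: batches by subject, run days by acquisition order
  subj_ids <- design$subjects$subject_id
  batch_of <- setNames(
    paste0("B", rep(seq_len(config$n_batches),
                    each = ceiling(length(subj_ids) / config$n_batches),
                    length.out = length(subj_ids))),
    subj_ids
  )
  samples <- samples |>
    dplyr::mutate(
      batch = if (config$layer == "protein") unname(batch_of[.data$subject_id]) else "B1",
      run_day = paste0("D", ceiling(dplyr::row_number() /
                                      ceiling(n_s / config$n_run_days)))
    )

  # linear predictor on the log10 scale
  b_subj <- setNames(rnorm(length(subj_ids), 0, config$subject_sd), subj_ids)
  batch_levels <- unique(samples$batch)
  batch_eff <- setNames(rnorm(length(batch_levels), 0, config$batch_sd), batch_levels)
  if (config$layer != "protein") batch_eff[] <- 0
  runday_levels <- unique(samples$run_day)
  runday_scale <- setNames(10^rnorm(length(runday_levels), 0, config$runday_log_sd),
                           runday_levels)

  mu <- runif(n_f, config$mu_range[1], config$mu_range[2])
  eta <- outer(rep(1, n_s), mu) +
    outer(samples$ft4, features$true_beta) +
    config$gamma_age * samples$age +
    config$gamma_bmi * samples$bmi +
    b_subj[samples$subject_id] +
    batch_eff[samples$batch]

  # idiosyncratic outlier shifts on the designated feature subset
  out_subj <- intersect(design$outlier_subjects, samples$subject_id)
  shifted <- which(features$outlier_shifted)
  if (length(out_subj) > 0 && length(shifted) > 0) {
    for (sb in out_subj) {
      rows <- which(samples$subject_id == sb)
      eta[rows, shifted] <- eta[rows, shifted] +
        rep(rnorm(length(shifted), 0, config$outlier_shift_sd), each = length(rows))
    }
  }

  eta <- eta + matrix(rnorm(n_s * n_f, 0, config$residual_sd), n_s, n_f)
  intensities <- 10^eta * runday_scale[samples$run_day]
  dimnames(intensities) <- list(samples$sample_id, features$feature_id)

  # feature-concentrated missingness
  if (config$missing_rate > 0 && config$missing_feature_frac > 0) {
    affected <- which(runif(n_f) < config$missing_feature_frac)
    rates <- runif(length(affected), 0, config$missing_rate)
    for (k in seq_along(affected)) {
      j <- affected[k]
      if (config$missing_mode == "mcar") {
        intensities[runif(n_s) < rates[k], j] <- NA_real_
      } else {
        cut <- quantile(intensities[, j], rates[k])
        intensities[intensities[, j] <= cut, j] <- NA_real_
      }
    }
  }

  structure(list(intensities = intensities, features = features,
                 samples = samples, config = config),
            class = "omics_layer")
}

#' @export
print.omics_layer <- function(x, ...) {
  cat("<omics_layer> ", x$config$layer, ": ",
      nrow(x$intensities), " samples x ", ncol(x$intensities), " features; ",
      sum(x$features$true_beta != 0), " with planted FT4 effects; ",
      sprintf("%.1f%%", 100 * mean(is.na(x$intensities))), " missing\n", sep = "")
  invisible(x)
}
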