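#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a vector of p-values; thin,
#' named wrapper so the pipeline's multiplicity control is explicit and
#' testable in one place.
#'
#' @param p Numeric vector of p-values in \[0, 1\] (`NA` allowed).
#' @return Adjusted q-values, capped at 1, order-preserving in p.
#' @export
adjust_bh <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.na(p) & (p < 0 | p > 1))) {
    abort("p-values must lie in [0, 1].", class = "thyromics_config_error")
  }
  p.adjust(p, method = "BH")
}

# Fixed-effect design matrix of the association model: intercept, FT4, and
# the baseline age/BMI adjustment; proteome fits additionally adjust for
# experimental batch.
association_design <- function(samples, layer) {
  X <- cbind(`(Intercept)` = 1, ft4 = samples$ft4,
             age = samples$age, bmi = samples$bmi)
  if (layer == "protein") {
    batch <- factor(samples$batch)
    if (nlevels(batch) > 1) {
      B <- stats::model.matrix(~batch)[, -1, drop = FALSE]
      X <- cbind(X, B)
    }
  }
  X
}

#' Fit the per-feature FT4 association model
#'
#' Linear mixed-effect regression of one feature's log10 intensity on serum
#' FT4 with fixed effects for baseline age and BMI (plus experimental batch
#' for the proteome) and a random intercept per study participant, fitted by
#' restricted maximum likelihood on complete cases. The FT4 coefficient is
#' tested by a Wald test with a normal reference. Singular fits (subject
#' variance estimated at zero) are accepted and reduce to ordinary least
#' squares.
#'
#' @param values Numeric vector of log10 intensities, one per sample row.
#' @param samples Sample records with `subject_id`, `ft4`, `age`, `bmi` (and
#'   `batch` for the protein layer).
#' @param layer `"metabolite"` or `"protein"`.
#' @param reml Fit by REML (default) or maximum likelihood.
#' @return One-row tibble: `beta`, `se`, `p`, `n_used`, `n_subjects`,
#'   `lambda` (subject-to-residual variance ratio), `converged`. A feature
#'   with fewer than 2 subjects contributing at least 2 non-missing time
#'   points each is flagged `converged = FALSE` with `NA` estimates.
#' @export
fit_feature_lmm <- function(values, samples, layer = c("metabolite", "protein"),
                            reml = TRUE) {
  layer <- match.arg(layer)
  X <- association_design(samples, layer)
  v <- fit_feature_lmm_impl(values, X, samples$subject_id, reml)
  tibble::tibble(beta = v[1], se = v[2], p = v[3],
                 n_used = as.integer(v[4]), n_subjects = as.integer(v[5]),
                 lambda = v[6], converged = v[7] == 1)
}

# Lean internal fitting path (plain numeric vector out) so that the
# robustness stage can refit thousands of features without per-fit
# allocation overhead.  Returns c(beta, se, p, n_used, n_subjects, lambda,
# converged).
fit_feature_lmm_impl <- function(values, X, subject, reml = TRUE) {
  keep <- which(!is.na(values))
  if (length(keep) == 0) {
    return(c(NA_real_, NA_real_, NA_real_, 0, 0, NA_real_, 0))
  }
  sub <- subject[keep]
  lev <- unique(sub)
  codes <- match(sub, lev)
  unfit <- c(NA_real_, NA_real_, NA_real_, length(keep), length(lev), NA_real_, 0)
  if (sum(tabulate(codes, length(lev)) >= 2) < 2) return(unfit)
  Xk <- X[keep, , drop = FALSE]
  # drop columns a subset may have made constant (e.g. a lost batch level)
  keep_col <- .lean_nonconstant_cols(Xk)
  Xk <- Xk[, keep_col, drop = FALSE]
  i <- match("ft4", colnames(Xk))
  if (is.na(i)) return(unfit)
  res <- .lmm_fit_one(Xk, values[keep], codes - 1L, length(lev), reml)
  if (!isTRUE(res$ok)) return(unfit)
  beta <- res$beta[i]
  se <- res$se[i]
  c(beta, se, 2 * pnorm(-abs(beta / se)),
    length(keep), length(lev), res$lambda, 1)
}

.lean_nonconstant_cols <- function(X) {
  out <- logical(ncol(X))
  out[1] <- TRUE
  for (j in seq_len(ncol(X))[-1]) {
    x <- X[, j]
    out[j] <- any(x != x[1])
  }
  out
}

#' Screen every feature of a layer for FT4 association
#'
#' Applies [fit_feature_lmm()] to each feature of a preprocessed (normalized,
#' filtered, log10) intensity matrix and adjusts the Wald p-values across all
#' converged fits of the layer by Benjamini-Hochberg. FDR is controlled per
#' omics layer: metabolome and proteome are adjusted separately.
#'
#' @param mat Samples x features matrix on the log10 scale, or an
#'   `omics_layer` as returned by [preprocess_layer()] (then `samples` and
#'   `layer` are taken from it).
#' @param samples Sample records aligned with the matrix rows.
#' @param layer `"metabolite"` or `"protein"`.
#' @param reml Passed to [fit_feature_lmm()].
#' @return Tibble with one row per feature: `feature_id`, `beta`, `se`, `p`,
#'   `q`, `n_used`, `converged`. Unconverged features carry `NA` and are
#'   excluded from the FDR adjustment (with a warning).
#' @examples
#' d <- design_study(seed = 1)
#' s <- simulate_hormones(d, seed = 1)
#' layer <- simulate_features(d, s, layer_config("metabolite", n_features = 12,
#'                                               missing_rate = 0), seed = 1)
#' res <- associate_layer(preprocess_layer(layer))
#' head(res)
#' @export
associate_layer <- function(mat, samples = NULL, layer = NULL, reml = TRUE) {
  if (inherits(mat, "omics_layer")) {
    samples <- samples %||% mat$samples
    layer <- layer %||% mat$config$layer
    mat <- mat$intensities
  }
  layer <- match.arg(layer, c("metabolite", "protein"))
  stopifnot(is.matrix(mat), nrow(mat) == nrow(samples))
  covars <- c("ft4", "age", "bmi")
  bad_row <- rowSums(is.na(samples[, covars])) > 0
  if (any(bad_row)) {
    warn(paste0(sum(bad_row), " sample(s) missing FT4/covariates dropped."))
    mat <- mat[!bad_row, , drop = FALSE]
    samples <- samples[!bad_row, ]
  }
  X <- association_design(samples, layer)
  fits <- vapply(seq_len(ncol(mat)), function(j) {
    fit_feature_lmm_impl(mat[, j], X, samples$subject_id, reml)
  }, numeric(7))
  out <- tibble::tibble(
    feature_id = colnames(mat),
    beta = fits[1, ], se = fits[2, ], p = fits[3, ],
    n_used = as.integer(fits[4, ]),
    lambda = fits[6, ], converged = fits[7, ] == 1
  )
  if (any(!out$converged)) {
    warn(paste0(sum(!out$converged),
                " feature(s) could not be fitted and are excluded from FDR."))
  }
  out$q <- NA_real_
  out$q[out$converged] <- adjust_bh(out$p[out$converged])
  dplyr::select(out, "feature_id", "beta", "se", "p", "q",
                "n_used", "lambda", "converged")
}
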