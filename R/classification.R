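#' Label samples by thyroid state
#'
#' Assigns the two classification labels: samples taken before treatment or 8
#' weeks after its cessation are euthyroid; samples from the two treatment
#' time points are hyperthyroid. The intermediate time point (4 weeks after
#' stopping, `w12`) is dropped because it represents a transitional state.
#'
#' @param samples Sample records with `time_point`.
#' @param euthyroid,hyperthyroid Time-point labels mapping to each class.
#' @param drop Time points excluded from classification.
#' @return The input rows for the retained time points with a `class` factor
#'   (`euthyroid`, `hyperthyroid`) added.
#' @examples
#' d <- design_study(seed = 1)
#' s <- simulate_hormones(d, seed = 1)
#' table(label_thyroid_state(s)$class) # 32 per class, 64 total
#' @export
label_thyroid_state <- function(samples,
                                euthyroid = c("bas", "w16"),
                                hyperthyroid = c("w4", "w8"),
                                drop = "w12") {
  tp <- as.character(samples$time_point)
  known <- c(euthyroid, hyperthyroid, drop)
  if (!all(tp %in% known)) {
    bad <- setdiff(unique(tp), known)
    abort(paste0("Unknown time-point label(s): ", paste(bad, collapse = ", ")),
          class = "thyromics_config_error")
  }
  out <- samples[!tp %in% drop, , drop = FALSE]
  out$class <- factor(
    ifelse(as.character(out$time_point) %in% hyperthyroid,
           "hyperthyroid", "euthyroid"),
    levels = c("euthyroid", "hyperthyroid")
  )
  inform(paste0("Labeled ", nrow(out), " samples (",
                sum(out$class == "euthyroid"), " euthyroid, ",
                sum(out$class == "hyperthyroid"), " hyperthyroid); ",
                nrow(samples) - nrow(out), " dropped."))
  out
}

#' Keep only features fully observed in the labeled samples
#'
#' Classification uses complete features only: a feature with any missing
#' value among the labeled samples is removed.
#'
#' @param mat Samples x features matrix (log scale, post-preprocessing).
#' @param labeled Labeled samples from [label_thyroid_state()]; rows of `mat`
#'   are matched by `sample_id`.
#' @return The matrix restricted to labeled samples and complete features.
#' @export
filter_complete_features <- function(mat, labeled) {
  stopifnot(is.matrix(mat))
  m <- mat[labeled$sample_id, , drop = FALSE]
  m[, colSums(is.na(m)) == 0, drop = FALSE]
}

#' Empirical ROC curve and AUC
#'
#' Computes the area under the empirical receiver operating characteristic
#' curve by the trapezoidal rule, with ties handled by the rank/midpoint
#' convention, so the AUC equals the pairwise concordance probability with
#' ties counted one half.
#'
#' @param scores Numeric classifier scores (higher = more likely positive),
#'   e.g. the fraction of forest votes for the positive class.
#' @param labels Logical vector (or factor whose second level is positive);
#'   both classes must be present.
#' @return List with `auc` and `points`, a tibble of `threshold`, `fpr`,
#'   `tpr` tracing the curve from (0,0) to (1,1).
#' @examples
#' roc_auc(c(0.9, 0.8, 0.2, 0.3), c(TRUE, TRUE, TRUE, FALSE))$auc
#' @export
roc_auc <- function(scores, labels) {
  if (is.factor(labels)) labels <- labels == levels(labels)[2]
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    abort("Both classes must be present to compute a ROC curve.",
          class = "thyromics_config_error")
  }
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(labels & scores >= t) / n_pos, 0)
  fpr <- vapply(thr, function(t) sum(!labels & scores >= t) / n_neg, 0)
  points <- tibble::tibble(threshold = c(Inf, thr),
                           fpr = c(0, fpr), tpr = c(0, tpr))
  list(auc = auc, points = points)
}

#' AUC-weighted aggregation of variable importances
#'
#' Averages per-loop Gini importances across inner cross-validation loops,
#' each loop weighted by its test-set ROC AUC:
#' \eqn{I_j = \sum_l w_l g_{lj} / \sum_l w_l} with \eqn{w_l = AUC_l}.
#'
#' @param gini Matrix of Gini importances, one row per inner loop, one column
#'   per feature (column names = feature ids).
#' @param aucs Numeric vector of per-loop AUCs (non-negative, not all zero).
#' @return Named numeric vector of aggregated importances.
#' @export
weighted_importance <- function(gini, aucs) {
  stopifnot(is.matrix(gini), nrow(gini) == length(aucs), all(aucs >= 0))
  if (sum(aucs) == 0) {
    abort("All AUC weights are zero; importances undefined.",
          class = "thyromics_config_error")
  }
  drop(crossprod(gini, aucs)) / sum(aucs)
}

# Stratified split of indices: for each class, a `frac` share (rounded, at
# least 1, at most size-1) goes to the training side.
stratified_split <- function(classes, frac) {
  train <- integer(0)
  for (cl in levels(classes)) {
    idx <- which(classes == cl)
    n_tr <- min(max(round(frac * length(idx)), 1L), length(idx) - 1L)
    train <- c(train, sample(idx, n_tr))
  }
  sort(train)
}

# Subject-aware variant: whole subjects are assigned to one side; split is
# stratified on each subject's majority class.
subject_split <- function(subjects, classes, frac) {
  subj <- unique(subjects)
  maj <- vapply(subj, function(s) {
    names(which.max(table(classes[subjects == s])))
  }, "")
  tr_subj <- character(0)
  for (cl in unique(maj)) {
    s_cl <- subj[maj == cl]
    n_tr <- min(max(round(frac * length(s_cl)), 1L), max(length(s_cl) - 1L, 1L))
    tr_subj <- c(tr_subj, sample(s_cl, n_tr))
  }
  which(subjects %in% tr_subj)
}

draw_split <- function(labeled, frac, subject_aware, max_tries = 50) {
  for (i in seq_len(max_tries)) {
    train <- if (subject_aware) {
      subject_split(labeled$subject_id, labeled$class, frac)
    } else {
      stratified_split(labeled$class, frac)
    }
    test <- setdiff(seq_len(nrow(labeled)), train)
    if (nlevels(droplevels(labeled$class[train])) == 2 &&
        nlevels(droplevels(labeled$class[test])) == 2) {
      return(list(train = train, test = test))
    }
  }
  abort("Could not draw a split containing both classes on both sides.",
        class = "thyromics_config_error")
}

rf_fit <- function(x, y, n_trees, mtry = NULL) {
  mtry <- mtry %||% max(1L, floor(sqrt(ncol(x))))
  randomForest::randomForest(x = x, y = y, ntree = n_trees, mtry = mtry,
                             importance = FALSE)
}

rf_scores <- function(fit, x) {
  unname(predict(fit, x, type = "vote")[, "hyperthyroid"])
}

top_panel <- function(importance, panel_size) {
  ord <- order(-importance, names(importance))
  tibble::tibble(rank = seq_len(panel_size),
                 feature_id = names(importance)[ord][seq_len(panel_size)],
                 importance = unname(importance[ord][seq_len(panel_size)]))
}

#' Two-stage nested cross-validation biomarker panel selection
#'
#' The panel-selection procedure: an outer loop repeatedly splits the labeled
#' samples into training and validation sets; within each outer training set
#' an inner loop repeatedly splits again into training and test sets, trains
#' a random forest on all features, records its test-set ROC AUC and Gini
#' variable importances, and aggregates the importances across inner loops
#' weighted by AUC ([weighted_importance()]). The `panel_size` most important
#' features are then taken forward to a new forest trained on the outer
#' training set, whose ROC on the untouched validation set yields that outer
#' loop's performance estimate. The single reported panel is the AUC-weighted
#' aggregate over all inner loops of all outer loops; per-outer-loop panels
#' are returned as well.
#'
#' @param mat Samples x features matrix, complete features only (see
#'   [filter_complete_features()]); rownames = sample ids.
#' @param labeled Labeled samples from [label_thyroid_state()].
#' @param n_outer,n_inner Numbers of outer and inner repetitions (defaults
#'   30 and 50).
#' @param train_frac Training share of each split (default 2/3), stratified
#'   by class.
#' @param panel_size Number of features in the biomarker panel (default 15).
#' @param n_trees Trees per forest (default 500).
#' @param mtry Candidate variables per split; default `floor(sqrt(p))`.
#' @param subject_aware If `TRUE`, all samples of a subject fall on the same
#'   side of every split (recommended for honest generalization; default
#'   `FALSE`, sample-level splits).
#' @param seed Integer seed; the whole procedure is reproducible.
#' @return A `nested_cv` object: `outer` (tibble: `loop`, `auc`, list-columns
#'   `panel`, `roc`, `train_ids`, `valid_ids`), `inner` (tibble: `outer_loop`,
#'   `inner_loop`, `auc`, `test_ids`), `importance` (tibble, globally
#'   aggregated), `panel` (tibble: `rank`, `feature_id`, `importance`),
#'   `mean_auc`, and the configuration. See [tidy.nested_cv()],
#'   [glance.nested_cv()], [autoplot.nested_cv()].
#' @export
nested_cv <- function(mat, labeled,
                      n_outer = 30, n_inner = 50,
                      train_frac = 2 / 3, panel_size = 15,
                      n_trees = 500, mtry = NULL,
                      subject_aware = FALSE, seed = 1L) {
  stopifnot(is.matrix(mat), !anyNA(mat))
  mat <- mat[labeled$sample_id, , drop = FALSE]
  if (panel_size > ncol(mat)) {
    abort("`panel_size` exceeds the number of available features.",
          class = "thyromics_config_error")
  }
  if (nlevels(droplevels(labeled$class)) < 2) {
    abort("Both classes must be present.", class = "thyromics_config_error")
  }
  set.seed(derive_seed(seed, "cv"))
  all_gini <- matrix(NA_real_, n_outer * n_inner, ncol(mat),
                     dimnames = list(NULL, colnames(mat)))
  all_auc <- numeric(n_outer * n_inner)
  inner_rows <- vector("list", n_outer)
  outer_rows <- vector("list", n_outer)

  for (o in seq_len(n_outer)) {
    sp <- draw_split(labeled, train_frac, subject_aware)
    tr_lab <- labeled[sp$train, , drop = FALSE]
    gini_o <- matrix(NA_real_, n_inner, ncol(mat),
                     dimnames = list(NULL, colnames(mat)))
    auc_o <- numeric(n_inner)
    inner_test_ids <- vector("list", n_inner)
    for (i in seq_len(n_inner)) {
      isp <- draw_split(tr_lab, train_frac, subject_aware)
      fit <- rf_fit(mat[tr_lab$sample_id[isp$train], , drop = FALSE],
                    droplevels(tr_lab$class[isp$train]), n_trees, mtry)
      sc <- rf_scores(fit, mat[tr_lab$sample_id[isp$test], , drop = FALSE])
      auc_o[i] <- roc_auc(sc, tr_lab$class[isp$test])$auc
      gini_o[i, ] <- randomForest::importance(fit)[, "MeanDecreaseGini"]
      inner_test_ids[[i]] <- tr_lab$sample_id[isp$test]
    }
    rows <- (o - 1) * n_inner + seq_len(n_inner)
    all_gini[rows, ] <- gini_o
    all_auc[rows] <- auc_o
    inner_rows[[o]] <- tibble::tibble(outer_loop = o,
                                      inner_loop = seq_len(n_inner),
                                      auc = auc_o,
                                      test_ids = inner_test_ids)

    imp_o <- weighted_importance(gini_o, auc_o)
    pan_o <- top_panel(imp_o, panel_size)
    fit2 <- rf_fit(mat[tr_lab$sample_id, pan_o$feature_id, drop = FALSE],
                   droplevels(tr_lab$class), n_trees,
                   min(mtry %||% max(1L, floor(sqrt(panel_size))), panel_size))
    va_lab <- labeled[sp$test, , drop = FALSE]
    sc <- rf_scores(fit2, mat[va_lab$sample_id, pan_o$feature_id, drop = FALSE])
    roc <- roc_auc(sc, va_lab$class)
    outer_rows[[o]] <- tibble::tibble(
      loop = o, auc = roc$auc,
      panel = list(pan_o), roc = list(roc$points),
      train_ids = list(tr_lab$sample_id),
      valid_ids = list(va_lab$sample_id)
    )
  }

  importance <- weighted_importance(all_gini, all_auc)
  outer <- dplyr::bind_rows(outer_rows)
  structure(list(
    outer = outer,
    inner = dplyr::bind_rows(inner_rows),
    importance = tibble::tibble(feature_id = names(importance),
                                importance = unname(importance)) |>
      dplyr::arrange(dplyr::desc(.data$importance), .data$feature_id),
    panel = top_panel(importance, panel_size),
    mean_auc = mean(outer$auc),
    config = list(n_outer = n_outer, n_inner = n_inner,
                  train_frac = train_frac, panel_size = panel_size,
                  n_trees = n_trees, mtry = mtry,
                  subject_aware = subject_aware, seed = seed)
  ), class = "nested_cv")
}

#' @export
print.nested_cv <- function(x, ...) {
  cat("<nested_cv> ", x$config$n_outer, " outer x ", x$config$n_inner,
      " inner loops; mean validation AUC = ", sprintf("%.3f", x$mean_auc),
      "\n", sep = "")
  cat("Selected panel (", nrow(x$panel), " features): ",
      paste(head(x$panel$feature_id, 5), collapse = ", "),
      if (nrow(x$panel) > 5) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Tidy the per-outer-loop results of a nested cross-validation
#'
#' @param x A `nested_cv` object.
#' @param ... Unused.
#' @return Tibble with one row per outer loop: `loop`, `auc`.
#' @export
tidy.nested_cv <- function(x, ...) {
  dplyr::select(x$outer, "loop", "auc")
}

#' One-row summary of a nested cross-validation
#'
#' @param x A `nested_cv` object.
#' @param ... Unused.
#' @return Tibble: `mean_auc`, `sd_auc`, `n_outer`, `n_inner`, `panel_size`.
#' @export
glance.nested_cv <- function(x, ...) {
  tibble::tibble(mean_auc = x$mean_auc, sd_auc = sd(x$outer$auc),
                 n_outer = x$config$n_outer, n_inner = x$config$n_inner,
                 panel_size = x$config$panel_size)
}

#' ROC curves of the outer validation loops
#'
#' @param object A `nested_cv` object.
#' @param ... Unused.
#' @return A ggplot overlaying the outer-loop validation ROC curves.
#' @export
autoplot.nested_cv <- function(object, ...) {
  df <- object$outer |>
    dplyr::select("loop", "roc") |>
    tidyr::unnest("roc")
  ggplot2::ggplot(df, ggplot2::aes(.data$fpr, .data$tpr, group = .data$loop)) +
    ggplot2::geom_step(alpha = 0.35, colour = "#2166AC") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("Outer-loop ROC curves (mean AUC = %.2f)",
                                  object$mean_auc)) +
    ggplot2::theme_minimal()
}
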