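suppressMessages({

test_that("thyroid-state labeling maps time points and drops the transition", {
  d <- design_study(seed = 2)
  s <- simulate_hormones(d, seed = 2)
  lab <- label_thyroid_state(s)
  expect_equal(nrow(lab), 64)
  expect_equal(as.vector(table(lab$class)), c(32, 32))
  expect_false("w12" %in% as.character(lab$time_point))
  expect_true(all(lab$class[lab$time_point %in% c("bas", "w16")] == "euthyroid"))
  expect_true(all(lab$class[lab$time_point %in% c("w4", "w8")] == "hyperthyroid"))

  d3 <- design_study(n_subjects = 3, seed = 2)
  expect_equal(nrow(label_thyroid_state(simulate_hormones(d3, seed = 2))), 12)
  expect_equal(nrow(label_thyroid_state(s[0, ])), 0)
  bad <- dplyr::mutate(s, time_point = as.character(time_point))
  bad$time_point[1] <- "w99"
  expect_error(label_thyroid_state(bad), "w99",
               class = "thyromics_config_error")
})

test_that("complete-feature filter keeps only fully observed features", {
  ts <- tiny_study(n_subjects = 6, seed = 3, n_features = 10, missing_rate = 0.4)
  lab <- label_thyroid_state(ts$layer$samples)
  m <- filter_complete_features(transform_log10(ts$layer$intensities), lab)
  expect_equal(nrow(m), nrow(lab))
  expect_false(anyNA(m))
  # a feature missing once among labeled samples is dropped even if complete
  # in the dropped w12 samples
  full <- transform_log10(ts$layer$intensities)
  full[, ] <- 1
  full[lab$sample_id[1], 2] <- NA
  kept <- filter_complete_features(full, lab)
  expect_false(colnames(full)[2] %in% colnames(kept))
  expect_equal(ncol(kept), ncol(full) - 1)
})

test_that("AUC-weighted importance matches hand arithmetic and is symmetric", {
  g <- rbind(c(1, 2), c(4, 6))
  colnames(g) <- c("f1", "f2")
  expect_equal(weighted_importance(g, c(1, 0.5)),
               c(f1 = (1 + 0.5 * 4) / 1.5, f2 = (2 + 0.5 * 6) / 1.5))
  expect_equal(weighted_importance(g, c(0.7, 0.7)), colMeans(g))
  expect_equal(weighted_importance(g[2:1, ], c(0.5, 1)),
               weighted_importance(g, c(1, 0.5)))
  expect_error(weighted_importance(g, c(0, 0)), class = "thyromics_config_error")
})

test_that("ROC AUC matches brute-force pairwise concordance", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  expect_equal(roc_auc(rep(0.5, 6), rep(c(TRUE, FALSE), 3))$auc, 0.5)
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.3),
                       c(TRUE, TRUE, TRUE, FALSE))$auc, 2 / 3)
  expect_error(roc_auc(c(0.2, 0.4), c(TRUE, TRUE)),
               class = "thyromics_config_error")
  set.seed(51)
  for (i in 1:30) {
    n <- sample(4:20, 1)
    labels <- c(TRUE, FALSE, runif(n - 2) > 0.5)
    scores <- sample(seq(0, 1, 0.1), n, replace = TRUE) # ties likely
    expect_equal(roc_auc(scores, labels)$auc, auc_brute(scores, labels),
                 tolerance = 1e-12)
  }
  pts <- roc_auc(c(0.9, 0.1, 0.6, 0.4), c(TRUE, FALSE, TRUE, FALSE))$points
  expect_equal(pts$fpr[1], 0)
  expect_equal(pts$tpr[1], 0)
  expect_equal(pts$fpr[nrow(pts)], 1)
  expect_equal(pts$tpr[nrow(pts)], 1)
})

strong_cv_input <- function(n_subjects = 16, n_features = 30, seed = 61,
                            beta = c(0.05, 0.08)) {
  d <- design_study(n_subjects = n_subjects, seed = seed)
  s <- simulate_hormones(d, seed = seed)
  layer <- simulate_features(
    d, s, layer_config("metabolite", n_features = n_features,
                       prop_assoc = 0.3, beta_range = beta,
                       residual_sd = 0.1, subject_sd = 0.1,
                       missing_rate = 0, runday_log_sd = 0,
                       outlier_feature_frac = 0),
    seed = seed)
  lab <- label_thyroid_state(layer$samples)
  list(mat = filter_complete_features(transform_log10(layer$intensities), lab),
       labeled = lab, truth = layer$features)
}

test_that("nested CV emits the configured loop structure and panel size", {
  inp <- strong_cv_input()
  cv <- nested_cv(inp$mat, inp$labeled, n_outer = 4, n_inner = 3,
                  n_trees = 50, panel_size = 5, seed = 71)
  expect_equal(nrow(cv$outer), 4)
  expect_equal(nrow(cv$inner), 4 * 3)
  expect_true(all(cv$outer$auc >= 0 & cv$outer$auc <= 1))
  expect_equal(cv$mean_auc, mean(cv$outer$auc))
  expect_equal(nrow(cv$panel), 5)
  expect_true(all(vapply(cv$outer$panel, nrow, 1L) == 5))
  expect_equal(nrow(glance(cv)), 1)
  expect_equal(nrow(tidy(cv)), 4)
  expect_s3_class(autoplot(cv), "ggplot")
  # reproducibility
  cv2 <- nested_cv(inp$mat, inp$labeled, n_outer = 4, n_inner = 3,
                   n_trees = 50, panel_size = 5, seed = 71)
  expect_identical(cv$panel, cv2$panel)
  expect_identical(cv$outer$auc, cv2$outer$auc)
  expect_error(nested_cv(inp$mat, inp$labeled, panel_size = 1000, seed = 1),
               class = "thyromics_config_error")
})

test_that("outer validation samples never enter inner-loop training or selection", {
  inp <- strong_cv_input(n_features = 20)
  cv <- nested_cv(inp$mat, inp$labeled, n_outer = 3, n_inner = 4,
                  n_trees = 50, panel_size = 5, seed = 73)
  for (o in seq_len(nrow(cv$outer))) {
    train <- cv$outer$train_ids[[o]]
    valid <- cv$outer$valid_ids[[o]]
    expect_length(intersect(train, valid), 0)
    expect_setequal(c(train, valid), inp$labeled$sample_id)
    inner_o <- cv$inner[cv$inner$outer_loop == o, ]
    for (ids in inner_o$test_ids) {
      expect_true(all(ids %in% train))
    }
  }
})

test_that("subject-aware splits keep each subject on one side", {
  inp <- strong_cv_input(n_features = 20)
  cv <- nested_cv(inp$mat, inp$labeled, n_outer = 3, n_inner = 2,
                  n_trees = 50, panel_size = 5, subject_aware = TRUE, seed = 79)
  subj_of <- setNames(inp$labeled$subject_id, inp$labeled$sample_id)
  for (o in seq_len(nrow(cv$outer))) {
    expect_length(intersect(unique(subj_of[cv$outer$train_ids[[o]]]),
                            unique(subj_of[cv$outer$valid_ids[[o]]])), 0)
  }
})

test_that("classifier separates strong signal and not permuted labels", {
  inp <- strong_cv_input(n_features = 30, beta = c(0.06, 0.1))
  cv <- nested_cv(inp$mat, inp$labeled, n_outer = 5, n_inner = 5,
                  n_trees = 100, panel_size = 10, seed = 83)
  expect_gt(cv$mean_auc, 0.9)
  # planted features dominate the selected panel
  planted <- inp$truth$feature_id[inp$truth$true_beta != 0]
  expect_gte(mean(cv$panel$feature_id %in% planted), 0.8)

  set.seed(91)
  perm <- inp$labeled
  perm$class <- sample(perm$class)
  cv0 <- nested_cv(inp$mat, perm, n_outer = 8, n_inner = 4,
                   n_trees = 100, panel_size = 10, seed = 91)
  expect_gt(cv0$mean_auc, 0.35)
  expect_lt(cv0$mean_auc, 0.65)
})

})
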