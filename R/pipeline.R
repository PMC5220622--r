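#' Write / read an intensity matrix as TSV
#'
#' Canonical table dialect of the pipeline: tab-delimited, header row, first
#' column `sample_id`, empty cell = missing, UTF-8, '.' decimal.
#'
#' @param mat Samples x features matrix with rownames.
#' @param path Output file.
#' @return `write_matrix_tsv()` returns `path` invisibly; `read_matrix_tsv()`
#'   returns the matrix.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(sample_id = rownames(mat), mat, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, na.strings = "")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

write_tsv_plain <- function(df, path) {
  df <- as.data.frame(lapply(df, function(x) {
    if (is.list(x)) vapply(x, paste, "", collapse = ",") else x
  }), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Assemble a pipeline configuration
#'
#' Bundles the knobs of every stage into one validated list. The defaults
#' reproduce the study conditions (16 subjects, 5 time points, 101-subset
#' robustness, 15-feature panel) on layers small enough for a quick demo run.
#'
#' @param n_subjects,n_outliers Passed to [design_study()].
#' @param hormone_params Passed to [simulate_hormones()].
#' @param layers Named list of [layer_config()]s (names are labels only; each
#'   config carries its own layer type).
#' @param threshold Missingness-filter threshold.
#' @param n_random Random leave-three-out draws (the fixed outlier triple is
#'   always added, so the plan has `n_random + 1` subsets).
#' @param cv List of overrides for [nested_cv()] arguments.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(n_subjects = 16, n_outliers = 3,
                            hormone_params = hormone_defaults(),
                            layers = list(
                              metabolite = layer_config("metabolite", n_features = 60),
                              protein = layer_config("protein", n_features = 60)
                            ),
                            threshold = 0.40,
                            n_random = 100,
                            cv = list(n_outer = 10, n_inner = 10,
                                      n_trees = 200, panel_size = 15)) {
  stopifnot(length(layers) >= 1,
            all(vapply(layers, inherits, TRUE, "layer_config")))
  structure(list(n_subjects = n_subjects, n_outliers = n_outliers,
                 hormone_params = hormone_params, layers = layers,
                 threshold = threshold, n_random = n_random, cv = cv),
            class = "pipeline_config")
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes simulate, preprocess, associate, robust, foldchange and classify
#' in order, writing every stage's tables to `out_dir` together with a run
#' manifest carrying the configuration hash and seed. All randomness flows
#' from the single `seed` through named per-stage substreams, so the same
#' configuration and seed reproduce the run exactly.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed Integer master seed.
#' @return Invisibly, a list with the in-memory stage results (`design`,
#'   `samples`, per-layer `layers`, `associations`, `robust`, `foldchange`,
#'   `cv`) and the `manifest` tibble.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, seed = 1L) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_hash <- rlang::hash(config)
  manifest <- list()
  note <- function(stage, output, n_rows) {
    manifest[[length(manifest) + 1]] <<- tibble::tibble(
      stage = stage, output = output, n_rows = n_rows,
      seed = seed, config_hash = cfg_hash)
  }

  design <- design_study(n_subjects = config$n_subjects,
                         n_outliers = config$n_outliers, seed = seed)
  samples <- simulate_hormones(design, config$hormone_params, seed = seed)

  results <- list(design = design, samples = samples, layers = list(),
                  associations = list(), robust = list(), foldchange = list())
  plan <- make_subsets(design$subjects$subject_id, n_random = config$n_random,
                       fixed_exclusion = design$outlier_subjects, seed = seed)
  inform(paste0("Robustness plan: ", nrow(plan), " subsets."))

  cv_mats <- list()
  for (nm in names(config$layers)) {
    lcfg <- config$layers[[nm]]
    layer <- simulate_features(design, samples, lcfg, seed = seed)
    results$layers[[nm]] <- layer
    write_matrix_tsv(layer$intensities,
                     file.path(out_dir, paste0(nm, "_intensities.tsv")))
    note("simulate", paste0(nm, "_intensities.tsv"), nrow(layer$intensities))

    pre <- preprocess_layer(layer, threshold = config$threshold)
    inform(paste0(nm, ": ", ncol(pre$intensities), " of ", lcfg$n_features,
                  " features pass the missingness filter."))

    assoc <- associate_layer(pre)
    results$associations[[nm]] <- assoc
    write_tsv_plain(assoc, file.path(out_dir, paste0("associations_", nm, ".tsv")))
    note("associate", paste0("associations_", nm, ".tsv"), nrow(assoc))

    rob <- robust_associate(pre, plan = plan)
    results$robust[[nm]] <- rob
    write_tsv_plain(rob, file.path(out_dir, paste0("robust_", nm, ".tsv")))
    note("robust", paste0("robust_", nm, ".tsv"), nrow(rob))
    inform(paste0(nm, ": ", sum(rob$significant),
                  " features significant by mean FDR < 0.05."))

    raw_kept <- layer$intensities[, colnames(pre$intensities), drop = FALSE]
    fc <- mean_log2fc(raw_kept, layer$samples)
    results$foldchange[[nm]] <- fc
    write_tsv_plain(dplyr::select(fc, -"n_subjects"),
                    file.path(out_dir, paste0("foldchange_", nm, ".tsv")))
    write_tsv_plain(dplyr::select(fc, -"mean_log2fc"),
                    file.path(out_dir, paste0("counts_", nm, ".tsv")))
    note("foldchange", paste0("foldchange_", nm, ".tsv"), nrow(fc))

    cv_mats[[nm]] <- pre$intensities
  }

  # classification on the combined layers, complete features only
  labeled <- label_thyroid_state(samples)
  combined <- do.call(cbind, cv_mats)
  cmat <- filter_complete_features(combined, labeled)
  cv_args <- utils::modifyList(
    list(mat = cmat, labeled = labeled, seed = seed), config$cv)
  cv <- do.call(nested_cv, cv_args)
  results$cv <- cv
  write_tsv_plain(cv$panel, file.path(out_dir, "panel.tsv"))
  write_tsv_plain(tidy(cv), file.path(out_dir, "auc_summary.tsv"))
  roc_pts <- cv$outer |>
    dplyr::select("loop", "roc") |>
    tidyr::unnest("roc")
  write_tsv_plain(roc_pts, file.path(out_dir, "roc_points.tsv"))
  note("classify", "panel.tsv", nrow(cv$panel))
  note("classify", "auc_summary.tsv", cv$config$n_outer)

  samples_out <- results$layers[[1]]$samples
  write_tsv_plain(samples_out, file.path(out_dir, "samples.tsv"))
  note("simulate", "samples.tsv", nrow(samples_out))
  truth <- dplyr::bind_rows(lapply(results$layers, function(l) l$features))
  write_tsv_plain(truth[, c("feature_id", "layer", "true_beta")],
                  file.path(out_dir, "truth.tsv"))
  note("simulate", "truth.tsv", nrow(truth))

  results$manifest <- dplyr::bind_rows(manifest)
  write_tsv_plain(results$manifest, file.path(out_dir, "manifest.tsv"))
  invisible(results)
}
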