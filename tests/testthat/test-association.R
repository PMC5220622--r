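sim_samples <- function(n_subj = 10, tp = 5, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    subject_id = rep(sprintf("S%02d", 1:n_subj), each = tp),
    ft4 = rnorm(n_subj * tp, 20, 6),
    age = rep(runif(n_subj, 22, 34), each = tp),
    bmi = rep(runif(n_subj, 21, 30), each = tp),
    batch = rep(rep(c("B1", "B2"), length.out = n_subj), each = tp)
  )
}

test_that("noiseless linear signal is recovered exactly", {
  s <- sim_samples()
  y <- 0.02 * s$ft4 + 3
  fit <- fit_feature_lmm(y, s, "metabolite")
  expect_true(fit$converged)
  expect_equal(fit$beta, 0.02, tolerance = 1e-8)
})

test_that("profiled fit at the true variance ratio matches dense GLS", {
  s <- sim_samples(n_subj = 8, seed = 7)
  lambda <- 2.5
  set.seed(7)
  subj <- factor(s$subject_id)
  y <- 1 + 0.015 * s$ft4 + 0.002 * s$age +
    rep(rnorm(nlevels(subj), 0, sqrt(lambda) * 0.2), each = 5) +
    rnorm(nrow(s), 0, 0.2)
  X <- cbind(1, s$ft4, s$age, s$bmi)
  Z <- model.matrix(~ subj - 1)
  V <- diag(nrow(s)) + lambda * tcrossprod(Z)
  beta_oracle <- solve(t(X) %*% solve(V, X), t(X) %*% solve(V, y))
  res <- thyromics:::.lmm_gls_fixed(X, y, as.integer(subj) - 1L,
                                    nlevels(subj), lambda)
  expect_equal(as.vector(res$beta), as.vector(beta_oracle), tolerance = 1e-6)
  # the implied covariance factor matches the dense computation too
  expect_equal(res$XVX, t(X) %*% solve(V, X), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("REML estimates agree with lme4 on realistic data", {
  skip_if_not_installed("lme4")
  s <- sim_samples(n_subj = 16, seed = 3)
  for (rep_seed in 1:3) {
    set.seed(rep_seed)
    y <- 2 + 0.01 * s$ft4 + 0.003 * s$age + 0.005 * s$bmi +
      rep(rnorm(16, 0, 0.2), each = 5) + rnorm(nrow(s), 0, 0.15)
    fit <- fit_feature_lmm(y, s, "metabolite")
    m <- lme4::lmer(y ~ ft4 + age + bmi + (1 | subject_id),
                    data = cbind(s, y = y), REML = TRUE)
    expect_equal(fit$beta, unname(lme4::fixef(m)["ft4"]), tolerance = 1e-5)
    expect_equal(fit$se, unname(sqrt(diag(as.matrix(vcov(m))))[2]),
                 tolerance = 1e-4)
  }
})

test_that("protein fits adjust for batch, metabolite fits do not", {
  s <- sim_samples(n_subj = 16, seed = 5)
  set.seed(5)
  batch_shift <- ifelse(s$batch == "B2", 0.8, 0)
  y <- 1 + 0.01 * s$ft4 + batch_shift +
    rep(rnorm(16, 0, 0.05), each = 5) + rnorm(nrow(s), 0, 0.05)
  prot <- fit_feature_lmm(y, s, "protein")
  metab <- fit_feature_lmm(y, s, "metabolite")
  expect_lt(abs(prot$beta - 0.01), 2e-3)
  # ignoring the batch shift inflates the apparent subject heterogeneity
  expect_gt(metab$lambda, prot$lambda)
})

test_that("insufficient data is flagged rather than fitted", {
  s <- sim_samples(n_subj = 3, tp = 5)
  y <- rnorm(nrow(s))
  y[6:15] <- NA # leaves one subject with >=2 points
  fit <- fit_feature_lmm(y, s, "metabolite")
  expect_false(fit$converged)
  expect_true(is.na(fit$beta))
})

test_that("BH adjustment matches the hand step-up formula", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(rep(1, 5)), rep(1, 5))
  expect_equal(adjust_bh(0.03), 0.03)
  expect_equal(adjust_bh(numeric(0)), numeric(0))
  set.seed(8)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))^sample(1:3, 1)
    q <- adjust_bh(p)
    expect_equal(q, bh_brute(p), tolerance = 1e-12)
    expect_true(all(q[order(p)] == cummax(q[order(p)]))) # monotone in p
    expect_true(all(q >= p & q <= 1))
  }
  expect_error(adjust_bh(c(0.2, 1.4)), class = "thyromics_config_error")
})

test_that("layer-wide screen: null calibration, ranking, and single-feature identity", {
  layer <- null_layer(n_features = 1000, seed = 17)
  pre <- preprocess_layer(layer, runday_normalize = FALSE)
  res <- associate_layer(pre)
  expect_true(all(res$converged))
  frac <- mean(res$p < 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 1000) + 0.01)
  ks <- suppressWarnings(stats::ks.test(res$p, "punif"))
  expect_gt(ks$p.value, 1e-3)

  # strong planted features outrank nulls by |beta|/se
  d <- design_study(seed = 19)
  s <- simulate_hormones(d, seed = 19)
  strong <- simulate_features(
    d, s, layer_config("metabolite", n_features = 40, prop_assoc = 0.25,
                       beta_range = c(0.05, 0.08), residual_sd = 0.05,
                       subject_sd = 0.05, missing_rate = 0,
                       runday_log_sd = 0, outlier_feature_frac = 0),
    seed = 19)
  res2 <- associate_layer(preprocess_layer(strong, runday_normalize = FALSE))
  z <- abs(res2$beta / res2$se)
  planted <- strong$features$true_beta != 0
  expect_gt(min(z[planted]), max(z[!planted]))

  one <- associate_layer(pre$intensities[, 1, drop = FALSE], pre$samples,
                         "metabolite")
  expect_equal(one$q, one$p)
})

test_that("estimates are invariant to feature order and sample-row permutation", {
  ts <- tiny_study(n_subjects = 10, seed = 23, n_features = 6)
  pre <- preprocess_layer(ts$layer, runday_normalize = FALSE)
  res <- associate_layer(pre)
  set.seed(1)
  perm_f <- sample(ncol(pre$intensities))
  res_f <- associate_layer(pre$intensities[, perm_f], pre$samples, "metabolite")
  # summation order perturbs the near-flat profiled optimum by float-epsilon
  # amounts, so the variance ratio is compared more loosely than the
  # coefficients
  cmp <- function(a, b) {
    expect_equal(dplyr::select(a, -lambda), dplyr::select(b, -lambda),
                 tolerance = 1e-6)
    expect_equal(a$lambda, b$lambda, tolerance = 1e-3)
  }
  cmp(dplyr::arrange(res_f, feature_id), dplyr::arrange(res, feature_id))
  perm_s <- sample(nrow(pre$intensities))
  res_s <- associate_layer(pre$intensities[perm_s, ], pre$samples[perm_s, ],
                           "metabolite")
  cmp(res_s, res)
})
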