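# Small simulated fixtures shared across test files.

tiny_study <- function(n_subjects = 8, seed = 11, n_features = 12,
                       missing_rate = 0, ...) {
  d <- design_study(n_subjects = n_subjects, seed = seed)
  s <- simulate_hormones(d, seed = seed)
  layer <- simulate_features(
    d, s, layer_config("metabolite", n_features = n_features,
                       missing_rate = missing_rate, ...),
    seed = seed)
  list(design = d, samples = s, layer = layer)
}

# A global-null layer: no planted effects, no technical structure unless
# asked for.
null_layer <- function(n_subjects = 16, n_features = 50, seed = 5, ...) {
  d <- design_study(n_subjects = n_subjects, seed = seed)
  s <- simulate_hormones(d, seed = seed)
  simulate_features(
    d, s, layer_config("metabolite", n_features = n_features,
                       prop_assoc = 0, missing_rate = 0,
                       runday_log_sd = 0, ...),
    seed = seed)
}

# Brute-force AUC: pairwise concordance probability with ties counted 1/2.
auc_brute <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  s <- 0
  for (a in pos) for (b in neg) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(pos) * length(neg))
}

# Hand-evaluated BH step-up: q_(i) = min_{j >= i} p_(j) * m / j, capped at 1.
bh_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- pmin(rev(cummin(rev(p[ord] * m / seq_len(m)))), 1)
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}
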