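test_that("stratified_kfold partitions samples with balanced class counts", {
  y <- label_vector(setNames(rep(c(0L, 1L), each = 50), sprintf("s%03d", 1:100)))
  sp <- stratified_kfold(y, k = 10, seed = 3)
  all_test <- unlist(lapply(sp$folds, `[[`, "test"))
  expect_setequal(all_test, names(y))
  expect_equal(anyDuplicated(all_test), 0L)
  for (f in sp$folds) {
    expect_equal(sum(y[f$test]), 5L)
    expect_length(f$test, 10L)
    expect_setequal(c(f$train, f$test), names(y))
  }

  # 11 positives, 9 negatives, k = 10 -> each fold has 1 or 2 positives
  y2 <- label_vector(setNames(c(rep(1L, 11), rep(0L, 9)), sprintf("t%02d", 1:20)))
  expect_error(stratified_kfold(y2, k = 10), ">= k")  # 9 negatives < k
  sp2 <- stratified_kfold(y2, k = 9, seed = 1)
  pos_per_fold <- vapply(sp2$folds, function(f) sum(y2[f$test]), integer(1))
  expect_true(all(pos_per_fold %in% 1:2))

  expect_identical(stratified_kfold(y, 10, seed = 7)$folds,
                   stratified_kfold(y, 10, seed = 7)$folds)
})

test_that("stratified_kfold invariants hold over many random label vectors", {
  set.seed(99)
  for (rep in 1:200) {
    k <- sample(2:6, 1)
    n_pos <- k + sample(0:30, 1)
    n_neg <- k + sample(0:30, 1)
    y <- label_vector(setNames(sample(c(rep(1L, n_pos), rep(0L, n_neg))),
                               sprintf("s%03d", seq_len(n_pos + n_neg))))
    sp <- stratified_kfold(y, k, seed = rep)
    all_test <- unlist(lapply(sp$folds, `[[`, "test"))
    expect_setequal(all_test, names(y))
    expect_equal(anyDuplicated(all_test), 0L)
    global_prop <- mean(y)
    for (f in sp$folds) {
      # positive count within 1 of proportionality
      expect_lte(abs(sum(y[f$test]) - global_prop * length(f$test)), 1 + 1e-9)
    }
  }
})

test_that("compute_metrics matches hand examples and the pair-concordance oracle", {
  m <- compute_metrics(c(a = 0, b = 0, c = 1, d = 1),
                       c(0.1, 0.4, 0.35, 0.8), score_type = "probability")
  expect_equal(unname(m[["auc"]]), 0.75)

  expect_equal(unname(compute_metrics(c(x = 0, y = 1), c(-3, 3))[["auc"]]), 1.0)
  expect_equal(unname(compute_metrics(c(x = 0, y = 1, z = 1),
                                      c(2, 2, 2))[["auc"]]), 0.5)
  expect_error(compute_metrics(c(a = 1, b = 1), c(0.2, 0.3)), "single class")

  set.seed(31)
  for (rep in 1:50) {
    n <- sample(4:50, 1)
    y <- c(0L, 1L, sample(0:1, n - 2, replace = TRUE))
    s <- sample(round(rnorm(n), 2))   # rounding forces occasional ties
    expect_equal(unname(compute_metrics(setNames(y, seq_len(n)), s)[["auc"]]),
                 oracle_auc(y, s))
  }
})

test_that("AUC is invariant under strictly increasing score transforms", {
  set.seed(12)
  y <- setNames(sample(0:1, 30, replace = TRUE), 1:30)
  y[1] <- 0; y[2] <- 1
  s <- rnorm(30)
  a0 <- compute_metrics(y, s)[["auc"]]
  expect_equal(compute_metrics(y, 3 * s + 2)[["auc"]], a0)
  expect_equal(compute_metrics(y, exp(s))[["auc"]], a0)
  expect_equal(compute_metrics(y, stats::plogis(s), "probability")[["auc"]], a0)
})

test_that("aggregate_folds computes mean and n-1 sd", {
  r <- data.frame(accuracy = c(0.6, 0.8), precision = c(0.5, 0.7),
                  recall = c(0.5, 0.9), f1 = c(0.5, 0.8), auc = c(0.6, 0.8))
  agg <- aggregate_folds(r)
  expect_equal(agg$mean[agg$metric == "auc"], 0.7)
  expect_equal(agg$sd[agg$metric == "auc"], 0.1414, tolerance = 1e-3)
  expect_equal(aggregate_folds(r[c(1, 1), ])$sd[5], 0)
  expect_true(is.na(aggregate_folds(r[1, ])$sd[1]))
})

test_that("t-tests follow the one-sided protocol and degenerate conventions", {
  aucs <- c(0.70, 0.72, 0.68, 0.71, 0.69, 0.73, 0.70, 0.69, 0.71, 0.72)
  expect_lt(test_vs_baseline(aucs, 0.65)$p_value, 0.001)
  expect_lt(test_vs_random_guess(aucs)$p_value, 1e-4)

  expect_warning(r1 <- test_vs_baseline(rep(0.6, 5), 0.6), "zero variance")
  expect_equal(r1$p_value, 1)
  expect_warning(r2 <- test_vs_baseline(rep(0.9, 10), 0.5), "zero variance")
  expect_equal(r2$p_value, 0)
  expect_warning(r3 <- test_vs_random_guess(rep(0.5, 4)), "zero variance")
  expect_equal(r3$p_value, 1)

  sym <- c(0.45, 0.55, 0.48, 0.52)
  expect_gte(test_vs_random_guess(sym)$p_value, 0.4)

  a <- c(0.7, 0.75, 0.72); b <- c(0.6, 0.66, 0.61)
  expect_lt(test_model_vs_model(a, b)$p_value, 0.05)
  expect_warning(ident <- test_model_vs_model(a, a), "zero variance")
  expect_equal(ident$p_value, 1)
  expect_warning(shift <- test_model_vs_model(b + 0.05, b), "zero variance")
  expect_equal(shift$p_value, 0)
  expect_error(test_model_vs_model(a, c(0.5, 0.6)), "equal-length")
})

test_that("bh_adjust matches the hand example, p.adjust and the brute-force oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.07, 6)), rep(0.07, 6))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(77)
  for (rep in 1:200) {
    p <- runif(sample(1:20, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p))
    expect_equal(adj, p.adjust(p, method = "BH"))
    expect_true(all(adj >= p - 1e-12))
    expect_true(all(adj <= 1))
    # monotone nondecreasing in raw-p rank order
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
  }
})

test_that("null_significance runs the per-fold t-tests with joint BH", {
  k <- 5
  orig <- rep(0.7, k)
  same <- matrix(0.7, k, 20)
  suppressWarnings(nc_same <- null_significance(orig, same))
  expect_equal(nc_same$p_raw, rep(1, k))

  set.seed(8)
  below <- matrix(rnorm(k * 100, mean = 0.6, sd = 0.02), k, 100)
  nc <- null_significance(orig, below)
  expect_true(all(nc$p_raw < 1e-10))
  expect_true(all(nc$p_adjusted >= nc$p_raw))
  expect_equal(nc$p_adjusted, bh_adjust(nc$p_raw))
})
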