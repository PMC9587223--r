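#' Stratified k-fold splits
#'
#' Shuffles each class independently and deals ids round-robin into k folds,
#' so fold class counts differ by at most one subject from perfect
#' proportionality. Deterministic given `seed`.
#'
#' @param labels a `label_vector`.
#' @param k number of folds (paper protocol: 10).
#' @param seed integer seed.
#' @return Object of class `cv_splits`: list with `k`, `seed`, `labels`, and
#'   `folds` — a list of `list(train, test)` id vectors whose test sets
#'   partition the sample set.
#' @export
stratified_kfold <- function(labels, k = 10L, seed = 1L) {
  assert_scalar_count(k, "k", min = 2L)
  ids <- names(labels)
  tab <- table(labels)
  if (any(tab < k)) {
    stop(sprintf("each class needs >= k members (have %s)",
                 paste(tab, collapse = "/")), call. = FALSE)
  }
  assign_fold <- integer(length(ids))
  names(assign_fold) <- ids
  with_seed(seed, {
    for (cls in c(0L, 1L)) {
      members <- sample(ids[labels == cls])
      assign_fold[members] <- rep_len(seq_len(k), length(members))
    }
  })
  folds <- lapply(seq_len(k), function(f) {
    test <- ids[assign_fold == f]
    list(train = setdiff(ids, test), test = test)
  })
  structure(list(k = as.integer(k), seed = as.integer(seed),
                 labels = labels, folds = folds), class = "cv_splits")
}

#' Classification metrics from scores
#'
#' AUC is the probability that a random positive outranks a random negative,
#' with ties counted one half (rank/Mann-Whitney formulation). Accuracy,
#' precision, recall and F1 use the 0.5 threshold on logistic-mapped scores
#' (`plogis(score)` when `score_type = "logit"`). Precision/F1 are 0 when
#' their denominator is 0.
#'
#' @param y_true named 0/1 vector; both classes must be present.
#' @param scores real-valued scores, same length/order (higher = more
#'   positive).
#' @param score_type `"logit"` (decision values mapped through the logistic
#'   function) or `"probability"`.
#' @return Named numeric vector: `accuracy`, `precision`, `recall`, `f1`,
#'   `auc`.
#' @export
compute_metrics <- function(y_true, scores, score_type = c("logit", "probability")) {
  score_type <- match.arg(score_type)
  y <- as.integer(y_true)
  stopifnot(length(y) == length(scores))
  if (length(unique(y)) < 2L) {
    stop("AUC undefined: y_true contains a single class", call. = FALSE)
  }
  prob <- if (score_type == "logit") stats::plogis(scores) else scores
  pred <- as.integer(prob >= 0.5)
  tp <- sum(pred == 1L & y == 1L); fp <- sum(pred == 1L & y == 0L)
  fn <- sum(pred == 0L & y == 1L)
  acc <- mean(pred == y)
  prec <- if (tp + fp > 0L) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0L) tp / (tp + fn) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  r <- rank(scores, ties.method = "average")
  npos <- sum(y == 1L); nneg <- sum(y == 0L)
  auc <- (sum(r[y == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)
  c(accuracy = acc, precision = prec, recall = rec, f1 = f1, auc = auc)
}

#' Aggregate fold results
#'
#' @param results data.frame of fold results (as produced by the training
#'   functions), with metric columns `accuracy`, `precision`, `recall`, `f1`,
#'   `auc`.
#' @return data.frame with one row per metric: `mean` and `sd` (sample sd,
#'   n - 1 denominator; `NA` for a single fold).
#' @export
aggregate_folds <- function(results) {
  metrics <- c("accuracy", "precision", "recall", "f1", "auc")
  metrics <- intersect(metrics, names(results))
  data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(results[[m]]), numeric(1L)),
    sd = vapply(metrics, function(m) {
      if (nrow(results) >= 2L) stats::sd(results[[m]]) else NA_real_
    }, numeric(1L)),
    row.names = NULL
  )
}

# shared one-sample t machinery with the degenerate zero-variance convention
one_sample_t <- function(x, mu, alternative, test_name) {
  n <- length(x)
  stopifnot(n >= 2L)
  if (stats::sd(x) == 0) {
    warning(sprintf("%s: zero variance, degenerate p by sign convention", test_name))
    p <- switch(alternative,
                greater = if (mean(x) > mu) 0 else 1,
                less = if (mean(x) < mu) 0 else 1)
    stat <- if (mean(x) == mu) 0 else sign(mean(x) - mu) * Inf
  } else {
    ht <- stats::t.test(x, mu = mu, alternative = alternative)
    p <- unname(ht$p.value)
    stat <- unname(ht$statistic)
  }
  structure(list(test = test_name, statistic = stat, p_value = p,
                 sidedness = paste0("one_sided_", alternative), n = n),
            class = "gb_test_result")
}

#' @export
print.gb_test_result <- function(x, ...) {
  cat(sprintf("%s: t=%.4g, p=%.4g (%s, n=%d)\n", x$test, x$statistic,
              x$p_value, x$sidedness, x$n))
  invisible(x)
}

#' One-sample t-test of fold AUCs against a baseline mean
#'
#' One-sided (greater): is the model's per-fold AUC distribution above the
#' baseline model's mean AUC, used as a fixed reference?
#'
#' @param fold_aucs numeric vector of per-fold AUCs (k >= 2).
#' @param baseline_mean reference value.
#' @return A `gb_test_result` (test name, statistic, p-value, sidedness, n).
#' @export
test_vs_baseline <- function(fold_aucs, baseline_mean) {
  one_sample_t(fold_aucs, baseline_mean, "greater", "vs_baseline")
}

#' One-sample t-test of fold AUCs against random guessing (AUC 0.5)
#'
#' @inheritParams test_vs_baseline
#' @return A `gb_test_result`.
#' @export
test_vs_random_guess <- function(fold_aucs) {
  one_sample_t(fold_aucs, 0.5, "greater", "vs_random")
}

#' Model-vs-model fold AUC comparison
#'
#' Tests whether model a outperforms model b, one-sided. Paired by default
#' (the models share the same folds); set `paired = FALSE` for a Welch
#' two-sample test.
#'
#' @param fold_aucs_a,fold_aucs_b per-fold AUC vectors (same fold order when
#'   paired).
#' @param paired use a paired design (default `TRUE`).
#' @return A `gb_test_result`.
#' @export
test_model_vs_model <- function(fold_aucs_a, fold_aucs_b, paired = TRUE) {
  if (paired) {
    if (length(fold_aucs_a) != length(fold_aucs_b)) {
      stop("paired test needs equal-length fold vectors", call. = FALSE)
    }
    one_sample_t(fold_aucs_a - fold_aucs_b, 0, "greater", "model_vs_model_paired")
  } else {
    ht <- stats::t.test(fold_aucs_a, fold_aucs_b, alternative = "greater")
    structure(list(test = "model_vs_model_welch",
                   statistic = unname(ht$statistic),
                   p_value = unname(ht$p.value),
                   sidedness = "one_sided_greater",
                   n = length(fold_aucs_a) + length(fold_aucs_b)),
              class = "gb_test_result")
  }
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `adjusted_i = min over ranks >= rank(i) of p_j * m / rank_j`, capped at 1.
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must be in [0, 1]", call. = FALSE)
  }
  m <- length(pvals)
  if (m == 0L) return(numeric())
  o <- order(pvals, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(m / (m:1) * pvals[o]))[ro]
  adj
}

#' Random-network significance of per-fold AUCs
#'
#' For each fold, a one-sample one-sided t-test asks whether the m null
#' (randomized-template) AUCs are LESS than the original template's AUC in
#' that fold; the k raw p-values are then BH-adjusted jointly across folds.
#'
#' @param original_fold_aucs numeric vector of k original per-fold AUCs.
#' @param null_aucs k x m matrix: row j holds the m null AUCs for fold j.
#' @return Object of class `null_comparison`: `original`, `null_aucs`,
#'   `p_raw`, `p_adjusted`.
#' @export
null_significance <- function(original_fold_aucs, null_aucs) {
  null_aucs <- as.matrix(null_aucs)
  k <- length(original_fold_aucs)
  stopifnot(nrow(null_aucs) == k, ncol(null_aucs) >= 2L)
  p_raw <- vapply(seq_len(k), function(j) {
    one_sample_t(null_aucs[j, ], original_fold_aucs[j], "less",
                 sprintf("null_fold_%d", j))$p_value
  }, numeric(1L))
  structure(list(original = original_fold_aucs, null_aucs = null_aucs,
                 p_raw = p_raw, p_adjusted = bh_adjust(p_raw)),
            class = "null_comparison")
}

#' @export
print.null_comparison <- function(x, ...) {
  k <- length(x$original)
  cat(sprintf("<null_comparison: %d folds x %d null members; %d/%d folds adj p < 0.05>\n",
              k, ncol(x$null_aucs), sum(x$p_adjusted < 0.05), k))
  invisible(x)
}
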