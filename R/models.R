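#' GNN configuration
#'
#' Architectural and training settings for the graph-level classifier. The
#' protocol constraints are fixed by the benchmark design: 2 message-passing
#' layers (matched to the small diameter of the disease subnetworks, to avoid
#' over-smoothing), 200 epochs with no early stopping, and 3 repeat seeds per
#' experiment. The remaining defaults follow the GraphGym recommended design
#' space: hidden_dim 128, sum aggregation, mean readout, Adam at learning
#' rate 0.01 with cosine decay, batch 32, weight decay 5e-4, dropout 0.
#'
#' @param n_message_layers number of message-passing layers (>= 0; 0 is the
#'   no-message-passing ablation, reducing the model to a GLM on pooled
#'   attributes).
#' @param epochs training epochs.
#' @param hidden_dim node embedding width.
#' @param aggregation neighbor aggregation: `"sum"`, `"mean"`, or `"max"`.
#' @param readout graph pooling: `"mean"` or `"sum"`.
#' @param learning_rate Adam learning rate (cosine-decayed over epochs when
#'   `cosine_decay`).
#' @param batch_size minibatch size.
#' @param weight_decay L2 penalty on weight matrices.
#' @param dropout dropout fraction on hidden activations.
#' @param n_seeds number of repeat runs averaged per experiment.
#' @param cosine_decay decay the learning rate with a cosine schedule.
#' @return A list of class `gnn_config`.
#' @export
gnn_config <- function(n_message_layers = 2L, epochs = 200L, hidden_dim = 128L,
                       aggregation = c("sum", "mean", "max"),
                       readout = c("mean", "sum"),
                       learning_rate = 0.01, batch_size = 32L,
                       weight_decay = 5e-4, dropout = 0, n_seeds = 3L,
                       cosine_decay = TRUE) {
  aggregation <- match.arg(aggregation)
  readout <- match.arg(readout)
  stopifnot(n_message_layers >= 0L, epochs >= 0L, n_seeds >= 1L,
            hidden_dim >= 1L, batch_size >= 1L, dropout >= 0, dropout < 1)
  structure(list(
    n_message_layers = as.integer(n_message_layers), epochs = as.integer(epochs),
    hidden_dim = as.integer(hidden_dim), aggregation = aggregation,
    readout = readout, learning_rate = learning_rate,
    batch_size = as.integer(batch_size), weight_decay = weight_decay,
    dropout = dropout, n_seeds = as.integer(n_seeds),
    cosine_decay = isTRUE(cosine_decay)
  ), class = "gnn_config")
}

fold_result_row <- function(dataset, model, fold, metrics, hyper = list()) {
  data.frame(dataset = dataset, model = model, fold = fold,
             accuracy = metrics[["accuracy"]], precision = metrics[["precision"]],
             recall = metrics[["recall"]], f1 = metrics[["f1"]],
             auc = metrics[["auc"]],
             hyperparams = jsonlite::toJSON(hyper, auto_unbox = TRUE,
                                            digits = NA),
             stringsAsFactors = FALSE)
}

#' Train and evaluate the GNN on one fold
#'
#' Runs the full GNN procedure once per seed (`config$n_seeds` repeats) on
#' the training subjects and averages the test metrics over seeds.
#'
#' @param dataset a `graph_dataset` (template must be connected).
#' @param split `list(train, test)` of disjoint subject-id vectors; training
#'   labels must contain both classes.
#' @param config a [gnn_config()].
#' @param seed integer seed; per-repeat seeds are derived from it.
#' @param fold fold index recorded in the result (default 0).
#' @param allow_disconnected accept a disconnected template (default `FALSE`:
#'   pipeline templates are expected to be largest connected components).
#'   Message passing itself is well defined on disconnected graphs, and
#'   degree-preserving rewired null templates may be disconnected, so the
#'   null-model path sets this to `TRUE`.
#' @return One-row data.frame of fold metrics (columns `dataset`, `model`,
#'   `fold`, the five metrics, `hyperparams`), with attributes `"per_seed"`
#'   (metrics matrix) and `"test_scores"` (per-seed-averaged logits, named by
#'   subject).
#' @export
train_gnn <- function(dataset, split, config = gnn_config(), seed = 1L,
                      fold = 0L, allow_disconnected = FALSE) {
  stopifnot(inherits(dataset, "graph_dataset"), inherits(config, "gnn_config"))
  if (!allow_disconnected && !igraph::is_connected(dataset$template$graph)) {
    stop("template is disconnected; apply largest_connected_component() first",
         call. = FALSE)
  }
  train <- split$train; test <- split$test
  if (length(intersect(train, test))) stop("train/test overlap", call. = FALSE)
  y_tr <- dataset$labels[train]
  if (length(unique(y_tr)) < 2L) {
    stop("training fold contains a single class", call. = FALSE)
  }
  node_idx <- stats::setNames(seq_along(dataset$node_order) - 1L, dataset$node_order)
  el <- network_edges(dataset$template)
  edges <- cbind(node_idx[el[, 1L]], node_idx[el[, 2L]])
  storage.mode(edges) <- "integer"
  X_tr <- dataset$attrs[train, , drop = FALSE]
  X_te <- dataset$attrs[test, , drop = FALSE]
  agg_code <- match(config$aggregation, c("sum", "mean", "max")) - 1L
  ro_code <- match(config$readout, c("mean", "sum")) - 1L

  per_seed <- NULL
  scores_acc <- 0
  for (s in seq_len(config$n_seeds)) {
    fit <- gnn_train_cpp(edges, length(dataset$node_order),
                         X_tr, as.numeric(y_tr), X_te,
                         config$epochs, config$hidden_dim,
                         config$n_message_layers, agg_code, ro_code,
                         config$learning_rate, config$batch_size,
                         config$weight_decay, config$dropout,
                         derive_seed(seed, s, "gnn"), config$cosine_decay)
    m <- compute_metrics(dataset$labels[test], as.numeric(fit$test_scores))
    per_seed <- rbind(per_seed, m)
    scores_acc <- scores_acc + as.numeric(fit$test_scores)
  }
  rownames(per_seed) <- paste0("seed", seq_len(config$n_seeds))
  out <- fold_result_row(dataset$name, "gnn", fold, colMeans(per_seed),
                         hyper = config[c("n_message_layers", "epochs",
                                          "hidden_dim", "aggregation",
                                          "readout", "learning_rate",
                                          "batch_size", "weight_decay",
                                          "dropout", "n_seeds")])
  attr(out, "per_seed") <- per_seed
  attr(out, "test_scores") <- stats::setNames(scores_acc / config$n_seeds, test)
  out
}

# ---- tabular model fitting primitives ---------------------------------------
# sklearn-style C parameterisation: minimize 0.5||w||^2 + C * sum(loss_i).
# Logistic loss for logreg, squared hinge for the SVMs (differentiable, so
# the primal can be solved with L-BFGS); the RBF machine is fit in function
# space f = K alpha + b with ridge term 0.5 alpha' K alpha.

fit_logreg <- function(X, y, C = 1) {
  X <- as.matrix(X); t <- 2 * y - 1
  p <- ncol(X)
  obj <- function(th) {
    w <- th[seq_len(p)]; b <- th[p + 1L]
    f <- drop(X %*% w) + b
    0.5 * sum(w^2) + C * sum(log1p(exp(-t * f)))
  }
  grd <- function(th) {
    w <- th[seq_len(p)]; b <- th[p + 1L]
    f <- drop(X %*% w) + b
    s <- stats::plogis(-t * f)   # sigmoid(-t f)
    gw <- w - C * drop(crossprod(X, t * s))
    c(gw, -C * sum(t * s))
  }
  th <- stats::optim(rep(0, p + 1L), obj, grd, method = "L-BFGS-B",
                     control = list(maxit = 200L))$par
  list(w = th[seq_len(p)], b = th[p + 1L],
       predict = function(Xn) drop(as.matrix(Xn) %*% th[seq_len(p)]) + th[p + 1L])
}

fit_svm_linear <- function(X, y, C = 1) {
  X <- as.matrix(X); t <- 2 * y - 1
  p <- ncol(X)
  obj <- function(th) {
    w <- th[seq_len(p)]; b <- th[p + 1L]
    h <- pmax(0, 1 - t * (drop(X %*% w) + b))
    0.5 * sum(w^2) + C * sum(h^2)
  }
  grd <- function(th) {
    w <- th[seq_len(p)]; b <- th[p + 1L]
    h <- pmax(0, 1 - t * (drop(X %*% w) + b))
    gw <- w - 2 * C * drop(crossprod(X, t * h))
    c(gw, -2 * C * sum(t * h))
  }
  th <- stats::optim(rep(0, p + 1L), obj, grd, method = "L-BFGS-B",
                     control = list(maxit = 200L))$par
  list(w = th[seq_len(p)], b = th[p + 1L],
       predict = function(Xn) drop(as.matrix(Xn) %*% th[seq_len(p)]) + th[p + 1L])
}

rbf_kernel <- function(A, B, gamma) {
  A <- as.matrix(A); B <- as.matrix(B)
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  exp(-gamma * pmax(d2, 0))
}

fit_svm_rbf <- function(X, y, C = 1, gamma = "scale", maxit = 150L) {
  X <- as.matrix(X); t <- 2 * y - 1
  n <- nrow(X)
  if (identical(gamma, "scale")) {
    v <- stats::var(as.vector(X))
    gamma <- if (v > 0) 1 / (ncol(X) * v) else 1
  } else {
    gamma <- as.numeric(gamma)
  }
  K <- rbf_kernel(X, X, gamma)
  obj <- function(th) {
    a <- th[seq_len(n)]; b <- th[n + 1L]
    f <- drop(K %*% a) + b
    h <- pmax(0, 1 - t * f)
    0.5 * sum(a * drop(K %*% a)) + C * sum(h^2)
  }
  grd <- function(th) {
    a <- th[seq_len(n)]; b <- th[n + 1L]
    Ka <- drop(K %*% a)
    h <- pmax(0, 1 - t * (Ka + b))
    ga <- Ka - 2 * C * drop(K %*% (t * h))
    c(ga, -2 * C * sum(t * h))
  }
  th <- stats::optim(rep(0, n + 1L), obj, grd, method = "L-BFGS-B",
                     control = list(maxit = as.integer(maxit)))$par
  a <- th[seq_len(n)]; b <- th[n + 1L]
  list(alpha = a, b = b, gamma = gamma,
       predict = function(Xn) drop(rbf_kernel(Xn, X, gamma) %*% a) + b)
}

#' Default hyperparameter grids for the tabular baselines
#'
#' Logistic regression `C` in \{0.01, 0.1, 1, 10, 100\}; SVMs `C` in
#' \{0.1, 1, 10, 100\} with RBF `gamma` in \{scale, 0.01, 0.1, 1\}; random
#' forest trees in \{100, 500\} and max depth in \{unlimited, 5, 10\}
#' (`0` codes unlimited).
#'
#' @return Named list of grids (one data.frame of candidates per model).
#' @export
default_grids <- function() {
  list(
    logreg = expand.grid(C = c(0.01, 0.1, 1, 10, 100),
                         stringsAsFactors = FALSE),
    svm_linear = expand.grid(C = c(0.1, 1, 10, 100), stringsAsFactors = FALSE),
    svm_rbf = expand.grid(C = c(0.1, 1, 10, 100),
                          gamma = c("scale", "0.01", "0.1", "1"),
                          stringsAsFactors = FALSE),
    random_forest = expand.grid(n_trees = c(100L, 500L),
                                max_depth = c(0L, 5L, 10L),
                                stringsAsFactors = FALSE)
  )
}

# fit one tabular model with given hyperparameters and score a held-out set;
# returns decision values ("logit"-type scores)
fit_and_score <- function(model, X_tr, y_tr, X_te, hyper, seed = 1L) {
  switch(model,
    logreg = fit_logreg(X_tr, y_tr, C = hyper$C)$predict(X_te),
    svm_linear = fit_svm_linear(X_tr, y_tr, C = hyper$C)$predict(X_te),
    svm_rbf = fit_svm_rbf(X_tr, y_tr, C = hyper$C, gamma = hyper$gamma,
                          maxit = hyper$maxit %||% 150L)$predict(X_te),
    random_forest = {
      fit <- rf_train_predict_cpp(as.matrix(X_tr), as.integer(y_tr),
                                  as.matrix(X_te), as.integer(hyper$n_trees),
                                  as.integer(hyper$max_depth), -1L, 1L,
                                  as.integer(seed))
      # map leaf probabilities to the logit scale used everywhere else
      stats::qlogis(pmin(pmax(fit$test_prob, 1e-6), 1 - 1e-6))
    },
    stop("unknown model: ", model, call. = FALSE)
  )
}

#' Nested cross-validated tabular baseline on one fold
#'
#' Features are the raw gene burden columns (tabular, no interaction
#' information). Hyperparameters are chosen by a stratified `inner_k`-fold
#' grid search on the training portion only (mean inner AUC; an inner fold
#' whose validation set has one class is skipped with a warning), the chosen
#' model is refit on the full training portion and evaluated on the test
#' portion. Test labels are never touched during selection.
#'
#' @param counts a [count_matrix()].
#' @param labels a `label_vector`.
#' @param split `list(train, test)` of subject ids.
#' @param model `"logreg"`, `"svm_linear"`, `"svm_rbf"` or `"random_forest"`.
#' @param grid data.frame of hyperparameter candidates (default
#'   [default_grids()] entry for `model`).
#' @param inner_k inner folds (paper protocol: 10).
#' @param seed integer seed for inner splits and the forest.
#' @param fold fold index recorded in the result.
#' @return One-row data.frame of fold metrics with the chosen hyperparameters
#'   in `hyperparams`; attribute `"test_scores"` holds the decision values.
#' @export
train_baseline <- function(counts, labels, split, model, grid = NULL,
                           inner_k = 10L, seed = 1L, fold = 0L) {
  grid <- grid %||% default_grids()[[model]]
  if (is.null(grid) || nrow(grid) == 0L) stop("empty hyperparameter grid", call. = FALSE)
  train <- split$train; test <- split$test
  X <- t(counts)
  y <- labels
  inner <- stratified_kfold(label_vector(y[train]), k = inner_k,
                            seed = derive_seed(seed, fold, "inner"))
  if (nrow(grid) == 1L) {
    best <- 1L
  } else {
    inner_auc <- vapply(seq_len(nrow(grid)), function(ci) {
      hyper <- as.list(grid[ci, , drop = FALSE])
      aucs <- vapply(inner$folds, function(f) {
        yv <- y[f$test]
        if (length(unique(yv)) < 2L) {
          warning("inner validation fold with a single class skipped")
          return(NA_real_)
        }
        sc <- fit_and_score(model, X[f$train, , drop = FALSE], y[f$train],
                            X[f$test, , drop = FALSE], hyper,
                            seed = derive_seed(seed, ci, "rf_inner"))
        unname(compute_metrics(yv, sc)[["auc"]])
      }, numeric(1L))
      mean(aucs, na.rm = TRUE)
    }, numeric(1L))
    best <- which.max(inner_auc)   # ties -> first candidate in grid order
  }
  hyper <- as.list(grid[best, , drop = FALSE])
  sc <- fit_and_score(model, X[train, , drop = FALSE], y[train],
                      X[test, , drop = FALSE], hyper,
                      seed = derive_seed(seed, 0L, "rf_final"))
  m <- compute_metrics(y[test], sc)
  out <- fold_result_row(attr(counts, "dataset_name") %||% "dataset",
                         model, fold, m, hyper = hyper)
  attr(out, "test_scores") <- stats::setNames(sc, test)
  out
}

#' Single-gene logistic baseline (APOE-style)
#'
#' A logistic regression taking only one gene's burden column as input, with
#' no hyperparameter search — the reference every other model is compared
#' against.
#'
#' @inheritParams train_baseline
#' @param gene gene symbol; must be a row of `counts`.
#' @return One-row fold-metrics data.frame (model `"apoe_baseline"`).
#' @export
apoe_baseline <- function(counts, labels, split, gene = "APOE", fold = 0L) {
  if (!gene %in% rownames(counts)) stop("gene not in counts: ", gene, call. = FALSE)
  train <- split$train; test <- split$test
  X <- t(counts[gene, , drop = FALSE])
  y <- labels
  fit <- fit_logreg(X[train, , drop = FALSE], y[train], C = 1)
  sc <- fit$predict(X[test, , drop = FALSE])
  m <- compute_metrics(y[test], sc)
  out <- fold_result_row(attr(counts, "dataset_name") %||% "dataset",
                         "apoe_baseline", fold, m, hyper = list(gene = gene))
  attr(out, "test_scores") <- stats::setNames(sc, test)
  out
}
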