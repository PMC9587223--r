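# shared small configs keep the suite fast; protocol-scale settings are
# exercised in test-acceptance.R
fast_gnn <- function(...) gnn_config(epochs = 60, hidden_dim = 8, n_seeds = 1, ...)

test_that("GNN separates a separable-by-construction fixture and is deterministic", {
  sepd <- separable_dataset(200L)
  ds <- build_graph_dataset(sepd$template, sepd$counts, sepd$labels, "sep")
  sp <- stratified_kfold(ds$labels, k = 4, seed = 1)$folds[[1]]

  r <- train_gnn(ds, sp, fast_gnn(), seed = 2)
  expect_gt(r$auc, 0.95)

  r2 <- train_gnn(ds, sp, fast_gnn(), seed = 2)
  expect_identical(r$auc, r2$auc)
  expect_identical(attr(r, "test_scores"), attr(r2, "test_scores"))

  # permuted labels -> chance-level test AUC (wide band)
  set.seed(4)
  perm <- ds
  perm$labels <- label_vector(setNames(sample(as.integer(ds$labels)),
                                       names(ds$labels)))
  rp <- train_gnn(perm, sp, fast_gnn(), seed = 3)
  expect_gte(rp$auc, 0.30)
  expect_lte(rp$auc, 0.70)
})

test_that("GNN guards its preconditions", {
  sepd <- separable_dataset(40L)
  ds <- build_graph_dataset(sepd$template, sepd$counts, sepd$labels)
  ids <- rownames(ds$attrs)
  expect_error(train_gnn(ds, list(train = ids[1:10], test = ids[10:20]),
                         fast_gnn()), "overlap")
  pos <- names(ds$labels)[ds$labels == 1]
  expect_error(train_gnn(ds, list(train = pos, test = setdiff(ids, pos)),
                         fast_gnn()), "single class")

  disc <- ds
  disc$template <- gene_network(rbind(c("APOE", "GENE1")),
                                nodes = ds$node_order)
  expect_error(train_gnn(disc, list(train = ids[1:30], test = ids[31:40]),
                         fast_gnn()), "disconnected")
})

test_that("GNN forward pass is permutation-equivariant", {
  sepd <- separable_dataset(60L)
  ds <- build_graph_dataset(sepd$template, sepd$counts, sepd$labels)
  node_idx <- setNames(seq_along(ds$node_order) - 1L, ds$node_order)
  el <- network_edges(ds$template)
  edges <- cbind(node_idx[el[, 1]], node_idx[el[, 2]])
  storage.mode(edges) <- "integer"
  X <- ds$attrs[1:30, ]
  y <- as.numeric(ds$labels[rownames(X)])

  for (epochs in c(0L, 3L)) {
    base <- graphburden:::gnn_train_cpp(edges, ncol(X), X, y, X,
                                        epochs, 8L, 2L, 0L, 0L,
                                        0.01, 8L, 0, 0, 11L, TRUE)
    perm <- sample(ncol(X))
    pmap <- order(perm)  # new index of old node i
    edges_p <- matrix(as.integer(pmap[edges + 1L] - 1L), ncol = 2L)
    Xp <- X[, perm]
    permuted <- graphburden:::gnn_train_cpp(edges_p, ncol(X), Xp, y, Xp,
                                            epochs, 8L, 2L, 0L, 0L,
                                            0.01, 8L, 0, 0, 11L, TRUE)
    expect_equal(base$test_scores, permuted$test_scores, tolerance = 1e-8)
  }
})

test_that("zero message-passing layers reduce the GNN to a pooled-attribute GLM", {
  sepd <- separable_dataset(200L)
  ds <- build_graph_dataset(sepd$template, sepd$counts, sepd$labels)
  sp <- stratified_kfold(ds$labels, k = 4, seed = 2)$folds[[1]]
  r0 <- train_gnn(ds, sp, gnn_config(n_message_layers = 0, readout = "sum",
                                     epochs = 120, hidden_dim = 8, n_seeds = 1),
                  seed = 5)
  pooled <- rowSums(ds$attrs)
  dtr <- data.frame(y = as.integer(ds$labels[sp$train]), pooled = pooled[sp$train])
  fit <- glm(y ~ pooled, data = dtr, family = binomial())
  sc <- predict(fit, newdata = data.frame(pooled = pooled[sp$test]))
  names(sc) <- sp$test
  auc_glm <- compute_metrics(ds$labels[sp$test], sc)[["auc"]]
  expect_lt(abs(r0$auc - auc_glm), 0.05)
})

test_that("training loss at convergence does not rise with hidden_dim", {
  sepd <- separable_dataset(120L)
  ds <- build_graph_dataset(sepd$template, sepd$counts, sepd$labels)
  ids <- rownames(ds$attrs)
  sp <- list(train = ids[1:90], test = ids[91:120])
  node_idx <- setNames(seq_along(ds$node_order) - 1L, ds$node_order)
  el <- network_edges(ds$template)
  edges <- cbind(node_idx[el[, 1]], node_idx[el[, 2]])
  storage.mode(edges) <- "integer"
  losses <- vapply(c(4L, 8L, 16L), function(h) {
    graphburden:::gnn_train_cpp(edges, ncol(ds$attrs),
                                ds$attrs[sp$train, ], as.numeric(ds$labels[sp$train]),
                                ds$attrs[sp$test, ],
                                150L, h, 2L, 0L, 0L, 0.01, 16L, 0, 0, 3L,
                                TRUE)$train_loss
  }, numeric(1))
  expect_lte(losses[2], losses[1] + 1e-3)
  expect_lte(losses[3], losses[2] + 1e-3)
})

test_that("tabular baselines separate the separable fixture", {
  sepd <- separable_dataset(200L)
  sp <- stratified_kfold(sepd$labels, k = 4, seed = 3)$folds[[1]]
  for (m in c("logreg", "svm_linear", "svm_rbf", "random_forest")) {
    r <- train_baseline(sepd$counts, sepd$labels, sp, m, inner_k = 3, seed = 1)
    expect_gt(r$auc, 0.95)
  }
})

test_that("constant features give AUC 0.5 and size-1 grids degenerate to a direct fit", {
  ids <- sprintf("c%03d", 1:60)
  counts <- count_matrix(matrix(1L, 3, 60, dimnames = list(paste0("G", 1:3), ids)))
  labels <- label_vector(setNames(rep(c(0L, 1L), 30), ids))
  sp <- stratified_kfold(labels, k = 3, seed = 1)$folds[[1]]
  r <- train_baseline(counts, labels, sp, "logreg", inner_k = 3, seed = 1)
  expect_equal(r$auc, 0.5)

  sepd <- separable_dataset(100L)
  sp2 <- stratified_kfold(sepd$labels, k = 3, seed = 2)$folds[[1]]
  g1 <- train_baseline(sepd$counts, sepd$labels, sp2, "logreg",
                       grid = data.frame(C = 1), inner_k = 3, seed = 1)
  expect_equal(jsonlite::fromJSON(g1$hyperparams)$C, 1)
  expect_error(train_baseline(sepd$counts, sepd$labels, sp2, "logreg",
                              grid = data.frame(C = numeric())), "empty")
})

test_that("nested CV selection never touches test labels", {
  sepd <- separable_dataset(120L, seed = 6)
  sp <- stratified_kfold(sepd$labels, k = 3, seed = 5)$folds[[1]]
  r1 <- train_baseline(sepd$counts, sepd$labels, sp, "svm_linear",
                       inner_k = 4, seed = 9)
  flipped <- sepd$labels
  flipped[sp$test] <- 1L - flipped[sp$test]
  # keep both classes in the flipped test set
  r2 <- train_baseline(sepd$counts, label_vector(flipped), sp, "svm_linear",
                       inner_k = 4, seed = 9)
  expect_identical(r1$hyperparams, r2$hyperparams)
  expect_identical(attr(r1, "test_scores"), attr(r2, "test_scores"))
  expect_false(isTRUE(all.equal(r1$auc, r2$auc)))
})

test_that("single-gene baseline behaves like its null and identity cases", {
  tmpl <- default_template(12, seed = 3)
  sim <- simulate_cohort(sim_params(n_subjects = 600, template = tmpl,
                                    beta_main = 0, seed = 21))
  labels <- label_vector(sim$truth$latent)
  sp <- stratified_kfold(labels, k = 3, seed = 1)$folds[[1]]
  r_null <- apoe_baseline(sim$counts, labels, sp)
  expect_gt(r_null$auc, 0.3); expect_lt(r_null$auc, 0.7)

  # duplicated single-gene table: full logreg (grid C = 1) == baseline exactly
  sepd <- separable_dataset(100L)
  single <- sepd$counts["APOE", , drop = FALSE]
  class(single) <- class(sepd$counts)
  sp2 <- stratified_kfold(sepd$labels, k = 3, seed = 2)$folds[[1]]
  ra <- apoe_baseline(single, sepd$labels, sp2)
  rl <- train_baseline(single, sepd$labels, sp2, "logreg",
                       grid = data.frame(C = 1), inner_k = 3, seed = 1)
  expect_equal(attr(ra, "test_scores"), attr(rl, "test_scores"))
  expect_equal(ra$auc, rl$auc)
  expect_error(apoe_baseline(sepd$counts, sepd$labels, sp2, gene = "NOPE"),
               "not in counts")
})

test_that("random forest is deterministic given a seed", {
  sepd <- separable_dataset(80L)
  X <- t(sepd$counts)
  y <- as.integer(sepd$labels)
  f1 <- graphburden:::rf_train_predict_cpp(X, y, X, 50L, 0L, -1L, 1L, 77L)
  f2 <- graphburden:::rf_train_predict_cpp(X, y, X, 50L, 0L, -1L, 1L, 77L)
  expect_identical(f1$test_prob, f2$test_prob)
})

test_that("a dominant main-effect gene makes the single-gene baseline competitive", {
  tmpl <- default_template(15, seed = 4)
  sim <- simulate_cohort(sim_params(n_subjects = 700, template = tmpl,
                                    beta_main = 3, seed = 31))
  labels <- label_vector(sim$truth$latent)
  sp <- stratified_kfold(labels, k = 3, seed = 2)$folds[[1]]
  r_apoe <- apoe_baseline(sim$counts, labels, sp)
  r_full <- train_baseline(sim$counts, labels, sp, "logreg", inner_k = 3, seed = 3)
  expect_gt(r_apoe$auc, 0.7)
  expect_lt(abs(r_apoe$auc - r_full$auc), 0.1)
})
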