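#' Benchmark run configuration
#'
#' Collects every input and seed of a full benchmark run. File-based inputs
#' (`paths`) and in-memory objects (`template`, `counts`, `labels`) are both
#' accepted; in-memory objects win when both are given. All randomness is
#' derived from `master_seed` unless a stage seed is set explicitly.
#'
#' @param paths named list of input files: `network`, `genes`, `vcf`,
#'   `counts`, `pheno` (all optional if in-memory objects are supplied).
#' @param template optional [gene_network()] template.
#' @param counts optional [count_matrix()].
#' @param labels optional `label_vector`.
#' @param label_rule `"pet"`, `"pet_dx"` or `"case_control"` (used when labels
#'   come from a phenotype table).
#' @param counting_mode `"site"` or `"dosage"` (used when counting from VCF).
#' @param k outer folds.
#' @param split_seed seed for the outer stratified split (default derived
#'   from `master_seed`).
#' @param gnn a [gnn_config()].
#' @param grids baseline grids (default [default_grids()]).
#' @param inner_k inner folds for the nested grid search.
#' @param models character vector of models to run; subset of
#'   `c("gnn", "logreg", "svm_linear", "svm_rbf", "random_forest")`.
#' @param ablate_gene gene deleted for the ablation arm (`NULL` disables);
#'   also the gene of the single-gene baseline.
#' @param null_method `"rewired"`, `"shuffled"`, or both; `NULL` disables
#'   null-model runs.
#' @param null_count ensemble members per method.
#' @param null_n_seeds GNN repeat seeds for null-template runs (default:
#'   same as `gnn$n_seeds`; can be lowered to trade the repeat protocol for
#'   runtime on large ensembles).
#' @param master_seed master seed for the run.
#' @param out_dir output directory (`NULL` = don't write files).
#' @param case_insensitive gene-symbol matching option for network extraction.
#' @return A list of class `run_config`.
#' @export
run_config <- function(paths = list(), template = NULL, counts = NULL,
                       labels = NULL,
                       label_rule = c("pet", "pet_dx", "case_control"),
                       counting_mode = c("site", "dosage"),
                       k = 10L, split_seed = NULL, gnn = gnn_config(),
                       grids = default_grids(), inner_k = 10L,
                       models = c("gnn", "logreg", "svm_linear", "svm_rbf",
                                  "random_forest"),
                       ablate_gene = "APOE",
                       null_method = NULL, null_count = 100L,
                       null_n_seeds = NULL,
                       master_seed = 1L, out_dir = NULL,
                       case_insensitive = FALSE) {
  label_rule <- match.arg(label_rule)
  counting_mode <- match.arg(counting_mode)
  assert_scalar_count(k, "k", min = 2L)
  structure(list(
    paths = paths, template = template, counts = counts, labels = labels,
    label_rule = label_rule, counting_mode = counting_mode,
    k = as.integer(k),
    split_seed = as.integer(split_seed %||% derive_seed(master_seed, 0L, "split")),
    gnn = gnn, grids = grids, inner_k = as.integer(inner_k),
    models = models, ablate_gene = ablate_gene,
    null_method = null_method, null_count = as.integer(null_count),
    null_n_seeds = if (is.null(null_n_seeds)) NULL else as.integer(null_n_seeds),
    master_seed = as.integer(master_seed), out_dir = out_dir,
    case_insensitive = case_insensitive
  ), class = "run_config")
}

#' Read a benchmark configuration from YAML
#'
#' Scalar fields mirror the [run_config()] arguments; `gnn:` is a mapping of
#' [gnn_config()] arguments.
#'
#' @param path YAML file.
#' @param overrides named list applied over the file values (CLI overrides).
#' @return A `run_config`.
#' @export
read_run_config <- function(path, overrides = list()) {
  y <- yaml::read_yaml(path)
  y[names(overrides)] <- overrides
  gnn_args <- y$gnn %||% list()
  y$gnn <- do.call(gnn_config, gnn_args)
  known <- names(formals(run_config))
  do.call(run_config, y[intersect(names(y), known)])
}

resolve_inputs <- function(config) {
  template <- config$template
  loss <- NULL
  if (is.null(template)) {
    if (is.null(config$paths$network)) stop("no template network configured", call. = FALSE)
    net <- read_edge_list(config$paths$network,
                          case_insensitive = config$case_insensitive)
    genes <- if (!is.null(config$paths$genes)) {
      read_gene_set(config$paths$genes, case_insensitive = config$case_insensitive)
    } else {
      network_nodes(net)
    }
    ext <- extract_subnetwork(net, genes, case_insensitive = config$case_insensitive)
    template <- ext$network
    loss <- ext$loss
  }
  counts <- config$counts
  if (is.null(counts)) {
    if (!is.null(config$paths$vcf)) {
      rec <- filter_missense(parse_annotated_vcf(config$paths$vcf))
      counts <- count_per_gene(rec, genes = network_nodes(template),
                               mode = config$counting_mode)
    } else if (!is.null(config$paths$counts)) {
      counts <- load_count_table(config$paths$counts)
    } else {
      stop("no genotype input (vcf or counts) configured", call. = FALSE)
    }
  }
  labels <- config$labels
  if (is.null(labels)) {
    if (is.null(config$paths$pheno)) stop("no phenotype input configured", call. = FALSE)
    pheno <- read_phenotype_table(config$paths$pheno)
    labels <- switch(config$label_rule,
                     pet = label_pet(pheno),
                     pet_dx = label_pet_dx(label_pet(pheno), pheno),
                     case_control = label_case_control(pheno))
  }
  list(template = template, counts = counts, labels = labels, loss = loss)
}

run_models_on_dataset <- function(dataset, counts, splits, config, tag) {
  results <- list()
  scores <- list()
  for (f in seq_along(splits$folds)) {
    sp <- splits$folds[[f]]
    if ("gnn" %in% config$models) {
      r <- train_gnn(dataset, sp, config$gnn,
                     seed = derive_seed(config$master_seed, f, paste0("gnn_", tag)),
                     fold = f - 1L)
      r$dataset <- tag
      results[[length(results) + 1L]] <- r
    }
    for (mdl in setdiff(config$models, "gnn")) {
      r <- train_baseline(counts, dataset$labels, sp, mdl,
                          grid = config$grids[[mdl]],
                          inner_k = config$inner_k,
                          seed = derive_seed(config$master_seed, f, paste0(mdl, "_", tag)),
                          fold = f - 1L)
      r$dataset <- tag
      results[[length(results) + 1L]] <- r
    }
  }
  do.call(rbind, c(results, list(make.row.names = FALSE)))
}

#' Run the full benchmark
#'
#' Executes the pipeline end to end: network extraction, burden counting,
#' labeling, dataset build, the GNN plus the tabular baselines plus the
#' single-gene logistic baseline across the outer folds, the optional
#' delete-the-main-gene ablation arm, the statistical test battery, and the
#' optional randomized-template null-model comparison. When
#' `config$out_dir` is set, results (CSV), statistics (JSON) and a manifest
#' (config hash, all seeds) are written there.
#'
#' @param config a [run_config()].
#' @return An object of class `benchmark_run`: list with `results` (per-fold
#'   metrics data.frame), `summary`, `stats`, `splits`, `null` (or `NULL`),
#'   `loss`, `manifest`.
#' @export
run_benchmark <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- "inputs"
  res <- tryCatch({
    inp <- resolve_inputs(config)

    stage <- "dataset"
    dataset <- build_graph_dataset(inp$template, inp$counts, inp$labels,
                                   name = "original")
    counts_used <- inp$counts[, rownames(dataset$attrs), drop = FALSE]
    class(counts_used) <- class(inp$counts)

    stage <- "splits"
    splits <- stratified_kfold(dataset$labels, k = config$k,
                               seed = config$split_seed)

    stage <- "baseline"
    base_gene <- config$ablate_gene %||% "APOE"
    baseline_rows <- NULL
    if (base_gene %in% rownames(counts_used)) {
      baseline_rows <- do.call(rbind, lapply(seq_along(splits$folds), function(f) {
        r <- apoe_baseline(counts_used, dataset$labels, splits$folds[[f]],
                           gene = base_gene, fold = f - 1L)
        r$dataset <- "original"
        r
      }))
    }

    stage <- "models"
    rows <- run_models_on_dataset(dataset, counts_used, splits, config, "original")
    results <- rbind(baseline_rows, rows)

    stage <- "ablation"
    if (!is.null(config$ablate_gene) &&
        config$ablate_gene %in% dataset$node_order) {
      dataset_wo <- drop_gene(dataset, config$ablate_gene)
      counts_wo <- counts_used[setdiff(rownames(counts_used), config$ablate_gene),
                               , drop = FALSE]
      class(counts_wo) <- class(counts_used)
      rows_wo <- run_models_on_dataset(dataset_wo, counts_wo, splits, config,
                                       "ablated")
      results <- rbind(results, rows_wo)
    }

    stage <- "statistics"
    stats_out <- benchmark_statistics(results)

    stage <- "nullmodels"
    null_out <- NULL
    if (!is.null(config$null_method) && "gnn" %in% config$models) {
      null_out <- lapply(config$null_method, function(method) {
        run_null_comparison(dataset, splits, config, method)
      })
      names(null_out) <- config$null_method
    }

    summary_df <- do.call(rbind, lapply(split(results,
                                              paste(results$dataset, results$model)),
                                        function(d) {
      agg <- aggregate_folds(d)
      data.frame(dataset = d$dataset[1L], model = d$model[1L],
                 metric = agg$metric, mean = agg$mean, sd = agg$sd,
                 stringsAsFactors = FALSE)
    }))
    rownames(summary_df) <- NULL

    manifest <- list(
      master_seed = config$master_seed,
      split_seed = config$split_seed,
      k = config$k,
      models = config$models,
      label_rule = config$label_rule,
      counting_mode = config$counting_mode,
      ablate_gene = config$ablate_gene,
      null_method = config$null_method,
      null_count = if (!is.null(config$null_method)) config$null_count else NULL,
      config_hash = text_checksum(utils::capture.output(utils::str(
        config[setdiff(names(config), c("template", "counts", "labels"))]))),
      n_subjects = nrow(dataset$attrs),
      template = dataset$template$name,
      n_nodes = length(dataset$node_order)
    )

    structure(list(results = results, summary = summary_df, stats = stats_out,
                   splits = splits, null = null_out, loss = inp$loss,
                   manifest = manifest),
              class = "benchmark_run")
  }, error = function(e) {
    stop(sprintf("benchmark failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(res$results, file.path(config$out_dir, "results.csv"),
                     row.names = FALSE)
    utils::write.csv(res$summary, file.path(config$out_dir, "summary.csv"),
                     row.names = FALSE)
    jsonlite::write_json(res$stats, file.path(config$out_dir, "statistics.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE,
                         null = "null")
    jsonlite::write_json(res$manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, null = "null")
    jsonlite::write_json(
      lapply(res$splits$folds, function(f) f["test"]),
      file.path(config$out_dir, "splits.json"), auto_unbox = FALSE)
    if (!is.null(res$null)) {
      for (method in names(res$null)) {
        nc <- res$null[[method]]
        utils::write.csv(
          data.frame(fold = seq_along(nc$original) - 1L,
                     original_auc = nc$original,
                     null_mean_auc = rowMeans(nc$null_aucs),
                     p_raw = nc$p_raw, p_adjusted = nc$p_adjusted),
          file.path(config$out_dir, sprintf("null_%s.csv", method)),
          row.names = FALSE)
      }
    }
  }
  res
}

# per-fold GNN AUCs on the original template vs an ensemble of randomized
# templates; null runs follow the same repeat-seed protocol as the original
# runs (config$gnn$n_seeds)
run_null_comparison <- function(dataset, splits, config, method) {
  ens <- generate_ensemble(dataset$template, method, config$null_count,
                           master_seed = derive_seed(config$master_seed, 0L,
                                                     paste0("null_", method)))
  k <- length(splits$folds)
  orig <- vapply(seq_len(k), function(f) {
    r <- train_gnn(dataset, splits$folds[[f]], config$gnn,
                   seed = derive_seed(config$master_seed, f, "gnn_original"),
                   fold = f - 1L)
    r$auc
  }, numeric(1L))
  null_cfg <- config$gnn
  if (!is.null(config$null_n_seeds)) null_cfg$n_seeds <- config$null_n_seeds
  null_aucs <- matrix(NA_real_, nrow = k, ncol = config$null_count)
  for (mi in seq_len(config$null_count)) {
    ds_null <- dataset
    ds_null$template <- ens$members[[mi]]
    ds_null$name <- sprintf("%s_%s_%03d", dataset$name, method, mi)
    for (f in seq_len(k)) {
      r <- train_gnn(ds_null, splits$folds[[f]], null_cfg,
                     seed = derive_seed(config$master_seed,
                                        mi * 1000L + f, "gnn_null"),
                     fold = f - 1L, allow_disconnected = TRUE)
      null_aucs[f, mi] <- r$auc
    }
  }
  out <- null_significance(orig, null_aucs)
  out$method <- method
  out$seeds <- ens$seeds
  out
}

# the paper's test battery on a results table: each model vs the single-gene
# baseline mean, vs AUC 0.5, vs the GNN (paired), and with-vs-without the
# ablated gene (paired)
benchmark_statistics <- function(results) {
  out <- list()
  by_arm <- split(results, results$dataset)
  for (arm in names(by_arm)) {
    d <- by_arm[[arm]]
    aucs <- split(d$auc, d$model)
    base_mean <- if ("apoe_baseline" %in% names(aucs)) {
      mean(aucs$apoe_baseline)
    } else {
      by_arm$original$auc[by_arm$original$model == "apoe_baseline"]
      # ablated arm is still compared against the original baseline mean
    }
    if (length(base_mean) > 1L) base_mean <- mean(base_mean)
    tests <- list()
    for (mdl in names(aucs)) {
      x <- aucs[[mdl]]
      if (length(x) < 2L) next
      entry <- list(
        vs_random = test_vs_random_guess(x)[c("statistic", "p_value")]
      )
      if (length(base_mean) == 1L && is.finite(base_mean) && mdl != "apoe_baseline") {
        entry$vs_baseline <- test_vs_baseline(x, base_mean)[c("statistic", "p_value")]
      }
      if ("gnn" %in% names(aucs) && mdl != "gnn") {
        entry$gnn_vs_this <- test_model_vs_model(aucs$gnn, x)[c("statistic", "p_value")]
      }
      tests[[mdl]] <- entry
    }
    out[[arm]] <- tests
  }
  if (all(c("original", "ablated") %in% names(by_arm))) {
    ab <- list()
    for (mdl in intersect(unique(by_arm$original$model),
                          unique(by_arm$ablated$model))) {
      a <- by_arm$original$auc[by_arm$original$model == mdl]
      b <- by_arm$ablated$auc[by_arm$ablated$model == mdl]
      if (length(a) == length(b) && length(a) >= 2L) {
        ab[[mdl]] <- test_model_vs_model(a, b, paired = TRUE)[c("statistic", "p_value")]
      }
    }
    out$with_vs_without_gene <- ab
  }
  out
}

#' @export
print.benchmark_run <- function(x, ...) {
  cat(sprintf("<benchmark_run: %d result rows, %d folds, models: %s>\n",
              nrow(x$results), x$splits$k,
              paste(unique(x$results$model), collapse = ", ")))
  invisible(x)
}
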