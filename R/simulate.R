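#' Simulation parameters for a synthetic cohort
#'
#' Describes the generative model for a cohort with the statistical structure
#' the benchmark assumes: sparse non-negative per-gene missense burden counts
#' (Poisson backgrounds with Gamma-distributed rates, most entries 0), one
#' dominant-effect "APOE-like" gene acting on a logistic liability, optional
#' edge-aligned epistatic signal (product interactions over selected template
#' edges), class-dependent SUVR values for threshold-based PET labeling, and a
#' diagnosis derived from the latent class with a configurable error rate.
#'
#' @param n_subjects cohort size (default 800, the smaller of the two cohort
#'   scales the benchmark emulates).
#' @param template a connected [gene_network()]; default
#'   `default_template(29)`.
#' @param background_rates per-gene Poisson means; default drawn
#'   Gamma(shape 2, mean 0.5), which puts roughly 60% of entries at 0, with
#'   the main gene's rate fixed at 0.5 so its dominance does not depend on
#'   the luck of the Gamma draw.
#' @param main_gene the dominant-effect gene (default `"APOE"`).
#' @param beta_main liability effect per count unit of `main_gene`.
#' @param beta_epi liability effect per interacting pair (`x_u * x_v` summed
#'   over `epi_edges`).
#' @param epi_edges two-column character matrix, a subset of template edges
#'   carrying the epistatic signal (default none).
#' @param target_prevalence desired positive-class fraction; the liability
#'   intercept is calibrated by bisection to reach it within 0.01.
#' @param dx_error_rate probability the diagnosis contradicts the latent class.
#' @param mci_fraction fraction of diagnosis flips recorded as MCI rather than
#'   the opposite pole.
#' @param suvr_means class-conditional SUVR means on the florbetapir scale
#'   (negative, positive); other tracers are shifted so the offset from the
#'   tracer threshold is preserved.
#' @param suvr_sd SUVR standard deviation.
#' @param seed master seed; all randomness flows from it through named
#'   substreams (counts, labels, suvr, dx, tracer).
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_subjects = 800,
                       template = default_template(29),
                       background_rates = NULL,
                       main_gene = "APOE",
                       beta_main = 2,
                       beta_epi = 0,
                       epi_edges = NULL,
                       target_prevalence = 0.5,
                       dx_error_rate = 0.1,
                       mci_fraction = 0.5,
                       suvr_means = c(1.0, 1.4),
                       suvr_sd = 0.15,
                       seed = 1L) {
  assert_scalar_count(n_subjects, "n_subjects")
  stopifnot(inherits(template, "gene_network"))
  nodes <- network_nodes(template)
  if (!main_gene %in% nodes) stop("main_gene not in template", call. = FALSE)
  if (!(target_prevalence > 0 && target_prevalence < 1)) {
    stop("target_prevalence must be in (0, 1)", call. = FALSE)
  }
  if (is.null(background_rates)) {
    background_rates <- with_seed(derive_seed(seed, 0L, "rates"), {
      stats::setNames(stats::rgamma(length(nodes), shape = 2, scale = 0.25), nodes)
    })
    # the dominant-effect gene emulates a common risk variant burden: a fixed
    # rate of 0.5 keeps it dominant rather than leaving dominance to the luck
    # of the Gamma draw
    background_rates[main_gene] <- 0.5
  }
  stopifnot(length(background_rates) == length(nodes))
  if (is.null(names(background_rates))) names(background_rates) <- nodes
  if (!is.null(epi_edges)) {
    epi_edges <- as.matrix(epi_edges)
    flip <- epi_edges[, 1L] > epi_edges[, 2L]
    epi_edges[flip, ] <- epi_edges[flip, 2:1]
    tmpl_keys <- paste(network_edges(template)[, 1L], network_edges(template)[, 2L])
    bad <- !paste(epi_edges[, 1L], epi_edges[, 2L]) %in% tmpl_keys
    if (any(bad)) stop("epi_edges must be a subset of template edges", call. = FALSE)
  }
  structure(list(
    n_subjects = as.integer(n_subjects), template = template,
    background_rates = background_rates, main_gene = main_gene,
    beta_main = beta_main, beta_epi = beta_epi, epi_edges = epi_edges,
    target_prevalence = target_prevalence, dx_error_rate = dx_error_rate,
    mci_fraction = mci_fraction, suvr_means = suvr_means, suvr_sd = suvr_sd,
    seed = as.integer(seed)
  ), class = "sim_params")
}

#' Simulate a synthetic cohort
#'
#' Draws counts `x(g, s) ~ Poisson(rate_g)` independently, computes the
#' liability
#' `eta_s = beta0 + beta_main * x(main, s) + beta_epi * sum_(u,v) x(u,s) x(v,s)`
#' over the epistatic edges, calibrates `beta0` by bisection so the mean of
#' `plogis(eta)` matches the target prevalence within 0.01, draws the latent
#' class `~ Bernoulli(plogis(eta))`, and derives SUVR (class-conditional
#' normal, tracer assigned uniformly with threshold-consistent means),
#' diagnosis (latent class flipped with probability `dx_error_rate`, a
#' fraction of flips recorded as MCI) and a diagnosis-derived case/control
#' column.
#'
#' @param p a [sim_params()] object.
#' @return List with `counts` (a [count_matrix()]), `pheno` (a
#'   [phenotype_table()]), `truth` (liability, latent class, parameter echo).
#' @examples
#' tmpl <- default_template(12, seed = 1)
#' sim <- simulate_cohort(sim_params(n_subjects = 50, template = tmpl,
#'                                   beta_main = 2, seed = 1))
#' dim(sim$counts)
#' table(label_pet(sim$pheno))
#' @export
simulate_cohort <- function(p) {
  stopifnot(inherits(p, "sim_params"))
  genes <- network_nodes(p$template)
  ids <- sprintf("S%04d", seq_len(p$n_subjects))

  counts <- with_seed(derive_seed(p$seed, 1L, "counts"), {
    m <- matrix(stats::rpois(length(genes) * p$n_subjects,
                             rep(p$background_rates[genes], times = p$n_subjects)),
                nrow = length(genes), ncol = p$n_subjects,
                dimnames = list(genes, ids))
    m
  })

  z <- p$beta_main * counts[p$main_gene, ]
  if (!is.null(p$epi_edges) && p$beta_epi != 0) {
    for (i in seq_len(nrow(p$epi_edges))) {
      z <- z + p$beta_epi * counts[p$epi_edges[i, 1L], ] * counts[p$epi_edges[i, 2L], ]
    }
  }

  # bisection on the intercept: mean(plogis(b0 + z)) is increasing in b0
  f <- function(b0) mean(stats::plogis(b0 + z)) - p$target_prevalence
  lo <- -20; hi <- 20
  if (f(lo) > 0 || f(hi) < 0) {
    stop("cannot calibrate intercept to target prevalence; reduce the betas",
         call. = FALSE)
  }
  for (it in seq_len(60L)) {
    mid <- (lo + hi) / 2
    if (abs(f(mid)) <= 0.01) break
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  b0 <- (lo + hi) / 2
  eta <- b0 + z

  latent <- with_seed(derive_seed(p$seed, 2L, "labels"),
                      stats::rbinom(p$n_subjects, 1L, stats::plogis(eta)))

  tracer <- with_seed(derive_seed(p$seed, 3L, "tracer"),
                      sample(c("florbetapir", "pib"), p$n_subjects, replace = TRUE))
  thr <- c(florbetapir = 1.11, pib = 1.27)
  # class-conditional means keep the same offset from each tracer's threshold
  offs <- p$suvr_means - thr[["florbetapir"]]
  mu <- thr[tracer] + offs[latent + 1L]
  suvr <- with_seed(derive_seed(p$seed, 4L, "suvr"),
                    stats::rnorm(p$n_subjects, mean = mu, sd = p$suvr_sd))

  dx <- with_seed(derive_seed(p$seed, 5L, "dx"), {
    flip <- stats::runif(p$n_subjects) < p$dx_error_rate
    mci <- flip & (stats::runif(p$n_subjects) < p$mci_fraction)
    d <- ifelse(latent == 1L, "Dementia", "CN")
    d[flip & !mci] <- ifelse(latent[flip & !mci] == 1L, "CN", "Dementia")
    d[mci] <- "MCI"
    d
  })

  pheno <- phenotype_table(data.frame(
    sample = ids, suvr = round(suvr, 4L), tracer = tracer, diagnosis = dx,
    case_control = ifelse(dx == "Dementia", "case",
                          ifelse(dx == "CN", "control", NA)),
    visit = 1L, stringsAsFactors = FALSE
  ))

  list(
    counts = count_matrix(counts),
    pheno = pheno,
    truth = structure(list(liability = stats::setNames(eta, ids),
                           latent = stats::setNames(latent, ids),
                           intercept = b0, params = p),
                      class = "sim_truth")
  )
}

#' Write a synthetic VCF realizing a count matrix
#'
#' Emits a VEP-style annotated VCF with invented loci such that site-mode
#' recounting with [count_per_gene()] recovers `counts` exactly: gene `g` gets
#' `max_s counts(g, s)` biallelic sites annotated `missense_variant`, and
#' sample `s` is heterozygous at the first `counts(g, s)` of them.
#'
#' @param counts a [count_matrix()].
#' @param path output VCF path.
#' @param seed unused placeholder kept for interface stability (site layout is
#'   deterministic).
#' @return `path`, invisibly.
#' @export
write_synthetic_vcf <- function(counts, path, seed = 1L) {
  samples <- colnames(counts)
  genes <- rownames(counts)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1>",
    paste0("##INFO=<ID=CSQ,Number=.,Type=String,Description=\"Consequence ",
           "annotations. Format: Allele|Consequence|SYMBOL\">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  ), con)
  for (gi in seq_along(genes)) {
    nsite <- if (ncol(counts)) max(counts[gi, ]) else 0L
    if (nsite == 0L) next
    base <- gi * 100000L
    for (s in seq_len(nsite)) {
      gt <- ifelse(counts[gi, ] >= s, "0/1", "0/0")
      row <- paste(c("1", base + s, ".", "A", "G", ".", "PASS",
                     sprintf("CSQ=G|missense_variant|%s", genes[gi]),
                     "GT", gt), collapse = "\t")
      writeLines(row, con)
    }
  }
  invisible(path)
}

#' Default synthetic template network
#'
#' Generates a connected gene network in the density range of the disease
#' subnetworks the benchmark uses (about 0.08-0.20). The highest-degree node
#' is named `"APOE"` by convention; the rest are `GENE001`, `GENE002`, ...
#'
#' For the `"barabasi_albert"` model, construction starts from `m` isolated
#' nodes and each new node attaches `m` distinct edges preferentially, giving
#' exactly `m * (n - m)` edges and a connected hub-dominated graph. `m`
#' defaults to `max(1, round(0.13 * (n - 1) / 2))` so the density lands in the
#' target band.
#'
#' @param n_genes number of nodes.
#' @param model `"barabasi_albert"` (default) or `"erdos_renyi"`.
#' @param seed integer seed.
#' @param ba_m edges added per node for the BA model (default auto).
#' @param er_p edge probability for the ER model (default 0.13); disconnected
#'   draws are resampled up to `max_tries` times, then an error is raised.
#' @param max_tries retry budget for the ER model.
#' @return A connected [gene_network()].
#' @export
default_template <- function(n_genes, model = c("barabasi_albert", "erdos_renyi"),
                             seed = 1L, ba_m = NULL, er_p = 0.13,
                             max_tries = 50L) {
  model <- match.arg(model)
  assert_scalar_count(n_genes, "n_genes", min = 3L)
  g <- with_seed(derive_seed(seed, 0L, paste0("template_", model)), {
    if (model == "barabasi_albert") {
      m <- ba_m %||% max(1L, round(0.13 * (n_genes - 1) / 2))
      igraph::sample_pa(n_genes, m = m, directed = FALSE,
                        algorithm = "psumtree",
                        start.graph = igraph::make_empty_graph(m, directed = FALSE))
    } else {
      for (try in seq_len(max_tries)) {
        gg <- igraph::sample_gnp(n_genes, er_p)
        if (igraph::is_connected(gg)) break
        gg <- NULL
      }
      if (is.null(gg)) stop("could not draw a connected Erdos-Renyi graph; raise er_p",
                            call. = FALSE)
      gg
    }
  })
  deg <- igraph::degree(g)
  hub <- which.max(deg)
  nm <- sprintf("GENE%03d", seq_len(n_genes))
  nm[hub] <- "APOE"
  igraph::V(g)$name <- nm
  el <- igraph::as_edgelist(g)
  gene_network(el, nodes = nm, name = sprintf("synthetic_%s_%d", model, n_genes))
}

#' Write all synthetic-cohort artifacts to a directory
#'
#' Materializes a simulated cohort in the same plain-text formats the
#' real-data path consumes: count table TSV, phenotype CSV, template edge
#' list, truth JSON, and optionally a VEP-style annotated VCF that round-trips
#' through the genotype module.
#'
#' @param p a [sim_params()] object.
#' @param out output directory.
#' @param vcf also write `cohort.vcf` (default `FALSE`).
#' @return Invisibly, the list of file paths written.
#' @export
simulate_command <- function(p, out, vcf = FALSE) {
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_cohort(p)
  paths <- list(
    counts = file.path(out, "counts.tsv"),
    pheno = file.path(out, "phenotype.csv"),
    template = file.path(out, "template.tsv"),
    truth = file.path(out, "truth.json")
  )
  write_count_table(sim$counts, paths$counts)
  utils::write.csv(as.data.frame(sim$pheno), paths$pheno, row.names = FALSE)
  write_edge_list(p$template, paths$template)
  jsonlite::write_json(list(
    liability = as.list(sim$truth$liability),
    latent = as.list(sim$truth$latent),
    intercept = sim$truth$intercept,
    seed = p$seed, n_subjects = p$n_subjects,
    beta_main = p$beta_main, beta_epi = p$beta_epi,
    main_gene = p$main_gene, target_prevalence = p$target_prevalence
  ), paths$truth, auto_unbox = TRUE, digits = NA)
  if (vcf) {
    paths$vcf <- file.path(out, "cohort.vcf")
    write_synthetic_vcf(sim$counts, paths$vcf)
  }
  invisible(paths)
}
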