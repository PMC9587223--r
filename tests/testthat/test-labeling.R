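make_pheno <- function(...) {
  phenotype_table(data.frame(..., stringsAsFactors = FALSE))
}

test_that("label_pet applies tracer-specific inclusive thresholds", {
  ph <- make_pheno(
    sample = c("a", "b", "c", "d", "e"),
    suvr = c(1.20, 1.05, 1.27, 1.26, NA),
    tracer = c("florbetapir", "florbetapir", "pib", "pib", "pib")
  )
  lab <- label_pet(ph)
  expect_equal(unname(lab[c("a", "b", "c", "d")]), c(1L, 0L, 1L, 0L))
  expect_false("e" %in% names(lab))  # missing SUVR excluded

  expect_equal(unname(label_pet(ph, inclusive = FALSE)["c"]), 0L)
  ph$tracer[1] <- "tau"
  expect_error(label_pet(ph), "unknown tracer")
})

test_that("label_pet_dx keeps only concordant subjects and never flips labels", {
  ph <- make_pheno(
    sample = c("a", "b", "c", "d"),
    suvr = c(1.5, 1.5, 1.0, 1.0),
    tracer = "florbetapir",
    diagnosis = c("Dementia", "CN", "MCI", "CN")
  )
  pet <- label_pet(ph)
  sub <- label_pet_dx(pet, ph)
  expect_equal(names(sub), c("a", "d"))
  expect_equal(unname(sub), c(1L, 0L))
  expect_true(all(sub[names(sub)] == pet[names(sub)]))
})

test_that("label_case_control maps case/control and drops missing with warning", {
  ph <- make_pheno(sample = letters[1:5],
                   case_control = c("case", "control", "case", "case", NA))
  expect_warning(lab <- label_case_control(ph), "missing")
  expect_equal(sum(lab), 3L)
  expect_length(lab, 4L)
  ph$case_control[1] <- "weird"
  expect_error(suppressWarnings(label_case_control(ph)), "unknown")
})

test_that("phenotype table keeps the last visit per sample", {
  df <- data.frame(sample = c("a", "a", "b"), suvr = c(1.0, 1.4, 1.2),
                   tracer = "florbetapir", visit = c(1, 3, 1))
  ph <- phenotype_table(df)
  expect_equal(nrow(ph), 2L)
  expect_equal(ph$suvr[ph$sample == "a"], 1.4)
})

test_that("build_graph_dataset aligns attributes to sorted node order", {
  tmpl <- gene_network(rbind(c("B", "A"), c("B", "C")))
  counts <- count_matrix(matrix(c(1L, 0L, 2L, 0L, 3L, 1L), nrow = 3,
                                dimnames = list(c("A", "B", "C"), c("s1", "s2"))))
  labels <- label_vector(c(s1 = 1L, s2 = 0L, s3 = 1L))
  expect_warning(ds <- build_graph_dataset(tmpl, counts, labels), "dropped")
  expect_equal(rownames(ds$attrs), c("s1", "s2"))
  expect_equal(ds$node_order, c("A", "B", "C"))
  expect_equal(unname(ds$attrs["s1", ]), c(1L, 0L, 2L))
  # per-subject attribute sum equals the sample's column sum over template genes
  expect_equal(unname(rowSums(ds$attrs)), unname(colSums(counts[ds$node_order, rownames(ds$attrs)])))

  # template gene missing from counts -> zero attribute (plus the drop warning)
  tmpl2 <- gene_network(rbind(c("A", "B"), c("B", "ZNEW")))
  expect_warning(expect_warning(ds2 <- build_graph_dataset(tmpl2, counts, labels),
                                "ZNEW"),
                 "dropped")
  expect_equal(unname(ds2$attrs[, "ZNEW"]), c(0L, 0L))

  no_overlap <- label_vector(c(zz = 1L))
  expect_error(build_graph_dataset(tmpl, counts, no_overlap), "no subjects")
})

test_that("drop_gene removes the gene, re-applies LCC, commutes with building", {
  p3 <- path_graph(c("A", "B", "C"))
  counts <- count_matrix(matrix(rpois(30, 1), nrow = 3,
                                dimnames = list(c("A", "B", "C"), sprintf("s%d", 1:10))))
  labels <- label_vector(setNames(rep(c(0L, 1L), 5), sprintf("s%d", 1:10)))
  ds <- build_graph_dataset(p3, counts, labels)

  leaf <- drop_gene(ds, "C")
  expect_equal(leaf$node_order, c("A", "B"))
  expect_equal(leaf$labels, ds$labels)

  cut <- drop_gene(ds, "B")   # removing the cut vertex -> LCC tie-break
  expect_equal(cut$node_order, "A")

  expect_error(drop_gene(ds, "Q"), "not in template")

  # drop-then-build == build-then-drop
  p3_minus <- largest_connected_component(
    induced_subgraph(p3, c("A", "B")))
  ds_direct <- build_graph_dataset(p3_minus, counts, labels)
  expect_equal(leaf$attrs, ds_direct$attrs)
  expect_equal(network_edges(leaf$template), network_edges(ds_direct$template))
})

test_that("29-node style template loses one node under ablation", {
  tmpl <- default_template(29, seed = 2)
  counts <- count_matrix(matrix(rpois(29 * 6, 1), nrow = 29,
                                dimnames = list(network_nodes(tmpl), sprintf("s%d", 1:6))))
  labels <- label_vector(setNames(rep(c(0L, 1L), 3), sprintf("s%d", 1:6)))
  ds <- build_graph_dataset(tmpl, counts, labels)
  ab <- drop_gene(ds, "APOE")
  expect_lte(length(ab$node_order), 28L)
  expect_true(igraph::is_connected(ab$template$graph))
})

test_that("graph dataset JSON serialization round-trips", {
  sepd <- separable_dataset(20L)
  ds <- build_graph_dataset(sepd$template, sepd$counts, sepd$labels, name = "rt")
  f <- withr::local_tempfile(fileext = ".json")
  write_graph_dataset(ds, f)
  back <- read_graph_dataset(f)
  expect_equal(back$attrs, ds$attrs)
  expect_equal(back$labels, ds$labels)
  expect_equal(back$node_order, ds$node_order)
  expect_equal(network_edges(back$template), network_edges(ds$template))
})
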