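test_that("read_edge_list drops self-loops and duplicates, handles direction and headers", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB", "B\tC", "A\tB", "C\tC"), f)
  expect_message(net <- read_edge_list(f), "dropped 2")
  expect_equal(network_nodes(net), c("A", "B", "C"))
  expect_equal(network_edges(net), rbind(c("A", "B"), c("B", "C")))

  writeLines(c("A\tB", "B\tA"), f)
  expect_equal(network_n_edges(suppressMessages(read_edge_list(f))), 1L)

  writeLines(character(), f)
  empty <- read_edge_list(f)
  expect_equal(network_n_nodes(empty), 0L)
  expect_equal(network_n_edges(empty), 0L)

  writeLines(c("geneA\tgeneB", "A\tB"), f)
  expect_equal(network_n_edges(read_edge_list(f)), 1L)

  writeLines(c("A\tB", "oops"), f)
  expect_error(read_edge_list(f), "line 2")
  expect_error(read_edge_list(file.path(tempdir(), "nope.tsv")), "not found")
})

test_that("edge list round-trip conserves nodes and edges (incl. isolates)", {
  net <- gene_network(rbind(c("A", "B"), c("B", "C")), nodes = c("A", "B", "C", "LONER"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(net, f)
  back <- read_edge_list_with_isolates(f)
  expect_equal(network_nodes(back), network_nodes(net))
  expect_equal(network_edges(back), network_edges(net))
})

test_that("induced_subgraph keeps only edges inside the gene set and is idempotent", {
  k3 <- gene_network(rbind(c("A", "B"), c("A", "C"), c("B", "C")))
  sub <- induced_subgraph(k3, c("A", "B"))
  expect_equal(network_nodes(sub), c("A", "B"))
  expect_equal(network_edges(sub), rbind(c("A", "B")))

  expect_equal(network_edges(induced_subgraph(k3, c("A", "B", "C", "Z"))),
               network_edges(k3))

  p4 <- path_graph(c("A", "B", "C", "D"))
  sub2 <- induced_subgraph(p4, c("A", "C", "D"))
  expect_equal(network_nodes(sub2), c("A", "C", "D"))
  expect_equal(network_edges(sub2), rbind(c("C", "D")))
  expect_equal(attr(induced_subgraph(p4, c("A", "B", "ZZZ")), "missing_genes"), "ZZZ")

  twice <- induced_subgraph(sub2, c("A", "C", "D"))
  expect_equal(network_edges(twice), network_edges(sub2))
  expect_equal(network_nodes(twice), network_nodes(sub2))
})

test_that("largest_connected_component picks the biggest component with lexicographic tie-break", {
  net <- gene_network(rbind(
    c("A", "B"), c("B", "C"), c("C", "D"), c("D", "E"),   # 5-node path
    c("X", "Y"), c("Y", "Z")                               # 3-node path
  ))
  expect_equal(network_nodes(largest_connected_component(net)),
               c("A", "B", "C", "D", "E"))

  connected <- path_graph(c("A", "B", "C"))
  expect_equal(network_edges(largest_connected_component(connected)),
               network_edges(connected))

  tie <- gene_network(rbind(c("M", "N"), c("A", "Z")))
  expect_equal(network_nodes(largest_connected_component(tie)), c("A", "Z"))

  empty <- gene_network(NULL)
  expect_equal(network_n_nodes(largest_connected_component(empty)), 0L)
})

test_that("graph_stats matches the closed-form examples", {
  k3 <- gene_network(rbind(c("A", "B"), c("A", "C"), c("B", "C")))
  s <- graph_stats(k3)
  expect_equal(s$n_nodes, 3L)
  expect_equal(s$n_edges, 3L)
  expect_equal(s$density, 1.0)
  expect_equal(s$diameter, 1L)

  p4 <- path_graph(c("A", "B", "C", "D"))
  s4 <- graph_stats(p4)
  expect_equal(s4$density, 0.5)
  expect_equal(s4$diameter, 3L)

  # any connected graph with n = 29, m = 52 has the printed density
  repeat {
    nodes <- sprintf("G%02d", 1:29)
    tree <- cbind(nodes[-1], nodes[floor(runif(28, 1, 1:28 + 1))])
    extra_pool <- t(combn(nodes, 2))
    key <- function(m) paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))
    extra_pool <- extra_pool[!key(extra_pool) %in% key(tree), ]
    el <- rbind(tree, extra_pool[sample(nrow(extra_pool), 24), ])
    net29 <- gene_network(el)
    if (network_n_edges(net29) == 52L && igraph::is_connected(net29$graph)) break
  }
  expect_equal(graph_stats(net29)$density, 0.1281, tolerance = 1e-4 / 0.1281)

  single <- gene_network(NULL, nodes = "A")
  expect_true(is.na(graph_stats(single)$diameter))
  disconnected <- gene_network(rbind(c("A", "B")), nodes = c("A", "B", "C"))
  expect_true(is.na(graph_stats(disconnected)$diameter))
})

test_that("density and diameter agree with brute-force oracles on random connected graphs", {
  set.seed(11)
  for (rep in 1:40) {
    net <- random_connected_net(sample(3:8, 1L))
    A <- adj_matrix(net)
    s <- graph_stats(net)
    expect_equal(s$density, oracle_density(A))
    expect_equal(s$diameter, oracle_diameter(A))
  }
})

test_that("node_loss_report reproduces the published loss arithmetic", {
  mk <- function(n_orig, n_kept) {
    genes <- sprintf("G%03d", seq_len(n_orig))
    kept <- genes[seq_len(n_kept)]
    net <- gene_network(cbind(kept[-length(kept)], kept[-1]), nodes = kept)
    node_loss_report(genes, net)
  }
  r <- mk(18, 12)
  expect_equal(r$lost_count, 6L)
  expect_equal(r$lost_pct, 33.33)
  expect_equal(mk(45, 36)$lost_pct, 20)
  expect_equal(mk(59, 52)$lost_pct, 11.86)

  no_loss <- mk(10, 10)
  expect_equal(no_loss$lost_count, 0L)
  expect_equal(no_loss$lost_pct, 0)

  rogue <- gene_network(rbind(c("A", "ZZ")))
  expect_error(node_loss_report(c("A", "B"), rogue), "not in the gene set")
})

test_that("extract_subnetwork output is connected (BFS reachability)", {
  set.seed(21)
  for (rep in 1:20) {
    full <- random_connected_net(8L, m_max = 10L)
    extra <- gene_network(rbind(network_edges(full), c("Q1", "Q2")),
                          nodes = c(network_nodes(full), "Q1", "Q2", "Q3"))
    genes <- sample(network_nodes(extra), sample(3:8, 1L))
    ext <- extract_subnetwork(extra, genes)
    if (network_n_nodes(ext$network) > 0L) {
      expect_true(igraph::is_connected(ext$network$graph))
    }
    expect_equal(ext$loss$original_count - ext$loss$retained_count,
                 ext$loss$lost_count)
  }
})
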