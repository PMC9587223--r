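# Shared fixtures and independent brute-force oracles. The oracles
# deliberately use the most literal definition available (adjacency counting,
# Floyd-Warshall, all-pairs concordance, the step-up definition of BH) so
# they stay independent of the implementation paths they check.

path_graph <- function(labels) {
  n <- length(labels)
  gene_network(cbind(labels[-n], labels[-1]), name = "path")
}

# adjacency matrix of a gene_network, in node-name order
adj_matrix <- function(net) {
  nodes <- network_nodes(net)
  A <- matrix(0L, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  el <- network_edges(net)
  for (i in seq_len(nrow(el))) {
    A[el[i, 1L], el[i, 2L]] <- 1L
    A[el[i, 2L], el[i, 1L]] <- 1L
  }
  A
}

oracle_density <- function(A) {
  n <- nrow(A)
  if (n < 2L) return(NA_real_)
  sum(A) / (n * (n - 1))
}

# Floyd-Warshall diameter; NA when disconnected or n < 2
oracle_diameter <- function(A) {
  n <- nrow(A)
  if (n < 2L) return(NA_integer_)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[A == 1L] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  }
  if (any(is.infinite(D))) return(NA_integer_)
  as.integer(max(D))
}

# all-pairs concordance AUC with half credit for ties
oracle_auc <- function(y, s) {
  pos <- s[y == 1L]; neg <- s[y == 0L]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# literal step-up BH: find largest k with p_(k) <= k q / m by scanning q
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(sorted[i:m] * m / (i:m))
  }
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

random_connected_net <- function(n, m_max = 10L) {
  repeat {
    pairs <- t(combn(sprintf("N%02d", seq_len(n)), 2L))
    m <- sample(seq(n - 1L, min(m_max, nrow(pairs))), 1L)
    el <- pairs[sample(nrow(pairs), m), , drop = FALSE]
    net <- gene_network(el, nodes = sprintf("N%02d", seq_len(n)))
    if (igraph::is_connected(net$graph)) return(net)
  }
}

# a hand-written annotated VCF fixture: 3 samples, two genes, one
# multi-allelic site (one missense alt, one synonymous alt), one compound
# consequence, one homozygote, one missing genotype
write_fixture_vcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1>",
    paste0("##INFO=<ID=CSQ,Number=.,Type=String,Description=\"Consequence ",
           "annotations from VEP. Format: Allele|Consequence|SYMBOL\">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3",
    "1\t100\t.\tA\tG\t.\tPASS\tCSQ=G|missense_variant|GENE1\tGT\t0/1\t0/0\t1/1",
    "1\t200\t.\tC\tT\t.\tPASS\tCSQ=T|missense_variant&splice_region_variant|GENE1\tGT\t0/1\t0/1\t0/0",
    "1\t300\t.\tG\tA,C\t.\tPASS\tCSQ=A|missense_variant|GENE2,C|synonymous_variant|GENE2\tGT\t0/1\t1/2\t2/2",
    "1\t400\t.\tT\tC\t.\tPASS\tCSQ=C|intron_variant|GENE2\tGT\t./.\t0/1\t0/0"
  ), path)
  path
}

# small cohort shared by model tests: one perfectly informative gene. APOE
# sits at a topologically unique hub position: message passing cannot
# distinguish attributes of nodes related by a graph automorphism, so a
# separable-by-construction GNN fixture needs an asymmetric template.
separable_dataset <- function(n = 200L, seed = 42L) {
  tmpl <- gene_network(rbind(c("APOE", "GENE1"), c("APOE", "GENE2"),
                             c("APOE", "GENE3"), c("GENE1", "GENE2")),
                       name = "sep")
  ids <- sprintf("P%03d", seq_len(n))
  set.seed(seed)
  counts <- matrix(rpois(4L * n, 0.5), nrow = 4L,
                   dimnames = list(c("APOE", "GENE1", "GENE2", "GENE3"), ids))
  y <- as.integer(counts["APOE", ] > 0L)
  # force both classes
  y[1:5] <- 1L; counts["APOE", 1:5] <- 1L
  y[6:10] <- 0L; counts["APOE", 6:10] <- 0L
  list(template = tmpl, counts = count_matrix(counts),
       labels = label_vector(setNames(y, ids)))
}
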