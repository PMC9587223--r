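#' Gene interaction networks
#'
#' A `gene_network` is an undirected simple graph whose vertices are gene
#' symbols, used as the reusable "template" that patient-specific graphs are
#' copied from. Internally it wraps an [igraph::igraph] object; self-loops and
#' duplicate edges are removed at construction.
#'
#' @param edges two-column character matrix (or data.frame) of gene-symbol
#'   pairs; may be empty.
#' @param nodes optional character vector of vertex names; vertices appearing
#'   in `edges` are always included.
#' @param name display name of the network.
#' @return An object of class `gene_network`.
#' @export
gene_network <- function(edges = NULL, nodes = NULL, name = "network") {
  if (is.null(edges) || NROW(edges) == 0L) {
    em <- matrix(character(), ncol = 2L)
  } else {
    em <- as.matrix(edges)[, 1:2, drop = FALSE]
    storage.mode(em) <- "character"
  }
  keep <- em[, 1L] != em[, 2L]
  em <- em[keep, , drop = FALSE]
  # canonical order inside each edge, then dedup
  flip <- em[, 1L] > em[, 2L]
  em[flip, ] <- em[flip, 2:1]
  em <- unique(em)
  verts <- sort(unique(c(as.vector(em), as.character(nodes %||% character()))))
  g <- igraph::graph_from_data_frame(
    data.frame(from = em[, 1L], to = em[, 2L], stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = if (length(verts)) data.frame(name = verts) else NULL
  )
  structure(list(name = name, graph = g), class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("<gene_network '%s': %d nodes, %d edges>\n",
              x$name, network_n_nodes(x), network_n_edges(x)))
  invisible(x)
}

#' Network accessors
#'
#' @param net a [gene_network()].
#' @return `network_nodes()`: sorted character vector of gene symbols;
#'   `network_edges()`: two-column character matrix with each row in
#'   lexicographic order and rows sorted; `network_n_nodes()` /
#'   `network_n_edges()`: integer counts.
#' @export
network_nodes <- function(net) sort(igraph::V(net$graph)$name)

#' @rdname network_nodes
#' @export
network_edges <- function(net) {
  el <- igraph::as_edgelist(net$graph)
  if (nrow(el) == 0L) return(matrix(character(), ncol = 2L))
  flip <- el[, 1L] > el[, 2L]
  el[flip, ] <- el[flip, 2:1]
  el[order(el[, 1L], el[, 2L]), , drop = FALSE]
}

#' @rdname network_nodes
#' @export
network_n_nodes <- function(net) igraph::vcount(net$graph)

#' @rdname network_nodes
#' @export
network_n_edges <- function(net) igraph::ecount(net$graph)

#' Read an interaction network from a two-column edge list
#'
#' Expects a TSV with at least two columns (`geneA<TAB>geneB`); lines starting
#' with `#` are comments. A header line is detected when both of the first two
#' fields match common column-name patterns (gene/node/protein/source/target/
#' from/to). Self-loops and duplicate (including reversed) edges are dropped
#' with a message.
#'
#' @param path path to the TSV file.
#' @param name network name (defaults to the file name).
#' @param case_insensitive uppercase gene symbols on read (default `FALSE`;
#'   silent case-folding can hide upstream data errors).
#' @return A [gene_network()].
#' @export
read_edge_list <- function(path, name = basename(path), case_insensitive = FALSE) {
  if (!file.exists(path)) stop("edge list file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) return(gene_network(NULL, name = name))
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) < 2L)
  if (length(bad)) {
    stop(sprintf("malformed edge-list row at line %d of %s (expected >= 2 tab-separated columns)",
                 idx[bad[1L]], path), call. = FALSE)
  }
  first <- trimws(fields[[1L]][1:2])
  header_rx <- "^(gene|node|protein|source|target|from|to)"
  if (all(grepl(header_rx, first, ignore.case = TRUE)) && length(fields) > 1L) {
    fields <- fields[-1L]
  }
  if (length(fields) == 0L) return(gene_network(NULL, name = name))
  em <- t(vapply(fields, function(f) trimws(f[1:2]), character(2L)))
  if (case_insensitive) em[] <- toupper(em)
  n_raw <- nrow(em)
  net <- gene_network(em, name = name)
  dropped <- n_raw - network_n_edges(net)
  if (dropped > 0L) {
    message(sprintf("read_edge_list: dropped %d duplicate/self-loop row(s) from %s",
                    dropped, path))
  }
  net
}

#' Write a network as a two-column TSV edge list
#'
#' Isolated vertices are preserved via `#node:` comment lines so that a
#' read/write round trip conserves node and edge counts.
#'
#' @param net a [gene_network()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  el <- network_edges(net)
  iso <- setdiff(network_nodes(net), unique(as.vector(el)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# network: %s", net$name), con)
  if (length(iso)) writeLines(sprintf("#node:\t%s", iso), con)
  if (nrow(el)) writeLines(paste(el[, 1L], el[, 2L], sep = "\t"), con)
  invisible(path)
}

#' @rdname read_edge_list
#' @export
read_edge_list_with_isolates <- function(path, name = basename(path),
                                         case_insensitive = FALSE) {
  lines <- readLines(path, warn = FALSE)
  iso <- sub("^#node:\\t", "", lines[grepl("^#node:\\t", lines)])
  if (case_insensitive) iso <- toupper(iso)
  net <- read_edge_list(path, name = name, case_insensitive = case_insensitive)
  if (length(iso)) {
    net <- gene_network(network_edges(net), nodes = union(network_nodes(net), iso),
                        name = name)
  }
  net
}

#' Read a gene set (one symbol per line)
#'
#' @param path text file with one gene symbol per line; `#` comments and blank
#'   lines are ignored.
#' @param case_insensitive uppercase symbols on read.
#' @return Character vector of unique, trimmed symbols.
#' @export
read_gene_set <- function(path, case_insensitive = FALSE) {
  if (!file.exists(path)) stop("gene set file not found: ", path, call. = FALSE)
  x <- trimws(readLines(path, warn = FALSE))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  if (case_insensitive) x <- toupper(x)
  unique(x)
}

#' Induced subgraph on a gene set
#'
#' Keeps the vertices of `net` present in `genes` and the edges with both
#' endpoints kept. Genes absent from the network are recorded in the
#' `"missing_genes"` attribute of the result (input to [node_loss_report()]).
#'
#' @param net a [gene_network()].
#' @param genes character vector of gene symbols.
#' @param case_insensitive match symbols after uppercasing both sides.
#' @return A [gene_network()].
#' @export
induced_subgraph <- function(net, genes, case_insensitive = FALSE) {
  genes <- trimws(genes)
  nodes <- network_nodes(net)
  if (case_insensitive) {
    keep <- nodes[toupper(nodes) %in% toupper(genes)]
    missing <- genes[!toupper(genes) %in% toupper(nodes)]
  } else {
    keep <- intersect(nodes, genes)
    missing <- setdiff(genes, nodes)
  }
  g <- igraph::induced_subgraph(net$graph, keep)
  out <- structure(list(name = net$name, graph = g), class = "gene_network")
  attr(out, "missing_genes") <- missing
  out
}

#' Largest connected component
#'
#' Ties on component size are broken deterministically: the component
#' containing the lexicographically smallest vertex name wins.
#'
#' @param net a [gene_network()].
#' @return A connected [gene_network()] (empty in, empty out).
#' @export
largest_connected_component <- function(net) {
  if (network_n_nodes(net) == 0L) return(net)
  comp <- igraph::components(net$graph)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    # representative = smallest vertex name in each tied component
    reps <- vapply(best, function(ci) {
      min(igraph::V(net$graph)$name[comp$membership == ci])
    }, character(1L))
    best <- best[which.min(match(reps, sort(reps)))]
  }
  keep <- igraph::V(net$graph)$name[comp$membership == best]
  out <- structure(
    list(name = net$name, graph = igraph::induced_subgraph(net$graph, keep)),
    class = "gene_network"
  )
  attr(out, "missing_genes") <- attr(net, "missing_genes")
  out
}

#' Graph statistics (density and diameter)
#'
#' Density uses the undirected simple-graph formula `2m / (n (n - 1))`;
#' diameter is the number of edges on the longest shortest path and is `NA`
#' unless the graph is connected with at least 2 nodes.
#'
#' @param net a [gene_network()].
#' @return A list of class `graph_stats` with `n_nodes`, `n_edges`, `density`,
#'   `diameter`.
#' @export
graph_stats <- function(net) {
  n <- network_n_nodes(net)
  m <- network_n_edges(net)
  dens <- if (n >= 2L) 2 * m / (n * (n - 1)) else NA_real_
  diam <- NA_integer_
  if (n >= 2L && igraph::is_connected(net$graph)) {
    diam <- as.integer(igraph::diameter(net$graph, weights = NA))
  }
  structure(list(n_nodes = n, n_edges = m, density = dens, diameter = diam),
            class = "graph_stats")
}

#' @export
print.graph_stats <- function(x, ...) {
  cat(sprintf("n=%d m=%d density=%.4f diameter=%s\n", x$n_nodes, x$n_edges,
              x$density, ifelse(is.na(x$diameter), "NA", x$diameter)))
  invisible(x)
}

#' Node-loss report after subnetwork extraction
#'
#' Summarizes how many of the original genes of interest survived the induced
#' subgraph + largest-connected-component restriction.
#'
#' @param genes the original gene set (character vector).
#' @param final_net the final [gene_network()]; its nodes must be a subset of
#'   `genes`.
#' @return A list of class `loss_report` with `original_count`,
#'   `retained_count`, `lost_count`, `lost_pct` (rounded to 2 decimals) and
#'   `lost_genes`.
#' @export
node_loss_report <- function(genes, final_net) {
  genes <- unique(trimws(genes))
  kept <- network_nodes(final_net)
  extra <- setdiff(kept, genes)
  if (length(extra)) {
    stop("final network contains node(s) not in the gene set: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  lost <- setdiff(genes, kept)
  structure(list(
    original_count = length(genes),
    retained_count = length(kept),
    lost_count = length(lost),
    lost_pct = round(100 * length(lost) / length(genes), 2L),
    lost_genes = sort(lost)
  ), class = "loss_report")
}

#' Extract a disease subnetwork from a full interaction network
#'
#' Convenience composition of [induced_subgraph()] and
#' [largest_connected_component()], returning the template network together
#' with its [node_loss_report()] and [graph_stats()].
#'
#' @inheritParams induced_subgraph
#' @return List with elements `network`, `loss`, `stats`.
#' @examples
#' net <- read_edge_list(system.file("extdata", "example_network.tsv",
#'                                   package = "graphburden"))
#' genes <- read_gene_set(system.file("extdata", "example_genes.txt",
#'                                    package = "graphburden"))
#' ext <- extract_subnetwork(net, genes)
#' ext$stats
#' ext$loss$lost_pct
#' @export
extract_subnetwork <- function(net, genes, case_insensitive = FALSE) {
  sub <- induced_subgraph(net, genes, case_insensitive = case_insensitive)
  lcc <- largest_connected_component(sub)
  list(network = lcc,
       loss = node_loss_report(if (case_insensitive) toupper(genes) else genes, lcc),
       stats = graph_stats(lcc))
}
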