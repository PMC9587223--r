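#' Node-label shuffled network
#'
#' Applies a uniformly random permutation to the vertex labels, preserving the
#' topology exactly (the result is isomorphic to the source by construction).
#' The permutation is recorded in the `"permutation"` attribute (named vector,
#' old label -> new label) so isomorphism can be asserted by permuted adjacency
#' equality.
#'
#' @param net a [gene_network()]; must be nonempty.
#' @param seed integer seed; the same seed yields the same permutation.
#' @return A [gene_network()] with attribute `"permutation"`.
#' @export
shuffle_network <- function(net, seed) {
  nodes <- network_nodes(net)
  if (length(nodes) == 0L) stop("cannot shuffle an empty network", call. = FALSE)
  perm <- with_seed(seed, sample(nodes))
  names(perm) <- nodes
  el <- network_edges(net)
  new_el <- cbind(perm[el[, 1L]], perm[el[, 2L]])
  out <- gene_network(new_el, nodes = nodes, name = paste0(net$name, "_shuffled"))
  attr(out, "permutation") <- perm
  out
}

#' Degree-preserving rewired network
#'
#' Randomizes edges by repeated double-edge swaps: two edges (a,b), (c,d) are
#' replaced by (a,d), (c,b). Swaps that would create a self-loop or duplicate
#' edge are rejected (counted against the attempt budget, so termination is
#' guaranteed). The per-node degree vector, node set and edge count are
#' preserved exactly. Connectedness is NOT enforced: the source rewiring
#' scheme does not preserve it, and neither does this one.
#'
#' @param net a [gene_network()] with at least 2 edges.
#' @param seed integer seed.
#' @param swap_factor attempted swaps = `ceiling(swap_factor * m)`; default 10,
#'   a standard mixing heuristic.
#' @return A [gene_network()] with the same degree sequence as `net`.
#' @export
rewire_network <- function(net, seed, swap_factor = 10) {
  el <- network_edges(net)
  m <- nrow(el)
  if (m < 2L) stop("rewire_network needs a network with >= 2 edges", call. = FALSE)
  stopifnot(swap_factor > 0)
  attempts <- ceiling(swap_factor * m)
  edge_key <- function(a, b) ifelse(a < b, paste(a, b, sep = "\r"), paste(b, a, sep = "\r"))
  present <- new.env(parent = emptyenv(), hash = TRUE)
  for (i in seq_len(m)) assign(edge_key(el[i, 1L], el[i, 2L]), TRUE, envir = present)
  with_seed(seed, {
    for (t in seq_len(attempts)) {
      ij <- sample.int(m, 2L)
      e1 <- el[ij[1L], ]
      e2 <- el[ij[2L], ]
      if (runif(1) < 0.5) e2 <- rev(e2)   # random orientation
      a <- e1[1L]; b <- e1[2L]; c <- e2[1L]; d <- e2[2L]
      # proposed: (a,d) and (c,b)
      if (a == d || c == b) next
      k1 <- edge_key(a, d); k2 <- edge_key(c, b)
      if (k1 == k2) next
      if (exists(k1, envir = present, inherits = FALSE) ||
          exists(k2, envir = present, inherits = FALSE)) next
      rm(list = c(edge_key(a, b), edge_key(c, d)), envir = present)
      assign(k1, TRUE, envir = present)
      assign(k2, TRUE, envir = present)
      el[ij[1L], ] <- sort(c(a, d))
      el[ij[2L], ] <- sort(c(c, b))
    }
  })
  gene_network(el, nodes = network_nodes(net), name = paste0(net$name, "_rewired"))
}

#' Generate an ensemble of randomized template networks
#'
#' Produces `count` randomized copies of `net` (negative-control templates).
#' Per-member seeds are derived deterministically from `master_seed` by a
#' counter scheme and recorded in the ensemble, so any member can be replayed
#' exactly.
#'
#' @param net source [gene_network()].
#' @param method `"shuffled"` (label permutation) or `"rewired"`
#'   (degree-preserving double-edge swaps).
#' @param count number of members (paper protocol uses 100).
#' @param master_seed integer master seed.
#' @param swap_factor passed to [rewire_network()].
#' @return An object of class `null_ensemble`: list with `method`, `source`
#'   (network name), `source_checksum`, `members` (list of networks), `seeds`.
#' @export
generate_ensemble <- function(net, method = c("shuffled", "rewired"), count,
                              master_seed, swap_factor = 10) {
  method <- match.arg(method)
  assert_scalar_count(count, "count")
  seeds <- vapply(seq_len(count), function(i) derive_seed(master_seed, i, method),
                  integer(1L))
  stopifnot(!anyDuplicated(seeds))
  members <- lapply(seeds, function(s) {
    switch(method,
           shuffled = shuffle_network(net, s),
           rewired = rewire_network(net, s, swap_factor = swap_factor))
  })
  el <- network_edges(net)
  structure(list(
    method = method,
    source = net$name,
    source_checksum = text_checksum(paste(el[, 1L], el[, 2L], sep = "-")),
    members = members,
    seeds = seeds,
    master_seed = as.integer(master_seed),
    swap_factor = if (method == "rewired") swap_factor else NULL
  ), class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("<null_ensemble: %d %s members of '%s'>\n",
              length(x$members), x$method, x$source))
  invisible(x)
}

#' Serialize / load a null ensemble
#'
#' Writes one edge-list TSV per member plus a JSON manifest (method, source
#' name and checksum, per-member seeds).
#'
#' @param ensemble a `null_ensemble`.
#' @param dir output directory (created if needed).
#' @return `write_ensemble()`: `dir`, invisibly; `read_ensemble()`: a
#'   `null_ensemble`.
#' @export
write_ensemble <- function(ensemble, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(ensemble$members)) {
    write_edge_list(ensemble$members[[i]],
                    file.path(dir, sprintf("member_%03d.tsv", i)))
  }
  manifest <- ensemble[c("method", "source", "source_checksum", "seeds",
                         "master_seed", "swap_factor")]
  manifest$count <- length(ensemble$members)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(dir)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  members <- lapply(seq_len(manifest$count), function(i) {
    read_edge_list_with_isolates(file.path(dir, sprintf("member_%03d.tsv", i)))
  })
  structure(list(
    method = manifest$method, source = manifest$source,
    source_checksum = manifest$source_checksum, members = members,
    seeds = as.integer(manifest$seeds),
    master_seed = as.integer(manifest$master_seed),
    swap_factor = manifest$swap_factor
  ), class = "null_ensemble")
}
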