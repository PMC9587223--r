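#' Build a dataset of patient-specific attributed graphs
#'
#' Every subject gets a copy of the template network with its per-gene
#' missense burden as a scalar node attribute and a binary label. Since the
#' template is shared, the dataset stores one attribute matrix (subjects x
#' nodes) aligned to a fixed lexicographic `node_order`, which is what makes
#' attribute alignment reproducible bit-for-bit.
#'
#' Subjects are the intersection of the count-matrix samples and the label
#' vector; template genes missing from the count matrix get attribute 0 for
#' everyone (with a warning).
#'
#' @param template a connected [gene_network()].
#' @param counts a [count_matrix()] (genes x samples).
#' @param labels a `label_vector`.
#' @param name dataset name.
#' @return An object of class `graph_dataset` with fields `template`,
#'   `node_order`, `attrs` (integer matrix subjects x nodes), `labels`
#'   (named 0/1 vector over the same subjects), `name`.
#' @export
build_graph_dataset <- function(template, counts, labels, name = "dataset") {
  subjects <- intersect(colnames(counts), names(labels))
  if (length(subjects) == 0L) {
    stop("no subjects shared between count matrix and labels", call. = FALSE)
  }
  dropped <- length(union(colnames(counts), names(labels))) - length(subjects)
  if (dropped > 0L) {
    warning(sprintf("%d sample(s) present in only one of counts/labels were dropped",
                    dropped))
  }
  node_order <- sort(network_nodes(template))
  missing <- setdiff(node_order, rownames(counts))
  if (length(missing)) {
    warning("template gene(s) absent from counts, attribute set to 0: ",
            paste(missing, collapse = ", "))
  }
  attrs <- matrix(0L, nrow = length(subjects), ncol = length(node_order),
                  dimnames = list(subjects, node_order))
  present <- intersect(node_order, rownames(counts))
  attrs[, present] <- t(counts[present, subjects, drop = FALSE])
  structure(list(
    template = template,
    node_order = node_order,
    attrs = attrs,
    labels = label_vector(stats::setNames(as.integer(labels[subjects]), subjects)),
    name = name
  ), class = "graph_dataset")
}

#' @export
print.graph_dataset <- function(x, ...) {
  cat(sprintf("<graph_dataset '%s': %d subjects x %d nodes, %d positives>\n",
              x$name, nrow(x$attrs), length(x$node_order), sum(x$labels)))
  invisible(x)
}

#' Delete a gene from a graph dataset (APOE-style ablation)
#'
#' Removes the gene from the template, re-applies the largest connected
#' component (removing a cut vertex can disconnect the template, and message
#' passing assumes connectedness), and re-aligns the attribute matrix. Labels
#' are unchanged.
#'
#' @param dataset a `graph_dataset`.
#' @param gene gene symbol to remove; must be in the template.
#' @return A `graph_dataset` on the reduced template.
#' @export
drop_gene <- function(dataset, gene) {
  nodes <- network_nodes(dataset$template)
  if (!gene %in% nodes) stop("gene not in template: ", gene, call. = FALSE)
  reduced <- gene_network(
    edges = {
      el <- network_edges(dataset$template)
      el[el[, 1L] != gene & el[, 2L] != gene, , drop = FALSE]
    },
    nodes = setdiff(nodes, gene),
    name = paste0(dataset$template$name, "_minus_", gene)
  )
  reduced <- largest_connected_component(reduced)
  keep <- sort(network_nodes(reduced))
  structure(list(
    template = reduced,
    node_order = keep,
    attrs = dataset$attrs[, keep, drop = FALSE],
    labels = dataset$labels,
    name = paste0(dataset$name, "_minus_", gene)
  ), class = "graph_dataset")
}

#' Serialize / load a graph dataset as a single JSON container
#'
#' The container stores the template edge list, the node order, and one
#' record per subject (`id`, `attrs`, `label`).
#'
#' @param dataset a `graph_dataset`.
#' @param path JSON file path.
#' @return `write_graph_dataset()`: `path`, invisibly; `read_graph_dataset()`:
#'   a `graph_dataset`.
#' @export
write_graph_dataset <- function(dataset, path) {
  el <- network_edges(dataset$template)
  obj <- list(
    name = dataset$name,
    template_name = dataset$template$name,
    nodes = network_nodes(dataset$template),
    edges = unname(apply(el, 1L, as.list)),
    node_order = dataset$node_order,
    subjects = lapply(rownames(dataset$attrs), function(s) {
      list(id = s, attrs = unname(dataset$attrs[s, ]),
           label = unname(dataset$labels[[s]]))
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_graph_dataset
#' @export
read_graph_dataset <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  edges <- if (length(obj$edges)) {
    if (is.matrix(obj$edges)) obj$edges
    else matrix(unlist(obj$edges), ncol = 2L, byrow = TRUE)
  } else NULL
  template <- gene_network(edges, nodes = obj$nodes, name = obj$template_name)
  ids <- as.character(unname(unlist(obj$subjects$id)))
  attrs <- do.call(rbind, lapply(obj$subjects$attrs, as.integer))
  dimnames(attrs) <- list(ids, obj$node_order)
  labels <- label_vector(stats::setNames(as.integer(obj$subjects$label), ids))
  structure(list(template = template, node_order = obj$node_order,
                 attrs = attrs, labels = labels, name = obj$name),
            class = "graph_dataset")
}
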