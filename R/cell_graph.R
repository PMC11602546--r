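#' Construct a cell graph
#'
#' The central data structure of the package: an undirected, simple graph of
#' cells. Nodes carry a color label (integer in `1..n_colors`), a centroid in
#' pixel coordinates (`x` = column, `y` = row, 0-based) and optionally a
#' pixel area; edges connect adjacent cells and may carry the geodesic
#' (in-vessel) centroid-to-centroid contact distance in pixels.
#'
#' @param nodes data.frame with columns `id` (unique integers), `color`
#'   (integers >= 1), `x`, `y` (finite, non-negative) and optionally `area`.
#' @param edges data.frame with columns `source`, `target` (node ids) and
#'   optionally `distance` (non-negative). May have zero rows.
#' @param meta named list of graph metadata. Recognized entries:
#'   `n_colors` (number of fluorophores, default `max(nodes$color)`),
#'   `pixel_size_um`, `image_id`, `animal_id`, `group`.
#' @return An object of class `cell_graph`.
#' @export
cell_graph <- function(nodes, edges = NULL, meta = list()) {
  nodes <- as.data.frame(nodes)
  req <- c("id", "color", "x", "y")
  miss <- setdiff(req, names(nodes))
  if (length(miss) > 0)
    stop("node table is missing column(s): ", paste(miss, collapse = ", "))
  nodes$id <- as.integer(nodes$id)
  nodes$color <- as.integer(nodes$color)
  if (anyDuplicated(nodes$id))
    stop("duplicate node id: ", nodes$id[duplicated(nodes$id)][1])
  if (nrow(nodes) > 0) {
    if (any(!is.finite(nodes$x)) || any(!is.finite(nodes$y)))
      stop("node centroids must be finite")
    if (any(nodes$color < 1)) stop("color labels must be >= 1")
  }
  if (is.null(edges)) {
    edges <- data.frame(source = integer(0), target = integer(0),
                        distance = numeric(0))
  }
  edges <- as.data.frame(edges)
  if (!all(c("source", "target") %in% names(edges)))
    stop("edge table is missing column(s): source/target")
  edges$source <- as.integer(edges$source)
  edges$target <- as.integer(edges$target)
  if (is.null(edges$distance)) edges$distance <- rep(NA_real_, nrow(edges))
  if (nrow(edges) > 0) {
    unknown <- setdiff(c(edges$source, edges$target), nodes$id)
    if (length(unknown) > 0)
      stop("edge references unknown node ", unknown[1])
    if (any(edges$source == edges$target))
      stop("self-loops are not allowed")
    key <- paste(pmin(edges$source, edges$target),
                 pmax(edges$source, edges$target))
    if (anyDuplicated(key)) stop("duplicate edge: ", key[duplicated(key)][1])
  }
  meta <- as.list(meta)
  if (is.null(meta$n_colors)) {
    meta$n_colors <- if (nrow(nodes) > 0) max(nodes$color) else 0L
  }
  meta$n_colors <- as.integer(meta$n_colors)
  if (nrow(nodes) > 0 && any(nodes$color > meta$n_colors))
    stop("color label exceeds n_colors")
  structure(list(nodes = nodes, edges = edges, meta = meta),
            class = "cell_graph")
}

#' @export
print.cell_graph <- function(x, ...) {
  cat(sprintf("cell_graph: %d nodes, %d edges, %d colors\n",
              nrow(x$nodes), nrow(x$edges), x$meta$n_colors))
  invisible(x)
}

#' Number of nodes in a cell graph
#' @param graph a `cell_graph`.
#' @return integer node count.
#' @export
n_nodes <- function(graph) nrow(graph$nodes)

#' Replace node colors
#'
#' Returns a copy of `graph` whose nodes carry `colors` (in node-table
#' order). Used to evaluate simulated colorings on the observed topology.
#'
#' @param graph a `cell_graph`.
#' @param colors integer vector, one color per node in node-table order.
#' @return a `cell_graph`.
#' @export
set_colors <- function(graph, colors) {
  stopifnot(length(colors) == nrow(graph$nodes))
  graph$nodes$color <- as.integer(colors)
  cell_graph(graph$nodes, graph$edges, graph$meta)
}

#' Convert a cell graph to an igraph object
#' @param graph a `cell_graph`.
#' @return an undirected `igraph` graph with node/edge attributes.
#' @export
as_igraph <- function(graph) {
  v <- graph$nodes
  v <- data.frame(name = as.character(v$id), v[setdiff(names(v), "id")])
  e <- graph$edges
  if (nrow(e) > 0) {
    e <- data.frame(from = as.character(e$source), to = as.character(e$target),
                    e[setdiff(names(e), c("source", "target"))])
  } else {
    e <- data.frame(from = character(0), to = character(0))
  }
  igraph::graph_from_data_frame(e, directed = FALSE, vertices = v)
}

# internal: adjacency structures used throughout.
# Returns list(n, deg, adj = sparse row-stochastic walk matrix P,
#              ei/ej = 1-based node indices of the 2|E| directed edges)
graph_internals <- function(graph) {
  n <- nrow(graph$nodes)
  ids <- graph$nodes$id
  si <- match(graph$edges$source, ids)
  ti <- match(graph$edges$target, ids)
  ei <- c(si, ti)
  ej <- c(ti, si)
  deg <- tabulate(ei, nbins = n)
  P <- NULL
  if (length(ei) > 0) {
    P <- Matrix::sparseMatrix(i = ei, j = ej, x = 1 / deg[ei], dims = c(n, n))
  }
  list(n = n, deg = deg, P = P, ei = ei, ej = ej)
}

#' Read a cell graph from disk
#'
#' Two dialects are supported. `format = "csv"`: a node CSV
#' (`<path>_nodes.csv`; columns id,color,x,y\[,area\]), an edge CSV
#' (`<path>_edges.csv`; columns source,target\[,distance\]) and an optional
#' JSON metadata sidecar (`<path>_meta.json`). `format = "graphml"`: a
#' single GraphML file with the same attributes (metadata carried as a JSON
#' graph attribute).
#'
#' @param path file stem (csv) or file path (graphml).
#' @param format `"csv"` or `"graphml"`.
#' @return a `cell_graph`.
#' @export
read_graph <- function(path, format = c("csv", "graphml")) {
  format <- match.arg(format)
  if (format == "csv") {
    nf <- paste0(path, "_nodes.csv")
    ef <- paste0(path, "_edges.csv")
    mf <- paste0(path, "_meta.json")
    if (!file.exists(nf)) stop("node file not found: ", nf)
    if (!file.exists(ef)) stop("edge file not found: ", ef)
    nodes <- read.csv(nf)
    edges <- read.csv(ef)
    meta <- if (file.exists(mf)) jsonlite::read_json(mf, simplifyVector = TRUE) else list()
    cell_graph(nodes, edges, meta)
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    va <- igraph::vertex_attr(g)
    nodes <- data.frame(id = as.integer(va$name), color = as.integer(va$color),
                        x = as.numeric(va$x), y = as.numeric(va$y))
    if (!is.null(va$area)) nodes$area <- as.numeric(va$area)
    el <- igraph::as_edgelist(g, names = TRUE)
    edges <- data.frame(source = as.integer(el[, 1]), target = as.integer(el[, 2]))
    ea <- igraph::edge_attr(g)
    if (!is.null(ea$distance)) edges$distance <- as.numeric(ea$distance)
    meta <- list()
    ga <- igraph::graph_attr(g)
    if (!is.null(ga$meta_json)) meta <- jsonlite::fromJSON(ga$meta_json)
    cell_graph(nodes, edges, meta)
  }
}

#' Write a cell graph to disk
#'
#' Emits the exact dialect [read_graph()] accepts; a round trip preserves
#' node and edge sets and all attributes.
#'
#' @param graph a `cell_graph`.
#' @inheritParams read_graph
#' @return invisibly, the paths written.
#' @export
write_graph <- function(graph, path, format = c("csv", "graphml")) {
  format <- match.arg(format)
  if (format == "csv") {
    nf <- paste0(path, "_nodes.csv")
    ef <- paste0(path, "_edges.csv")
    mf <- paste0(path, "_meta.json")
    write.csv(graph$nodes, nf, row.names = FALSE)
    write.csv(graph$edges, ef, row.names = FALSE)
    jsonlite::write_json(graph$meta, mf, auto_unbox = TRUE, digits = NA,
                         null = "null")
    invisible(c(nf, ef, mf))
  } else {
    g <- as_igraph(graph)
    g <- igraph::set_graph_attr(g, "meta_json",
                                as.character(jsonlite::toJSON(graph$meta,
                                                              auto_unbox = TRUE,
                                                              digits = NA)))
    igraph::write_graph(g, path, format = "graphml")
    invisible(path)
  }
}

#' Split a cell graph into connected components
#'
#' @param graph a `cell_graph`.
#' @return list of `cell_graph`, ordered by node count descending, ties by
#'   smallest node id; node ids are preserved.
#' @export
connected_components <- function(graph) {
  n <- nrow(graph$nodes)
  if (n == 0) return(list())
  gi <- graph_internals(graph)
  memb <- if (is.null(gi$P)) {
    seq_len(n)
  } else {
    igraph::components(as_igraph(graph))$membership[as.character(graph$nodes$id)]
  }
  comps <- split(seq_len(n), memb)
  sizes <- vapply(comps, length, integer(1))
  minid <- vapply(comps, function(ix) min(graph$nodes$id[ix]), integer(1))
  ord <- order(-sizes, minid)
  lapply(unname(comps[ord]), function(ix) {
    ids <- graph$nodes$id[ix]
    e <- graph$edges[graph$edges$source %in% ids & graph$edges$target %in% ids, ,
                     drop = FALSE]
    cell_graph(graph$nodes[ix, , drop = FALSE], e, graph$meta)
  })
}

#' Keep only sufficiently large graphs
#'
#' Graphs below the size cutoff carry too little color-mixing information
#' for inference; by default only graphs with more than 70 nodes are kept.
#'
#' @param graphs list of `cell_graph`.
#' @param min_nodes minimum node count to keep (default 71, i.e. strictly
#'   more than 70 nodes).
#' @return filtered list; a message reports kept/dropped counts and a
#'   warning is raised when nothing survives.
#' @export
filter_by_size <- function(graphs, min_nodes = 71) {
  stopifnot(min_nodes >= 1)
  sizes <- vapply(graphs, n_nodes, integer(1))
  keep <- sizes >= min_nodes
  message(sprintf("size filter (>= %d nodes): kept %d of %d graphs",
                  min_nodes, sum(keep), length(graphs)))
  if (length(graphs) > 0 && !any(keep))
    warning("no graph passes the size filter")
  graphs[keep]
}

#' Mean distance between adjacent cell centroids
#'
#' Arithmetic mean over graph edges of the inter-centroid distance, either
#' straight-line (`euclidean`) or the stored in-vessel geodesic contact
#' distance (`geodesic`), scaled to micrometers.
#'
#' @param graph a `cell_graph` with at least one edge.
#' @param use `"euclidean"` or `"geodesic"`.
#' @param scale_um_per_px micrometers per pixel (default from graph
#'   metadata, else 1).
#' @return mean neighbor distance in micrometers.
#' @export
mean_neighbor_distance <- function(graph, use = c("euclidean", "geodesic"),
                                   scale_um_per_px = NULL) {
  use <- match.arg(use)
  if (nrow(graph$edges) == 0)
    stop("mean_neighbor_distance is undefined on an edgeless graph")
  if (is.null(scale_um_per_px))
    scale_um_per_px <- if (!is.null(graph$meta$pixel_size_um))
      graph$meta$pixel_size_um else 1
  if (use == "euclidean") {
    si <- match(graph$edges$source, graph$nodes$id)
    ti <- match(graph$edges$target, graph$nodes$id)
    d <- sqrt((graph$nodes$x[si] - graph$nodes$x[ti])^2 +
              (graph$nodes$y[si] - graph$nodes$y[ti])^2)
  } else {
    d <- graph$edges$distance
    if (anyNA(d)) stop("geodesic distances are missing on some edges")
  }
  mean(d) * scale_um_per_px
}
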