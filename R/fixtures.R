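#' Synthetic vessel-tube graph
#'
#' Generates a connected, elongated, locally planar cell graph emulating a
#' vessel fragment: cell centroids are laid out on a jittered grid inside a
#' band a few cells wide, edges connect centroids within a contact radius,
#' and colors are drawn i.i.d. from `color_freqs`. Mean degree lands in the
#' 3-6 range typical of a planar monolayer.
#'
#' @param n_cells number of cells (>= 2).
#' @param spacing mean cell spacing in pixels (default 12).
#' @param width_cells cells across the tube (default 3).
#' @param jitter centroid jitter as a fraction of spacing (default 0.35).
#' @param radius_factor contact radius in units of spacing (default 1.45).
#' @param n_colors number of fluorophores (default 3).
#' @param color_freqs color sampling probabilities (default uniform).
#' @param seed RNG seed.
#' @return a connected `cell_graph` (up to 10 resampling attempts, then an
#'   error).
#' @export
make_tube_graph <- function(n_cells, spacing = 12, width_cells = 3,
                            jitter = 0.35, radius_factor = 1.45,
                            n_colors = 3, color_freqs = NULL, seed = 1L) {
  stopifnot(n_cells >= 2, spacing > 0)
  if (is.null(color_freqs)) color_freqs <- rep(1 / n_colors, n_colors)
  set.seed(seed)
  for (attempt in 1:10) {
    len_cells <- ceiling(n_cells / width_cells)
    gx <- rep(seq_len(len_cells), each = width_cells)[seq_len(n_cells)]
    gy <- rep(seq_len(width_cells), times = len_cells)[seq_len(n_cells)]
    x <- (gx - 0.5) * spacing + runif(n_cells, -jitter, jitter) * spacing
    y <- (gy - 0.5) * spacing + runif(n_cells, -jitter, jitter) * spacing
    d <- as.matrix(dist(cbind(x, y)))
    adj <- d <= radius_factor * spacing
    diag(adj) <- FALSE
    idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
    nodes <- data.frame(id = seq_len(n_cells),
                        color = sample.int(n_colors, n_cells, replace = TRUE,
                                           prob = color_freqs),
                        x = x, y = y)
    edges <- data.frame(source = idx[, 1], target = idx[, 2],
                        distance = d[idx])
    g <- cell_graph(nodes, edges, meta = list(n_colors = n_colors,
                                              image_id = sprintf("tube_%d_%d", n_cells, seed)))
    comp <- igraph::components(as_igraph(g))
    if (comp$no == 1) return(g)
  }
  stop("could not draw a connected tube graph in 10 attempts")
}

#' Synthetic vessel-tube raster masks with ground truth
#'
#' Rasterizes a tube-shaped vessel, partitions it into cell regions by
#' geodesic nearest-seed assignment (an in-mask Voronoi tessellation),
#' shrinks each region by one pixel to emulate segmented instances with
#' visible boundaries, assigns i.i.d. colors, and returns everything the
#' mask-to-graph pipeline consumes plus the pixel-adjacency ground-truth
#' graph.
#'
#' @param n_cells number of cells.
#' @param spacing mean cell spacing in pixels (default 14).
#' @param width_cells cells across the tube (default 3).
#' @param n_colors number of fluorophores (default 3).
#' @param seed RNG seed.
#' @return list: `vessel` (logical matrix), `masks` (list of per-color
#'   label matrices), `regions` (full Voronoi partition),
#'   `truth` (ground-truth `cell_graph` whose edges come from an
#'   exhaustive 8-neighbor scan of the region partition), `cells`
#'   (data.frame id, color, x, y, area).
#' @export
make_tube_masks <- function(n_cells, spacing = 14, width_cells = 3,
                            n_colors = 3, seed = 1L) {
  stopifnot(n_cells >= 2)
  set.seed(seed)
  len_cells <- ceiling(n_cells / width_cells)
  H <- width_cells * spacing + 2
  Wd <- len_cells * spacing + 2
  vessel <- matrix(FALSE, H, Wd)
  vessel[2:(H - 1), 2:(Wd - 1)] <- TRUE
  gx <- rep(seq_len(len_cells), each = width_cells)[seq_len(n_cells)]
  gy <- rep(seq_len(width_cells), times = len_cells)[seq_len(n_cells)]
  cx <- pmin(pmax(round((gx - 0.5) * spacing +
                        runif(n_cells, -0.25, 0.25) * spacing), 2), Wd - 1)
  cy <- pmin(pmax(round((gy - 0.5) * spacing +
                        runif(n_cells, -0.25, 0.25) * spacing), 2), H - 1)
  seeds <- matrix(0L, H, Wd)
  seeds[cbind(cy, cx)] <- seq_len(n_cells)
  if (length(unique(seeds[seeds > 0])) < n_cells)
    stop("seed collision; use a larger spacing")
  vor <- .cpp_geodesic_voronoi(vessel, seeds)
  regions <- vor$label
  regions[!vessel] <- 0L
  # shrink each region by 1 px (4-neighbor erosion) to form instances
  instances <- erode_labels(regions)
  # never lose a cell entirely: keep at least the seed pixel
  for (i in seq_len(n_cells)) {
    if (!any(instances == i)) instances[seeds == i] <- i
  }
  colors <- sample.int(n_colors, n_cells, replace = TRUE)
  masks <- lapply(seq_len(n_colors), function(k) {
    m <- instances
    m[!(m %in% which(colors == k))] <- 0L
    m
  })
  cells <- data.frame(id = seq_len(n_cells), color = colors,
                      x = vapply(seq_len(n_cells), function(i) {
                        px <- which(regions == i)
                        mean((px - 1L) %/% H)
                      }, numeric(1)),
                      y = vapply(seq_len(n_cells), function(i) {
                        px <- which(regions == i)
                        mean((px - 1L) %% H)
                      }, numeric(1)),
                      area = as.integer(tabulate(regions[regions > 0],
                                                 nbins = n_cells)))
  contacts <- domain_contacts(regions)
  truth <- cell_graph(cells,
                      data.frame(source = contacts$a, target = contacts$b,
                                 distance = NA_real_, contacts = contacts$n),
                      meta = list(n_colors = n_colors))
  list(vessel = vessel, masks = masks, regions = regions,
       instances = instances, truth = truth, cells = cells, seeds = seeds)
}

# internal: remove the 4-connected boundary layer of every labeled region
erode_labels <- function(lab) {
  nr <- nrow(lab); nc <- ncol(lab)
  pad <- matrix(-1L, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- lab
  keep <- lab > 0
  for (sh in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
    nb <- pad[(2 + sh[1]):(nr + 1 + sh[1]), (2 + sh[2]):(nc + 1 + sh[2])]
    keep <- keep & nb == lab
  }
  out <- lab
  out[!keep] <- 0L
  out
}

#' Clonal coloring with known ground truth
#'
#' Thin wrapper over [simulate_regeneration()] for recovery experiments:
#' returns the simulated coloring together with the parameters that
#' generated it.
#'
#' @param graph a `cell_graph`.
#' @param params a [sim_params()] object.
#' @return list: `coloring` (data.frame from [simulate_regeneration()]),
#'   `graph` (the recolored `cell_graph`), `params`.
#' @export
make_clonal_coloring <- function(graph, params) {
  sim <- simulate_regeneration(graph, params)
  list(coloring = sim, graph = set_colors(graph, sim$color), params = params)
}
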