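#' Merge per-color instance label masks into one global label raster
#'
#' Each color channel carries its own instance ids; this renumbers all
#' instances into one id space (1..M), records each instance's color,
#' centroid (mean pixel coordinate over *all* its pixels) and area, and
#' resolves cross-channel overlaps: instances are painted in decreasing
#' area order (ties: lower color index, then lower within-channel id), and
#' an instance whose pixels overlap already-painted instances by more than
#' `max_overlap` of its own area is dropped with a warning. Instances
#' entirely outside the vessel mask are dropped with a warning.
#'
#' @param masks list of integer matrices (0 = background, k > 0 = instance
#'   id), one per color, in color order 1..K; all the same shape.
#' @param vessel optional logical matrix (vessel foreground) of the same
#'   shape.
#' @param max_overlap maximum tolerated overlap fraction per instance
#'   (default 0.5).
#' @return list: `labels` (global label matrix), `cells` (data.frame id,
#'   color, x, y, area; x = column - 1, y = row - 1, 0-based).
#' @export
merge_color_masks <- function(masks, vessel = NULL, max_overlap = 0.5) {
  stopifnot(length(masks) >= 1)
  dims <- dim(masks[[1]])
  for (m in masks) if (!identical(dim(m), dims)) stop("mask shapes differ")
  if (!is.null(vessel) && !identical(dim(vessel), dims))
    stop("vessel mask shape differs from label masks")
  inst <- list()
  for (k in seq_along(masks)) {
    mk <- masks[[k]]
    ids <- sort(unique(mk[mk > 0]))
    for (id in ids) {
      px <- which(mk == id)
      inst[[length(inst) + 1]] <- list(color = k, chan_id = id, px = px,
                                       area = length(px))
    }
  }
  if (length(inst) == 0) stop("no labeled instances in any channel")
  ord <- order(-vapply(inst, `[[`, numeric(1), "area"),
               vapply(inst, `[[`, numeric(1), "color"),
               vapply(inst, `[[`, numeric(1), "chan_id"))
  labels <- matrix(0L, dims[1], dims[2])
  cells <- list()
  gid <- 0L
  for (ii in ord) {
    it <- inst[[ii]]
    if (!is.null(vessel) && !any(vessel[it$px])) {
      warning(sprintf("instance %d (color %d) lies entirely outside the vessel mask; dropped",
                      it$chan_id, it$color))
      next
    }
    overlap <- mean(labels[it$px] != 0L)
    if (overlap > max_overlap) {
      warning(sprintf("instance %d (color %d) overlaps earlier instances by %.0f%%; dropped",
                      it$chan_id, it$color, 100 * overlap))
      next
    }
    gid <- gid + 1L
    free <- it$px[labels[it$px] == 0L]
    labels[free] <- gid
    rows <- (it$px - 1L) %% dims[1] + 1L
    cols <- (it$px - 1L) %/% dims[1] + 1L
    cells[[gid]] <- data.frame(id = gid, color = it$color,
                               x = mean(cols) - 1, y = mean(rows) - 1,
                               area = it$area)
  }
  if (gid == 0L) stop("all instances were dropped")
  cells <- do.call(rbind, cells)
  # renumber in id order (painting order) -> relabel to ascending by color/id
  list(labels = labels, cells = cells)
}

#' Geodesic distance map from instance boundaries
#'
#' Fast-marching (Eikonal) distance, measured inside the vessel mask, from
#' the boundary pixels of the labeled instances: zero on boundaries,
#' growing into unlabeled vessel space, forming the low-value basins
#' around each instance that the watershed floods.
#'
#' @param vessel logical vessel mask.
#' @param labels global label matrix from [merge_color_masks()].
#' @return numeric matrix: geodesic distance; `NA` outside the mask,
#'   `Inf` for in-mask pixels unreachable from any instance.
#' @export
boundary_geodesic_basins <- function(vessel, labels) {
  stopifnot(identical(dim(vessel), dim(labels)))
  if (!any(labels > 0)) stop("no labeled pixels")
  mask <- vessel | labels > 0
  boundary <- instance_boundaries(labels)
  .cpp_fmm_distance(mask, boundary)
}

# internal: pixels of an instance 8-adjacent to a different/background
# pixel (or the image border)
instance_boundaries <- function(labels) {
  nr <- nrow(labels); nc <- ncol(labels)
  pad <- matrix(-1L, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- labels
  b <- matrix(FALSE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- pad[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
    b <- b | (labels > 0 & nb != labels)
  }
  b
}

#' Partition the vessel into per-cell domains
#'
#' Marker-controlled watershed of the basin map, seeded by the labeled
#' instances and restricted to the vessel foreground: every vessel pixel is
#' assigned to exactly one cell. Flood ties are broken toward the lower
#' cell id.
#'
#' @param basins distance map from [boundary_geodesic_basins()].
#' @param labels global label matrix (watershed markers).
#' @param vessel logical vessel mask.
#' @return integer domain matrix (0 outside the vessel).
#' @export
partition_domains <- function(basins, labels, vessel) {
  stopifnot(identical(dim(basins), dim(labels)),
            identical(dim(basins), dim(vessel)))
  mask <- vessel | labels > 0
  .cpp_priority_flood(basins, labels, mask)
}

#' Build the region adjacency graph of cell domains
#'
#' One node per domain (color, instance centroid, domain pixel area); an
#' edge joins two domains sharing at least `min_contact` 8-adjacent pixel
#' pairs. Edge `distance` is the geodesic (in-mask) distance between the
#' two cell centroids, computed by fast marching from one centroid (snapped
#' to the nearest pixel of its own domain).
#'
#' @param domains domain matrix from [partition_domains()].
#' @param cells data.frame (id, color, x, y, area) from
#'   [merge_color_masks()].
#' @param vessel logical vessel mask.
#' @param min_contact minimum adjacent pixel pairs per edge (default 1).
#' @param pixel_size_um micrometers per pixel, stored as metadata.
#' @param geodesic_edges compute geodesic edge distances (default TRUE;
#'   disable for speed when only topology is needed).
#' @return a `cell_graph`.
#' @export
build_rag <- function(domains, cells, vessel, min_contact = 1,
                      pixel_size_um = 1, geodesic_edges = TRUE) {
  contacts <- domain_contacts(domains)
  contacts <- contacts[contacts$n >= min_contact, , drop = FALSE]
  edges <- data.frame(source = contacts$a, target = contacts$b,
                      distance = NA_real_, contacts = contacts$n)
  mask <- vessel | domains > 0
  if (geodesic_edges && nrow(edges) > 0) {
    # snap each centroid to the nearest pixel of its own domain
    nr <- nrow(domains)
    snap <- integer(nrow(cells))
    for (i in seq_len(nrow(cells))) {
      px <- which(domains == cells$id[i])
      if (length(px) == 0) px <- which(mask)
      rows <- (px - 1L) %% nr + 1L
      cols <- (px - 1L) %/% nr + 1L
      d2 <- (cols - 1 - cells$x[i])^2 + (rows - 1 - cells$y[i])^2
      snap[i] <- px[which.min(d2)]
    }
    for (i in seq_len(nrow(cells))) {
      id <- cells$id[i]
      sel <- edges$source == id
      if (!any(sel)) next
      src <- matrix(FALSE, nrow(domains), ncol(domains))
      src[snap[i]] <- TRUE
      dmap <- .cpp_fmm_distance(mask, src)
      tgt <- match(edges$target[sel], cells$id)
      edges$distance[sel] <- dmap[snap[tgt]]
    }
  }
  areas <- tabulate(domains[domains > 0], nbins = max(cells$id))
  nodes <- cells
  nodes$area <- areas[nodes$id]
  cell_graph(nodes, edges, meta = list(pixel_size_um = pixel_size_um,
                                       n_colors = max(cells$color)))
}

# internal: 8-connectivity contact counts between distinct domains.
# Exhaustively compares each pixel with its 4 forward neighbors (right,
# down, down-right, down-left), which enumerates every unordered adjacent
# pair once.
domain_contacts <- function(domains) {
  nr <- nrow(domains); nc <- ncol(domains)
  pairs <- list(
    cbind(as.vector(domains[, -nc]), as.vector(domains[, -1])),
    cbind(as.vector(domains[-nr, ]), as.vector(domains[-1, ])),
    cbind(as.vector(domains[-nr, -nc]), as.vector(domains[-1, -1])),
    cbind(as.vector(domains[-nr, -1]), as.vector(domains[-1, -nc])))
  pp <- do.call(rbind, pairs)
  pp <- pp[pp[, 1] > 0 & pp[, 2] > 0 & pp[, 1] != pp[, 2], , drop = FALSE]
  if (nrow(pp) == 0)
    return(data.frame(a = integer(0), b = integer(0), n = integer(0)))
  a <- pmin(pp[, 1], pp[, 2]); b <- pmax(pp[, 1], pp[, 2])
  key <- paste(a, b)
  agg <- table(key)
  ab <- do.call(rbind, strsplit(names(agg), " "))
  data.frame(a = as.integer(ab[, 1]), b = as.integer(ab[, 2]),
             n = as.integer(agg))
}

#' Full mask-to-graph pipeline
#'
#' Merges the per-color label masks, computes the boundary geodesic basins,
#' partitions the vessel into cell domains by marker watershed, and builds
#' the region adjacency graph.
#'
#' @inheritParams merge_color_masks
#' @inheritParams build_rag
#' @return a `cell_graph` (possibly disconnected; split with
#'   [connected_components()] and filter with [filter_by_size()]).
#' @export
masks_to_graph <- function(masks, vessel, max_overlap = 0.5, min_contact = 1,
                           pixel_size_um = 1, geodesic_edges = TRUE) {
  merged <- merge_color_masks(masks, vessel = vessel, max_overlap = max_overlap)
  basins <- boundary_geodesic_basins(vessel, merged$labels)
  domains <- partition_domains(basins, merged$labels, vessel)
  build_rag(domains, merged$cells, vessel, min_contact = min_contact,
            pixel_size_um = pixel_size_um, geodesic_edges = geodesic_edges)
}
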