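# small graph builders and independent oracles shared across test files

path_colored <- function(colors, gaps = NULL) {
  n <- length(colors)
  if (is.null(gaps)) gaps <- rep(1, n - 1)
  cell_graph(data.frame(id = seq_len(n), color = colors,
                        x = c(0, cumsum(gaps)), y = 0),
             data.frame(source = seq_len(n - 1), target = 2:n))
}

triangle_colored <- function(colors = c(1, 1, 1)) {
  cell_graph(data.frame(id = 1:3, color = colors, x = c(0, 1, 0.5), y = c(0, 0, 1)),
             data.frame(source = c(1, 1, 2), target = c(2, 3, 3)))
}

cycle_colored <- function(colors) {
  n <- length(colors)
  cell_graph(data.frame(id = seq_len(n), color = colors,
                        x = cos(2 * pi * seq_len(n) / n),
                        y = 1 + sin(2 * pi * seq_len(n) / n)),
             data.frame(source = seq_len(n), target = c(2:n, 1)))
}

# connected Erdos-Renyi-ish colored graph; guarantees >= 2 colors present
random_colored_graph <- function(n, K = 3, p_edge = 0.35, seed = 1,
                                 force_triangle = FALSE) {
  set.seed(seed)
  repeat {
    adj <- matrix(runif(n * n) < p_edge, n, n)
    adj[lower.tri(adj, diag = TRUE)] <- FALSE
    if (force_triangle && n >= 3) adj[1, 2] <- adj[2, 3] <- adj[1, 3] <- TRUE
    idx <- which(adj, arr.ind = TRUE)
    colors <- sample.int(K, n, replace = TRUE)
    if (length(unique(colors)) < 2) next
    g <- try(cell_graph(data.frame(id = seq_len(n), color = colors,
                                   x = runif(n, 0, 10), y = runif(n, 0, 10)),
                        data.frame(source = idx[, 1], target = idx[, 2]),
                        meta = list(n_colors = K)), silent = TRUE)
    if (inherits(g, "try-error")) next
    if (nrow(g$edges) == 0) next
    if (igraph::components(as_igraph(g))$no != 1) next
    return(g)
  }
}

edge_key <- function(edges) {
  sort(paste(pmin(edges$source, edges$target),
             pmax(edges$source, edges$target)))
}

# independent brute-force Newman assortativity (plain loops, no shared code
# with mixing_matrix)
newman_r_oracle <- function(graph) {
  K <- graph$meta$n_colors
  ids <- graph$nodes$id
  col <- graph$nodes$color
  cnt <- matrix(0, K, K)
  for (i in seq_len(nrow(graph$edges))) {
    a <- col[ids == graph$edges$source[i]]
    b <- col[ids == graph$edges$target[i]]
    cnt[a, b] <- cnt[a, b] + 1
    cnt[b, a] <- cnt[b, a] + 1
  }
  e <- cnt / sum(cnt)
  ab <- sum(rowSums(e) * colSums(e))
  (sum(diag(e)) - ab) / (1 - ab)
}

# dense linear-solve personalized PageRank oracle
ppr_solve_oracle <- function(graph, restart, damping) {
  gi <- clonograph:::graph_internals(graph)
  n <- gi$n
  P <- as.matrix(gi$P)
  u <- numeric(n)
  u[match(restart, graph$nodes$id)] <- 1 / length(restart)
  as.numeric(solve(diag(n) - damping * t(P), (1 - damping) * u))
}

# brute-force 8-connectivity contact scan over a domain raster (independent
# of domain_contacts' vectorized shifts)
pixel_contact_oracle <- function(domains) {
  nr <- nrow(domains); nc <- ncol(domains)
  counts <- list()
  bump <- function(a, b) {
    k <- paste(min(a, b), max(a, b))
    counts[[k]] <<- (if (is.null(counts[[k]])) 0 else counts[[k]]) + 1
  }
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    v <- domains[r, c]
    if (v == 0) next
    for (sh in list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))) {
      rr <- r + sh[1]; cc <- c + sh[2]
      if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
      w <- domains[rr, cc]
      if (w > 0 && w != v) bump(v, w)
    }
  }
  if (length(counts) == 0)
    return(data.frame(a = integer(0), b = integer(0), n = integer(0)))
  ab <- do.call(rbind, strsplit(names(counts), " "))
  out <- data.frame(a = as.integer(ab[, 1]), b = as.integer(ab[, 2]),
                    n = as.integer(unlist(counts)))
  out[order(out$a, out$b), ]
}
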