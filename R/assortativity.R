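#' Color mixing matrix of a cell graph
#'
#' Entry `e[g, h]` is the fraction of directed edges running from a node of
#' color `g` to a node of color `h`; each undirected edge is counted as two
#' directed edges in opposite directions, so the matrix is symmetric and
#' sums to 1.
#'
#' @param graph a `cell_graph` with at least one edge.
#' @return K x K numeric matrix of class `mixing_matrix` (K = number of
#'   colors), with attributes `a` (row sums) and `b` (column sums).
#' @export
mixing_matrix <- function(graph) {
  if (nrow(graph$edges) == 0) stop("mixing matrix is undefined on an edgeless graph")
  K <- graph$meta$n_colors
  gi <- graph_internals(graph)
  y <- graph$nodes$color
  tab <- table(factor(y[gi$ei], levels = seq_len(K)),
               factor(y[gi$ej], levels = seq_len(K)))
  e <- unclass(tab / sum(tab))
  dimnames(e) <- NULL
  structure(e, class = c("mixing_matrix", "matrix"),
            a = rowSums(e), b = colSums(e))
}

# internal: ||a^2|| = sum of all entries of e %*% e = sum_g a_g b_g
a2_norm <- function(e) {
  sum(as.numeric(e %*% e))
}

#' Global assortativity of a colored graph
#'
#' Newman-style assortativity coefficient
#' `r = (sum_g e_gg - ||a^2||) / (1 - ||a^2||)` where `||a^2||` is the sum
#' of all entries of the matrix product `e . e` (equivalently
#' `sum_g a_g b_g`). `r = 1` means all edges join same-colored cells;
#' negative values mean disassortative mixing.
#'
#' @param x a `mixing_matrix` or a `cell_graph`.
#' @return scalar assortativity, or `NA` with a warning when `||a^2|| = 1`
#'   (e.g. a monochromatic graph), in which case the graph must be excluded
#'   downstream.
#' @export
global_assortativity <- function(x) {
  e <- if (inherits(x, "cell_graph")) mixing_matrix(x) else x
  a2 <- a2_norm(e)
  if (1 - a2 < 1e-12) {
    warning("assortativity undefined: ||a^2|| = 1 (monochromatic graph?)")
    return(NA_real_)
  }
  (sum(diag(e)) - a2) / (1 - a2)
}

#' Personalized PageRank weights
#'
#' Solves the fixed point `w = (1 - d) u + d w P`, where `u` is uniform on
#' the restart set and `P` is the uniform random-walk matrix of the
#' undirected graph, by power iteration. The damping factor `d` sets the
#' locality range: small `d` confines the weights to the immediate
#' neighborhood of the restart set, `d -> 1` spreads them toward the
#' degree-proportional stationary distribution.
#'
#' @param graph a connected `cell_graph` (no isolated nodes).
#' @param restart node id(s) forming the restart ("point of return") set.
#' @param damping damping factor in (0, 1).
#' @param tol L1 convergence tolerance.
#' @param max_iter iteration cap.
#' @return numeric vector of weights in node-table order, summing to 1.
#' @export
personalized_pagerank <- function(graph, restart, damping, tol = 1e-10,
                                  max_iter = 100000) {
  stopifnot(damping > 0, damping < 1)
  gi <- graph_internals(graph)
  ridx <- match(restart, graph$nodes$id)
  if (length(ridx) == 0 || anyNA(ridx)) stop("restart set contains unknown node ids")
  if (any(gi$deg == 0)) stop("graph has isolated nodes; analyze connected components")
  u <- numeric(gi$n)
  u[ridx] <- 1 / length(ridx)
  w <- u
  for (it in seq_len(max_iter)) {
    w_new <- (1 - damping) * u + damping * as.numeric(Matrix::crossprod(gi$P, w))
    if (sum(abs(w_new - w)) < tol) return(w_new)
    w <- w_new
  }
  stop(sprintf("personalized PageRank did not converge in %d iterations (residual %.3g)",
               max_iter, sum(abs(w_new - w))))
}

#' All-nodes personalized PageRank matrix
#'
#' Computes the full matrix `W` with `W[l, i]` = personalized-PageRank
#' weight of node `i` when restarting at node `l`, by power iteration on
#' all restart vectors simultaneously. Rows sum to 1. Computing `W` once
#' per graph and damping factor makes whole-graph local-assortativity
#' profiles and repeated simulations cheap (each profile is then a single
#' matrix-vector product).
#'
#' @inheritParams personalized_pagerank
#' @return dense N x N matrix in node-table order.
#' @export
ppr_matrix <- function(graph, damping, tol = 1e-10, max_iter = 100000) {
  stopifnot(damping > 0, damping < 1)
  gi <- graph_internals(graph)
  if (any(gi$deg == 0)) stop("graph has isolated nodes; analyze connected components")
  n <- gi$n
  W <- diag(n)
  U <- (1 - damping) * diag(n)
  for (it in seq_len(max_iter)) {
    W_new <- U + damping * as.matrix(W %*% gi$P)
    if (max(abs(W_new - W)) * n < tol) return(W_new)
    W <- W_new
  }
  stop("ppr_matrix power iteration did not converge")
}

#' Locality-weighted mixing matrix around a node
#'
#' `e[g, h](l) = sum_{i: y_i = g} sum_{j: y_j = h} w(i; l) A_ij / deg(i)`:
#' the mixing matrix in which each directed edge `i -> j` is weighted by the
#' personalized-PageRank locality `w(i; l)` of its origin. Sums to 1 for
#' any probability vector `w`.
#'
#' @param graph a `cell_graph`.
#' @param omega per-node weights in node-table order (a probability vector),
#'   e.g. from [personalized_pagerank()].
#' @return K x K matrix.
#' @export
local_mixing <- function(graph, omega) {
  gi <- graph_internals(graph)
  stopifnot(length(omega) == gi$n)
  K <- graph$meta$n_colors
  y <- graph$nodes$color
  wgt <- omega[gi$ei] / gi$deg[gi$ei]
  e <- matrix(0, K, K)
  idx <- cbind(y[gi$ei], y[gi$ej])
  for (r in seq_along(wgt)) e[idx[r, 1], idx[r, 2]] <- e[idx[r, 1], idx[r, 2]] + wgt[r]
  e
}

#' Local assortativity of one node
#'
#' `r_local(l) = (sum_g e_gg(l) - ||a^2||) / (1 - ||a^2||)`, where the
#' locality weights come from personalized PageRank restarted at `l` and
#' `||a^2||` is taken from the *global* mixing matrix. As `damping -> 1`,
#' `r_local(l) -> r_global` for every node.
#'
#' @param graph a `cell_graph`.
#' @param l node id.
#' @param damping PageRank damping factor in (0, 1).
#' @return scalar local assortativity, `NA` with warning if undefined.
#' @export
local_assortativity <- function(graph, l, damping) {
  e_glob <- mixing_matrix(graph)
  a2 <- a2_norm(e_glob)
  if (1 - a2 < 1e-12) {
    warning("local assortativity undefined: ||a^2|| = 1")
    return(NA_real_)
  }
  omega <- personalized_pagerank(graph, l, damping)
  el <- local_mixing(graph, omega)
  (sum(diag(el)) - a2) / (1 - a2)
}

#' Local-assortativity profile of a graph
#'
#' Local assortativity of every node at one damping factor. Uses the
#' identity `sum_g e_gg(l) = sum_i w(i; l) s_i` with
#' `s_i = #(same-colored neighbors of i) / deg(i)`, so the whole profile is
#' the matrix-vector product `W s`.
#'
#' @param graph a `cell_graph`.
#' @param damping PageRank damping factor.
#' @param W optional precomputed [ppr_matrix()] for this graph/damping.
#' @return numeric vector of per-node local assortativities in node-table
#'   order, with the damping factor as attribute `damping`.
#' @export
assortativity_profile <- function(graph, damping, W = NULL) {
  e_glob <- mixing_matrix(graph)
  a2 <- a2_norm(e_glob)
  if (1 - a2 < 1e-12) {
    warning("assortativity profile undefined: ||a^2|| = 1")
    return(rep(NA_real_, nrow(graph$nodes)))
  }
  if (is.null(W)) W <- ppr_matrix(graph, damping)
  s <- same_color_fraction(graph)
  r <- (as.numeric(W %*% s) - a2) / (1 - a2)
  attr(r, "damping") <- damping
  r
}

# internal: s_i = fraction of i's directed out-edges landing on i's color.
# Accepts an alternative coloring to score simulated labelings cheaply.
same_color_fraction <- function(graph, colors = NULL) {
  gi <- graph_internals(graph)
  y <- if (is.null(colors)) graph$nodes$color else as.integer(colors)
  same <- as.numeric(y[gi$ei] == y[gi$ej]) / gi$deg[gi$ei]
  s <- numeric(gi$n)
  agg <- rowsum(same, gi$ei)
  s[as.integer(rownames(agg))] <- agg[, 1]
  s
}

# internal: profiles for many colorings at once. colors: N x m matrix.
# Returns list(r = N x m matrix of local assortativities, a2 = length-m,
# valid = logical m (FALSE where ||a^2|| = 1)).
profile_batch <- function(graph, colors, W) {
  gi <- graph_internals(graph)
  K <- graph$meta$n_colors
  m <- ncol(colors)
  S <- matrix(0, gi$n, m)
  a2 <- numeric(m)
  inv_deg <- 1 / gi$deg[gi$ei]
  for (k in seq_len(m)) {
    y <- colors[, k]
    same <- as.numeric(y[gi$ei] == y[gi$ej]) * inv_deg
    agg <- rowsum(same, gi$ei)
    S[as.integer(rownames(agg)), k] <- agg[, 1]
    tab <- tabulate(y[gi$ei] + K * (y[gi$ej] - 1L), nbins = K * K)
    e <- matrix(tab / length(gi$ei), K, K)
    a2[k] <- a2_norm(e)
  }
  valid <- (1 - a2) >= 1e-12
  TT <- W %*% S
  r <- sweep(sweep(TT, 2, a2, "-"), 2, pmax(1 - a2, 1e-300), "/")
  list(r = r, a2 = a2, valid = valid)
}
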