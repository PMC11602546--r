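#' Regeneration simulation parameters
#'
#' @param progenitor_fraction fraction `p` in (0, 1] of surviving (initial)
#'   cells that re-enter the cell cycle and found clones.
#' @param new_fraction fraction `f` in \[0, 1) of cells in the observed
#'   network that were generated after injury.
#' @param color_freqs length-K probability vector of fluorophore
#'   frequencies for surviving cells; `NULL` (default) uses the empirical
#'   color frequencies of the observed graph.
#' @param seed integer RNG seed for one simulation.
#' @return a `sim_params` list.
#' @export
sim_params <- function(progenitor_fraction, new_fraction, color_freqs = NULL,
                       seed = 1L) {
  stopifnot(progenitor_fraction > 0, progenitor_fraction <= 1,
            new_fraction >= 0, new_fraction < 1)
  if (!is.null(color_freqs)) {
    stopifnot(all(color_freqs >= 0), abs(sum(color_freqs) - 1) < 1e-8)
  }
  structure(list(progenitor_fraction = progenitor_fraction,
                 new_fraction = new_fraction,
                 color_freqs = color_freqs,
                 seed = as.integer(seed)),
            class = "sim_params")
}

# round half up: deterministic across platforms, unlike round()'s
# round-half-to-even
round_half_up <- function(x) floor(x + 0.5)

#' Randomly assign regeneration roles to graph nodes
#'
#' Draws `n_new = round(f N)` new cells and, among the remaining survivors,
#' `n_prog = round(p (N - n_new))` progenitors (at least 1 whenever there
#' are new cells); the rest are passive survivors.
#'
#' @param graph a `cell_graph` with at least 2 nodes.
#' @param params a [sim_params()] object.
#' @return factor vector of roles (`"new"`, `"progenitor"`, `"passive"`) in
#'   node-table order, with counts in attribute `counts`. Uses the current
#'   RNG state; seed handling lives in [simulate_regeneration()].
#' @export
assign_roles <- function(graph, params) {
  N <- nrow(graph$nodes)
  stopifnot(N >= 2)
  n_new <- as.integer(round_half_up(params$new_fraction * N))
  n_prog <- as.integer(round_half_up(params$progenitor_fraction * (N - n_new)))
  if (n_new > 0 && n_prog == 0) {
    warning("progenitor count rounded to 0 with new cells present; forcing 1")
    n_prog <- 1L
  }
  n_prog <- min(n_prog, N - n_new)
  perm <- sample.int(N)
  roles <- rep("passive", N)
  if (n_new > 0) roles[perm[seq_len(n_new)]] <- "new"
  if (n_prog > 0) roles[perm[n_new + seq_len(n_prog)]] <- "progenitor"
  roles <- factor(roles, levels = c("new", "progenitor", "passive"))
  attr(roles, "counts") <- c(new = n_new, progenitor = n_prog,
                             passive = N - n_new - n_prog)
  roles
}

#' Move new cells next to progenitors by label swapping
#'
#' Computes a gradient over the graph as personalized PageRank restarted
#' uniformly on the progenitor set, then repeatedly swaps roles across
#' edges where a passive cell sits higher on the gradient than an adjacent
#' new cell ("pushing" passive cells away from progenitors), until no such
#' edge remains. Progenitors never move. Each swap strictly increases the
#' total gradient mass on new cells, so the process terminates.
#'
#' Scheduling is deterministic: each pass collects all violating edges,
#' processes them in decreasing order of gradient difference (skipping
#' nodes already swapped this pass), and repeats until clean.
#'
#' @param graph a `cell_graph`.
#' @param roles role factor from [assign_roles()].
#' @param gradient optional precomputed progenitor-restart PageRank vector.
#' @param damping damping factor for the gradient (default 0.7).
#' @return updated role factor (same levels/counts), with the number of
#'   swaps in attribute `n_swaps` and the gradient in attribute `gradient`.
#' @export
rearrange_labels <- function(graph, roles, gradient = NULL, damping = 0.7) {
  counts <- attr(roles, "counts")
  role <- as.character(roles)
  prog <- which(role == "progenitor")
  if (sum(role == "new") == 0 || sum(role == "passive") == 0 ||
      length(prog) == 0) {
    attr(roles, "n_swaps") <- 0L
    return(roles)
  }
  if (is.null(gradient))
    gradient <- personalized_pagerank(graph, graph$nodes$id[prog], damping)
  gi <- graph_internals(graph)
  ei <- gi$ei; ej <- gi$ej  # directed edges, both orientations present
  N <- gi$n
  n_swaps <- 0L
  max_swaps <- N * N
  repeat {
    viol <- which(role[ei] == "passive" & role[ej] == "new" &
                  gradient[ei] > gradient[ej])
    if (length(viol) == 0) break
    dgrad <- gradient[ei[viol]] - gradient[ej[viol]]
    ord <- viol[order(-dgrad, ei[viol], ej[viol])]
    touched <- logical(N)
    for (v in ord) {
      a <- ei[v]; b <- ej[v]
      if (touched[a] || touched[b]) next
      if (role[a] != "passive" || role[b] != "new") next
      role[a] <- "new"; role[b] <- "passive"
      touched[a] <- TRUE; touched[b] <- TRUE
      n_swaps <- n_swaps + 1L
      if (n_swaps > max_swaps)
        stop("label rearrangement exceeded N^2 swaps; this should be unreachable")
    }
  }
  out <- factor(role, levels = levels(roles))
  attr(out, "counts") <- counts
  attr(out, "n_swaps") <- n_swaps
  attr(out, "gradient") <- gradient
  out
}

#' Partition a graph into progenitor domains
#'
#' Every node is claimed by the progenitor whose personalized PageRank
#' (restarted at that progenitor alone) is highest at the node; ties go to
#' the progenitor with the lowest id, and each progenitor always owns its
#' own node.
#'
#' @param graph a `cell_graph`.
#' @param roles role factor with at least one progenitor.
#' @param W optional precomputed [ppr_matrix()] at `damping`.
#' @param damping damping factor (default 0.7).
#' @return integer vector of domain ids (progenitor node ids) in node-table
#'   order.
#' @export
partition_progenitor_domains <- function(graph, roles, W = NULL, damping = 0.7) {
  prog <- which(as.character(roles) == "progenitor")
  if (length(prog) == 0) stop("no progenitors to partition around")
  prog <- prog[order(graph$nodes$id[prog])]  # ascending id for tie-breaking
  if (is.null(W)) {
    rows <- ppr_rows(graph, graph$nodes$id[prog], damping)
  } else {
    rows <- W[prog, , drop = FALSE]
  }
  # max.col with ties.method = "first" => lowest progenitor id wins ties
  owner <- max.col(t(rows), ties.method = "first")
  dom <- graph$nodes$id[prog][owner]
  dom[prog] <- graph$nodes$id[prog]
  dom
}

# internal: personalized-PageRank rows for a set of restart nodes, batched
# power iteration (each row = one single-node restart).
ppr_rows <- function(graph, restart_ids, damping, tol = 1e-10,
                     max_iter = 100000) {
  gi <- graph_internals(graph)
  ridx <- match(restart_ids, graph$nodes$id)
  m <- length(ridx)
  U <- matrix(0, m, gi$n)
  U[cbind(seq_len(m), ridx)] <- 1 - damping
  W <- U / (1 - damping)
  for (it in seq_len(max_iter)) {
    W_new <- U + damping * as.matrix(W %*% gi$P)
    if (max(abs(W_new - W)) * gi$n < tol) return(W_new)
    W <- W_new
  }
  stop("ppr_rows power iteration did not converge")
}

#' Recolor a graph according to simulated clonal regeneration
#'
#' Surviving cells (progenitor and passive) draw independent colors from
#' `color_freqs`; each new cell is stripped of its original identity, takes
#' the identity of the progenitor domain it falls in, and inherits that
#' progenitor's color.
#'
#' @param graph a `cell_graph`.
#' @param roles role factor.
#' @param domains domain ids from [partition_progenitor_domains()] (may be
#'   `NULL` when there are no new cells).
#' @param params a [sim_params()] object.
#' @return data.frame (id, role, clone, color) in node-table order: `clone`
#'   is the progenitor ancestor id for new cells and the node's own id
#'   otherwise.
#' @export
recolor <- function(graph, roles, domains, params) {
  N <- nrow(graph$nodes)
  K <- graph$meta$n_colors
  freqs <- params$color_freqs
  if (is.null(freqs)) {
    freqs <- tabulate(graph$nodes$color, nbins = K) / N
  }
  role <- as.character(roles)
  color <- integer(N)
  surv <- role != "new"
  color[surv] <- sample.int(K, sum(surv), replace = TRUE, prob = freqs)
  clone <- graph$nodes$id
  if (any(!surv)) {
    if (is.null(domains)) stop("domains required when new cells are present")
    newi <- which(!surv)
    clone[newi] <- domains[newi]
    prog_color <- color[match(domains[newi], graph$nodes$id)]
    color[newi] <- prog_color
  }
  data.frame(id = graph$nodes$id, role = role, clone = clone, color = color)
}

#' Simulate clonal regeneration on an observed graph
#'
#' Runs the full simulation on a fixed topology, changing only the color
#' labels: role assignment, label rearrangement toward progenitors,
#' progenitor-domain partition, and clonal recoloring. Deterministic given
#' `params$seed`.
#'
#' @param graph a connected `cell_graph` (>= 2 nodes).
#' @param params a [sim_params()] object.
#' @param W optional precomputed [ppr_matrix()] at `damping` (a large
#'   speedup when simulating many times on one graph).
#' @param damping damping factor used for the gradient and the domain
#'   partition (default 0.7).
#' @return data.frame (id, role, clone, color), as [recolor()], with the
#'   parameters in attribute `params`.
#' @export
simulate_regeneration <- function(graph, params, W = NULL, damping = 0.7) {
  set.seed(params$seed)
  roles <- assign_roles(graph, params)
  n_new <- attr(roles, "counts")[["new"]]
  domains <- NULL
  if (n_new > 0) {
    prog <- which(as.character(roles) == "progenitor")
    gradient <- if (!is.null(W)) {
      colMeans(W[prog, , drop = FALSE])
    } else NULL
    roles <- rearrange_labels(graph, roles, gradient = gradient,
                              damping = damping)
    domains <- partition_progenitor_domains(graph, roles, W = W,
                                            damping = damping)
  }
  out <- recolor(graph, roles, domains, params)
  attr(out, "params") <- params
  out
}
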