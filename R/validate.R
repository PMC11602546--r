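#' Normalized histogram
#'
#' Counts values into the bins defined by `edges` and normalizes to a
#' probability vector. The outer bins are open: values outside the edge
#' range are clamped into the first/last bin.
#'
#' @param values numeric vector (non-empty).
#' @param edges increasing numeric vector of bin edges (length = bins + 1).
#' @return probability vector of length `length(edges) - 1`, summing to 1.
#' @export
histogram_probs <- function(values, edges) {
  if (length(values) == 0) stop("cannot histogram an empty vector")
  stopifnot(length(edges) >= 2, !is.unsorted(edges))
  idx <- findInterval(values, edges, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), length(edges) - 1L)
  tabulate(idx, nbins = length(edges) - 1L) / length(values)
}

#' Bhattacharyya distance between two histograms
#'
#' `D = -ln sum_i sqrt(h1_i h2_i)`: zero iff the histograms are identical,
#' symmetric, and infinite for disjoint supports, in which case the value
#' is capped at `d_max` and flagged.
#'
#' @param h1,h2 probability vectors over the same bins.
#' @param d_max cap for disjoint supports (default 20).
#' @return distance (attribute `capped = TRUE` when the cap was applied).
#' @export
bhattacharyya_distance <- function(h1, h2, d_max = 20) {
  stopifnot(length(h1) == length(h2))
  bc <- sum(sqrt(h1 * h2))
  if (bc <= exp(-d_max)) {
    return(structure(d_max, capped = TRUE))
  }
  -log(bc)
}

# internal: shared binning across observed + simulated profile values
shared_edges <- function(..., n_bins = 50) {
  vals <- unlist(list(...))
  rng <- range(vals, finite = TRUE)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  seq(rng[1], rng[2], length.out = n_bins + 1)
}

# internal: simulate n_sim colorings at fixed (p, f) and return the matrix
# of local-assortativity profiles at `damping` (invalid sims dropped)
simulate_envelope <- function(graph, p, f, n_sim, damping, seed, W = NULL,
                              Wsim = NULL, damping_sim = 0.7) {
  N <- nrow(graph$nodes)
  if (is.null(W)) W <- ppr_matrix(graph, damping)
  if (is.null(Wsim)) Wsim <- if (damping_sim == damping) W else ppr_matrix(graph, damping_sim)
  colors <- matrix(0L, N, n_sim)
  for (i in seq_len(n_sim)) {
    pars <- sim_params(p, f, seed = seed + i)
    colors[, i] <- simulate_regeneration(graph, pars, W = Wsim,
                                         damping = damping_sim)$color
  }
  pb <- profile_batch(graph, colors, W)
  pb$r[, pb$valid, drop = FALSE]
}

#' Posterior-predictive check of fitted regeneration parameters
#'
#' Re-simulates the graph `n_sim` times at the fitted `(p, f)`, bins all
#' local-assortativity profiles on a shared 50-bin grid, and measures how
#' typical the observed profile is among the simulations: the observed
#' graph's median Bhattacharyya distance to the simulations is ranked
#' against each simulation's median distance to the others. A fit is
#' consistent when the observed percentile does not exceed
#' `percentile_threshold`.
#'
#' @param graph the observed `cell_graph`.
#' @param p,f fitted progenitor and new-cell fractions.
#' @param n_sim number of posterior-predictive simulations (default 500).
#' @param damping damping factor of the compared profiles (default 0.1).
#' @param n_bins histogram bins.
#' @param percentile_threshold typicality threshold (default 95).
#' @param seed RNG seed.
#' @return list: `typicality_percentile`, `consistent` (logical),
#'   `observed_median_distance`, `sim_median_distances`, `edges`,
#'   `observed_hist`, `sim_hists` (matrix, one column per simulation).
#' @export
predictive_check <- function(graph, p, f, n_sim = 500, damping = 0.1,
                             n_bins = 50, percentile_threshold = 95,
                             seed = 1L) {
  obs <- assortativity_profile(graph, damping)
  if (anyNA(obs)) stop("assortativity undefined for the observed graph")
  R <- simulate_envelope(graph, p, f, n_sim, damping, seed)
  if (ncol(R) < 2) {
    warning("fewer than 2 valid simulations; predictive check is degenerate")
    return(list(typicality_percentile = NA_real_, consistent = NA,
                observed_median_distance = NA_real_,
                sim_median_distances = numeric(0)))
  }
  edges <- shared_edges(obs, R, n_bins = n_bins)
  obs_h <- histogram_probs(obs, edges)
  sim_h <- apply(R, 2, histogram_probs, edges = edges)
  m <- ncol(sim_h)
  sq <- sqrt(sim_h)
  # all pairwise Bhattacharyya coefficients in one crossprod
  bc <- crossprod(sq)
  bc <- pmin(pmax(bc, exp(-20)), 1)
  D <- -log(bc)
  sim_med <- vapply(seq_len(m), function(k) median(D[k, -k]), numeric(1))
  obs_d <- -log(pmin(pmax(as.numeric(crossprod(sqrt(obs_h), sq)), exp(-20)), 1))
  obs_med <- median(obs_d)
  pct <- 100 * mean(sim_med <= obs_med)
  list(typicality_percentile = pct,
       consistent = pct <= percentile_threshold,
       observed_median_distance = obs_med,
       sim_median_distances = sim_med,
       edges = edges, observed_hist = obs_h, sim_hists = sim_h,
       seed = seed, p = p, f = f, n_sim = m)
}

#' Sensitivity check for rare progenitor clones
#'
#' Large clones founded by a rare progenitor pool would surface as excess
#' mass in the upper tail of the local-assortativity distribution. The
#' check simulates envelopes at the fitted `p` and at an alternative
#' `alt_p` (default 1%, same `f`), takes the 95th percentile of the pooled
#' fitted-`p` envelope as the tail cutoff, and compares upper-tail masses.
#' The observed graph is flagged as carrying a rare-clone signature when
#' its tail mass exceeds the `flag_prob` quantile of the per-simulation
#' tail masses of the fitted-`p` envelope (a Monte-Carlo test; the
#' pooled envelope mass itself is 5% by construction).
#'
#' @inheritParams predictive_check
#' @param alt_p alternative rare progenitor fraction (default 0.01).
#' @param tail_prob pooled-envelope quantile defining the tail (default
#'   0.95).
#' @param flag_prob Monte-Carlo flag quantile (default 0.95).
#' @return list: `flag` (logical), `observed_tail_mass`,
#'   `fitted_tail_masses`, `alt_tail_masses` (per-simulation),
#'   `tail_cutoff`, `flag_threshold`.
#' @export
rare_progenitor_sensitivity <- function(graph, p, f, alt_p = 0.01,
                                        n_sim = 500, damping = 0.1,
                                        tail_prob = 0.95, flag_prob = 0.95,
                                        seed = 1L) {
  obs <- assortativity_profile(graph, damping)
  if (anyNA(obs)) stop("assortativity undefined for the observed graph")
  W <- ppr_matrix(graph, damping)
  Wsim <- ppr_matrix(graph, 0.7)
  R_fit <- simulate_envelope(graph, p, f, n_sim, damping, seed, W = W, Wsim = Wsim)
  R_alt <- simulate_envelope(graph, alt_p, f, n_sim, damping,
                             seed + n_sim + 1, W = W, Wsim = Wsim)
  cutoff <- quantile(as.numeric(R_fit), probs = tail_prob, names = FALSE)
  tails_fit <- colMeans(R_fit > cutoff)
  tails_alt <- colMeans(R_alt > cutoff)
  obs_tail <- mean(obs > cutoff)
  thr <- quantile(tails_fit, probs = flag_prob, names = FALSE)
  list(flag = obs_tail > thr,
       observed_tail_mass = obs_tail,
       fitted_tail_masses = tails_fit,
       alt_tail_masses = tails_alt,
       tail_cutoff = cutoff, flag_threshold = thr,
       p = p, alt_p = alt_p, f = f, seed = seed)
}
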