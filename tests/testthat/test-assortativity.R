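test_that("mixing matrix counts each undirected edge as two directed edges", {
  e <- mixing_matrix(path_colored(c(1, 1, 2)))
  expect_equal(unclass(e)[1:2, 1:2], matrix(c(0.5, 0.25, 0.25, 0), 2, 2),
               ignore_attr = TRUE)

  mono <- mixing_matrix(triangle_colored(c(1, 1, 1)))
  expect_equal(unclass(mono)[1, 1], 1)

  alt <- mixing_matrix(cycle_colored(c(1, 2, 1, 2)))
  expect_equal(unclass(alt)[1:2, 1:2], matrix(c(0, 0.5, 0.5, 0), 2, 2),
               ignore_attr = TRUE)

  lone <- cell_graph(data.frame(id = 1, color = 1, x = 0, y = 0))
  expect_error(mixing_matrix(lone), "edgeless")

  for (s in 1:25) {
    e <- mixing_matrix(random_colored_graph(10, seed = s))
    expect_equal(sum(e), 1, tolerance = 1e-12)
    expect_equal(unclass(e), t(unclass(e)), tolerance = 1e-14, ignore_attr = TRUE)
  }
})

test_that("global assortativity hits the textbook landmark values", {
  # two monochrome cliques, no cross edges
  cliques <- cell_graph(
    data.frame(id = 1:6, color = c(1, 1, 1, 2, 2, 2), x = 1:6, y = 0),
    data.frame(source = c(1, 1, 2, 4, 4, 5), target = c(2, 3, 3, 5, 6, 6)))
  expect_equal(global_assortativity(cliques), 1)

  expect_equal(global_assortativity(cycle_colored(c(1, 2, 1, 2))), -1)
  expect_equal(global_assortativity(path_colored(c(1, 1, 2))), -1 / 3)

  expect_warning(r <- global_assortativity(triangle_colored(c(1, 1, 1))),
                 "undefined")
  expect_true(is.na(r))
})

test_that("global assortativity equals independent Newman computations", {
  for (s in 1:40) {
    g <- random_colored_graph(sample(4:12, 1), K = sample(2:3, 1),
                              seed = 1000 + s)
    e <- mixing_matrix(g)
    # ||a^2|| identity: sum of entries of e.e equals sum_g a_g b_g
    expect_equal(sum(e %*% e), sum(attr(e, "a") * attr(e, "b")),
                 tolerance = 1e-14)
    r <- global_assortativity(g)
    expect_equal(r, newman_r_oracle(g), tolerance = 1e-12)
    r_ig <- igraph::assortativity_nominal(as_igraph(g),
                                          types = g$nodes$color)
    expect_equal(r, r_ig, tolerance = 1e-12)
  }
})

test_that("personalized PageRank solves its fixed point", {
  tri <- triangle_colored()
  w <- personalized_pagerank(tri, restart = 1, damping = 0.5)
  expect_equal(w, c(0.6, 0.2, 0.2), tolerance = 1e-8)

  for (s in 1:10) {
    g <- random_colored_graph(12, seed = 200 + s)
    d <- runif(1, 0.05, 0.95)
    restart <- sample(g$nodes$id, sample(1:3, 1))
    w <- personalized_pagerank(g, restart, d)
    expect_equal(sum(w), 1, tolerance = 1e-10)
    expect_true(all(w >= 0))
    expect_equal(w, ppr_solve_oracle(g, restart, d), tolerance = 1e-8)
    # igraph as an independent library oracle
    reset <- numeric(n_nodes(g))
    reset[match(restart, g$nodes$id)] <- 1
    w_ig <- igraph::page_rank(as_igraph(g), damping = d,
                              personalized = reset)$vector
    expect_equal(w, as.numeric(w_ig), tolerance = 1e-6)
  }

  # teleport-dominated limit: indicator of the restart set
  g <- random_colored_graph(10, seed = 77)
  w <- personalized_pagerank(g, g$nodes$id[3], damping = 1e-6)
  expect_equal(w[3], 1, tolerance = 1e-5)

  expect_error(personalized_pagerank(tri, restart = 99, damping = 0.5),
               "unknown node")
})

test_that("ppr_matrix rows equal single-restart PageRank vectors", {
  g <- random_colored_graph(15, seed = 31)
  for (d in c(0.1, 0.7)) {
    W <- ppr_matrix(g, d)
    expect_equal(rowSums(W), rep(1, 15), tolerance = 1e-9)
    for (l in c(1, 7, 15)) {
      expect_equal(W[l, ], personalized_pagerank(g, g$nodes$id[l], d),
                   tolerance = 1e-9)
    }
  }
})

test_that("local mixing conserves mass and recovers the global matrix", {
  g <- random_colored_graph(12, seed = 5)
  gi <- clonograph:::graph_internals(g)
  # degree-proportional stationary weights reproduce the global mixing matrix
  w_stat <- gi$deg / sum(gi$deg)
  expect_equal(local_mixing(g, w_stat), unclass(mixing_matrix(g)),
               tolerance = 1e-12, ignore_attr = TRUE)
  # any probability weight vector conserves total mass 1
  for (s in 1:5) {
    set.seed(s)
    w <- runif(12); w <- w / sum(w)
    expect_equal(sum(local_mixing(g, w)), 1, tolerance = 1e-10)
  }
  # single-edge graph: sum 1 regardless of weights
  g1 <- path_colored(c(1, 2))
  expect_equal(sum(local_mixing(g1, c(0.9, 0.1))), 1, tolerance = 1e-12)
})

test_that("profile equals per-node local assortativity and is equivariant", {
  g <- random_colored_graph(14, seed = 8)
  prof <- assortativity_profile(g, 0.3)
  expect_length(prof, 14)
  for (l in c(2, 9, 14)) {
    expect_equal(prof[l], local_assortativity(g, g$nodes$id[l], 0.3),
                 tolerance = 1e-8)
  }
  # permuting node order permutes the profile identically
  perm <- sample(14)
  g2 <- cell_graph(g$nodes[perm, ], g$edges, g$meta)
  expect_equal(assortativity_profile(g2, 0.3), prof[perm],
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("damping near 1 drives local assortativity to the global value", {
  for (s in 1:3) {
    g <- random_colored_graph(25, seed = 300 + s, force_triangle = TRUE)
    r_glob <- global_assortativity(g)
    prof <- assortativity_profile(g, 0.999, W = ppr_matrix(g, 0.999))
    expect_lt(max(abs(prof - r_glob)), 0.02)
  }
})

test_that("a node deep inside a monochrome patch is locally assortative", {
  # two-color path: long run of color 1, then color 2
  g <- path_colored(c(rep(1, 15), rep(2, 15)))
  deep <- 8  # mid-patch node
  r_deep <- local_assortativity(g, deep, damping = 0.1)
  expect_gt(r_deep, 0.9)
  r_border <- local_assortativity(g, 15, damping = 0.1)
  expect_lt(r_border, r_deep)
})

test_that("local assortativity averages to the global value on a ring", {
  # on a vertex-transitive graph the PageRank matrix is doubly stochastic,
  # so the node-mean of r_local equals r_global exactly, for any coloring
  n <- 24
  base <- cycle_colored(rep(1:2, n / 2))
  W <- ppr_matrix(base, 0.3)
  set.seed(99)
  means <- replicate(200, {
    g <- set_colors(base, sample(1:2, n, replace = TRUE))
    e <- mixing_matrix(g)
    if (1 - sum(e %*% e) < 1e-12) return(NA_real_)
    m <- mean(assortativity_profile(g, 0.3, W = W))
    expect_equal(m, global_assortativity(g), tolerance = 1e-9)
    m
  })
  means <- means[!is.na(means)]
  se <- sd(means) / sqrt(length(means))
  # centered at zero up to the O(1/n) small-sample bias of the estimator
  expect_lt(abs(mean(means)), 2 / n + 3 * se)
})

test_that("small damping sharpens the local assortativity distribution", {
  g <- make_tube_graph(150, seed = 21)
  sim <- simulate_regeneration(g, sim_params(0.05, 0.4, seed = 3))
  gc <- set_colors(g, sim$color)
  p01 <- assortativity_profile(gc, 0.1)
  p07 <- assortativity_profile(gc, 0.7)
  expect_false(isTRUE(all.equal(p01, p07)))
  expect_gt(sd(p01), sd(p07))  # tighter locality -> heavier tails
})
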