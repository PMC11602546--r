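test_that("channel merging renumbers instances and resolves conflicts", {
  m1 <- matrix(0L, 6, 12); m2 <- matrix(0L, 6, 12)
  m1[2:3, 2:3] <- 1L; m1[2:3, 6:7] <- 2L
  m2[5, 2:3] <- 1L; m2[5, 6:7] <- 2L; m2[5, 10:11] <- 7L
  out <- merge_color_masks(list(m1, m2))
  expect_equal(nrow(out$cells), 5)
  expect_equal(sort(table(out$cells$color)), sort(c(`1` = 2, `2` = 3)),
               ignore_attr = TRUE)
  expect_setequal(unique(out$labels[out$labels > 0]), out$cells$id)

  # identical instance in two channels: one survivor, lower color index
  dup1 <- matrix(0L, 5, 5); dup1[2:3, 2:3] <- 1L
  expect_warning(out2 <- merge_color_masks(list(dup1, dup1)), "overlaps")
  expect_equal(nrow(out2$cells), 1)
  expect_equal(out2$cells$color, 1)

  # instance partially outside the vessel: kept, centroid over all pixels
  vessel <- matrix(TRUE, 5, 5); vessel[, 5] <- FALSE
  part <- matrix(0L, 5, 5); part[3, 2:5] <- 1L
  out3 <- merge_color_masks(list(part), vessel = vessel)
  expect_equal(out3$cells$x, mean(1:4))  # 0-based columns 1..4

  # instance fully outside: dropped with a warning
  outside <- matrix(0L, 5, 5); outside[3, 5] <- 2L; outside[2, 2] <- 1L
  expect_warning(out4 <- merge_color_masks(list(outside), vessel = vessel),
                 "outside")
  expect_equal(nrow(out4$cells), 1)

  expect_error(merge_color_masks(list(m1, matrix(0L, 3, 3))), "shapes differ")
})

test_that("fast marching reproduces arc length in a thin tube", {
  # straight 1-px tube: distance increases by 1 per step
  vessel <- matrix(FALSE, 3, 12); vessel[2, 2:11] <- TRUE
  labels <- matrix(0L, 3, 12); labels[2, 2] <- 1L
  b <- boundary_geodesic_basins(vessel, labels)
  expect_equal(b[2, 2:11], 0:9)
  expect_true(is.na(b[1, 1]))  # outside the vessel: sentinel

  expect_error(boundary_geodesic_basins(vessel, matrix(0L, 3, 12)),
               "no labeled pixels")
})

test_that("geodesic distance follows the tube around a U-bend", {
  # U-shaped 1-px corridor
  vessel <- matrix(FALSE, 10, 7)
  vessel[2:9, 2] <- TRUE; vessel[9, 2:6] <- TRUE; vessel[2:9, 6] <- TRUE
  labels <- matrix(0L, 10, 7); labels[2, 2] <- 1L
  b <- boundary_geodesic_basins(vessel, labels)
  # Dijkstra oracle on the 4-connected pixel lattice
  px <- which(vessel)
  nr <- nrow(vessel)
  coord <- cbind((px - 1) %% nr + 1, (px - 1) %/% nr + 1)
  adj <- which(outer(coord[, 1], coord[, 1], function(a, b) abs(a - b)) +
               outer(coord[, 2], coord[, 2], function(a, b) abs(a - b)) == 1,
               arr.ind = TRUE)
  ig <- igraph::graph_from_edgelist(adj[adj[, 1] < adj[, 2], , drop = FALSE],
                                    directed = FALSE)
  src <- which(px == which(labels == 1L))
  d4 <- as.numeric(igraph::distances(ig, v = src))
  tip <- which(coord[, 1] == 2 & coord[, 2] == 6)
  # around the U, not across the gap
  straight <- sqrt(sum((coord[tip, ] - coord[src, ])^2))
  expect_gt(b[2, 6], 3 * straight)
  # matches arc length up to the corner discretization of the Eikonal stencil
  expect_equal(b[2, 6], d4[tip], tolerance = 0.1)
  expect_true(all(abs(b[px] - d4) <= 1))
})

test_that("watershed partitions a tube symmetrically with lower-id ties", {
  vessel <- matrix(FALSE, 3, 11); vessel[2, 2:10] <- TRUE
  labels <- matrix(0L, 3, 11); labels[2, 2] <- 1L; labels[2, 10] <- 2L
  b <- boundary_geodesic_basins(vessel, labels)
  dom <- partition_domains(b, labels, vessel)
  expect_equal(as.integer(table(dom[dom > 0])), c(5L, 4L))
  expect_equal(dom[2, 6], 1L)  # midpoint tie -> lower id

  # a single cell claims the whole blob
  blob <- matrix(TRUE, 6, 6)
  lab1 <- matrix(0L, 6, 6); lab1[3, 3] <- 1L
  d1 <- partition_domains(boundary_geodesic_basins(blob, lab1), lab1, blob)
  expect_true(all(d1 == 1L))
})

test_that("voronoi fixtures: domains cover the vessel and hold their seeds", {
  for (s in 1:3) {
    fx <- make_tube_masks(40, seed = s)
    merged <- merge_color_masks(fx$masks, vessel = fx$vessel)
    basins <- boundary_geodesic_basins(fx$vessel, merged$labels)
    dom <- partition_domains(basins, merged$labels, fx$vessel)
    # exact cover of the vessel foreground
    expect_true(all(dom[fx$vessel] > 0))
    expect_true(all(dom[!fx$vessel] == 0))
    expect_equal(length(unique(dom[dom > 0])), nrow(merged$cells))
    # each domain contains its own seed and no other seed
    seed_px <- which(fx$seeds > 0)
    expect_equal(length(unique(dom[seed_px])), length(seed_px))
    # merged instance pixels stay inside their own domain
    expect_true(all(dom[merged$labels > 0] == merged$labels[merged$labels > 0]))
  }
})

test_that("region adjacency extraction matches the brute-force pixel scan", {
  sq <- matrix(0L, 6, 10)
  sq[2:5, 2:5] <- 1L; sq[2:5, 6:9] <- 2L
  vessel <- sq > 0
  cells <- data.frame(id = 1:2, color = c(1, 2), x = c(2.5, 6.5), y = c(2.5, 2.5),
                      area = c(16, 16))
  g <- build_rag(sq, cells, vessel)
  expect_equal(n_nodes(g), 2)
  expect_equal(nrow(g$edges), 1)

  row3 <- matrix(0L, 6, 15)
  row3[2:5, 2:5] <- 1L; row3[2:5, 6:9] <- 2L; row3[2:5, 10:13] <- 3L
  cells3 <- data.frame(id = 1:3, color = 1:3, x = c(2.5, 6.5, 10.5),
                       y = 2.5, area = 16)
  g3 <- build_rag(row3, cells3, row3 > 0)
  expect_equal(edge_key(g3$edges), edge_key(data.frame(source = c(1, 2),
                                                       target = c(2, 3))))

  # fixture domains vs the independent per-pixel oracle
  fx <- make_tube_masks(40, seed = 4)
  merged <- merge_color_masks(fx$masks, vessel = fx$vessel)
  basins <- boundary_geodesic_basins(fx$vessel, merged$labels)
  dom <- partition_domains(basins, merged$labels, fx$vessel)
  rag <- build_rag(dom, merged$cells, fx$vessel, geodesic_edges = FALSE)
  oracle <- pixel_contact_oracle(dom)
  expect_equal(edge_key(rag$edges),
               edge_key(data.frame(source = oracle$a, target = oracle$b)))
  expect_equal(rag$edges$contacts[order(rag$edges$source, rag$edges$target)],
               oracle$n)
})

test_that("rag is invariant under instance renumbering", {
  fx <- make_tube_masks(25, seed = 6)
  merged <- merge_color_masks(fx$masks, vessel = fx$vessel)
  basins <- boundary_geodesic_basins(fx$vessel, merged$labels)
  dom <- partition_domains(basins, merged$labels, fx$vessel)
  g1 <- build_rag(dom, merged$cells, fx$vessel, geodesic_edges = FALSE)

  set.seed(1)
  perm <- sample(nrow(merged$cells))  # new id of old id i is perm[i]
  dom2 <- dom; dom2[dom > 0] <- perm[dom[dom > 0]]
  cells2 <- merged$cells
  cells2$id <- perm[cells2$id]
  cells2 <- cells2[order(cells2$id), ]
  g2 <- build_rag(dom2, cells2, fx$vessel, geodesic_edges = FALSE)

  expect_equal(edge_key(g2$edges),
               edge_key(data.frame(source = perm[g1$edges$source],
                                   target = perm[g1$edges$target])))
  expect_equal(g2$nodes$color[match(perm[g1$nodes$id], g2$nodes$id)],
               g1$nodes$color)
})

test_that("geodesic edge distances dominate euclidean, agree when convex", {
  fx <- make_tube_masks(30, seed = 7)
  g <- masks_to_graph(fx$masks, fx$vessel)
  si <- match(g$edges$source, g$nodes$id)
  ti <- match(g$edges$target, g$nodes$id)
  eu <- sqrt((g$nodes$x[si] - g$nodes$x[ti])^2 +
             (g$nodes$y[si] - g$nodes$y[ti])^2)
  expect_true(all(g$edges$distance >= eu - 1))
  # the fixture vessel is a convex rectangle: agreement within 8%
  expect_true(all(g$edges$distance <= eu * 1.08 + 1))
})
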