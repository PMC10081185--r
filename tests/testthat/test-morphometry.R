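test_that("straight two-point segment has closed-form metrics", {
  g <- straight_segment(r = 10, len = 100)
  m <- segment_metrics(g)
  expect_equal(m$length, 100)
  expect_equal(m$radius, 10)
  expect_equal(m$tortuosity, 1)
  expect_equal(m$length_radius_ratio, 10)
  expect_equal(m$volume, pi * 100 * 100)
  expect_equal(c(m$mid_x, m$mid_y, m$mid_z), c(0, 0, 50))
  # literal (chord/path) flag and diameter-based LDR flag
  expect_equal(segment_metrics(g, literal_tortuosity = TRUE)$tortuosity, 1)
  expect_equal(segment_metrics(g, ldr_uses_diameter = TRUE)
               $length_radius_ratio, 5)
})

test_that("tortuosity of a densely sampled semicircle converges to pi/2", {
  R <- 100
  errs <- sapply(c(10, 60, 180), function(nstep) {
    th <- seq(0, pi, length.out = nstep + 1)
    pts <- data.frame(segment_id = 1, x = R * cos(th), y = R * sin(th),
                      z = 0, radius = 5)
    nodes <- data.frame(id = 1:2, x = c(R, -R), y = 0, z = 0)
    g <- spatial_graph(nodes,
                       data.frame(id = 1, start_node = 1, end_node = 2), pts)
    abs(segment_metrics(g)$tortuosity - pi / 2)
  })
  expect_lt(errs[3], 1e-4)
  expect_true(all(diff(errs) < 0)) # converges with sampling density
})

test_that("degenerate zero-chord segments are flagged", {
  # closed loop back to the start node position
  th <- seq(0, 2 * pi, length.out = 13)
  nodes <- data.frame(id = 1:2, x = c(100, 100), y = c(0, 0), z = c(0, 1e-9))
  pts <- data.frame(segment_id = 1, x = 100 * cos(th), y = 100 * sin(th),
                    z = seq(0, 1e-9, length.out = 13), radius = 5)
  g <- spatial_graph(nodes, data.frame(id = 1, start_node = 1, end_node = 2),
                     pts, tolerance = 1)
  m <- segment_metrics(g)
  expect_true(m$degenerate || m$tortuosity > 100) # chord ~ 0
})

test_that("branching angles follow planar geometry", {
  # symmetric Y: parent along +z, children 30 degrees off the parent axis
  a <- 30 * pi / 180
  nodes <- data.frame(id = 1:4,
                      x = c(0, 0, 100 * sin(a), -100 * sin(a)),
                      y = 0,
                      z = c(0, 100, 100 + 100 * cos(a), 100 + 100 * cos(a)))
  segs <- data.frame(id = 1:3, start_node = c(1, 2, 2), end_node = c(2, 3, 4))
  pts <- do.call(rbind, lapply(1:3, function(k) {
    i <- segs$start_node[k]; j <- segs$end_node[k]
    data.frame(segment_id = k, x = c(nodes$x[i], nodes$x[j]), y = 0,
               z = c(nodes$z[i], nodes$z[j]), radius = 5)
  }))
  g <- spatial_graph(nodes, segs, pts)
  ang <- branching_angles(g, root = 1)
  expect_equal(sort(ang$child_parent$angle), c(150, 150), tolerance = 1e-9)
  expect_equal(ang$child_child$angle, 60, tolerance = 1e-9)
})

test_that("straight continuation scores 180 and a side branch 90", {
  nodes <- data.frame(id = 1:4, x = c(0, 0, 0, 60), y = 0,
                      z = c(0, 50, 130, 50))
  segs <- data.frame(id = 1:3, start_node = c(1, 2, 2), end_node = c(2, 3, 4))
  pts <- do.call(rbind, lapply(1:3, function(k) {
    i <- segs$start_node[k]; j <- segs$end_node[k]
    data.frame(segment_id = k, x = c(nodes$x[i], nodes$x[j]), y = 0,
               z = c(nodes$z[i], nodes$z[j]), radius = 5)
  }))
  g <- spatial_graph(nodes, segs, pts)
  ang <- branching_angles(g, root = 1)
  cp <- ang$child_parent
  expect_equal(cp$angle[cp$child_segment == 2], 180)
  expect_equal(cp$angle[cp$child_segment == 3], 90)
})

test_that("midpoint inter-vessel distances match brute force", {
  # two parallel equal segments offset by d
  nodes <- data.frame(id = 1:4, x = c(0, 0, 25, 25), y = 0, z = c(0, 80, 0, 80))
  segs <- data.frame(id = 1:2, start_node = c(1, 3), end_node = c(2, 4))
  pts <- data.frame(segment_id = c(1, 1, 2, 2), x = c(0, 0, 25, 25), y = 0,
                    z = c(0, 80, 0, 80), radius = 3)
  g <- spatial_graph(nodes, segs, pts)
  ivd <- intervessel_midpoint_distance(g)
  expect_equal(ivd$distance, c(25, 25))

  g20 <- random_tree_graph(20, seed = 44)
  m <- segment_metrics(g20)
  got <- intervessel_midpoint_distance(g20, m)
  M <- as.matrix(m[, c("mid_x", "mid_y", "mid_z")])
  want <- sapply(1:20, function(i)
    min(sqrt(rowSums(sweep(M[-i, , drop = FALSE], 2, M[i, ])^2))))
  expect_equal(got$distance, want)

  one <- straight_segment()
  expect_error(intervessel_midpoint_distance(one), "at least 2")
})

test_that("voxel inter-vessel distance restricted by zones orders as built", {
  # a tube confined to one half of a two-zone slab
  arr <- array(FALSE, c(30, 10, 10)); arr[3:5, 4:6, 4:6] <- TRUE
  mask <- voxel_volume(arr, 10)
  labs <- array(1L, c(30, 10, 10)); labs[16:30, , ] <- 2L
  zl <- voxel_volume(labs, 10)
  out <- intervessel_voxel_distance(mask, zl)
  pz <- out$per_zone
  expect_gt(pz$mean[pz$label == 2], pz$mean[pz$label == 1])
  expect_true(all(out$field$data[arr] == 0))
  # grid mismatch
  expect_error(intervessel_voxel_distance(mask, voxel_volume(labs, 5)),
               "grid")
})

test_that("cumulative volume fraction accumulates to one", {
  metrics <- data.frame(segment_id = 1:9, volume = rep(3, 9))
  ordering <- data.frame(segment_id = 1:9, strahler = 1:9, generation = 1:9)
  cv <- cumulative_volume_by_order(metrics, ordering)
  expect_equal(cv$cumulative_fraction[4], 4 / 9)
  expect_equal(cv$cumulative_fraction[9], 1)
  # random tree: fractions match direct sums
  g <- generate_tree(tree_spec(depth = 5, branching_ratio = 2.6, seed = 12))
  m <- segment_metrics(g)
  o <- strahler_order(g, find_root(g))
  cv2 <- cumulative_volume_by_order(m, o)
  ords <- o$strahler[match(m$segment_id, o$segment_id)]
  direct <- cumsum(sapply(seq_len(max(ords)), function(k)
    sum(m$volume[ords == k]))) / sum(m$volume)
  expect_equal(cv2$cumulative_fraction, direct)
  expect_equal(tail(cv2$cumulative_fraction, 1), 1)
  expect_error(cumulative_volume_by_order(m, o[-1, ]), "unordered")
})

test_that("grouped summary has Table-1 shape and exact per-order stats", {
  g <- generate_tree(tree_spec(depth = 4, branching_ratio = 2,
                               tortuosity_amp = 0, seed = 13))
  m <- segment_metrics(g)
  o <- strahler_order(g, find_root(g))
  ang <- branching_angles(g, find_root(g))
  ivd <- intervessel_midpoint_distance(g, m)
  gs <- grouped_summary(m, o, ang, ivd)
  expect_equal(gs$n, c(8, 4, 2, 1))
  # constant radii per order (murray symmetric, no noise) -> SD 0
  expect_true(all(gs$radius_sd[gs$n > 1] < 1e-9))
  expect_true(is.na(gs$radius_sd[gs$n == 1]))
  # single-segment graph
  g1 <- straight_segment()
  gs1 <- grouped_summary(segment_metrics(g1), strahler_order(g1, 1))
  expect_equal(nrow(gs1), 1)
  expect_equal(gs1$n, 1)
})

test_that("per-order volumes sum to the total network volume", {
  g <- generate_tree(tree_spec(depth = 5, branching_ratio = 3, seed = 14))
  m <- segment_metrics(g)
  o <- strahler_order(g, find_root(g))
  cv <- cumulative_volume_by_order(m, o)
  expect_equal(sum(cv$volume), sum(m$volume))
})

test_that("midpoint IVD is translation-invariant", {
  g <- random_tree_graph(15, seed = 55)
  d1 <- intervessel_midpoint_distance(g)$distance
  g2 <- g
  g2$nodes[, c("x", "y", "z")] <- g2$nodes[, c("x", "y", "z")] + 500
  g2$points[, c("x", "y", "z")] <- g2$points[, c("x", "y", "z")] + 500
  d2 <- intervessel_midpoint_distance(g2)$distance
  expect_equal(d1, d2)
})
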