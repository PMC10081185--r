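make_zigzag <- function(order = 7) {
  # one segment, jagged in x, oriented along z, thick enough to qualify
  z <- seq(0, 300, length.out = 13)
  x <- rep(c(0, 8), length.out = 13); x[1] <- 0; x[13] <- 0
  nodes <- data.frame(id = 1:2, x = c(0, 0), y = 0, z = c(0, 300))
  g <- spatial_graph(nodes,
                     data.frame(id = 1, start_node = 1, end_node = 2),
                     data.frame(segment_id = 1, x = x, y = 0, z = z,
                                radius = 40))
  ordering <- data.frame(segment_id = 1L, strahler = order,
                         generation = 1L)
  list(g = g, ordering = ordering)
}

turning <- function(g) {
  m <- as.matrix(g$points[, c("x", "y", "z")])
  v <- diff(m)
  sum(sapply(seq_len(nrow(v) - 1), function(i) {
    acos(min(max(sum(v[i, ] * v[i + 1, ]) /
                   sqrt(sum(v[i, ]^2) * sum(v[i + 1, ]^2)), -1), 1))
  }))
}

test_that("smoothing is a no-op on straight polylines and anchors endpoints", {
  g <- straight_segment(r = 40, len = 300)
  g$points <- data.frame(segment_id = 1L, x = 0, y = 0,
                         z = seq(0, 300, length.out = 9), radius = 40)
  ordering <- data.frame(segment_id = 1L, strahler = 7L, generation = 1L)
  sm <- multiscale_smooth(g, ordering)
  expect_equal(sm$points, g$points, tolerance = 1e-12)

  zz <- make_zigzag()
  sm2 <- multiscale_smooth(zz$g, zz$ordering)
  n <- nrow(zz$g$points)
  expect_identical(as.numeric(sm2$points[1, c("x", "y", "z")]),
                   as.numeric(zz$g$points[1, c("x", "y", "z")]))
  expect_identical(as.numeric(sm2$points[n, c("x", "y", "z")]),
                   as.numeric(zz$g$points[n, c("x", "y", "z")]))
  expect_identical(sm2$points$radius, zz$g$points$radius)
})

test_that("smoothing strictly reduces the turning angle of a zig-zag", {
  zz <- make_zigzag()
  for (kern in c("gaussian", "uniform")) {
    sm <- multiscale_smooth(zz$g, zz$ordering, kernel = kern)
    expect_lt(turning(sm), turning(zz$g))
  }
})

test_that("segments below the order threshold are untouched", {
  zz <- make_zigzag(order = 3)
  sm <- multiscale_smooth(zz$g, zz$ordering, min_order = 6)
  expect_identical(sm$points, zz$g$points)
  expect_error(multiscale_smooth(zz$g, zz$ordering, min_order = 0),
               "config")
})

test_that("per-order percentile rule flags exactly the depressed segment", {
  metrics <- data.frame(segment_id = 1:11,
                        radius = c(rep(1.0, 10), 0.2))
  ordering <- data.frame(segment_id = 1:11, strahler = 1L, generation = 1L)
  det <- detect_collapsed(metrics, ordering, percentile = 10,
                          min_segments_per_order = 5)
  expect_equal(det$candidates, 11L)
  # all radii equal: nothing flagged
  metrics$radius <- 1
  expect_length(detect_collapsed(metrics, ordering,
                                 min_segments_per_order = 5)$candidates, 0)
  expect_error(detect_collapsed(metrics, ordering, percentile = 0),
               "percentile")
})

test_that("injected factor-0.2 collapses are recovered at >= 90%", {
  g <- generate_tree(tree_spec(depth = 9, branching_ratio = 2, seed = 4))
  gp <- perturb_graph(g, radius_noise_sd = 0.08, collapse_fraction = 0.05,
                      collapse_factor = 0.2, seed = 9)
  gt <- attr(gp, "ground_truth")
  ord <- strahler_order(gp, find_root(gp))
  det <- detect_collapsed(segment_metrics(gp), ord)
  recovery <- mean(gt$collapsed_ids %in% det$candidates)
  expect_gte(recovery, 0.9)
})

test_that("the percentile rule flags ~p% of iid continuous radii", {
  set.seed(123)
  n <- 10000
  metrics <- data.frame(segment_id = seq_len(n),
                        radius = rlnorm(n, meanlog = 3, sdlog = 0.4))
  ordering <- data.frame(segment_id = seq_len(n), strahler = 1L,
                         generation = 1L)
  det <- detect_collapsed(metrics, ordering, percentile = 10)
  frac <- 100 * length(det$candidates) / n
  expect_lt(abs(frac - 10), 1)
})

test_that("perimeter correction restores open-tube radii within 5%", {
  n <- 7
  nodes <- data.frame(id = 1:2, x = 0, y = 0, z = c(0, 200))
  tube <- spatial_graph(nodes,
    data.frame(id = 1, start_node = 1, end_node = 2),
    data.frame(segment_id = 1, x = 0, y = 0,
               z = seq(0, 200, length.out = n), radius = 25))
  mask <- voxelize(tube, 2.5)
  collapsed <- tube
  collapsed$points$radius <- 5 # stored radius is wrong; mask holds truth
  out <- correct_radius_from_perimeter(collapsed, mask, 1, half_width = 60)
  rep <- attr(out, "correction_report")
  expect_true(all(rep$corrected))
  expect_lt(abs(mean(rep$new_radius) - 25) / 25, 0.05)
  expect_equal(out$points$radius, rep$new_radius)
})

test_that("elliptical lumens recover the Ramanujan equivalent radius within 5%", {
  a <- 50; b <- 5
  d <- c(130, 40, 60)
  arr <- array(FALSE, d)
  for (i in 1:d[1]) for (j in 1:d[2])
    arr[i, j, ] <- ((i - 65.3) / a)^2 + ((j - 20.2) / b)^2 <= 1
  mask <- voxel_volume(arr, 1)
  g <- spatial_graph(
    data.frame(id = 1:2, x = 64.3, y = 19.2, z = c(5, 55)),
    data.frame(id = 1, start_node = 1, end_node = 2),
    data.frame(segment_id = 1, x = 64.3, y = 19.2,
               z = seq(5, 55, length.out = 5), radius = 5))
  out <- correct_radius_from_perimeter(g, mask, 1, half_width = 60)
  rep <- attr(out, "correction_report")
  target <- ramanujan_perimeter(a, b) / (2 * pi)
  expect_lt(abs(mean(rep$new_radius) - target) / target, 0.05)
  # equivalent radius exceeds the inscribed-circle radius (isoperimetry)
  expect_gt(mean(rep$new_radius), b)
})

test_that("segments outside the mask raise an error", {
  g <- straight_segment(r = 5, len = 50)
  mask <- voxelize(g, 1)
  far <- g
  far$nodes$x <- far$nodes$x + 1e4
  far$points$x <- far$points$x + 1e4
  expect_error(correct_radius_from_perimeter(far, mask, 1, half_width = 20),
               "foreground|outside")
  expect_error(correct_radius_from_perimeter(g, mask, 99), "unknown segment")
})

test_that("correction operations preserve graph topology", {
  g <- generate_tree(tree_spec(depth = 3, branching_ratio = 2,
                               root_radius = 12,
                               length_radius_ratio = 10, seed = 3))
  ord <- strahler_order(g, find_root(g))
  sm <- multiscale_smooth(g, ord, min_order = 2)
  expect_identical(sm$segments, g$segments)
  expect_identical(sm$nodes, g$nodes)
  expect_equal(validate_graph(sm)$n_cycles, 0)
})
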