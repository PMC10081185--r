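test_that("a symmetric full bifurcation of depth 4 has 15 segments", {
  g <- generate_tree(tree_spec(depth = 4, branching_ratio = 2,
                               tortuosity_amp = 0, seed = 1))
  expect_equal(nrow(g$segments), 15)
  expect_equal(nrow(g$nodes), 16)
  deg <- table(c(g$segments$start_node, g$segments$end_node))
  expect_equal(sum(deg == 1), 9) # 8 leaves + root stub
  expect_equal(sum(deg == 3), 7) # internal junctions
})

test_that("murray law with symmetric children gives the closed-form radius", {
  g <- generate_tree(tree_spec(depth = 3, branching_ratio = 2, asymmetry = 1,
                               tortuosity_amp = 0, root_radius = 100,
                               seed = 2))
  m <- segment_metrics(g)
  expect_equal(sort(unique(round(m$radius, 9))),
               sort(round(100 * 2^(-(0:2) / 3), 9)))
  # exact cube conservation with asymmetry
  ga <- generate_tree(tree_spec(depth = 2, branching_ratio = 2,
                                asymmetry = 0.5, tortuosity_amp = 0,
                                root_radius = 100, seed = 3))
  ma <- segment_metrics(ga)
  kids <- sort(ma$radius[2:3])
  expect_equal(kids[1] / kids[2], 0.5, tolerance = 1e-12)
  expect_equal(sum(kids^3), 100^3, tolerance = 1e-6)
})

test_that("generation is deterministic in the seed", {
  s <- tree_spec(depth = 5, seed = 77)
  g1 <- generate_tree(s); g2 <- generate_tree(s)
  expect_identical(g1$points, g2$points)
  g3 <- generate_tree(tree_spec(depth = 5, seed = 78))
  expect_false(identical(g1$points, g3$points))
})

test_that("generator output always passes validation", {
  for (seed in 1:5) {
    g <- generate_tree(tree_spec(depth = sample(3:6, 1),
                                 branching_ratio = runif(1, 2, 3.5),
                                 asymmetry = runif(1, 0.5, 1), seed = seed))
    v <- validate_graph(g)
    expect_equal(nrow(v$defects), 0)
    expect_equal(v$n_components, 1)
    expect_equal(v$n_cycles, 0)
  }
})

test_that("impossible specs are rejected", {
  expect_error(tree_spec(depth = 0), "depth")
  expect_error(tree_spec(branch_prob = 0, depth = 3), "branch probability")
  expect_error(tree_spec(root_radius = -1), "root_radius")
  expect_error(tree_spec(asymmetry = 0), "asymmetry")
})

test_that("perturb_graph collapse scales radii and records ground truth", {
  g <- generate_tree(tree_spec(depth = 4, branching_ratio = 2,
                               tortuosity_amp = 0, seed = 5))
  m0 <- segment_metrics(g)
  gp <- perturb_graph(g, collapse_fraction = 1 / nrow(g$segments),
                      collapse_factor = 0.2, seed = 3)
  gt <- attr(gp, "ground_truth")
  expect_length(gt$collapsed_ids, 1)
  m1 <- segment_metrics(gp)
  k <- match(gt$collapsed_ids, m1$segment_id)
  expect_equal(m1$radius[k], 0.2 * m0$radius[k], tolerance = 1e-12)
  expect_equal(m1$radius[-k], m0$radius[-k])
})

test_that("deleting zero branches is the identity", {
  g <- generate_tree(tree_spec(depth = 4, seed = 6))
  gp <- perturb_graph(g, delete_fraction = 0, seed = 1)
  expect_identical(gp$points, g$points)
  expect_identical(gp$segments, g$segments)
})

test_that("branch deletion never disconnects the root component", {
  g <- generate_tree(tree_spec(depth = 5, branching_ratio = 3, seed = 7))
  gp <- perturb_graph(g, delete_fraction = 0.5, seed = 2)
  expect_gt(length(attr(gp, "ground_truth")$deleted_ids), 0)
  v <- validate_graph(gp)
  expect_equal(v$n_components, 1)
})

test_that("jitter increases tortuosity by the amount a brute-force path/chord gives", {
  g <- straight_segment(r = 5, len = 100)
  # need interior points to jitter
  g$points <- data.frame(segment_id = 1L, x = 0, y = 0,
                         z = seq(0, 100, length.out = 9), radius = 5)
  gp <- perturb_graph(g, jitter_sd = 1, seed = 4)
  m <- segment_metrics(gp)
  pm <- as.matrix(gp$points[, c("x", "y", "z")])
  path <- sum(sqrt(rowSums(diff(pm)^2)))
  chord <- sqrt(sum((pm[9, ] - pm[1, ])^2))
  expect_gt(m$tortuosity, 1)
  expect_equal(m$tortuosity, path / chord, tolerance = 1e-12)
})

test_that("voxelizing a straight tube gives the analytic cross-section area", {
  g <- straight_segment(r = 5, len = 100)
  mask <- voxelize(g, voxel_size = 1)
  kz <- round(dim(mask$data)[3] / 2)
  expect_equal(sum(mask$data[, , kz]), pi * 25, tolerance = 0.1)
  # empty graph -> all background
  empty <- spatial_graph(data.frame(id = integer(0), x = numeric(0),
                                    y = numeric(0), z = numeric(0)),
                         data.frame(id = integer(0), start_node = integer(0),
                                    end_node = integer(0)),
                         data.frame(segment_id = integer(0), x = numeric(0),
                                    y = numeric(0), z = numeric(0),
                                    radius = numeric(0)))
  expect_false(any(voxelize(empty, 1)$data))
})

test_that("disjoint tubes voxelize to as many mask components as graph components", {
  nodes <- data.frame(id = 1:4, x = c(0, 0, 40, 40), y = 0,
                      z = c(0, 60, 0, 60))
  segs <- data.frame(id = 1:2, start_node = c(1, 3), end_node = c(2, 4))
  pts <- data.frame(segment_id = c(1, 1, 2, 2), x = c(0, 0, 40, 40), y = 0,
                    z = c(0, 60, 0, 60), radius = 4)
  g <- spatial_graph(nodes, segs, pts)
  mask <- voxelize(g, 1)
  lab <- vasctree:::label_components(mask)
  expect_equal(max(lab$data), 2)
  expect_equal(validate_graph(g)$n_components, 2)
})

test_that("voxelize rejects a grid that cannot hold the padded graph", {
  g <- straight_segment(r = 5, len = 100)
  expect_error(voxelize(g, 1, shape = c(10L, 10L, 10L),
                        origin = c(0, 0, 0)), "exceeds")
})

test_that("zone phantom labels and volumes are analytic", {
  sp <- phantom_spec(pillar_count = 0)
  ph <- generate_zone_phantom(sp)
  expect_false(4 %in% ph$data) # no pillars requested
  vs <- sp$voxel_size
  shell <- function(r1, r0) 4 / 3 * pi * (r1^3 - r0^3) / vs^3
  expect_equal(sum(ph$data == 1),
               shell(sp$cortex_radius, sp$medulla_radius), tolerance = 0.05)
  expect_equal(sum(ph$data == 2),
               shell(sp$medulla_radius, sp$hilum_radius), tolerance = 0.05)
  expect_equal(sum(ph$data == 3), shell(sp$hilum_radius, 0),
               tolerance = 0.05)
  # pillars carve volume out of the medulla only
  ph4 <- generate_zone_phantom(phantom_spec(pillar_count = 4))
  expect_true(4 %in% ph4$data)
  expect_equal(sum(ph4$data %in% c(2, 4)), sum(ph$data == 2))
  expect_error(phantom_spec(hilum_radius = 800, medulla_radius = 700),
               "nested")
})

test_that("murray-law trees regress onto the identity line exactly", {
  for (a in c(1, 0.7, 0.4)) {
    g <- generate_tree(tree_spec(depth = 5, branching_ratio = 2,
                                 asymmetry = a, root_radius = 800,
                                 seed = 10 + round(10 * a)))
    m <- segment_metrics(g)
    ord <- strahler_order(g, find_root(g))
    recs <- extract_bifurcations(g, m, ord)
    fit <- murray_regression(recs, unit_scale = 1, Q = NA)
    expect_equal(fit$slope, 1, tolerance = 1e-10)
    expect_equal(fit$intercept, 0, tolerance = 1e-8)
    expect_equal(fit$r2, 1, tolerance = 1e-10)
  }
})

test_that("log-linear radius law is recovered within 5% over 7+ orders", {
  for (s in c(0.2, 0.35, 0.5)) {
    g <- generate_tree(tree_spec(depth = 7, branching_ratio = 2,
                                 radius_law = "log_linear", log_slope = s,
                                 root_radius = 3000,
                                 length_radius_ratio = 4,
                                 seed = round(100 * s)))
    ord <- strahler_order(g, find_root(g))
    m <- segment_metrics(g)
    pr <- tapply(m$radius, ord$strahler, mean)
    fit <- lm(log(pr) ~ as.numeric(names(pr)))
    expect_lt(abs(coef(fit)[2] - s) / s, 0.05)
  }
})
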