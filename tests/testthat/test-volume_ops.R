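test_that("median filter: constant volumes are fixed points, impulses vanish", {
  v <- voxel_volume(array(3.5, c(6, 6, 6)), 1)
  expect_equal(median_filter_3d(v)$data, v$data)
  imp <- array(0, c(7, 7, 7)); imp[4, 4, 4] <- 100
  out <- median_filter_3d(voxel_volume(imp, 1), iterations = 1)
  expect_equal(max(out$data), 0)
})

test_that("one median pass equals the exhaustive neighbourhood median", {
  set.seed(11)
  v <- voxel_volume(array(runif(125), c(5, 5, 5)), 1)
  for (conn in c(6, 26)) {
    got <- median_filter_3d(v, iterations = 1, neighbourhood = conn)
    exp_arr <- array(0, c(5, 5, 5))
    offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
    if (conn == 6)
      offs <- offs[abs(offs$dx) + abs(offs$dy) + abs(offs$dz) <= 1, ]
    for (i in 1:5) for (j in 1:5) for (k in 1:5) {
      nb <- apply(offs, 1, function(o)
        v$data[min(max(i + o[1], 1), 5), min(max(j + o[2], 1), 5),
               min(max(k + o[3], 1), 5)])
      exp_arr[i, j, k] <- median(nb)
    }
    expect_equal(got$data, exp_arr)
  }
  expect_error(median_filter_3d(v, neighbourhood = 18), "6 or 26")
})

test_that("region growing fills exactly the connected in-range voxels", {
  arr <- array(0, c(20, 10, 10))
  arr[3:8, 4:6, 4:6] <- 1     # tube A
  arr[13:18, 4:6, 4:6] <- 1   # tube B (disjoint)
  v <- voxel_volume(arr, 1)
  mA <- region_grow(v, c(5, 5, 5), c(0.5, 1.5))
  expect_equal(sum(mA$data), 6 * 3 * 3)
  expect_true(all(which(mA$data, arr.ind = TRUE)[, 1] <= 8))
  expect_error(region_grow(v, c(5, 5, 5), c(2, 1)), "lo > hi")
  expect_error(region_grow(v, c(1, 1, 1), c(0.5, 1.5)), "background")
  # idempotence: growing again from any output voxel returns the same set
  seed2 <- which(mA$data, arr.ind = TRUE)[10, ]
  mA2 <- region_grow(v, seed2, c(0.5, 1.5))
  expect_equal(mA2$data, mA$data)
})

test_that("distance transform: plane, all-foreground, and brute force", {
  arr <- array(FALSE, c(4, 4, 6)); arr[, , 1] <- TRUE
  d <- distance_transform(voxel_volume(arr, 50))
  expect_equal(d$data[2, 3, 4], 150) # 3 voxels from the plane at 50 um
  allfg <- voxel_volume(array(TRUE, c(3, 3, 3)), 5)
  expect_true(all(distance_transform(allfg)$data == 0))
  expect_error(distance_transform(voxel_volume(array(FALSE, c(3, 3, 3)), 1)),
               "empty mask")
  set.seed(21)
  m <- voxel_volume(array(runif(8^3) < 0.08, c(8, 8, 8)), 2)
  if (!any(m$data)) m$data[1] <- TRUE
  expect_equal(distance_transform(m)$data, edt_oracle(m))
})

test_that("distance transform matches brute force on random masks up to 16^3", {
  set.seed(31)
  for (rep in 1:8) {
    dims <- sample(2:16, 3, replace = TRUE)
    arr <- array(runif(prod(dims)) < runif(1, 0.02, 0.4), dims)
    if (!any(arr)) arr[sample(length(arr), 1)] <- TRUE
    m <- voxel_volume(arr, 1)
    expect_equal(distance_transform(m)$data, edt_oracle(m))
  }
})

test_that("cross-sections normal to a tube show the analytic disc", {
  g <- straight_segment(r = 10, len = 80)
  mask <- voxelize(g, 1)
  sec <- extract_cross_section(mask, point = c(0, 0, 40),
                               tangent = c(0, 0, 1),
                               half_width = 25, spacing = 1)
  area <- sum(sec$image > 0.5) * sec$spacing^2
  expect_equal(area, pi * 100, tolerance = 0.1)
  # plane parallel to the tube axis through the middle: a band of width 2r,
  # area far above the disc area over the same window
  sec2 <- extract_cross_section(mask, point = c(0, 0, 40),
                                tangent = c(1, 0, 0),
                                half_width = 25, spacing = 1)
  band_rows <- colSums(sec2$image > 0.5)
  expect_equal(max(rowSums(sec2$image > 0.5)), 2 * 10 + 1, tolerance = 0.1)
  expect_gt(sum(sec2$image > 0.5), sum(sec$image > 0.5))
  expect_error(extract_cross_section(mask, c(0, 0, 40), c(0, 0, 0), 25, 1),
               "zero tangent")
  expect_error(extract_cross_section(mask, c(1e6, 1e6, 1e6), c(0, 0, 1),
                                     10, 1), "outside")
})

test_that("cross-section axes are deterministic and orthonormal", {
  g <- straight_segment(r = 5, len = 50)
  mask <- voxelize(g, 1)
  s1 <- extract_cross_section(mask, c(0, 0, 25), c(0.2, 0.3, 0.93), 10, 1)
  s2 <- extract_cross_section(mask, c(0, 0, 25), c(0.2, 0.3, 0.93), 10, 1)
  expect_identical(s1$image, s2$image)
  expect_equal(sum(s1$axes[1, ] * s1$axes[2, ]), 0, tolerance = 1e-12)
  expect_equal(rowSums(s1$axes^2), c(u = 1, v = 1), tolerance = 1e-12)
})

test_that("perimeter of digitized discs and squares is within 2%", {
  mk_section <- function(img, spacing = 1)
    structure(list(image = img, origin = c(0, 0, 0),
                   axes = rbind(c(1, 0, 0), c(0, 1, 0)), spacing = spacing,
                   offset = 0), class = "cross_section")
  n <- 51
  disc <- outer(1:n, 1:n, function(i, j)
    ((i - 26.3)^2 + (j - 26.1)^2 <= 400) + 0)
  p <- perimeter_of_component(mk_section(disc))
  expect_equal(p, 2 * pi * 20, tolerance = 0.02)
  sq <- matrix(0, 40, 40); sq[10:29, 10:29] <- 1
  expect_equal(perimeter_of_component(mk_section(sq), hint = c(20, 20)),
               80, tolerance = 0.02)
  # spacing scales the answer linearly
  expect_equal(perimeter_of_component(mk_section(disc, spacing = 2.5)),
               2.5 * p)
})

test_that("perimeter conventions: single pixel and hint handling", {
  mk_section <- function(img)
    structure(list(image = img, origin = c(0, 0, 0),
                   axes = rbind(c(1, 0, 0), c(0, 1, 0)), spacing = 1,
                   offset = 0), class = "cross_section")
  px <- matrix(0, 7, 7); px[4, 4] <- 1
  # documented convention: Steiner offset of the degenerate hull
  expect_equal(perimeter_of_component(mk_section(px)), 2 * pi * 0.4)
  bg <- matrix(0, 7, 7); bg[2, 2] <- 1
  expect_error(perimeter_of_component(mk_section(bg)), "background")
  expect_equal(perimeter_of_component(mk_section(bg), hint_tolerance = 4),
               2 * pi * 0.4)
})

test_that("disc perimeter is stable under sub-pixel translation (< 3%)", {
  mk_section <- function(img)
    structure(list(image = img, origin = c(0, 0, 0),
                   axes = rbind(c(1, 0, 0), c(0, 1, 0)), spacing = 1,
                   offset = 0), class = "cross_section")
  n <- 51
  per <- sapply(seq(0, 0.9, by = 0.1), function(dx) {
    disc <- outer(1:n, 1:n, function(i, j)
      ((i - 26 - dx)^2 + (j - 26.1)^2 <= 400) + 0)
    perimeter_of_component(mk_section(disc))
  })
  expect_lt((max(per) - min(per)) / mean(per), 0.03)
})

test_that("volume files round-trip through TIFF and NRRD", {
  set.seed(5)
  v <- voxel_volume(array(round(runif(60), 4), c(5, 4, 3)), 13,
                    origin = c(1, 2, 3))
  tf <- tempfile(fileext = ".tif")
  write_volume(v, tf)
  v2 <- read_volume(tf, voxel_size = 13, origin = c(1, 2, 3))
  expect_equal(v2$data, v$data, tolerance = 1e-6)
  nf <- tempfile(fileext = ".nrrd")
  write_volume(v, nf)
  v3 <- read_volume(nf)
  expect_equal(v3$data, v$data)
  expect_equal(v3$voxel_size, 13)
  expect_equal(v3$origin, c(1, 2, 3))
})
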