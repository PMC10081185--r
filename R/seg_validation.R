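#' Skeletonize a binary mask by topological thinning
#'
#' Sequentially removes simple points (voxels whose deletion preserves
#' local topology), deepest-last by distance-transform ordering with
#' lexicographic tie-breaking, while preserving curve endpoints. This is
#' validation plumbing: it yields a one-voxel-wide centreline adequate for
#' overlap metrics, not a production skeletonization.
#'
#' @param mask binary [voxel_volume].
#' @param prune remove spur branches (surface-bump artifacts of thinning)
#'   shorter than `prune_factor` times the local mask depth at their
#'   junction (default `TRUE`).
#' @param prune_factor spur length threshold as a multiple of the local
#'   vessel depth (distance-to-background, voxels).
#' @return A binary [voxel_volume] holding the skeleton voxels.
#' @export
skeletonize_mask <- function(mask, prune = TRUE, prune_factor = 2) {
  fg <- as.logical(mask$data)
  out <- array(cpp_thin3d(fg, dim(mask$data)), dim(mask$data))
  if (prune) {
    depth <- array(cpp_edt3d(!fg, dim(mask$data)), dim(mask$data))
    out <- prune_spurs(out, depth, prune_factor)
  }
  voxel_volume(out, mask$voxel_size, mask$origin)
}

# number of 26-connected components of skeleton voxels in the
# neighbourhood of each skeleton voxel (centre removed); 0/1 endpoint,
# 2 path, >= 3 junction. The component rule is robust to the extra
# diagonal adjacencies of staircase paths.
neigh_comp_counts <- function(sk, coords) {
  d <- dim(sk)
  vapply(seq_len(nrow(coords)), function(r) {
    p <- coords[r, ]
    xs <- max(1, p[1] - 1):min(d[1], p[1] + 1)
    ys <- max(1, p[2] - 1):min(d[2], p[2] + 1)
    zs <- max(1, p[3] - 1):min(d[3], p[3] + 1)
    blk <- array(sk[xs, ys, zs], c(length(xs), length(ys), length(zs)))
    blk[p[1] - xs[1] + 1, p[2] - ys[1] + 1, p[3] - zs[1] + 1] <- FALSE
    max(cpp_label3d(blk, dim(blk), 26L))
  }, 0L)
}

# number of foreground 26-neighbours of every voxel
raw_neighbour_counts <- function(sk) {
  d <- dim(sk)
  cnt <- array(0L, d)
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    xs <- max(1, 1 + dx):min(d[1], d[1] + dx)
    ys <- max(1, 1 + dy):min(d[2], d[2] + dy)
    zs <- max(1, 1 + dz):min(d[3], d[3] + dz)
    cnt[xs - dx, ys - dy, zs - dz] <-
      cnt[xs - dx, ys - dy, zs - dz] + sk[xs, ys, zs]
  }
  cnt
}

# Remove spur branches by iterative parallel endpoint erosion. Spurs are
# thinning artifacts seeded by surface bumps; their length is bounded by
# the local vessel radius, so eroding endpoints for
# prune_factor * max(depth) rounds removes them entirely while real
# branches (whose length is a multiple of their radius) only shorten.
# Removing endpoints can never fragment or change the topology of the
# skeleton; isolated voxels are kept.
prune_spurs <- function(sk, depth, prune_factor) {
  if (!any(sk)) return(sk)
  rounds <- ceiling(prune_factor * max(depth[sk]))
  array(cpp_prune_endpoints(sk, dim(sk), rounds), dim(sk))
}

#' Topological precision and recall between two binary masks
#'
#' Both masks are thinned to skeletons. Precision is the fraction of
#' predicted-skeleton voxels lying within `tolerance` voxels of the
#' reference mask; recall is the fraction of reference-skeleton voxels
#' within `tolerance` of the predicted mask. This centreline-overlap
#' formulation rewards topological agreement rather than volumetric
#' overlap. An empty prediction yields precision 0 with
#' `empty_prediction = TRUE` (a convention, so batch sweeps do not abort).
#'
#' @param pred_mask,ref_mask binary [voxel_volume]s on the same grid.
#' @param tolerance matching tolerance in voxels (default 1).
#' @return list `precision`, `recall`, `tolerance`, `empty_prediction`.
#' @export
topo_precision_recall <- function(pred_mask, ref_mask, tolerance = 1) {
  if (!same_grid(pred_mask, ref_mask)) stop("grids do not match")
  if (!any(as.logical(ref_mask$data))) stop("empty reference mask")
  empty_pred <- !any(as.logical(pred_mask$data))
  d_ref <- cpp_edt3d(as.logical(ref_mask$data), dim(ref_mask$data))
  if (empty_pred) {
    return(list(precision = 0, recall = 0, tolerance = tolerance,
                empty_prediction = TRUE))
  }
  d_pred <- cpp_edt3d(as.logical(pred_mask$data), dim(pred_mask$data))
  sk_pred <- as.logical(skeletonize_mask(pred_mask)$data)
  sk_ref <- as.logical(skeletonize_mask(ref_mask)$data)
  precision <- mean(d_ref[sk_pred] <= tolerance)
  recall <- mean(d_pred[sk_ref] <= tolerance)
  list(precision = precision, recall = recall, tolerance = tolerance,
       empty_prediction = FALSE)
}

# branch-point voxel centroids of a skeleton volume. A voxel is a junction
# when, with the voxel removed, the skeleton voxels in a surrounding box
# (radius `radius`) fall into >= 3 connected components that reach the box
# boundary (i.e. >= 3 emanating strands). The component rule is robust to
# the extra diagonal adjacencies of staircase paths, and the radius-3
# default separates strands that merge in the immediate neighbourhood of
# shallow-angle bifurcations. Adjacent junction voxels are clustered into
# a single centroid.
branch_point_centroids <- function(skel, radius = 3) {
  d <- dim(skel$data)
  sk <- skel$data
  idx <- which(sk)
  if (!length(idx)) return(matrix(numeric(0), ncol = 3))
  coords <- arrayInd(idx, d)
  nbranch <- vapply(seq_len(nrow(coords)), function(r) {
    p <- coords[r, ]
    xs <- max(1, p[1] - radius):min(d[1], p[1] + radius)
    ys <- max(1, p[2] - radius):min(d[2], p[2] + radius)
    zs <- max(1, p[3] - radius):min(d[3], p[3] + radius)
    blk <- array(sk[xs, ys, zs], c(length(xs), length(ys), length(zs)))
    blk[p[1] - xs[1] + 1, p[2] - ys[1] + 1, p[3] - zs[1] + 1] <- FALSE
    lab <- array(cpp_label3d(blk, dim(blk), 26L), dim(blk))
    bnd <- unique(c(lab[1, , ], lab[dim(lab)[1], , ], lab[, 1, ],
                    lab[, dim(lab)[2], ], lab[, , 1], lab[, , dim(lab)[3]]))
    length(setdiff(bnd, 0L))
  }, 0L)
  bp <- coords[nbranch >= 3, , drop = FALSE]
  if (!nrow(bp)) return(matrix(numeric(0), ncol = 3))
  bmask <- array(FALSE, d)
  bmask[bp] <- TRUE
  lab <- array(cpp_label3d(bmask, d, 26L), d)
  labs <- lab[bp]
  cent <- vapply(sort(unique(labs)), function(l)
    colMeans(bp[labs == l, , drop = FALSE]), numeric(3))
  cent <- t(matrix(cent, nrow = 3))
  sweep((cent - 1) * skel$voxel_size, 2, skel$origin, "+")
}

# greedy nearest-pair matching within a tolerance; deterministic by
# (distance, index) ordering
greedy_match <- function(A, B, tol) {
  if (!nrow(A) || !nrow(B)) return(0L)
  pairs <- list()
  for (i in seq_len(nrow(A)))
    for (j in seq_len(nrow(B))) {
      d <- sqrt(sum((A[i, ] - B[j, ])^2))
      if (d <= tol) pairs[[length(pairs) + 1L]] <- c(d, i, j)
    }
  if (!length(pairs)) return(0L)
  P <- do.call(rbind, pairs)
  P <- P[order(P[, 1], P[, 2], P[, 3]), , drop = FALSE]
  usedA <- logical(nrow(A)); usedB <- logical(nrow(B))
  m <- 0L
  for (r in seq_len(nrow(P))) {
    i <- P[r, 2]; j <- P[r, 3]
    if (!usedA[i] && !usedB[j]) { usedA[i] <- TRUE; usedB[j] <- TRUE
      m <- m + 1L }
  }
  m
}

#' Weighted five-term skeleton super-metric
#'
#' Projects the discrepancy between a reconstructed skeleton (spatial
#' graph) and a reference segmentation mask onto a weighted space of five
#' terms: relative network-volume deviation, connected-component count
#' deviation, Euler-number deviation, centreline sensitivity (fraction of
#' skeleton points inside the mask) and bifurcation DICE (greedy matching
#' of branch points within a tolerance radius). The score is the weighted
#' sum with sensitivity and DICE entering as `1 - value`; 0 means perfect
#' agreement under the given weights.
#'
#' @param skel a [spatial_graph].
#' @param ref_mask binary [voxel_volume] in the same world frame.
#' @param weights numeric length-5 non-negative weights, in term order
#'   volume, components, Euler, sensitivity, DICE (default all 1).
#' @param tolerance branch-point matching tolerance in voxels (default 2).
#' @return A `supermetric_result` list with the five terms, the weights
#'   and the score.
#' @export
skeleton_supermetric <- function(skel, ref_mask, weights = rep(1, 5),
                                 tolerance = 2) {
  if (length(weights) != 5 || any(weights < 0))
    stop("weights must be 5 non-negative values")
  vref <- sum(as.logical(ref_mask$data))
  if (vref == 0) stop("reference mask has zero volume")
  d <- dim(ref_mask$data)
  # volume: voxelize the skeleton with its radii on the reference grid
  skel_mask <- voxelize(skel, ref_mask$voxel_size, shape = d,
                        origin = ref_mask$origin)
  vol_dev <- abs(sum(skel_mask$data) - vref) / vref
  # components
  cc_ref <- max(cpp_label3d(as.logical(ref_mask$data), d, 26L))
  ig <- as_igraph_nodes(skel)
  cc_skel <- igraph::count_components(ig)
  cc_dev <- abs(cc_skel - cc_ref)
  # Euler characteristic: components - independent cycles
  chi_skel <- cc_skel - (nrow(skel$segments) - nrow(skel$nodes) + cc_skel)
  thin <- skeletonize_mask(ref_mask)
  chi_mask <- euler_of_skeleton_volume(thin)
  euler_dev <- abs(chi_skel - chi_mask)
  # centreline sensitivity: skeleton points inside the mask
  idx <- round(world_to_index(ref_mask,
                              as.matrix(skel$points[, c("x", "y", "z")]))) + 1
  inside <- idx[, 1] >= 1 & idx[, 1] <= d[1] & idx[, 2] >= 1 &
    idx[, 2] <= d[2] & idx[, 3] >= 1 & idx[, 3] <= d[3]
  inmask <- logical(nrow(idx))
  if (any(inside))
    inmask[inside] <- as.logical(ref_mask$data[idx[inside, , drop = FALSE]])
  cl_sens <- mean(inmask)
  # bifurcation DICE
  deg <- node_degrees(skel)
  bnodes <- skel$nodes[deg[as.character(skel$nodes$id)] >= 3, c("x", "y", "z")]
  A <- as.matrix(bnodes)
  B <- branch_point_centroids(thin)
  tol_um <- tolerance * ref_mask$voxel_size
  m <- greedy_match(A, B, tol_um)
  bb_dice <- if (nrow(A) + nrow(B) == 0) 1 else 2 * m / (nrow(A) + nrow(B))
  devs <- c(vol_deviation = vol_dev, cc_deviation = cc_dev,
            euler_deviation = euler_dev, cl_sensitivity = cl_sens,
            bifurcation_dice = bb_dice)
  score <- sum(weights * c(vol_dev, cc_dev, euler_dev, 1 - cl_sens,
                           1 - bb_dice))
  structure(c(as.list(devs), list(weights = weights, score = score)),
            class = "supermetric_result")
}

# Euler characteristic of a voxel set via its cubical complex: each voxel
# contributes a unit cube; chi = V - E + F - C over the distinct vertices,
# edges, faces and cubes of the union. For a topology-preserving skeleton
# of a tree-shaped mask this equals components - independent cycles = 1.
euler_of_skeleton_volume <- function(skel) {
  idx <- which(skel$data)
  if (!length(idx)) return(0L)
  coords <- arrayInd(idx, dim(skel$data))
  key <- function(m) paste(m[, 1], m[, 2], m[, 3], sep = ",")
  # vertices: 8 corners per cube at half-integer offsets (doubled coords)
  cc2 <- 2 * coords
  verts <- edges <- faces <- character(0)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  for (o in seq_len(nrow(offs))) {
    m <- abs(offs[o, 1]) + abs(offs[o, 2]) + abs(offs[o, 3])
    if (m == 0) next
    cell <- key(sweep(cc2, 2, -as.numeric(offs[o, ])))
    if (m == 3) verts <- c(verts, cell)
    else if (m == 2) edges <- c(edges, cell)
    else faces <- c(faces, cell)
  }
  nV <- length(unique(verts))
  nE <- length(unique(edges))
  nF <- length(unique(faces))
  nC <- nrow(coords)
  nV - nE + nF - nC
}

#' Annotation recall from proofreading counts
#'
#' Recall of the iterative human segmentation loop: the proof-reader
#' counts vessel cross-sections in randomised slices, recording true
#' positives (segmented) and false negatives (missed).
#'
#' @param true_positives,false_negatives non-negative counts with
#'   `tp + fn >= 1`.
#' @return recall fraction `tp / (tp + fn)`.
#' @export
annotation_recall <- function(true_positives, false_negatives) {
  if (true_positives < 0 || false_negatives < 0)
    stop("counts must be non-negative")
  if (true_positives + false_negatives == 0)
    stop("tp + fn must be at least 1")
  true_positives / (true_positives + false_negatives)
}
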