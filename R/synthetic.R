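#' Specification for a synthetic arterial tree
#'
#' Defaults emulate the arterial architecture observed in a whole human
#' kidney: roughly nine Strahler orders, a branching ratio near 2.9, a root
#' radius in the millimetre range, near-straight segments (tortuosity about
#' 1.1) and Murray-law radius scaling at bifurcations.
#'
#' @param depth number of branching levels (target Strahler-order count for
#'   a fully branching tree).
#' @param branch_prob probability that a tip branches at each level; 1
#'   gives a full tree of `depth` levels.
#' @param branching_ratio target branching ratio: expected number of
#'   children per junction (2 to 4; fractional parts realised by random
#'   trifurcation, so the realised ratio is an emergent, seed-dependent
#'   quantity).
#' @param asymmetry child-radius asymmetry `a` in (0, 1]: consecutive
#'   children have radii in ratio `a`; 1 is symmetric.
#' @param radius_law `"murray"` (children satisfy
#'   `sum(r_i^exponent) = r_parent^exponent` exactly) or `"log_linear"`
#'   (every child radius is `exp(-log_slope)` times its parent's, giving an
#'   exact log-linear radius-vs-order law).
#' @param murray_exponent exponent of the bifurcation law (default 3).
#' @param log_slope per-order log-radius decrement for `"log_linear"`.
#' @param root_radius radius of the root segment, micrometres.
#' @param length_radius_ratio segment chord length as a multiple of its
#'   radius; scalar, or one value per level from the root.
#' @param tortuosity_amp relative amplitude of the sinusoidal centreline
#'   perturbation (0 gives straight two-point segments; the default 0.65
#'   yields per-segment tortuosity near 1.1, the value typical of kidney
#'   arteries).
#' @param points_per_segment centreline points per segment when
#'   `tortuosity_amp > 0`.
#' @param cone_half_angle half-angle (degrees) of the sampling cone for
#'   child directions about the parent direction.
#' @param seed integer seed; the same spec always generates the same tree.
#' @return A `tree_spec` list.
#' @export
tree_spec <- function(depth = 9, branch_prob = 1, branching_ratio = 2.9,
                      asymmetry = 1, radius_law = c("murray", "log_linear"),
                      murray_exponent = 3, log_slope = 0.35,
                      root_radius = 2900, length_radius_ratio = 8,
                      tortuosity_amp = 0.65, points_per_segment = 7,
                      cone_half_angle = 40, seed = 1L) {
  radius_law <- match.arg(radius_law)
  if (depth < 1) stop("depth must be >= 1")
  if (root_radius <= 0) stop("root_radius must be > 0")
  if (tortuosity_amp < 0) stop("tortuosity_amp must be >= 0")
  if (asymmetry <= 0 || asymmetry > 1) stop("asymmetry must be in (0, 1]")
  if (branching_ratio < 2 || branching_ratio > 4)
    stop("branching_ratio must be in [2, 4]")
  if (branch_prob <= 0 && depth > 1)
    stop("zero branch probability with depth > 1 cannot realise the tree")
  structure(list(depth = depth, branch_prob = branch_prob,
                 branching_ratio = branching_ratio, asymmetry = asymmetry,
                 radius_law = radius_law, murray_exponent = murray_exponent,
                 log_slope = log_slope, root_radius = root_radius,
                 length_radius_ratio = length_radius_ratio,
                 tortuosity_amp = tortuosity_amp,
                 points_per_segment = points_per_segment,
                 cone_half_angle = cone_half_angle, seed = as.integer(seed)),
            class = "tree_spec")
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else on.exit(rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

# unit vector within a cone of half-angle (rad) about dir, given azimuth
cone_dir <- function(dir, polar, azim) {
  dir <- dir / sqrt(sum(dir^2))
  # orthonormal frame about dir
  k <- which.min(abs(dir))[1]
  e <- c(0, 0, 0); e[k] <- 1
  u <- c(e[2] * dir[3] - e[3] * dir[2], e[3] * dir[1] - e[1] * dir[3],
         e[1] * dir[2] - e[2] * dir[1])
  u <- u / sqrt(sum(u^2))
  v <- c(dir[2] * u[3] - dir[3] * u[2], dir[3] * u[1] - dir[1] * u[3],
         dir[1] * u[2] - dir[2] * u[1])
  cos(polar) * dir + sin(polar) * (cos(azim) * u + sin(azim) * v)
}

#' Generate a synthetic vascular tree
#'
#' Grows a rooted tree from a single inlet segment. Children of each
#' junction receive radii from the configured radius law; chord lengths
#' are `length_radius_ratio` times the radius; centrelines are straight
#' chords with an optional sinusoidal perpendicular perturbation. Child
#' directions are drawn within a cone about the parent direction, with
#' azimuths spread evenly so siblings separate; candidate tips colliding
#' with existing nodes are re-sampled up to a retry cap.
#'
#' @param spec a [tree_spec()].
#' @return A [spatial_graph]; `attr(, "levels")` holds each segment's
#'   level from the root (1 = root segment).
#' @export
generate_tree <- function(spec) {
  stopifnot(inherits(spec, "tree_spec"))
  with_seed(spec$seed, {
    nodes <- list(); segs <- list(); pts <- list(); levels <- integer(0)
    node_xyz <- matrix(numeric(0), ncol = 3)
    add_node <- function(p) {
      nodes[[length(nodes) + 1L]] <<- p
      node_xyz <<- rbind(node_xyz, p)
      length(nodes)
    }
    lrr <- function(level) {
      v <- spec$length_radius_ratio
      v[min(level, length(v))]
    }
    make_points <- function(sid, p0, p1, r, dir) {
      if (spec$tortuosity_amp == 0) {
        return(data.frame(segment_id = sid,
                          x = c(p0[1], p1[1]), y = c(p0[2], p1[2]),
                          z = c(p0[3], p1[3]), radius = r))
      }
      n <- max(3L, as.integer(spec$points_per_segment))
      tt <- seq(0, 1, length.out = n)
      perp <- cone_dir(dir, pi / 2, stats::runif(1, 0, 2 * pi))
      chord <- sqrt(sum((p1 - p0)^2))
      off <- spec$tortuosity_amp * chord * sin(pi * tt) / pi
      data.frame(segment_id = sid,
                 x = p0[1] + tt * (p1[1] - p0[1]) + off * perp[1],
                 y = p0[2] + tt * (p1[2] - p0[2]) + off * perp[2],
                 z = p0[3] + tt * (p1[3] - p0[3]) + off * perp[3],
                 radius = r)
    }
    add_segment <- function(from_id, p0, dir, r, level) {
      chord <- lrr(level) * r
      retries <- 0L
      repeat {
        p1 <- p0 + chord * dir
        clash <- nrow(node_xyz) > 1 &&
          any(sqrt(rowSums(sweep(node_xyz, 2, p1)^2)) < r)
        if (!clash || retries >= 10L) break
        dir <- cone_dir(dir, stats::runif(1, 0, spec$cone_half_angle * pi / 180),
                        stats::runif(1, 0, 2 * pi))
        retries <- retries + 1L
      }
      to_id <- add_node(p1)
      sid <- length(segs) + 1L
      segs[[sid]] <<- c(sid, from_id, to_id)
      pts[[sid]] <<- make_points(sid, p0, p1, r, dir)
      levels[sid] <<- level
      list(node = to_id, pos = p1, dir = dir)
    }
    root_id <- add_node(c(0, 0, 0))
    tip <- add_segment(root_id, c(0, 0, 0), c(0, 0, 1), spec$root_radius, 1L)
    tips <- list(list(node = tip$node, pos = tip$pos, dir = tip$dir,
                      radius = spec$root_radius))
    half <- spec$cone_half_angle * pi / 180
    for (level in seq_len(spec$depth - 1L) + 1L) {
      new_tips <- list()
      for (tp in tips) {
        if (stats::runif(1) > spec$branch_prob) next
        k <- 2L + stats::rbinom(1, 2L, (spec$branching_ratio - 2) / 2)
        a <- spec$asymmetry
        m <- spec$murray_exponent
        if (spec$radius_law == "murray") {
          r1 <- tp$radius * (sum(a^(m * (seq_len(k) - 1))))^(-1 / m)
          rads <- r1 * a^(seq_len(k) - 1)
        } else {
          rads <- rep(tp$radius * exp(-spec$log_slope), k)
        }
        base_azim <- stats::runif(1, 0, 2 * pi)
        for (i in seq_len(k)) {
          azim <- base_azim + 2 * pi * (i - 1) / k +
            stats::runif(1, -0.3, 0.3) * 2 * pi / k
          polar <- stats::runif(1, 0.35, 1) * half
          dir <- cone_dir(tp$dir, polar, azim)
          child <- add_segment(tp$node, tp$pos, dir, rads[i], level)
          new_tips[[length(new_tips) + 1L]] <-
            list(node = child$node, pos = child$pos, dir = child$dir,
                 radius = rads[i])
        }
      }
      tips <- new_tips
      if (!length(tips)) break
    }
    nodes_df <- data.frame(id = seq_along(nodes),
                           x = vapply(nodes, `[`, 0, 1),
                           y = vapply(nodes, `[`, 0, 2),
                           z = vapply(nodes, `[`, 0, 3))
    segs_df <- as.data.frame(do.call(rbind, segs))
    names(segs_df) <- c("id", "start_node", "end_node")
    g <- spatial_graph(nodes_df, segs_df, do.call(rbind, pts),
                       provenance = sprintf("synthetic tree (seed %d)",
                                            spec$seed))
    attr(g, "levels") <- levels
    g
  })
}

#' Perturb a spatial graph (noise, collapse and pruning fixtures)
#'
#' Applies, in order: centreline jitter, radius noise, collapsed-vessel
#' injection (multiplying all point radii of selected segments by a
#' factor), and terminal-branch deletion. Jitter moves interior points
#' only, so node/endpoint coincidence is preserved. Deletions remove
#' randomly chosen terminal segments, which can never disconnect the root
#' component. Ground truth is attached as `attr(, "ground_truth")`:
#' `collapsed_ids` and `deleted_ids`.
#'
#' @param g a [spatial_graph].
#' @param jitter_sd standard deviation (micrometres) of isotropic Gaussian
#'   jitter on interior points, 0 to disable.
#' @param radius_noise_sd relative lognormal-ish radius noise (multiplies
#'   each point radius by `exp(rnorm(1, 0, sd))`), 0 to disable.
#' @param collapse_fraction fraction of segments to collapse in `[0, 1]`.
#' @param collapse_factor radius multiplier in (0, 1) for collapsed
#'   segments.
#' @param delete_fraction fraction of terminal segments to delete.
#' @param seed integer seed.
#' @return A perturbed [spatial_graph] with a `ground_truth` attribute.
#' @export
perturb_graph <- function(g, jitter_sd = 0, radius_noise_sd = 0,
                          collapse_fraction = 0, collapse_factor = 0.2,
                          delete_fraction = 0, seed = 1L) {
  if (collapse_fraction < 0 || collapse_fraction > 1 ||
      delete_fraction < 0 || delete_fraction > 1)
    stop("fractions must lie in [0, 1]")
  if (collapse_fraction > 0 && (collapse_factor <= 0 || collapse_factor >= 1))
    stop("collapse_factor must lie in (0, 1)")
  with_seed(seed, {
    pts <- g$points
    sp <- segment_point_rows(g)
    if (jitter_sd > 0) {
      for (rows in sp) {
        n <- length(rows)
        if (n > 2) {
          mid <- rows[2:(n - 1)]
          pts$x[mid] <- pts$x[mid] + stats::rnorm(n - 2, 0, jitter_sd)
          pts$y[mid] <- pts$y[mid] + stats::rnorm(n - 2, 0, jitter_sd)
          pts$z[mid] <- pts$z[mid] + stats::rnorm(n - 2, 0, jitter_sd)
        }
      }
    }
    if (radius_noise_sd > 0)
      pts$radius <- pts$radius * exp(stats::rnorm(nrow(pts), 0,
                                                  radius_noise_sd))
    collapsed_ids <- integer(0)
    if (collapse_fraction > 0) {
      n_coll <- max(1L, round(collapse_fraction * nrow(g$segments)))
      collapsed_ids <- sort(sample(g$segments$id, n_coll))
      sel <- pts$segment_id %in% collapsed_ids
      pts$radius[sel] <- pts$radius[sel] * collapse_factor
    }
    segs <- g$segments
    nodes <- g$nodes
    deleted_ids <- integer(0)
    if (delete_fraction > 0) {
      deg <- node_degrees(g)
      term_nodes <- as.integer(names(deg)[deg == 1])
      root_guess <- find_root(g)
      term_nodes <- setdiff(term_nodes, root_guess)
      term_segs <- segs$id[segs$start_node %in% term_nodes |
                             segs$end_node %in% term_nodes]
      n_del <- round(delete_fraction * length(term_segs))
      if (n_del > 0) {
        deleted_ids <- sort(sample(term_segs, n_del))
        segs <- segs[!segs$id %in% deleted_ids, ]
        pts <- pts[!pts$segment_id %in% deleted_ids, ]
        keep_nodes <- unique(c(segs$start_node, segs$end_node))
        nodes <- nodes[nodes$id %in% keep_nodes, ]
      }
    }
    out <- spatial_graph(nodes, segs, pts,
                         voxel_size = g$meta$voxel_size,
                         origin = g$meta$origin,
                         provenance = paste(g$meta$provenance, "+ perturbed"),
                         tolerance = g$meta$tolerance)
    attr(out, "ground_truth") <- list(collapsed_ids = collapsed_ids,
                                      deleted_ids = deleted_ids)
    out
  })
}

#' Voxelize a spatial graph into a binary mask
#'
#' Inverse of skeletonization: a voxel is foreground iff its centre lies
#' within the linearly interpolated radius of any sub-segment (a union of
#' capsules).
#'
#' @param g a [spatial_graph].
#' @param voxel_size voxel edge length, micrometres.
#' @param shape optional `c(nx, ny, nz)`; derived from the padded bounding
#'   box when `NULL`.
#' @param origin optional world position of the first voxel centre.
#' @param pad padding around the bounding box in multiples of the maximum
#'   radius (used only when `shape` is `NULL`).
#' @return A binary [voxel_volume].
#' @export
voxelize <- function(g, voxel_size, shape = NULL, origin = NULL, pad = 1.5) {
  if (!nrow(g$points)) {
    if (is.null(shape)) shape <- c(2L, 2L, 2L)
    if (is.null(origin)) origin <- c(0, 0, 0)
    return(voxel_volume(array(FALSE, shape), voxel_size, origin))
  }
  rmax <- max(g$points$radius)
  if (is.null(origin))
    origin <- c(min(g$points$x), min(g$points$y), min(g$points$z)) -
      pad * rmax
  if (is.null(shape)) {
    hi <- c(max(g$points$x), max(g$points$y), max(g$points$z)) + pad * rmax
    shape <- pmax(2L, as.integer(ceiling((hi - origin) / voxel_size)) + 1L)
  } else {
    hi_world <- origin + (shape - 1) * voxel_size
    lo_need <- c(min(g$points$x), min(g$points$y), min(g$points$z)) - rmax
    hi_need <- c(max(g$points$x), max(g$points$y), max(g$points$z)) + rmax
    if (any(lo_need < origin - voxel_size / 2) ||
        any(hi_need > hi_world + voxel_size / 2))
      stop("graph (padded by max radius) exceeds the requested grid")
  }
  sp <- segment_point_rows(g)
  P <- Q <- matrix(0, 0, 3); rp <- rq <- numeric(0)
  for (rows in sp) {
    m <- as.matrix(g$points[rows, c("x", "y", "z")])
    r <- g$points$radius[rows]
    n <- length(rows)
    P <- rbind(P, m[-n, , drop = FALSE])
    Q <- rbind(Q, m[-1, , drop = FALSE])
    rp <- c(rp, r[-n]); rq <- c(rq, r[-1])
  }
  mask <- cpp_voxelize(as.integer(shape), voxel_size, origin, P, Q, rp, rq)
  voxel_volume(array(mask, shape), voxel_size, origin)
}

#' Specification for a zonal kidney phantom
#'
#' Concentric spherical compartments mimicking the anatomical zones used
#' for regional statistics: an inner hilum sphere, a medulla shell crossed
#' by azimuthal inter-medullary pillar wedges, and an outer cortex shell.
#'
#' @param shape grid dimensions `c(nx, ny, nz)`.
#' @param voxel_size voxel edge, micrometres.
#' @param hilum_radius,medulla_radius,cortex_radius nested shell radii in
#'   micrometres (`hilum < medulla < cortex`).
#' @param pillar_count number of pillar wedges (0 for none).
#' @param pillar_half_width half-width of each wedge in radians.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(48, 48, 48), voxel_size = 50,
                         hilum_radius = 300, medulla_radius = 700,
                         cortex_radius = 1100, pillar_count = 0,
                         pillar_half_width = 0.2) {
  if (!(hilum_radius < medulla_radius && medulla_radius < cortex_radius))
    stop("shells must be nested: hilum < medulla < cortex")
  if (min(hilum_radius, medulla_radius, cortex_radius) <= 0)
    stop("shell radii must be positive")
  structure(list(shape = as.integer(shape), voxel_size = voxel_size,
                 hilum_radius = hilum_radius,
                 medulla_radius = medulla_radius,
                 cortex_radius = cortex_radius,
                 pillar_count = as.integer(pillar_count),
                 pillar_half_width = pillar_half_width),
            class = "phantom_spec")
}

#' Zone labels used by the phantom generator and zonal analysis
#' @export
zone_labels <- c(background = 0L, cortex = 1L, medulla = 2L, hilum = 3L,
                 pillars = 4L)

#' Generate a zone-label phantom volume
#'
#' @param spec a [phantom_spec()].
#' @return A label [voxel_volume] with values `zone_labels`.
#' @export
generate_zone_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$shape
  centre <- (d - 1) / 2 * spec$voxel_size
  ix <- (seq_len(d[1]) - 1) * spec$voxel_size - centre[1]
  iy <- (seq_len(d[2]) - 1) * spec$voxel_size - centre[2]
  iz <- (seq_len(d[3]) - 1) * spec$voxel_size - centre[3]
  X <- array(rep(ix, times = d[2] * d[3]), dim = d)
  Y <- array(rep(rep(iy, each = d[1]), times = d[3]), dim = d)
  Z <- array(rep(iz, each = d[1] * d[2]), dim = d)
  R <- sqrt(X^2 + Y^2 + Z^2)
  lab <- array(0L, dim = d)
  lab[R <= spec$cortex_radius] <- zone_labels[["cortex"]]
  med <- R <= spec$medulla_radius
  lab[med] <- zone_labels[["medulla"]]
  if (spec$pillar_count > 0) {
    azim <- atan2(Y, X)
    wedge_centres <- 2 * pi * (seq_len(spec$pillar_count) - 1) /
      spec$pillar_count - pi
    inpillar <- array(FALSE, dim = d)
    for (w in wedge_centres) {
      dang <- abs(((azim - w + pi) %% (2 * pi)) - pi)
      inpillar <- inpillar | dang <= spec$pillar_half_width
    }
    lab[med & inpillar & R > spec$hilum_radius] <- zone_labels[["pillars"]]
  }
  lab[R <= spec$hilum_radius] <- zone_labels[["hilum"]]
  voxel_volume(lab, spec$voxel_size, -centre)
}
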