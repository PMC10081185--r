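#' Per-segment geometric metrics
#'
#' For each segment: `length` is the sum of sub-segment lengths; `radius`
#' the mean of sub-segment radii (a sub-segment's radius being the mean of
#' its two endpoint radii); `tortuosity` the path length divided by the
#' start-to-end chord length (>= 1; `literal_tortuosity = TRUE` returns
#' the reciprocal, chord/path); `length_radius_ratio` is length/radius
#' (`ldr_uses_diameter = TRUE` divides by the diameter instead); `volume`
#' sums one cylinder per sub-segment. The midpoint is the point at half
#' cumulative path length, linearly interpolated within a sub-segment.
#'
#' @param g a [spatial_graph].
#' @param literal_tortuosity report chord/path instead of path/chord.
#' @param ldr_uses_diameter divide length by diameter instead of radius.
#' @return data.frame with one row per segment: `segment_id`, `radius`,
#'   `length`, `chord`, `tortuosity`, `length_radius_ratio`, `volume`,
#'   `mid_x`, `mid_y`, `mid_z`, `degenerate` (TRUE when the chord length
#'   is zero and tortuosity is undefined).
#' @export
segment_metrics <- function(g, literal_tortuosity = FALSE,
                            ldr_uses_diameter = FALSE) {
  sp <- segment_point_rows(g)
  ns <- nrow(g$segments)
  out <- data.frame(segment_id = g$segments$id, radius = NA_real_,
                    length = NA_real_, chord = NA_real_,
                    tortuosity = NA_real_, length_radius_ratio = NA_real_,
                    volume = NA_real_, mid_x = NA_real_, mid_y = NA_real_,
                    mid_z = NA_real_, degenerate = FALSE)
  for (k in seq_len(ns)) {
    rows <- sp[[k]]
    m <- as.matrix(g$points[rows, c("x", "y", "z")])
    r <- g$points$radius[rows]
    dseg <- sqrt(rowSums(diff(m)^2))
    rsub <- (r[-1] + r[-length(r)]) / 2
    len <- sum(dseg)
    chord <- sqrt(sum((m[nrow(m), ] - m[1, ])^2))
    rad <- mean(rsub)
    out$radius[k] <- rad
    out$length[k] <- len
    out$chord[k] <- chord
    out$volume[k] <- sum(pi * rsub^2 * dseg)
    if (chord == 0) {
      out$degenerate[k] <- TRUE
    } else {
      out$tortuosity[k] <- if (literal_tortuosity) chord / len else len / chord
    }
    out$length_radius_ratio[k] <-
      if (ldr_uses_diameter) len / (2 * rad) else len / rad
    # midpoint at half path length
    cum <- c(0, cumsum(dseg))
    half <- len / 2
    j <- findInterval(half, cum, rightmost.closed = TRUE)
    j <- min(max(j, 1L), length(dseg))
    t <- if (dseg[j] > 0) (half - cum[j]) / dseg[j] else 0
    mid <- m[j, ] + t * (m[j + 1, ] - m[j, ])
    out$mid_x[k] <- mid[1]; out$mid_y[k] <- mid[2]; out$mid_z[k] <- mid[3]
  }
  out
}

angle_deg <- function(u, v) {
  cu <- sqrt(sum(u^2)); cv <- sqrt(sum(v^2))
  if (cu == 0 || cv == 0) stop("zero-length chord at junction")
  acos(pmin(pmax(sum(u * v) / (cu * cv), -1), 1)) * 180 / pi
}

#' Branching angles at every junction of a rooted tree
#'
#' Every incident segment at a junction is represented by its chord
#' (start-node to end-node vector, ignoring tortuosity) pointing away from
#' the junction. The child-parent angle is measured between a child's
#' away-vector and the parent's away-vector, so a straight continuation
#' scores 180 degrees. Child-child angles are reported for every pair of
#' children (all pairs at junctions with more than two).
#'
#' @param g a [spatial_graph].
#' @param root root node id.
#' @return list with `child_parent` (data.frame: `node_id`,
#'   `child_segment`, `parent_segment`, `angle`) and `child_child`
#'   (data.frame: `node_id`, `segment_a`, `segment_b`, `angle`).
#' @export
branching_angles <- function(g, root) {
  rt <- root_tree(g, root)
  nidx <- match(g$nodes$id, g$nodes$id)
  pos <- as.matrix(g$nodes[, c("x", "y", "z")])
  cp <- list(); cc <- list()
  for (k in seq_len(nrow(g$segments))) {
    if (!rt$in_component[k]) next
    ch <- rt$children[[k]]
    if (length(ch) < 2) next # junction = node with >= 2 children
    node_i <- rt$far_node_idx[k]
    away <- function(seg) {
      a <- rt$near_node_idx[seg]; b <- rt$far_node_idx[seg]
      if (a == node_i) pos[b, ] - pos[node_i, ] else pos[a, ] - pos[node_i, ]
    }
    par_away <- pos[rt$near_node_idx[k], ] - pos[node_i, ]
    for (s in ch)
      cp[[length(cp) + 1L]] <- data.frame(
        node_id = g$nodes$id[node_i], child_segment = g$segments$id[s],
        parent_segment = g$segments$id[k],
        angle = angle_deg(away(s), par_away))
    prs <- utils::combn(ch, 2)
    for (j in seq_len(ncol(prs)))
      cc[[length(cc) + 1L]] <- data.frame(
        node_id = g$nodes$id[node_i],
        segment_a = g$segments$id[prs[1, j]],
        segment_b = g$segments$id[prs[2, j]],
        angle = angle_deg(away(prs[1, j]), away(prs[2, j])))
  }
  list(child_parent = if (length(cp)) do.call(rbind, cp) else
         data.frame(node_id = integer(0), child_segment = integer(0),
                    parent_segment = integer(0), angle = numeric(0)),
       child_child = if (length(cc)) do.call(rbind, cc) else
         data.frame(node_id = integer(0), segment_a = integer(0),
                    segment_b = integer(0), angle = numeric(0)))
}

#' Nearest-neighbour distance between segment midpoints
#'
#' Euclidean distance from every segment midpoint to its nearest other
#' segment midpoint. Only the segment itself is excluded by default;
#' `exclude_neighbours = TRUE` additionally excludes segments sharing a
#' node.
#'
#' @param g a [spatial_graph] with at least two segments.
#' @param metrics optional precomputed [segment_metrics()] table.
#' @param exclude_neighbours exclude topological neighbours as well.
#' @return data.frame with `segment_id`, `nearest_segment`, `distance`.
#' @export
intervessel_midpoint_distance <- function(g, metrics = NULL,
                                          exclude_neighbours = FALSE) {
  if (nrow(g$segments) < 2)
    stop("midpoint inter-vessel distance needs at least 2 segments")
  if (is.null(metrics)) metrics <- segment_metrics(g)
  M <- as.matrix(metrics[, c("mid_x", "mid_y", "mid_z")])
  n <- nrow(M)
  nn_id <- integer(n); nn_d <- numeric(n)
  adj <- NULL
  if (exclude_neighbours) {
    adj <- lapply(seq_len(n), function(k) {
      a <- g$segments$start_node[k]; b <- g$segments$end_node[k]
      which((g$segments$start_node %in% c(a, b) |
               g$segments$end_node %in% c(a, b)) &
              seq_len(n) != k)
    })
  }
  chunk <- 512L
  for (s in seq(1, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    D2 <- outer(rowSums(M[s:e, , drop = FALSE]^2), rowSums(M^2), "+") -
      2 * M[s:e, , drop = FALSE] %*% t(M)
    for (i in s:e) {
      row <- D2[i - s + 1, ]
      row[i] <- Inf
      if (exclude_neighbours) row[adj[[i]]] <- Inf
      j <- which.min(row)
      nn_id[i] <- metrics$segment_id[j]
      nn_d[i] <- sqrt(max(row[j], 0))
    }
  }
  data.frame(segment_id = metrics$segment_id, nearest_segment = nn_id,
             distance = nn_d)
}

#' Voxel-wise inter-vessel distance field
#'
#' Distance of every non-vessel voxel to the nearest vessel voxel via the
#' 3D distance transform; with zone labels, per-zone summaries of the
#' distances over that zone's voxels.
#'
#' @param mask binary vessel [voxel_volume].
#' @param labels optional zone-label [voxel_volume] on the same grid.
#' @return list with `field` (distance [voxel_volume], micrometres) and,
#'   when labels are given, `per_zone` (data.frame: `zone`, `label`,
#'   `n_voxels`, `mean`, `sd`, `max`).
#' @export
intervessel_voxel_distance <- function(mask, labels = NULL) {
  field <- distance_transform(mask)
  out <- list(field = field)
  if (!is.null(labels)) {
    if (!same_grid(mask, labels))
      stop("zone label grid does not match the mask grid")
    labs <- labels$data
    per <- lapply(zone_labels_of(labs), function(l) {
      sel <- labs == l
      d <- field$data[sel]
      data.frame(label = l, n_voxels = sum(sel), mean = mean(d),
                 sd = sd(d), max = max(d))
    })
    per <- do.call(rbind, per)
    nm <- names(zone_labels)[match(per$label, zone_labels)]
    per$zone <- ifelse(is.na(nm), as.character(per$label), nm)
    out$per_zone <- per[, c("zone", "label", "n_voxels", "mean", "sd", "max")]
  }
  out
}

zone_labels_of <- function(labs) sort(unique(as.integer(labs[labs != 0])))

#' Cumulative vascular volume fraction by Strahler order
#'
#' @param metrics [segment_metrics()] table.
#' @param ordering `ordering_result` on the same graph; every segment must
#'   carry an order.
#' @return data.frame with `order`, `volume`, `cumulative_fraction`
#'   (ascending accumulation from order 1; the final value is 1).
#' @export
cumulative_volume_by_order <- function(metrics, ordering) {
  ord <- ordering$strahler[match(metrics$segment_id, ordering$segment_id)]
  if (anyNA(ord)) stop("unordered segments present")
  v <- tapply(metrics$volume, factor(ord, levels = seq_len(max(ord))), sum,
              default = 0)
  v[is.na(v)] <- 0
  data.frame(order = seq_along(v), volume = as.numeric(v),
             cumulative_fraction = cumsum(v) / sum(v))
}

#' Per-order summary of branching metrics
#'
#' One row per Strahler order with the segment count and mean +/- SD of
#' radius, length, tortuosity, length:radius ratio, volume, child-parent
#' branching angle (attributed to the child's order) and midpoint
#' inter-vessel distance. SDs are NA for single-segment orders.
#'
#' @param metrics [segment_metrics()] table.
#' @param ordering `ordering_result` on the same graph.
#' @param angles optional [branching_angles()] result.
#' @param ivd optional [intervessel_midpoint_distance()] result.
#' @return data.frame, one row per order.
#' @export
grouped_summary <- function(metrics, ordering, angles = NULL, ivd = NULL) {
  ord <- ordering$strahler[match(metrics$segment_id, ordering$segment_id)]
  if (anyNA(ord)) stop("unordered segments present")
  lv <- seq_len(max(ord))
  f <- factor(ord, levels = lv)
  agg <- function(x) list(mean = tapply(x, f, mean), sd = tapply(x, f, sd))
  r <- agg(metrics$radius); l <- agg(metrics$length)
  tt <- agg(metrics$tortuosity); ldr <- agg(metrics$length_radius_ratio)
  vv <- agg(metrics$volume)
  out <- data.frame(order = lv, n = as.integer(table(f)),
                    radius_mean = as.numeric(r$mean),
                    radius_sd = as.numeric(r$sd),
                    length_mean = as.numeric(l$mean),
                    length_sd = as.numeric(l$sd),
                    tortuosity_mean = as.numeric(tt$mean),
                    tortuosity_sd = as.numeric(tt$sd),
                    ldr_mean = as.numeric(ldr$mean),
                    ldr_sd = as.numeric(ldr$sd),
                    volume_mean = as.numeric(vv$mean),
                    volume_sd = as.numeric(vv$sd))
  if (!is.null(angles) && nrow(angles$child_parent)) {
    aord <- ord[match(angles$child_parent$child_segment,
                      metrics$segment_id)]
    af <- factor(aord, levels = lv)
    out$angle_mean <- as.numeric(tapply(angles$child_parent$angle, af, mean))
    out$angle_sd <- as.numeric(tapply(angles$child_parent$angle, af, sd))
  }
  if (!is.null(ivd)) {
    iord <- ord[match(ivd$segment_id, metrics$segment_id)]
    iff <- factor(iord, levels = lv)
    out$ivd_mean <- as.numeric(tapply(ivd$distance, iff, mean))
    out$ivd_sd <- as.numeric(tapply(ivd$distance, iff, sd))
  }
  out
}
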