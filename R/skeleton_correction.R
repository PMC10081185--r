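#' Multiscale smoothing of large-vessel centrelines
#'
#' Skeletonization of multiscale vasculature leaves jagged centrelines in
#' the largest vessels (many voxels wide). For segments at or above a
#' Strahler-order threshold, each interior point is replaced by the
#' kernel-weighted average of the original points within an arc-length
#' window proportional to the local radius; the first and last points
#' (node anchors) are never moved, radii are unchanged, and all other
#' segments are untouched — so topology is exactly preserved.
#'
#' @param g a [spatial_graph].
#' @param ordering `ordering_result` covering `g`.
#' @param min_order smallest Strahler order smoothed (default 6).
#' @param window_scale window half-width as a multiple of the local point
#'   radius (default 2).
#' @param kernel `"gaussian"` (sigma = half-width / 2) or `"uniform"`.
#' @return The smoothed [spatial_graph].
#' @export
multiscale_smooth <- function(g, ordering, min_order = 6, window_scale = 2,
                              kernel = c("gaussian", "uniform")) {
  kernel <- match.arg(kernel)
  if (min_order < 1 || window_scale <= 0) stop("invalid smoothing config")
  ord <- ordering$strahler[match(g$segments$id, ordering$segment_id)]
  sp <- segment_point_rows(g)
  pts <- g$points
  for (k in seq_len(nrow(g$segments))) {
    if (is.na(ord[k]) || ord[k] < min_order) next
    rows <- sp[[k]]
    n <- length(rows)
    if (n < 3) next
    m <- as.matrix(pts[rows, c("x", "y", "z")])
    arc <- c(0, cumsum(sqrt(rowSums(diff(m)^2))))
    r <- pts$radius[rows]
    new <- m
    for (i in 2:(n - 1)) {
      hw <- window_scale * r[i]
      w <- abs(arc - arc[i]) <= hw
      wt <- if (kernel == "gaussian")
        dnorm(arc[w], mean = arc[i], sd = hw / 2) else rep(1, sum(w))
      target <- colSums(m[w, , drop = FALSE] * wt) / sum(wt)
      # move only across the local tangent: lateral jitter is averaged out
      # while points never slide along the centreline, so straight
      # polylines are exact fixed points of the operator
      tang <- m[i + 1, ] - m[i - 1, ]
      tl <- sqrt(sum(tang^2))
      disp <- target - m[i, ]
      if (tl > 0) {
        tang <- tang / tl
        disp <- disp - sum(disp * tang) * tang
      }
      new[i, ] <- m[i, ] + disp
    }
    pts$x[rows] <- new[, 1]; pts$y[rows] <- new[, 2]; pts$z[rows] <- new[, 3]
  }
  g$points <- pts
  g
}

#' Detect collapsed-vessel candidates from per-order radius outliers
#'
#' Vessels whose lumen closed during preparation register an artifactually
#' small centreline radius. Within each Strahler order holding enough
#' segments, segments whose mean radius falls below that order's lower
#' `percentile` are flagged as candidates for confirmation (against a
#' ground-truth manifest, or by a human in the original workflow).
#'
#' @param metrics [segment_metrics()] table.
#' @param ordering `ordering_result` on the same graph.
#' @param percentile lower-tail percentile in (0, 50] (default 10).
#' @param min_segments_per_order minimum per-order sample size (default 20).
#' @return list with `candidates` (segment ids) and `thresholds`
#'   (data.frame: `order`, `n`, `threshold`).
#' @export
detect_collapsed <- function(metrics, ordering, percentile = 10,
                             min_segments_per_order = 20) {
  if (percentile <= 0 || percentile > 50)
    stop("percentile must lie in (0, 50]")
  ord <- ordering$strahler[match(metrics$segment_id, ordering$segment_id)]
  cands <- integer(0); thr <- list()
  for (o in sort(unique(ord[!is.na(ord)]))) {
    sel <- which(ord == o)
    if (length(sel) < min_segments_per_order) next
    q <- quantile(metrics$radius[sel], percentile / 100, names = FALSE)
    flag <- sel[metrics$radius[sel] < q]
    cands <- c(cands, metrics$segment_id[flag])
    thr[[length(thr) + 1L]] <- data.frame(order = o, n = length(sel),
                                          threshold = q)
  }
  list(candidates = sort(cands),
       thresholds = if (length(thr)) do.call(rbind, thr) else
         data.frame(order = integer(0), n = integer(0),
                    threshold = numeric(0)))
}

#' Restore collapsed-vessel radii from cross-section perimeters
#'
#' For each listed segment, a plane normal to the local centreline tangent
#' (central difference of neighbouring points) is extracted from the
#' binary mask at every centreline point; the perimeter `P` of the
#' foreground component at the projected centreline point gives the
#' equivalent radius `P / (2 * pi)`, which replaces that point's radius.
#' Points whose plane misses foreground keep their prior radius and are
#' flagged. A collapsed (e.g. elliptical) lumen thereby recovers the
#' radius of the circular tube with the same wall perimeter.
#'
#' @param g a [spatial_graph] in the same world frame as `mask`.
#' @param mask binary [voxel_volume].
#' @param segment_ids segments to correct.
#' @param half_width sampling window half-extent, micrometres; default 6x
#'   the graph's maximum point radius.
#' @param spacing in-plane sampling step, micrometres; default the mask's
#'   voxel size.
#' @param hint_tolerance pixels searched around the projected centreline
#'   point when it falls on background (default 3).
#' @param method perimeter method, see [perimeter_of_component()].
#' @return The corrected [spatial_graph]; `attr(, "correction_report")` is
#'   a data.frame with one row per centreline point of the corrected
#'   segments (`segment_id`, `point`, `old_radius`, `new_radius`,
#'   `corrected`).
#' @export
correct_radius_from_perimeter <- function(g, mask, segment_ids,
                                          half_width = NULL, spacing = NULL,
                                          hint_tolerance = 3,
                                          method = "hull") {
  missing_seg <- setdiff(segment_ids, g$segments$id)
  if (length(missing_seg))
    stop("unknown segment ids: ", paste(missing_seg, collapse = ", "))
  if (is.null(spacing)) spacing <- mask$voxel_size
  if (is.null(half_width)) half_width <- 6 * max(g$points$radius)
  sp <- segment_point_rows(g)
  pts <- g$points
  report <- list()
  for (sid in segment_ids) {
    k <- match(sid, g$segments$id)
    rows <- sp[[k]]
    m <- as.matrix(pts[rows, c("x", "y", "z")])
    n <- nrow(m)
    any_hit <- FALSE
    for (i in seq_len(n)) {
      a <- max(i - 1L, 1L); b <- min(i + 1L, n)
      tangent <- m[b, ] - m[a, ]
      r_new <- NA_real_
      if (sum(tangent^2) > 0) {
        sec <- tryCatch(
          extract_cross_section(mask, m[i, ], tangent, half_width, spacing),
          error = function(e) NULL)
        if (!is.null(sec)) {
          per <- tryCatch(
            perimeter_of_component(sec, method = method,
                                   hint_tolerance = hint_tolerance),
            error = function(e) NA_real_)
          if (!is.na(per)) r_new <- per / (2 * pi)
        }
      }
      old_r <- pts$radius[rows[i]]
      if (!is.na(r_new)) {
        pts$radius[rows[i]] <- r_new
        any_hit <- TRUE
      }
      report[[length(report) + 1L]] <-
        data.frame(segment_id = sid, point = i, old_radius = old_r,
                   new_radius = if (is.na(r_new)) old_r else r_new,
                   corrected = !is.na(r_new))
    }
    if (!any_hit)
      stop("segment ", sid, ": no cross-section plane intersected ",
           "foreground (segment outside the mask?)")
  }
  g$points <- pts
  attr(g, "correction_report") <- do.call(rbind, report)
  g
}
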