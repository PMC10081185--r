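#' Assign vessel segments to anatomical zones
#'
#' Samples every centreline point at its containing voxel of the label
#' volume. A segment whose sampled points are unanimous receives that
#' zone; mixed-zone segments are `"crossing"`; segments sampling only
#' label 0 or falling outside the grid are `"outside"`. Unanimity (rather
#' than majority) means any boundary contact excludes the segment from
#' zone rows, matching the convention that segments crossing two regions
#' are excluded from per-zone statistics; `rule = "majority"` is offered
#' as an alternative.
#'
#' @param g a [spatial_graph] in the same world frame as `labels`.
#' @param labels zone-label [voxel_volume] (values as [zone_labels]).
#' @param rule `"unanimity"` (default) or `"majority"`.
#' @return data.frame with `segment_id`, `zone` (zone name, `"crossing"`
#'   or `"outside"`), `label` (integer label, NA for crossing/outside).
#' @export
assign_zones <- function(g, labels, rule = c("unanimity", "majority")) {
  rule <- match.arg(rule)
  d <- dim(labels$data)
  idx <- round(world_to_index(labels,
                              as.matrix(g$points[, c("x", "y", "z")]))) + 1
  inside <- idx[, 1] >= 1 & idx[, 1] <= d[1] & idx[, 2] >= 1 &
    idx[, 2] <= d[2] & idx[, 3] >= 1 & idx[, 3] <= d[3]
  lab <- rep(NA_integer_, nrow(idx))
  lab[inside] <- labels$data[idx[inside, , drop = FALSE]]
  lab[!inside] <- 0L
  sp <- split(lab, factor(g$points$segment_id, levels = g$segments$id))
  zone_of <- function(l) {
    l_nz <- l[l != 0]
    if (!length(l_nz)) return(c("outside", NA))
    if (rule == "unanimity") {
      u <- unique(l)
      if (length(u) == 1L && u != 0L) {
        nm <- names(zone_labels)[match(u, zone_labels)]
        return(c(ifelse(is.na(nm), as.character(u), nm), u))
      }
      return(c("crossing", NA))
    }
    tab <- table(l_nz)
    top <- as.integer(names(tab)[which.max(tab)])
    if (sum(l == top) > length(l) / 2) {
      nm <- names(zone_labels)[match(top, zone_labels)]
      return(c(ifelse(is.na(nm), as.character(top), nm), top))
    }
    c("crossing", NA)
  }
  res <- t(vapply(sp, zone_of, character(2)))
  data.frame(segment_id = g$segments$id, zone = res[, 1],
             label = suppressWarnings(as.integer(res[, 2])))
}

#' Per-zone tissue and vessel summary
#'
#' One row per zone plus an organ-total row. Tissue volume is voxel count
#' times voxel volume per label. Crossing segments are excluded from zone
#' rows but included in the organ total, so zone segment counts sum to
#' less than the organ count whenever any segment crosses a boundary.
#'
#' @param g a [spatial_graph].
#' @param metrics [segment_metrics()] table.
#' @param assignment [assign_zones()] result.
#' @param labels zone-label [voxel_volume].
#' @param ivd optional [intervessel_midpoint_distance()] result.
#' @return data.frame, one row per zone and a final `"organ"` row:
#'   `zone`, `tissue_volume`, `tissue_fraction`, `n_segments`,
#'   `segment_fraction`, mean/sd of length, radius, volume, tortuosity,
#'   and (when `ivd` is given) inter-vessel distance.
#' @export
zone_summary <- function(g, metrics, assignment, labels, ivd = NULL) {
  if (!identical(sort(assignment$segment_id), sort(metrics$segment_id)))
    stop("assignment and metrics cover different segments")
  vox_vol <- labels$voxel_size^3
  labs <- labels$data
  zl <- zone_labels_of(labs)
  total_tissue <- sum(labs != 0) * vox_vol
  n_total <- nrow(metrics)
  row_for <- function(zone_name, sel, tissue) {
    msub <- metrics[sel, , drop = FALSE]
    stat <- function(x) c(mean = if (nrow(msub)) mean(x) else NA_real_,
                          sd = if (nrow(msub)) sd(x) else NA_real_)
    r <- data.frame(zone = zone_name, tissue_volume = tissue,
                    tissue_fraction = tissue / total_tissue,
                    n_segments = nrow(msub),
                    segment_fraction = nrow(msub) / n_total,
                    length_mean = stat(msub$length)[1],
                    length_sd = stat(msub$length)[2],
                    radius_mean = stat(msub$radius)[1],
                    radius_sd = stat(msub$radius)[2],
                    volume_mean = stat(msub$volume)[1],
                    volume_sd = stat(msub$volume)[2],
                    tortuosity_mean = stat(msub$tortuosity)[1],
                    tortuosity_sd = stat(msub$tortuosity)[2])
    if (!is.null(ivd)) {
      dsub <- ivd$distance[match(msub$segment_id, ivd$segment_id)]
      r$ivd_mean <- if (length(dsub)) mean(dsub) else NA_real_
      r$ivd_sd <- if (length(dsub) > 1) sd(dsub) else NA_real_
    }
    r
  }
  rows <- list()
  for (l in zl) {
    nm <- names(zone_labels)[match(l, zone_labels)]
    nm <- ifelse(is.na(nm), as.character(l), nm)
    sel <- which(!is.na(assignment$label) & assignment$label == l)
    rows[[length(rows) + 1L]] <- row_for(nm, sel, sum(labs == l) * vox_vol)
  }
  rows[[length(rows) + 1L]] <- row_for("organ", seq_len(n_total),
                                       total_tissue)
  do.call(rbind, rows)
}

#' Per-zone inter-vessel distance distributions
#'
#' Restricts the vessel distance-transform field to each zone, returning
#' histograms, summary statistics, and the fraction of zone voxels whose
#' distance exceeds a threshold (default 4.5 mm — a hypoxia-relevant
#' diffusion distance).
#'
#' @param mask binary vessel [voxel_volume].
#' @param labels zone-label [voxel_volume] on the same grid.
#' @param breaks histogram breaks (micrometres) or a count.
#' @param threshold distance threshold in micrometres (default 4500).
#' @return list with `summary` (data.frame: `zone`, `label`, `n_voxels`,
#'   `mean`, `sd`, `max`, `frac_above_threshold`) and `histograms` (named
#'   list of `hist` objects).
#' @export
zone_ivd_distribution <- function(mask, labels, breaks = 30,
                                  threshold = 4500) {
  if (!same_grid(mask, labels)) stop("grids do not match")
  field <- distance_transform(mask)
  labs <- labels$data
  zl <- zone_labels_of(labs)
  hists <- list(); rows <- list()
  for (l in zl) {
    nm <- names(zone_labels)[match(l, zone_labels)]
    nm <- ifelse(is.na(nm), as.character(l), nm)
    dvals <- field$data[labs == l]
    hists[[nm]] <- hist(dvals, breaks = breaks, plot = FALSE)
    rows[[length(rows) + 1L]] <-
      data.frame(zone = nm, label = l, n_voxels = length(dvals),
                 mean = mean(dvals), sd = sd(dvals), max = max(dvals),
                 frac_above_threshold = mean(dvals > threshold))
  }
  list(summary = do.call(rbind, rows), histograms = hists)
}
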