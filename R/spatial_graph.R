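#' Construct a spatial graph of a vessel network
#'
#' A spatial graph is the centreline representation of a vessel network:
#' *nodes* are branching points or terminal ends, *segments* connect two
#' nodes, and each segment carries an ordered list of centreline *points*
#' with associated radii. The interval between two consecutive points is a
#' *sub-segment*; all geometric quantities (length, volume, tortuosity) are
#' accumulated over sub-segments. Coordinates are world coordinates in
#' micrometres. Storage is undirected; flow direction (parent to child) is
#' always derived from a chosen root at analysis time.
#'
#' @param nodes data.frame with columns `id`, `x`, `y`, `z` (micrometres).
#' @param segments data.frame with columns `id`, `start_node`, `end_node`.
#' @param points data.frame with columns `segment_id`, `x`, `y`, `z`,
#'   `radius`, rows ordered along each segment from its start node to its
#'   end node. Every segment needs at least two points and `radius > 0`.
#' @param voxel_size voxel edge length in micrometres of the raster the
#'   skeleton was derived from (metadata only), or `NA`.
#' @param origin length-3 world origin of that raster in micrometres.
#' @param provenance free-text provenance note.
#' @param tolerance maximum allowed distance (micrometres) between a
#'   segment's first/last point and its start/end node position. Foreign
#'   files may store rounded coordinates, hence configurable.
#' @param check if `FALSE`, skip invariant checks (internal use).
#'
#' @return An object of class `spatial_graph`.
#' @export
spatial_graph <- function(nodes, segments, points,
                          voxel_size = NA_real_, origin = c(0, 0, 0),
                          provenance = "", tolerance = 1e-6, check = TRUE) {
  nodes <- as.data.frame(nodes)[, c("id", "x", "y", "z")]
  segments <- as.data.frame(segments)[, c("id", "start_node", "end_node")]
  points <- as.data.frame(points)[, c("segment_id", "x", "y", "z", "radius")]
  nodes$id <- as.integer(nodes$id)
  segments$id <- as.integer(segments$id)
  segments$start_node <- as.integer(segments$start_node)
  segments$end_node <- as.integer(segments$end_node)
  points$segment_id <- as.integer(points$segment_id)
  rownames(nodes) <- rownames(segments) <- rownames(points) <- NULL
  g <- structure(list(nodes = nodes, segments = segments, points = points,
                      meta = list(voxel_size = voxel_size,
                                  origin = as.numeric(origin),
                                  provenance = provenance,
                                  tolerance = tolerance)),
                 class = "spatial_graph")
  if (check) assert_graph(g)
  g
}

# hard invariant checks; used by the constructor and the writers
assert_graph <- function(g) {
  nodes <- g$nodes; segments <- g$segments; points <- g$points
  if (anyDuplicated(nodes$id)) stop("duplicate node ids")
  if (anyDuplicated(segments$id)) stop("duplicate segment ids")
  if (!all(is.finite(as.matrix(nodes[, c("x", "y", "z")]))))
    stop("non-finite node coordinates")
  if (!all(is.finite(as.matrix(points[, c("x", "y", "z", "radius")]))))
    stop("non-finite point data")
  miss <- setdiff(c(segments$start_node, segments$end_node), nodes$id)
  if (length(miss))
    stop("segments reference unknown nodes: ", paste(miss, collapse = ", "))
  if (any(points$radius <= 0)) stop("non-positive point radius")
  cnt <- table(factor(points$segment_id, levels = segments$id))
  if (any(cnt < 2))
    stop("segments with fewer than 2 points: ",
         paste(segments$id[cnt < 2], collapse = ", "))
  tol <- g$meta$tolerance
  sp <- split(seq_len(nrow(points)), points$segment_id)
  nid <- match(segments$start_node, nodes$id)
  nid2 <- match(segments$end_node, nodes$id)
  for (k in seq_len(nrow(segments))) {
    rows <- sp[[as.character(segments$id[k])]]
    p1 <- as.numeric(points[rows[1], c("x", "y", "z")])
    p2 <- as.numeric(points[rows[length(rows)], c("x", "y", "z")])
    a <- as.numeric(nodes[nid[k], c("x", "y", "z")])
    b <- as.numeric(nodes[nid2[k], c("x", "y", "z")])
    if (sqrt(sum((p1 - a)^2)) > tol || sqrt(sum((p2 - b)^2)) > tol)
      stop("segment ", segments$id[k],
           ": endpoint does not coincide with its node within tolerance")
    d <- diff(as.matrix(points[rows, c("x", "y", "z")]))
    if (any(rowSums(d^2) == 0))
      stop("segment ", segments$id[k], ": consecutive duplicate points")
  }
  invisible(g)
}

#' @export
print.spatial_graph <- function(x, ...) {
  cat("spatial_graph:", nrow(x$nodes), "nodes,", nrow(x$segments),
      "segments,", nrow(x$points), "points\n")
  if (!is.na(x$meta$voxel_size))
    cat("  voxel size:", x$meta$voxel_size, "um\n")
  if (nzchar(x$meta$provenance))
    cat("  provenance:", x$meta$provenance, "\n")
  invisible(x)
}

# per-node degree (number of incident segments), named by node id
node_degrees <- function(g) {
  inc <- c(g$segments$start_node, g$segments$end_node)
  tab <- table(factor(inc, levels = g$nodes$id))
  setNames(as.integer(tab), g$nodes$id)
}

# list of point-row indices per segment, names = segment id
segment_point_rows <- function(g) {
  split(seq_len(nrow(g$points)), factor(g$points$segment_id,
                                        levels = g$segments$id))
}

# igraph view of the node/segment structure (undirected multigraph)
as_igraph_nodes <- function(g) {
  igraph::graph_from_data_frame(
    data.frame(from = as.character(g$segments$start_node),
               to = as.character(g$segments$end_node)),
    directed = FALSE,
    vertices = data.frame(name = as.character(g$nodes$id)))
}

#' Validate a spatial graph and report structural defects
#'
#' Reporting counterpart of the constructor's hard checks: never errors,
#' instead lists defects so that foreign files can be triaged.
#'
#' @param g a [spatial_graph].
#' @return A list with `defects` (data.frame of `kind`, `id`, `detail`),
#'   `n_components` and `n_cycles` (number of independent cycles,
#'   `E - V + C` on the node/segment graph).
#' @export
validate_graph <- function(g) {
  defects <- list()
  add <- function(kind, id, detail)
    defects[[length(defects) + 1L]] <<- data.frame(kind = kind, id = id,
                                                   detail = detail)
  deg <- node_degrees(g)
  for (id in names(deg)[deg == 0])
    add("orphan node", as.integer(id), "node with no incident segments")
  bad <- unique(g$points$segment_id[g$points$radius <= 0])
  for (id in bad) add("non-positive radius", id, "point radius <= 0")
  dup <- g$segments$id[duplicated(g$segments$id)]
  for (id in dup) add("duplicate segment", id, "segment id repeated")
  tol <- g$meta$tolerance
  sp <- segment_point_rows(g)
  nidx <- match(g$segments$start_node, g$nodes$id)
  nidx2 <- match(g$segments$end_node, g$nodes$id)
  for (k in seq_len(nrow(g$segments))) {
    rows <- sp[[k]]
    if (length(rows) < 2) { add("too few points", g$segments$id[k],
                                "fewer than 2 centreline points"); next }
    p1 <- as.numeric(g$points[rows[1], c("x", "y", "z")])
    p2 <- as.numeric(g$points[rows[length(rows)], c("x", "y", "z")])
    a <- as.numeric(g$nodes[nidx[k], c("x", "y", "z")])
    b <- as.numeric(g$nodes[nidx2[k], c("x", "y", "z")])
    if (sqrt(sum((p1 - a)^2)) > tol || sqrt(sum((p2 - b)^2)) > tol)
      add("endpoint mismatch", g$segments$id[k],
          "segment endpoints do not coincide with node positions")
  }
  ig <- as_igraph_nodes(g)
  ncomp <- igraph::count_components(ig)
  ncyc <- nrow(g$segments) - nrow(g$nodes) + ncomp
  defects <- if (length(defects)) do.call(rbind, defects) else
    data.frame(kind = character(), id = integer(), detail = character())
  list(defects = defects, n_components = ncomp, n_cycles = ncyc)
}

#' Choose the root node of a vessel tree
#'
#' The physiological root of an arterial network is the cut end of the
#' feeding artery: a terminal (degree-1) node attached to the thickest
#' vessel. Direction of flow everywhere else is derived from this choice.
#'
#' @param g a [spatial_graph].
#' @param strategy `"max_radius_terminal"` picks the degree-1 node whose
#'   incident segment has the largest mean point radius (ties broken by the
#'   lowest node id); or pass an explicit node id via `node_id`.
#' @param node_id explicit node id (used when `strategy = "explicit"`).
#' @return A node id (integer).
#' @export
find_root <- function(g, strategy = c("max_radius_terminal", "explicit"),
                      node_id = NULL) {
  strategy <- match.arg(strategy)
  if (strategy == "explicit") {
    if (is.null(node_id) || !(node_id %in% g$nodes$id))
      stop("explicit root node id not present in graph")
    return(as.integer(node_id))
  }
  deg <- node_degrees(g)
  term <- as.integer(names(deg)[deg == 1])
  if (!length(term))
    stop("no terminal (degree-1) nodes: cannot pick a root on a cyclic graph")
  segrad <- tapply(g$points$radius, factor(g$points$segment_id,
                                           levels = g$segments$id), mean)
  best <- -Inf; best_id <- NA_integer_
  for (nd in sort(term)) {
    k <- which(g$segments$start_node == nd | g$segments$end_node == nd)[1]
    r <- segrad[[k]]
    if (r > best + 1e-12) { best <- r; best_id <- nd }
  }
  best_id
}

# Rooted orientation of a tree-shaped spatial graph.
# Returns, per segment (in g$segments order): near_node (closer to root),
# far_node, parent segment index (NA for root-adjacent segments), and a
# children list indexed by segment. Errors on cycles reachable from root.
root_tree <- function(g, root) {
  if (!(root %in% g$nodes$id)) stop("root node not in graph")
  ns <- nrow(g$segments)
  inc <- vector("list", nrow(g$nodes))
  sidx <- match(g$segments$start_node, g$nodes$id)
  eidx <- match(g$segments$end_node, g$nodes$id)
  for (k in seq_len(ns)) {
    inc[[sidx[k]]] <- c(inc[[sidx[k]]], k)
    inc[[eidx[k]]] <- c(inc[[eidx[k]]], k)
  }
  near <- integer(ns); far <- integer(ns); parent <- rep(NA_integer_, ns)
  visited_seg <- logical(ns)
  visited_node <- logical(nrow(g$nodes))
  rooti <- match(root, g$nodes$id)
  visited_node[rooti] <- TRUE
  queue <- list()
  for (k in inc[[rooti]]) queue[[length(queue) + 1L]] <- c(k, rooti, NA_integer_)
  head_i <- 1L
  order_out <- integer(0)
  while (head_i <= length(queue)) {
    it <- queue[[head_i]]; head_i <- head_i + 1L
    k <- it[1]; from <- it[2]; par <- it[3]
    if (visited_seg[k]) stop("cycle reachable from root: graph is not a tree")
    visited_seg[k] <- TRUE
    near[k] <- from
    to <- if (sidx[k] == from) eidx[k] else sidx[k]
    if (visited_node[to]) stop("cycle reachable from root: graph is not a tree")
    visited_node[to] <- TRUE
    far[k] <- to
    parent[k] <- par
    order_out <- c(order_out, k)
    for (k2 in inc[[to]]) if (k2 != k)
      queue[[length(queue) + 1L]] <- c(k2, to, k)
  }
  children <- vector("list", ns)
  for (k in seq_len(ns)) {
    p <- parent[k]
    if (!is.na(p) && visited_seg[k]) children[[p]] <- c(children[[p]], k)
  }
  list(root = root, in_component = visited_seg,
       near_node_idx = near, far_node_idx = far,
       parent = parent, children = children,
       bfs_order = order_out)
}
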