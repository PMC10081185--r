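# Shared fixtures and independent oracles. Everything here is deliberately
# naive (brute force / direct recursion) so package results are checked
# against code that shares no logic with the implementation.

# straight two-point single-segment graph
straight_segment <- function(r = 10, len = 100) {
  spatial_graph(
    nodes = data.frame(id = 1:2, x = 0, y = 0, z = c(0, len)),
    segments = data.frame(id = 1L, start_node = 1L, end_node = 2L),
    points = data.frame(segment_id = 1L, x = 0, y = 0, z = c(0, len),
                        radius = r))
}

# deterministic right-angle binary tree (H-tree), Murray radii; wide
# branching angles keep voxel skeleton junctions well separated
h_tree <- function(r0 = 8) {
  r1 <- r0 * 2^(-1 / 3); r2 <- r1 * 2^(-1 / 3)
  nodes <- data.frame(id = 1:8,
    x = c(0, 0, 60, -60, 60, 60, -60, -60),
    y = c(0, 0, 0, 0, 50, -50, 50, -50),
    z = c(0, 70, 70, 70, 70, 70, 70, 70))
  segs <- data.frame(id = 1:7, start_node = c(1, 2, 2, 3, 3, 4, 4),
                     end_node = c(2, 3, 4, 5, 6, 7, 8))
  mkpts <- function(sid, a, b, r)
    data.frame(segment_id = sid, x = c(nodes$x[a], nodes$x[b]),
               y = c(nodes$y[a], nodes$y[b]),
               z = c(nodes$z[a], nodes$z[b]), radius = r)
  pts <- rbind(mkpts(1, 1, 2, r0), mkpts(2, 2, 3, r1), mkpts(3, 2, 4, r1),
               mkpts(4, 3, 5, r2), mkpts(5, 3, 6, r2), mkpts(6, 4, 7, r2),
               mkpts(7, 4, 8, r2))
  spatial_graph(nodes, segs, pts)
}

# random tree on n segments by random attachment; passthrough chains
# appear via degree-2 nodes when a node is extended exactly once
random_tree_graph <- function(n_segments, seed) {
  set.seed(seed)
  nodes <- data.frame(id = 1L, x = 0, y = 0, z = 0)
  segs <- data.frame(id = integer(0), start_node = integer(0),
                     end_node = integer(0))
  for (k in seq_len(n_segments)) {
    from <- sample(nodes$id, 1)
    pos <- as.numeric(nodes[nodes$id == from, c("x", "y", "z")]) +
      stats::rnorm(3, 0, 50)
    nid <- max(nodes$id) + 1L
    nodes <- rbind(nodes, data.frame(id = nid, x = pos[1], y = pos[2],
                                     z = pos[3]))
    segs <- rbind(segs, data.frame(id = k, start_node = from,
                                   end_node = nid))
  }
  pts <- do.call(rbind, lapply(seq_len(nrow(segs)), function(k) {
    a <- segs$start_node[k]; b <- segs$end_node[k]
    data.frame(segment_id = segs$id[k],
               x = c(nodes$x[nodes$id == a], nodes$x[nodes$id == b]),
               y = c(nodes$y[nodes$id == a], nodes$y[nodes$id == b]),
               z = c(nodes$z[nodes$id == a], nodes$z[nodes$id == b]),
               radius = stats::runif(2, 1, 20))
  }))
  spatial_graph(nodes, segs, pts)
}

# independent Strahler/generation oracle by direct recursion on nodes
ordering_oracle <- function(g, root) {
  segs <- g$segments
  inc_of <- function(nd) {
    which(segs$start_node == nd | segs$end_node == nd)
  }
  strahler <- rep(NA_integer_, nrow(segs))
  generation <- rep(NA_integer_, nrow(segs))
  rec_strahler <- function(k, from) {
    to <- if (segs$start_node[k] == from) segs$end_node[k] else
      segs$start_node[k]
    ch <- setdiff(inc_of(to), k)
    if (!length(ch)) { strahler[k] <<- 1L; return(1L) }
    os <- vapply(ch, rec_strahler, 0L, from = to)
    mx <- max(os)
    strahler[k] <<- if (sum(os == mx) >= 2) mx + 1L else mx
    strahler[k]
  }
  rec_gen <- function(k, from, gen) {
    generation[k] <<- gen
    to <- if (segs$start_node[k] == from) segs$end_node[k] else
      segs$start_node[k]
    ch <- setdiff(inc_of(to), k)
    for (k2 in ch) rec_gen(k2, to, gen + (length(ch) >= 2))
  }
  for (k in inc_of(root)) {
    rec_strahler(k, root)
    rec_gen(k, root, 1L)
  }
  data.frame(segment_id = segs$id, strahler = strahler,
             generation = generation)
}

# brute-force nearest-foreground distance (micrometres)
edt_oracle <- function(mask) {
  d <- dim(mask$data)
  fg <- which(mask$data, arr.ind = TRUE)
  out <- array(NA_real_, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3]))
    out[i, j, k] <- sqrt(min((fg[, 1] - i)^2 + (fg[, 2] - j)^2 +
                               (fg[, 3] - k)^2)) * mask$voxel_size
  out
}

ramanujan_perimeter <- function(a, b)
  pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
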