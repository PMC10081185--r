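#' Strahler order and topological generation of a rooted vessel tree
#'
#' Strahler ordering is centripetal: the most distal segments are order 1;
#' where two children of equal order meet, the parent is one order higher;
#' otherwise the parent takes the larger child order. At junctions with
#' more than two children the standard generalisation applies: the parent
#' order increments iff at least two children attain the maximum.
#' Topological generation is centrifugal: the root-adjacent segment is
#' generation 1 and every branching node (two or more children) increments
#' the label. Degree-2 passthrough nodes affect neither scheme, so both
#' orderings are invariant under segment subdivision.
#'
#' @param g a [spatial_graph] whose root component is a tree (cycles are
#'   an error, not silently broken).
#' @param root root node id (see [find_root()]).
#' @return An `ordering_result`: data.frame with `segment_id`, `strahler`,
#'   `generation` (NA for segments outside the root's component), plus the
#'   root id as an attribute.
#' @export
strahler_order <- function(g, root) {
  rt <- root_tree(g, root)
  ns <- nrow(g$segments)
  strahler <- rep(NA_integer_, ns)
  generation <- rep(NA_integer_, ns)
  # generations: walk down in BFS order
  for (k in rt$bfs_order) {
    p <- rt$parent[k]
    if (is.na(p)) generation[k] <- 1L
    else {
      siblings <- length(rt$children[[p]])
      generation[k] <- generation[p] + (siblings >= 2L)
    }
  }
  # strahler: walk up in reverse BFS order
  for (k in rev(rt$bfs_order)) {
    ch <- rt$children[[k]]
    if (!length(ch)) strahler[k] <- 1L
    else {
      os <- strahler[ch]
      mx <- max(os)
      strahler[k] <- if (sum(os == mx) >= 2L) mx + 1L else mx
    }
  }
  out <- data.frame(segment_id = g$segments$id, strahler = strahler,
                    generation = generation)
  structure(out, root = root, class = c("ordering_result", "data.frame"))
}

#' @rdname strahler_order
#' @export
topological_generation <- function(g, root) strahler_order(g, root)

#' Per-order segment counts
#'
#' Histogram of Strahler orders: the `N` against `O` table behind the
#' branching-ratio fit.
#'
#' @param ordering an `ordering_result` from [strahler_order()].
#' @return data.frame with `order` and `n`.
#' @export
order_counts <- function(ordering) {
  s <- ordering$strahler[!is.na(ordering$strahler)]
  if (!length(s)) return(data.frame(order = integer(0), n = integer(0)))
  tab <- table(factor(s, levels = seq_len(max(s))))
  data.frame(order = as.integer(names(tab)), n = as.integer(tab))
}
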