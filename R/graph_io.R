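#' Read a spatial graph from disk
#'
#' Two ASCII dialects are supported. The AmiraMesh SpatialGraph dialect
#' (`"amira_ascii"`) is the interchange format of the Amira family of tools:
#' a `# AmiraMesh 3D ASCII 2.0` header, `define VERTEX/EDGE/POINT` counts and
#' `@n` data blocks holding vertex coordinates, edge connectivity (0-based
#' vertex indices), per-edge point counts, point coordinates and a per-point
#' `thickness` scalar. The native tabular dialect (`"native_tabular"`) is
#' the package's own delimited format written by [write_spatial_graph()].
#' With `dialect = "auto"` the header line decides.
#'
#' @param path file path.
#' @param dialect `"auto"`, `"amira_ascii"` or `"native_tabular"`.
#' @param thickness_is one of `"radius"` (default) or `"diameter"`: how the
#'   Amira `thickness` attribute is interpreted. Halved when `"diameter"`.
#' @param tolerance endpoint/node coincidence tolerance passed to
#'   [spatial_graph()]; foreign files may store rounded coordinates.
#' @return A [spatial_graph].
#' @export
read_spatial_graph <- function(path,
                               dialect = c("auto", "amira_ascii",
                                           "native_tabular"),
                               thickness_is = c("radius", "diameter"),
                               tolerance = 1e-6) {
  dialect <- match.arg(dialect)
  thickness_is <- match.arg(thickness_is)
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  first <- lines[nzchar(trimws(lines))][1]
  if (dialect == "auto") {
    dialect <- if (grepl("AmiraMesh", first, fixed = TRUE)) "amira_ascii"
    else if (grepl("vasctree spatialgraph", first, fixed = TRUE)) "native_tabular"
    else stop("cannot auto-detect dialect: header is neither ",
              "'# AmiraMesh 3D ASCII 2.0' nor '# vasctree spatialgraph'")
  }
  if (dialect == "amira_ascii")
    read_amira_graph(lines, thickness_is, tolerance)
  else
    read_tabular_graph(lines, tolerance)
}

read_amira_graph <- function(lines, thickness_is, tolerance) {
  if (!grepl("AmiraMesh", lines[nzchar(trimws(lines))][1], fixed = TRUE))
    stop("not an AmiraMesh ASCII file (missing header)")
  getdef <- function(what) {
    m <- grep(paste0("^\\s*define\\s+", what, "\\s+"), lines, value = TRUE)
    if (!length(m)) stop("Amira parse error: missing 'define ", what, "'")
    as.integer(sub(paste0(".*define\\s+", what, "\\s+(\\d+).*"), "\\1", m[1]))
  }
  nv <- getdef("VERTEX"); ne <- getdef("EDGE"); np <- getdef("POINT")
  # map declared sections to their @ markers
  decl <- grep("@\\d+\\s*$", lines, value = TRUE)
  decl <- decl[!grepl("^\\s*@", decl)]
  marker_of <- function(pattern) {
    m <- decl[grepl(pattern, decl)]
    if (!length(m)) return(NA_integer_)
    as.integer(sub(".*@(\\d+)\\s*$", "\\1", m[1]))
  }
  m_vert <- marker_of("VertexCoordinates")
  m_conn <- marker_of("EdgeConnectivity")
  m_npts <- marker_of("NumEdgePoints")
  m_pts  <- marker_of("EdgePointCoordinates")
  m_thick <- marker_of("thickness|Thickness|Radius|radius")
  if (is.na(m_vert)) stop("Amira parse error: VERTEX section lacks VertexCoordinates")
  if (is.na(m_conn)) stop("Amira parse error: EDGE section lacks EdgeConnectivity")
  if (is.na(m_npts)) stop("Amira parse error: EDGE section lacks NumEdgePoints")
  if (is.na(m_pts)) stop("Amira parse error: POINT section lacks EdgePointCoordinates")
  if (is.na(m_thick)) stop("Amira parse error: missing radius attribute ",
                           "(no 'thickness' POINT section)")
  read_block <- function(marker, n_expect, ncol) {
    at <- grep(paste0("^\\s*@", marker, "\\s*$"), lines)
    if (!length(at)) stop("Amira parse error: data block @", marker, " missing")
    i <- at[1] + 1L
    vals <- numeric(0)
    while (i <= length(lines)) {
      ln <- trimws(lines[i])
      if (grepl("^@\\d+", ln)) break
      if (nzchar(ln)) vals <- c(vals, as.numeric(strsplit(ln, "\\s+")[[1]]))
      if (length(vals) >= n_expect * ncol) break
      i <- i + 1L
    }
    if (length(vals) < n_expect * ncol)
      stop("Amira parse error: block @", marker, " has ", length(vals),
           " values, expected ", n_expect * ncol)
    matrix(vals[seq_len(n_expect * ncol)], ncol = ncol, byrow = TRUE)
  }
  verts <- read_block(m_vert, nv, 3)
  conn <- read_block(m_conn, ne, 2)
  npts <- as.integer(read_block(m_npts, ne, 1))
  pts <- read_block(m_pts, np, 3)
  thick <- as.numeric(read_block(m_thick, np, 1))
  if (sum(npts) != np)
    stop("Amira parse error: NumEdgePoints sums to ", sum(npts),
         " but POINT count is ", np)
  if (any(conn < 0) || any(conn >= nv))
    stop("Amira parse error: EdgeConnectivity references vertex outside 0..",
         nv - 1)
  radius <- if (thickness_is == "diameter") thick / 2 else thick
  nodes <- data.frame(id = seq_len(nv), x = verts[, 1], y = verts[, 2],
                      z = verts[, 3])
  segments <- data.frame(id = seq_len(ne), start_node = conn[, 1] + 1L,
                         end_node = conn[, 2] + 1L)
  points <- data.frame(segment_id = rep(seq_len(ne), npts),
                       x = pts[, 1], y = pts[, 2], z = pts[, 3],
                       radius = radius)
  spatial_graph(nodes, segments, points, tolerance = tolerance,
                provenance = "amira_ascii import")
}

read_tabular_graph <- function(lines, tolerance) {
  meta <- list(voxel_size = NA_real_, origin = c(0, 0, 0), provenance = "")
  sec <- NULL
  nodes_l <- segs_l <- pts_l <- character(0)
  for (ln in lines) {
    t <- trimws(ln)
    if (!nzchar(t)) next
    if (startsWith(t, "#")) {
      body <- trimws(sub("^#", "", t))
      if (grepl("^NODES", body)) sec <- "nodes"
      else if (grepl("^SEGMENTS", body)) sec <- "segments"
      else if (grepl("^POINTS", body)) sec <- "points"
      else if (grepl("^voxel_size", body))
        meta$voxel_size <- suppressWarnings(
          as.numeric(strsplit(body, "\\s+")[[1]][2]))
      else if (grepl("^origin", body))
        meta$origin <- as.numeric(strsplit(body, "\\s+")[[1]][2:4])
      else if (grepl("^provenance", body))
        meta$provenance <- sub("^provenance\\s*", "", body)
      next
    }
    if (is.null(sec)) next
    if (sec == "nodes") nodes_l <- c(nodes_l, t)
    else if (sec == "segments") segs_l <- c(segs_l, t)
    else pts_l <- c(pts_l, t)
  }
  parse_tab <- function(x, what, cols) {
    if (length(x) < 2) stop("tabular parse error: section ", what, " empty")
    df <- read.table(text = x, header = TRUE, sep = "\t")
    if (!all(cols %in% names(df)))
      stop("tabular parse error: section ", what, " lacks columns ",
           paste(setdiff(cols, names(df)), collapse = ", "))
    df
  }
  nodes <- parse_tab(nodes_l, "NODES", c("id", "x", "y", "z"))
  segments <- parse_tab(segs_l, "SEGMENTS", c("id", "start_node", "end_node"))
  points <- parse_tab(pts_l, "POINTS",
                      c("segment_id", "ordinal", "x", "y", "z", "radius"))
  points <- points[order(match(points$segment_id, segments$id),
                         points$ordinal), ]
  spatial_graph(nodes, segments, points,
                voxel_size = meta$voxel_size, origin = meta$origin,
                provenance = meta$provenance, tolerance = tolerance)
}

#' Write a spatial graph to disk
#'
#' @param g a [spatial_graph].
#' @param path output file path.
#' @param dialect `"native_tabular"` (two delimited tables: nodes, then
#'   points keyed by segment id and ordinal) or `"amira_ascii"`.
#' @return `path`, invisibly.
#' @export
write_spatial_graph <- function(g, path,
                                dialect = c("native_tabular", "amira_ascii")) {
  dialect <- match.arg(dialect)
  assert_graph(g)
  if (dialect == "amira_ascii") write_amira_graph(g, path)
  else write_tabular_graph(g, path)
  invisible(path)
}

fmt_num <- function(x) formatC(x, digits = 17, format = "g")

write_tabular_graph <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vasctree spatialgraph v1",
               paste("# voxel_size", fmt_num(g$meta$voxel_size)),
               paste("# origin", paste(fmt_num(g$meta$origin), collapse = " ")),
               paste("# provenance", g$meta$provenance),
               "# NODES"), con)
  writeLines("id\tx\ty\tz", con)
  writeLines(paste(g$nodes$id, fmt_num(g$nodes$x), fmt_num(g$nodes$y),
                   fmt_num(g$nodes$z), sep = "\t"), con)
  writeLines(c("# SEGMENTS", "id\tstart_node\tend_node"), con)
  writeLines(paste(g$segments$id, g$segments$start_node, g$segments$end_node,
                   sep = "\t"), con)
  writeLines(c("# POINTS", "segment_id\tordinal\tx\ty\tz\tradius"), con)
  ord <- sequence(tabulate(factor(g$points$segment_id,
                                  levels = g$segments$id)))
  writeLines(paste(g$points$segment_id, ord, fmt_num(g$points$x),
                   fmt_num(g$points$y), fmt_num(g$points$z),
                   fmt_num(g$points$radius), sep = "\t"), con)
}

write_amira_graph <- function(g, path) {
  nv <- nrow(g$nodes); ne <- nrow(g$segments); np <- nrow(g$points)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# AmiraMesh 3D ASCII 2.0", "",
               paste("define VERTEX", nv),
               paste("define EDGE", ne),
               paste("define POINT", np), "",
               "Parameters {", "    ContentType \"HxSpatialGraph\"", "}", "",
               "VERTEX { float[3] VertexCoordinates } @1",
               "EDGE { int[2] EdgeConnectivity } @2",
               "EDGE { int NumEdgePoints } @3",
               "POINT { float[3] EdgePointCoordinates } @4",
               "POINT { float thickness } @5", ""), con)
  writeLines("@1", con)
  writeLines(paste(fmt_num(g$nodes$x), fmt_num(g$nodes$y), fmt_num(g$nodes$z)),
             con)
  writeLines(c("", "@2"), con)
  s0 <- match(g$segments$start_node, g$nodes$id) - 1L
  e0 <- match(g$segments$end_node, g$nodes$id) - 1L
  writeLines(paste(s0, e0), con)
  writeLines(c("", "@3"), con)
  writeLines(as.character(tabulate(factor(g$points$segment_id,
                                          levels = g$segments$id))), con)
  writeLines(c("", "@4"), con)
  writeLines(paste(fmt_num(g$points$x), fmt_num(g$points$y),
                   fmt_num(g$points$z)), con)
  writeLines(c("", "@5"), con)
  writeLines(fmt_num(g$points$radius), con)
}
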