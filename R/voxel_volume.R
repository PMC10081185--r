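#' Construct a voxel volume
#'
#' An isotropic 3D raster: scalar intensities, a binary mask, or integer
#' zone labels. Data are stored as a base R array indexed `[x, y, z]`
#' (1-based); the world coordinate of the centre of voxel `(i, j, k)` is
#' `origin + (c(i, j, k) - 1) * voxel_size`, in micrometres.
#'
#' @param data a 3D array (a matrix is promoted to a single-slice volume).
#' @param voxel_size voxel edge length in micrometres (> 0, isotropic).
#' @param origin length-3 world position of the first voxel centre.
#' @return An object of class `voxel_volume`.
#' @export
voxel_volume <- function(data, voxel_size, origin = c(0, 0, 0)) {
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1L))
  if (length(dim(data)) != 3) stop("data must be a 3D array")
  if (!length(data)) stop("empty volume")
  if (!is.numeric(voxel_size) || voxel_size <= 0)
    stop("voxel_size must be > 0")
  structure(list(data = data, voxel_size = voxel_size,
                 origin = as.numeric(origin)),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  cat("voxel_volume:", paste(dim(x$data), collapse = " x "),
      "voxels at", x$voxel_size, "um\n")
  invisible(x)
}

# world coordinate -> fractional 0-based voxel index
world_to_index <- function(vol, xyz) {
  sweep(xyz, 2, vol$origin) / vol$voxel_size
}

same_grid <- function(a, b) {
  identical(dim(a$data), dim(b$data)) &&
    isTRUE(all.equal(a$voxel_size, b$voxel_size)) &&
    isTRUE(all.equal(a$origin, b$origin))
}

#' Write a volume to disk (multi-page TIFF or ASCII NRRD)
#'
#' TIFF stores one z-slice per page as 32-bit float; NRRD is written with
#' ASCII encoding so files stay plain text. Voxel size and origin are
#' carried in the NRRD header (`spacings`, `axis mins`); TIFF cannot carry
#' them, so supply them again when reading.
#'
#' @param vol a [voxel_volume].
#' @param path output path; format chosen by extension (`.tif`/`.tiff` or
#'   `.nrrd`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    slices <- lapply(seq_len(dim(vol$data)[3]),
                     function(k) t(vol$data[, , k]))
    tiff::writeTIFF(slices, path, bits.per.sample = 32L)
  } else if (ext == "nrrd") {
    d <- dim(vol$data)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("NRRD0004", "type: double", "dimension: 3",
                 paste("sizes:", d[1], d[2], d[3]),
                 paste("spacings:", vol$voxel_size, vol$voxel_size,
                       vol$voxel_size),
                 paste("axis mins:", vol$origin[1], vol$origin[2],
                       vol$origin[3]),
                 "encoding: ascii", ""), con)
    writeLines(fmt_num(as.vector(vol$data)), con)
  } else stop("unsupported volume format: .", ext)
  invisible(path)
}

#' Read a volume written by [write_volume()]
#'
#' @param path input path (`.tif`/`.tiff` or `.nrrd`).
#' @param voxel_size,origin grid metadata, required for TIFF (which cannot
#'   store them); ignored for NRRD.
#' @return A [voxel_volume].
#' @export
read_volume <- function(path, voxel_size = 1, origin = c(0, 0, 0)) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    slices <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(slices)) slices <- list(slices)
    arr <- array(0, dim = c(ncol(slices[[1]]), nrow(slices[[1]]),
                            length(slices)))
    for (k in seq_along(slices)) arr[, , k] <- t(slices[[k]])
    voxel_volume(arr, voxel_size, origin)
  } else if (ext == "nrrd") {
    lines <- readLines(path, warn = FALSE)
    blank <- which(!nzchar(trimws(lines)))[1]
    hdr <- lines[seq_len(blank - 1)]
    getf <- function(key) {
      m <- grep(paste0("^", key, ":"), hdr, value = TRUE)
      if (!length(m)) return(NULL)
      strsplit(trimws(sub(paste0("^", key, ":"), "", m[1])), "\\s+")[[1]]
    }
    sizes <- as.integer(getf("sizes"))
    sp <- as.numeric(getf("spacings"))
    org <- getf("axis mins")
    org <- if (is.null(org)) c(0, 0, 0) else as.numeric(org)
    vals <- as.numeric(unlist(strsplit(trimws(
      lines[(blank + 1):length(lines)]), "\\s+")))
    vals <- vals[!is.na(vals)]
    voxel_volume(array(vals, dim = sizes), sp[1], org)
  } else stop("unsupported volume format: .", ext)
}
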