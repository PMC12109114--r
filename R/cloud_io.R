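#' Write a point cloud to PLY, PCD or XYZ
#'
#' The format is chosen by file extension: `.ply` (ASCII by default, or
#' binary little-endian with `binary = TRUE`), `.pcd` (ASCII) or `.xyz`
#' (whitespace-separated text).
#'
#' @param cloud a [point_cloud()].
#' @param path output file path.
#' @param binary write binary little-endian PLY (ignored for other
#'   formats).
#' @return `path`, invisibly.
#' @export
write_point_cloud <- function(cloud, path, binary = FALSE) {
  p <- as_point_matrix(cloud)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    ply = write_ply(p, path, binary),
    pcd = write_pcd(p, path),
    xyz = utils::write.table(format(p, digits = 9, trim = TRUE,
                                    scientific = FALSE),
                             path, row.names = FALSE, col.names = FALSE,
                             quote = FALSE),
    stop("unsupported point cloud extension: .", ext)
  )
  invisible(path)
}

write_ply <- function(p, path, binary) {
  fmt <- if (binary) "binary_little_endian" else "ascii"
  hdr <- c("ply", paste("format", fmt, "1.0"),
           paste("element vertex", nrow(p)),
           "property float x", "property float y", "property float z",
           "end_header")
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con, sep = "\n")
    writeBin(as.numeric(t(p)), con, size = 4L, endian = "little")
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    utils::write.table(format(p, digits = 9, trim = TRUE,
                              scientific = FALSE),
                       con, row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  }
}

write_pcd <- function(p, path) {
  hdr <- c("# .PCD v0.7 - Point Cloud Data file format",
           "VERSION 0.7", "FIELDS x y z", "SIZE 4 4 4", "TYPE F F F",
           "COUNT 1 1 1", paste("WIDTH", nrow(p)), "HEIGHT 1",
           "VIEWPOINT 0 0 0 1 0 0 0", paste("POINTS", nrow(p)),
           "DATA ascii")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(format(p, digits = 9, trim = TRUE,
                            scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
}

#' Read a point cloud from PLY, PCD or XYZ
#'
#' Supports the dialects written by [write_point_cloud()]: ASCII and
#' binary little-endian PLY with float x/y/z vertices, ASCII PCD, and XYZ
#' text.
#'
#' @param path input file path.
#' @param source_plane tag for the returned cloud.
#' @return A [point_cloud()].
#' @export
read_point_cloud <- function(path, source_plane = "merged") {
  ext <- tolower(tools::file_ext(path))
  p <- switch(ext,
    ply = read_ply(path),
    pcd = read_pcd(path),
    xyz = as.matrix(utils::read.table(path)),
    stop("unsupported point cloud extension: .", ext)
  )
  point_cloud(p, source_plane)
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character(0)
  repeat {
    line <- readLines(con, 1L)
    hdr <- c(hdr, line)
    if (identical(line, "end_header")) break
    if (length(hdr) > 100L) stop("malformed PLY header")
  }
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", hdr, value = TRUE)))
  binary <- any(grepl("binary_little_endian", hdr))
  if (binary) {
    v <- readBin(con, "numeric", 3L * nv, size = 4L, endian = "little")
    matrix(v, ncol = 3, byrow = TRUE)
  } else {
    m <- utils::read.table(path, skip = length(hdr), nrows = nv)
    as.matrix(m[, 1:3])
  }
}

read_pcd <- function(path) {
  lines <- readLines(path)
  start <- grep("^DATA", lines)
  if (grepl("ascii", lines[start]) != TRUE)
    stop("only ASCII PCD files are supported")
  m <- utils::read.table(text = lines[-seq_len(start)])
  as.matrix(m[, 1:3])
}
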