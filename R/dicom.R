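## Minimal single-frame CT DICOM series writer/reader.
## Dialect: Explicit VR Little Endian (1.2.840.10008.1.2.1), one file per
## axial slice, monotone ImagePositionPatient, unsigned 16-bit pixels with
## RescaleSlope/Intercept carrying the HU mapping. This is the simplest
## dialect conforming readers accept; multi-frame/compressed syntaxes and
## non-axial orientations are out of scope.

ct_sop_class_uid <- "1.2.840.10008.5.1.4.1.1.2"
explicit_vr_le_uid <- "1.2.840.10008.1.2.1"
impl_class_uid <- "1.2.826.0.1.3680043.9.7431.1"
uid_root <- "1.2.826.0.1.3680043.9.7431"

uint16_le <- function(v) {
  v <- as.integer(v)
  as.raw(c(rbind(v %% 256L, v %/% 256L)))
}

uint32_le <- function(v) {
  v <- as.numeric(v)
  as.raw(c(v %% 256, (v %/% 256) %% 256, (v %/% 65536) %% 256,
           (v %/% 16777216) %% 256))
}

# one data element; value padded to even length (strings with space,
# UIDs with NUL, binary already even)
dcm_element <- function(group, element, vr, value) {
  if (vr == "US") value <- uint16_le(value)
  if (is.character(value)) {
    value <- charToRaw(paste(value, collapse = "\\"))
    if (length(value) %% 2L == 1L)
      value <- c(value, if (vr == "UI") as.raw(0L) else charToRaw(" "))
  }
  stopifnot(is.raw(value))
  hdr <- c(uint16_le(group), uint16_le(element), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    hdr <- c(hdr, as.raw(c(0L, 0L)), uint32_le(length(value)))
  } else {
    hdr <- c(hdr, uint16_le(length(value)))
  }
  c(hdr, value)
}

dcm_ds <- function(x) paste(sprintf("%.10g", x), collapse = "\\")

#' Write a voxel volume as a DICOM CT series
#'
#' One Explicit-VR-little-endian single-frame CT file per axial slice, with
#' pixel spacing, slice positions and rescale slope/intercept set so that a
#' conforming reader recovers the HU grid exactly: pixels are stored as
#' `HU + 1024` in unsigned 16 bits with `RescaleSlope 1` and
#' `RescaleIntercept -1024`. HU values must therefore be integer-valued and
#' within `[-1024, 30000]`.
#'
#' @param volume a [voxel_volume()].
#' @param directory output directory, created if missing.
#' @return Character vector of the written file paths (one per slice, in
#'   slice order), invisibly.
#' @export
write_dicom_series <- function(volume, directory) {
  stopifnot(inherits(volume, "voxel_volume"))
  n <- volume$shape
  if (any(n < 1L)) stop("volume is empty")
  hu <- volume$hu
  if (any(hu != round(hu)))
    stop("HU values must be integer-valued for exact DICOM round-trip")
  if (min(hu) < -1024 || max(hu) > 30000)
    stop("HU values outside the representable range [-1024, 30000]")
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create directory: ", directory)
  series_uid <- paste0(uid_root, ".1.", abs(sum(n)) + 7L)
  study_uid <- paste0(uid_root, ".2.", abs(sum(n)) + 7L)
  sx <- volume$spacing_mm[1]; sy <- volume$spacing_mm[2]
  sz <- volume$spacing_mm[3]
  files <- character(n[3])
  for (k in seq_len(n[3])) {
    z <- volume$origin_mm[3] + (k - 1) * sz
    sop_uid <- paste0(series_uid, ".", k)
    raw_px <- as.integer(hu[, , k]) + 1024L   # column index (x) fastest
    raw_px[raw_px > 32767L] <- raw_px[raw_px > 32767L] - 65536L
    px <- writeBin(raw_px, raw(), size = 2L, endian = "little")
    meta <- c(
      dcm_element(0x0002, 0x0001, "OB", as.raw(c(0L, 1L))),
      dcm_element(0x0002, 0x0002, "UI", ct_sop_class_uid),
      dcm_element(0x0002, 0x0003, "UI", sop_uid),
      dcm_element(0x0002, 0x0010, "UI", explicit_vr_le_uid),
      dcm_element(0x0002, 0x0012, "UI", impl_class_uid)
    )
    body <- c(
      dcm_element(0x0008, 0x0016, "UI", ct_sop_class_uid),
      dcm_element(0x0008, 0x0018, "UI", sop_uid),
      dcm_element(0x0008, 0x0020, "DA", "20260101"),
      dcm_element(0x0008, 0x0060, "CS", "CT"),
      dcm_element(0x0010, 0x0010, "PN", "PHANTOM^SYNTHETIC"),
      dcm_element(0x0010, 0x0020, "LO", "CT2SKIN"),
      dcm_element(0x0018, 0x0050, "DS", dcm_ds(sz)),
      dcm_element(0x0020, 0x000D, "UI", study_uid),
      dcm_element(0x0020, 0x000E, "UI", series_uid),
      dcm_element(0x0020, 0x0011, "IS", "1"),
      dcm_element(0x0020, 0x0013, "IS", as.character(k)),
      dcm_element(0x0020, 0x0032, "DS",
                  dcm_ds(c(volume$origin_mm[1], volume$origin_mm[2], z))),
      dcm_element(0x0020, 0x0037, "DS", dcm_ds(c(1, 0, 0, 0, 1, 0))),
      dcm_element(0x0028, 0x0002, "US", 1L),
      dcm_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
      dcm_element(0x0028, 0x0010, "US", n[2]),          # Rows (y)
      dcm_element(0x0028, 0x0011, "US", n[1]),          # Columns (x)
      dcm_element(0x0028, 0x0030, "DS", dcm_ds(c(sy, sx))),
      dcm_element(0x0028, 0x0100, "US", 16L),
      dcm_element(0x0028, 0x0101, "US", 16L),
      dcm_element(0x0028, 0x0102, "US", 15L),
      dcm_element(0x0028, 0x0103, "US", 0L),
      dcm_element(0x0028, 0x1052, "DS", "-1024"),
      dcm_element(0x0028, 0x1053, "DS", "1"),
      dcm_element(0x7FE0, 0x0010, "OW", px)
    )
    meta <- c(dcm_element(0x0002, 0x0000, "UL", uint32_le(length(meta))),
              meta)
    path <- file.path(directory, sprintf("slice_%04d.dcm", k))
    con <- file(path, "wb")
    writeBin(c(raw(128L), charToRaw("DICM"), meta, body), con)
    close(con)
    files[k] <- path
  }
  invisible(files)
}

## --- reading -----------------------------------------------------------

# parse one explicit-VR-LE file into a list of the tags we need
parse_dicom_file <- function(path) {
  buf <- readBin(path, raw(), file.size(path))
  if (length(buf) < 140L ||
      rawToChar(buf[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", path)
  pos <- 133L
  out <- list()
  u16 <- function(i) as.integer(buf[i]) + 256L * as.integer(buf[i + 1L])
  u32 <- function(i) as.integer(buf[i]) + 256 * as.integer(buf[i + 1L]) +
    65536 * as.integer(buf[i + 2L]) + 16777216 * as.integer(buf[i + 3L])
  while (pos + 7L <= length(buf)) {
    group <- u16(pos); element <- u16(pos + 2L)
    vr <- rawToChar(buf[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr))
      stop("unsupported (implicit VR?) encoding in ", path)
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      len <- u32(pos + 8L)
      vstart <- pos + 12L
    } else {
      len <- u16(pos + 6L)
      vstart <- pos + 8L
    }
    if (vr == "SQ") stop("sequences are not supported: ", path)
    val <- buf[vstart:(vstart + len - 1L)]
    key <- sprintf("%04X,%04X", group, element)
    out[[key]] <- list(vr = vr, value = val)
    pos <- vstart + len
  }
  out
}

dcm_str <- function(el) {
  if (is.null(el)) return(NULL)
  sub(" +$", "", rawToChar(el$value[el$value != as.raw(0L)]))
}

dcm_num <- function(el) {
  s <- dcm_str(el)
  if (is.null(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

dcm_us <- function(el) {
  if (is.null(el)) return(NULL)
  readBin(el$value, "integer", length(el$value) / 2L, size = 2L,
          signed = FALSE, endian = "little")
}

#' Load a CT DICOM series (or NIfTI volume) into a voxel volume
#'
#' Reads every `.dcm` file in `path` (one single-frame axial CT series,
#' Explicit VR Little Endian), applies the rescale slope/intercept to
#' recover HU, orders slices by their world z position (not by filename),
#' and derives the slice spacing from the inter-slice distance. A file
#' ending in `.nii`/`.nii.gz` is read through the same contract via the
#' RNifti package when available.
#'
#' @param path directory containing the DICOM series, or a NIfTI file.
#' @return A [voxel_volume()].
#' @section Errors:
#' Mixed series, missing spacing tags, inconsistent slice geometry,
#' non-axial orientation (gantry tilt) and non-uniform slice gaps beyond
#' 1e-3 mm are rejected with descriptive errors rather than resampled.
#' @export
load_volume <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path)) return(load_nifti_volume(path))
  files <- list.files(path, pattern = "\\.dcm$", full.names = TRUE,
                      ignore.case = TRUE)
  if (length(files) == 0L)
    stop("no DICOM files found in: ", path)
  parsed <- lapply(files, parse_dicom_file)
  series <- vapply(parsed, function(p) dcm_str(p[["0020,000E"]]) %||% "",
                   "")
  if (length(unique(series)) != 1L)
    stop("directory contains more than one series")
  meta <- lapply(parsed, function(p) {
    ps <- dcm_num(p[["0028,0030"]])
    ipp <- dcm_num(p[["0020,0032"]])
    if (is.null(ps) || is.null(ipp))
      stop("missing PixelSpacing or ImagePositionPatient tag")
    iop <- dcm_num(p[["0020,0037"]])
    if (!is.null(iop) && max(abs(iop - c(1, 0, 0, 0, 1, 0))) > 1e-6)
      stop("non-axial image orientation (gantry tilt?) is not supported")
    list(rows = dcm_us(p[["0028,0010"]]), cols = dcm_us(p[["0028,0011"]]),
         ps = ps, ipp = ipp,
         slope = (dcm_num(p[["0028,1053"]]) %||% 1),
         intercept = (dcm_num(p[["0028,1052"]]) %||% 0),
         signed = (dcm_us(p[["0028,0103"]]) %||% 0L) == 1L)
  })
  rows <- unique(vapply(meta, `[[`, 0L, "rows"))
  cols <- unique(vapply(meta, `[[`, 0L, "cols"))
  ps <- unique(do.call(rbind, lapply(meta, `[[`, "ps")))
  if (length(rows) != 1L || length(cols) != 1L || nrow(ps) != 1L)
    stop("inconsistent slice dimensions or pixel spacing across the series")
  z <- vapply(meta, function(m) m$ipp[3], 0)
  ord <- order(z)
  z <- z[ord]
  if (length(z) > 1L) {
    gaps <- diff(z)
    if (any(gaps <= 0))
      stop("duplicate slice positions in series")
    if (max(gaps) - min(gaps) > 1e-3)
      stop("non-uniform slice gaps (range ",
           format(max(gaps) - min(gaps)), " mm) exceed 1e-3 mm")
    sz <- mean(gaps)
  } else {
    sz <- 1
  }
  nx <- cols; ny <- rows; nz <- length(files)
  hu <- array(0, dim = c(nx, ny, nz))
  for (j in seq_len(nz)) {
    p <- parsed[[ord[j]]]
    m <- meta[[ord[j]]]
    px <- p[["7FE0,0010"]]
    if (is.null(px)) stop("missing PixelData")
    v <- readBin(px$value, "integer", nx * ny, size = 2L,
                 signed = m$signed, endian = "little")
    if (!m$signed) v[v < 0L] <- v[v < 0L] + 65536L
    hu[, , j] <- m$slope * v + m$intercept
  }
  origin <- c(meta[[ord[1]]]$ipp[1:2], z[1])
  spacing <- c(ps[1, 2], ps[1, 1], sz)    # PixelSpacing is (row, col) = (y, x)
  voxel_volume(hu, spacing, origin)
}

load_nifti_volume <- function(path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("NIfTI input requires the RNifti package")
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) stop("only 3D NIfTI volumes are supported")
  hdr <- RNifti::niftiHeader(img)
  spacing <- hdr$pixdim[2:4]
  origin <- c(hdr$qoffset_x, hdr$qoffset_y, hdr$qoffset_z)
  voxel_volume(array(as.numeric(img), dim = dim(img)), spacing, origin)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
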