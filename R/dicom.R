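# Minimal DICOM series reader: single-frame, uncompressed, explicit-VR
# little-endian files (transfer syntax 1.2.840.10008.1.2.1). This covers
# exported axial CT series; compressed or implicit-VR files are rejected
# with a clear error naming the offending file.

EXPLICIT_VR_LE <- "1.2.840.10008.1.2.1"

read_uint <- function(raw, n) sum(as.numeric(raw[seq_len(n)]) * 256^(seq_len(n) - 1))

parse_dicom_file <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  sz <- file.info(path)$size
  buf <- readBin(con, "raw", n = sz)
  if (sz < 132 || rawToChar(buf[129:132]) != "DICM")
    stop_bpr("not a DICOM file (missing DICM magic): %s", path,
             class = "bpr_format_error")
  pos <- 133L
  tags <- list()
  long_vrs <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UT", "UN", "UC", "UR")
  while (pos + 8 <= sz + 1) {
    group <- read_uint(buf[pos:(pos + 1)], 2)
    element <- read_uint(buf[(pos + 2):(pos + 3)], 2)
    vr <- rawToChar(buf[(pos + 4):(pos + 5)])
    if (!grepl("^[A-Z]{2}$", vr))
      stop_bpr("unsupported transfer syntax (implicit VR?) in %s", path,
               class = "bpr_format_error")
    if (vr %in% long_vrs) {
      len <- read_uint(buf[(pos + 8):(pos + 11)], 4)
      pos <- pos + 12L
    } else {
      len <- read_uint(buf[(pos + 6):(pos + 7)], 2)
      pos <- pos + 8L
    }
    if (len == 4294967295)
      stop_bpr("undefined-length element (%04x,%04x) unsupported in %s",
               group, element, path, class = "bpr_format_error")
    key <- sprintf("%04x,%04x", group, element)
    value <- buf[seq_len(len) + pos - 1L]
    pos <- pos + as.integer(len)
    tags[[key]] <- list(vr = vr, value = value)
    if (key == "7fe0,0010") break
  }
  tags
}

dcm_string <- function(tags, key) {
  el <- tags[[key]]
  if (is.null(el)) return(NULL)
  trimws(gsub("\\x00", "", rawToChar(el$value), useBytes = TRUE))
}

dcm_numbers <- function(tags, key) {
  s <- dcm_string(tags, key)
  if (is.null(s) || !nzchar(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

dcm_uint16 <- function(tags, key) {
  el <- tags[[key]]
  if (is.null(el)) return(NULL)
  read_uint(el$value, 2)
}

# Read one uncompressed explicit-VR LE DICOM slice.
read_dicom_slice <- function(path) {
  tags <- parse_dicom_file(path)
  ts <- dcm_string(tags, "0002,0010")
  if (!is.null(ts) && ts != EXPLICIT_VR_LE)
    stop_bpr("unsupported transfer syntax %s in %s", ts, path,
             class = "bpr_format_error")
  rows <- dcm_uint16(tags, "0028,0010")
  cols <- dcm_uint16(tags, "0028,0011")
  bits <- dcm_uint16(tags, "0028,0100")
  signed <- identical(dcm_uint16(tags, "0028,0103"), 1)
  px <- tags[["7fe0,0010"]]
  if (is.null(rows) || is.null(cols) || is.null(px))
    stop_bpr("missing Rows/Columns/PixelData in %s", path,
             class = "bpr_format_error")
  if (!identical(bits, 16))
    stop_bpr("only 16-bit pixel data supported (got %s) in %s",
             as.character(bits), path, class = "bpr_format_error")
  vals <- readBin(px$value, "integer", n = rows * cols, size = 2L,
                  signed = signed, endian = "little")
  slope <- dcm_numbers(tags, "0028,1053")
  intercept <- dcm_numbers(tags, "0028,1052")
  if (!is.null(slope)) vals <- vals * slope
  if (!is.null(intercept)) vals <- vals + intercept
  # PixelData is row-major (rows of the image in sequence)
  pix <- t(matrix(vals, nrow = cols, ncol = rows))
  list(pixels = pix,
       series_uid = dcm_string(tags, "0020,000e"),
       position = dcm_numbers(tags, "0020,0032"),
       orientation = dcm_numbers(tags, "0020,0037"),
       pixel_spacing = dcm_numbers(tags, "0028,0030"))
}

#' Read an axial DICOM series directory as a volume
#'
#' Reads all files in `dir` (uncompressed explicit-VR little-endian,
#' single-frame), verifies they belong to one series, sorts slices by their
#' position along the slice normal, and returns the stack with axis 1
#' running inferior to superior.
#'
#' @param dir directory containing the series.
#' @param subject_id identifier for the resulting volume.
#' @return a `bpr_volume`.
#' @export
read_dicom_series <- function(dir, subject_id = basename(dir)) {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  assert_that(length(files) >= 1, "no files in DICOM directory %s", dir,
              class = "bpr_format_error")
  slices <- lapply(files, read_dicom_slice)
  uids <- unique(vapply(slices, function(s) s$series_uid %||% "", ""))
  if (length(uids) > 1)
    stop_bpr("directory %s mixes %d series UIDs: %s", dir, length(uids),
             paste(uids, collapse = ", "), class = "bpr_format_error")
  iop <- slices[[1]]$orientation %||% c(1, 0, 0, 0, 1, 0)
  normal <- c(iop[2] * iop[6] - iop[3] * iop[5],
              iop[3] * iop[4] - iop[1] * iop[6],
              iop[1] * iop[5] - iop[2] * iop[4])
  zpos <- vapply(slices, function(s) {
    p <- s$position %||% c(0, 0, 0)
    sum(p * normal)
  }, 0)
  ord <- order(zpos)           # ascending along +normal = inferior -> superior
  slices <- slices[ord]
  zpos <- zpos[ord]
  shp <- dim(slices[[1]]$pixels)
  same <- vapply(slices, function(s) identical(dim(s$pixels), shp), TRUE)
  if (!all(same))
    stop_bpr("inconsistent slice dimensions in %s (first offender: %s)",
             dir, files[ord][which(!same)[1]], class = "bpr_format_error")
  vox <- array(0, c(length(slices), shp[1], shp[2]))
  for (i in seq_along(slices)) vox[i, , ] <- slices[[i]]$pixels
  dz <- if (length(zpos) > 1) stats::median(diff(zpos)) else 1
  ps <- slices[[1]]$pixel_spacing %||% c(1, 1)
  as_volume(vox, spacing = c(abs(dz), ps[1], ps[2]), subject_id = subject_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
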