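# Minimal single-channel 32-bit float TIFF I/O for diffusivity grids.
#
# No TIFF package is available in the target library set, so the package
# carries a deliberately small writer/reader pair for exactly one layout:
# uncompressed, little-endian, one strip, SampleFormat = IEEE float,
# 32 bits/sample, 1 sample/pixel. Grids travel with a JSON lattice sidecar
# (origin, bin size in um, row-major, 0-based, y increasing downward), which
# is the authoritative georeferencing.

.tiff_tag <- function(id, type, count, value_raw) {
  # value_raw must be exactly 4 bytes (value fits inline for our tags)
  c(writeBin(as.integer(id), raw(), size = 2, endian = "little"),
    writeBin(as.integer(type), raw(), size = 2, endian = "little"),
    writeBin(as.integer(count), raw(), size = 4, endian = "little"),
    value_raw)
}
.u4 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")
.u2pad <- function(x) c(writeBin(as.integer(x), raw(), size = 2,
                                 endian = "little"), as.raw(c(0, 0)))

#' Write a numeric matrix as a 32-bit float grayscale TIFF
#'
#' Row 1 of the matrix becomes the top image row (y increasing downward).
#' A JSON lattice descriptor is written alongside as `<path>.json`.
#'
#' @param m numeric matrix.
#' @param path output path (`.tif`).
#' @param bin_size_um,origin_um lattice descriptor fields.
#' @param na_value value substituted for NA pixels (default NaN, the
#'   conventional masked-pixel encoding in float TIFFs).
#' @return `path`, invisibly.
#' @export
write_field_tiff <- function(m, path, bin_size_um = 0.4, origin_um = c(0, 0),
                             na_value = NaN) {
  stopifnot(is.matrix(m))
  nr <- nrow(m); nc <- ncol(m)
  m[is.na(m)] <- na_value
  pix <- writeBin(as.numeric(t(m)), raw(), size = 4, endian = "little")
  n_tags <- 10L
  ifd_offset <- 8L
  data_offset <- ifd_offset + 2L + n_tags * 12L + 4L
  tags <- c(
    .tiff_tag(256, 4, 1, .u4(nc)),                 # ImageWidth
    .tiff_tag(257, 4, 1, .u4(nr)),                 # ImageLength
    .tiff_tag(258, 3, 1, .u2pad(32)),              # BitsPerSample
    .tiff_tag(259, 3, 1, .u2pad(1)),               # Compression: none
    .tiff_tag(262, 3, 1, .u2pad(1)),               # Photometric: BlackIsZero
    .tiff_tag(273, 4, 1, .u4(data_offset)),        # StripOffsets
    .tiff_tag(277, 3, 1, .u2pad(1)),               # SamplesPerPixel
    .tiff_tag(278, 4, 1, .u4(nr)),                 # RowsPerStrip
    .tiff_tag(279, 4, 1, .u4(length(pix))),        # StripByteCounts
    .tiff_tag(339, 3, 1, .u2pad(3)))               # SampleFormat: IEEE float
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(c(charToRaw("II"), writeBin(42L, raw(), size = 2, endian = "little"),
             .u4(ifd_offset)), con)
  writeBin(writeBin(n_tags, raw(), size = 2, endian = "little"), con)
  writeBin(tags, con)
  writeBin(.u4(0), con)  # no next IFD
  writeBin(pix, con)
  jsonlite::write_json(
    list(schema = "smdmtools/lattice/v1", n_rows = nr, n_cols = nc,
         bin_size_um = bin_size_um, origin_um = origin_um,
         order = "row-major", index_base = 0, y_axis = "downward"),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a grayscale float TIFF written by [write_field_tiff()]
#'
#' Supports only the package's own layout (uncompressed little-endian
#' single-strip 32-bit float); anything else is rejected.
#'
#' @param path TIFF path.
#' @return numeric matrix (NaN pixels mapped back to NA).
#' @export
read_field_tiff <- function(path) {
  raw_all <- readBin(path, raw(), file.size(path))
  rd_u <- function(off, size) {
    readBin(raw_all[(off + 1):(off + size)], "integer", size = size,
            endian = "little", signed = size > 2)
  }
  if (rawToChar(raw_all[1:2]) != "II" || rd_u(2, 2) != 42L)
    stop_input("not a little-endian TIFF: ", path)
  ifd <- rd_u(4, 4)
  n_tags <- rd_u(ifd, 2)
  tags <- list()
  for (i in seq_len(n_tags)) {
    base <- ifd + 2L + (i - 1L) * 12L
    id <- rd_u(base, 2); type <- rd_u(base + 2, 2)
    val <- if (type == 3) rd_u(base + 8, 2) else rd_u(base + 8, 4)
    tags[[as.character(id)]] <- val
  }
  need <- function(id, default = NULL) tags[[as.character(id)]] %||% default
  if (need(259, 1) != 1 || need(339, 1) != 3 || need(258, 1) != 32)
    stop_input("unsupported TIFF layout (need uncompressed 32-bit float): ", path)
  nc <- need(256); nr <- need(257); off <- need(273); nbytes <- need(279)
  vals <- readBin(raw_all[(off + 1):(off + nbytes)], "numeric", n = nr * nc,
                  size = 4, endian = "little")
  vals[is.nan(vals)] <- NA_real_
  matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
}
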