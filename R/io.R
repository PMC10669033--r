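# Image readers/writers. Grayscale throughout; 8-bit PNG values v map to
# v / 127.5 - 1 so that the decoder's quantization lattice has bin width
# 2/255 (half-width delta = 1/255). A minimal NIfTI-1 reader covers .nii
# and .nii.gz volumes (no R NIfTI package is assumed); NIfTI writing is out
# of scope.

#' Read a grayscale image into \[-1, 1\]
#'
#' PNG: 8-bit values `v` map linearly to `v / 127.5 - 1` (RGB(A) inputs are
#' averaged to one channel). NIfTI (`.nii` / `.nii.gz`): the requested slice
#' of the volume is extracted and the whole volume is rescaled to \[-1, 1\]
#' by its global min/max (patient-wise normalization). Provenance needed to
#' invert the scaling is attached as attribute `"provenance"`.
#'
#' @param path File path (`.png`, `.nii`, `.nii.gz`).
#' @param slice Slice index along the third axis (NIfTI only). Default 1.
#' @return Numeric matrix in \[-1, 1\].
#' @export
read_image <- function(path, slice = 1L) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  lower <- tolower(path)
  if (grepl("\\.png$", lower)) {
    v <- png::readPNG(path)
    if (length(dim(v)) == 3L) v <- apply(v[, , seq_len(min(3, dim(v)[3])),
                                           drop = FALSE], c(1, 2), mean)
    img <- v * 2 - 1   # readPNG returns v/255 for 8-bit data
    attr(img, "provenance") <- list(source = "png", path = path,
                                    scale = c(0, 255))
    img
  } else if (grepl("\\.nii(\\.gz)?$", lower)) {
    vol <- read_nifti(path)
    if (slice < 1L || slice > dim(vol)[3])
      stop(sprintf("slice %d out of range 1..%d", slice, dim(vol)[3]))
    lo <- min(vol)
    hi <- max(vol)
    sl <- vol[, , slice]
    img <- if (hi > lo) 2 * (sl - lo) / (hi - lo) - 1 else sl * 0
    attr(img, "provenance") <- list(source = "nifti", path = path,
                                    slice = as.integer(slice),
                                    norm_range = c(lo, hi))
    img
  } else {
    stop(sprintf("unsupported image format: %s (PNG or NIfTI expected)", path))
  }
}

#' Write a \[-1, 1\] image as an 8-bit grayscale PNG
#'
#' Values map by `round((x + 1) * 127.5)`, clamped to 0..255.
#'
#' @param img Numeric matrix in (approximately) \[-1, 1\].
#' @param path Destination path.
#' @export
write_image <- function(img, path) {
  v <- round((clamp_unit(img) + 1) * 127.5)
  png::writePNG(v / 255, path)
  invisible(path)
}

# Minimal NIfTI-1 reader: single-file .nii (optionally gzipped), data types
# uint8 / int16 / int32 / float32 / float64, no scaling slope support beyond
# scl_slope/scl_inter.
read_nifti <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348)
  if (length(hdr) < 348) stop("truncated NIfTI header")
  rd <- function(what, n, size, offset, endian) {
    readBin(hdr[(offset + 1):length(hdr)], what, n = n, size = size,
            endian = endian)
  }
  endian <- "little"
  sizeof <- rd("integer", 1, 4, 0, endian)
  if (sizeof != 348L) {
    endian <- "big"
    if (rd("integer", 1, 4, 0, endian) != 348L) stop("not a NIfTI-1 file")
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("not a NIfTI-1 file (bad magic)")
  if (magic == "ni1") stop("two-file NIfTI (.hdr/.img) is not supported")
  dims <- rd("integer", 8, 2, 40, endian)
  ndim <- dims[1]
  if (ndim < 2) stop("NIfTI volume must have at least 2 dimensions")
  dd <- dims[2:(1 + max(ndim, 3))]
  dd[dd == 0 | is.na(dd)] <- 1L
  dd <- dd[1:3]
  datatype <- rd("integer", 1, 2, 70, endian)
  scl_slope <- rd("numeric", 1, 4, 112, endian)
  scl_inter <- rd("numeric", 1, 4, 116, endian)
  vox_offset <- rd("numeric", 1, 4, 108, endian)
  n <- prod(dd)
  skip <- max(vox_offset, 352) - 348
  if (skip > 0) readBin(con, "raw", skip)
  vals <- switch(as.character(datatype),
    "2" = as.numeric(readBin(con, "integer", n, size = 1, signed = FALSE,
                             endian = endian)),
    "4" = as.numeric(readBin(con, "integer", n, size = 2, endian = endian)),
    "8" = as.numeric(readBin(con, "integer", n, size = 4, endian = endian)),
    "16" = readBin(con, "numeric", n, size = 4, endian = endian),
    "64" = readBin(con, "numeric", n, size = 8, endian = endian),
    stop(sprintf("unsupported NIfTI datatype code %d", datatype)))
  if (length(vals) < n) stop("truncated NIfTI data section")
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  array(vals, dim = dd)
}
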