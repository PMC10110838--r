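## Volume I/O: multi-page TIFF, directory of numbered TIFF slices,
## NIfTI (.nii/.nii.gz), and raw binary + JSON sidecar. All formats use the
## (z, y, x) axis convention with z = 1 at the top of the volume; on-disk
## coordinates in sidecars and seed files are 0-based.

SUPPORTED_FORMATS <- c("tiff", "tiff_dir", "nifti", "raw")

detect_format <- function(path, format_hint = NULL) {
  if (!is.null(format_hint)) {
    hint <- match.arg(format_hint, SUPPORTED_FORMATS)
    return(hint)
  }
  if (dir.exists(path)) return("tiff_dir")
  lp <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lp)) return("nifti")
  if (grepl("\\.tiff?$", lp)) return("tiff")
  if (grepl("\\.raw$", lp)) return("raw")
  stop(sprintf("cannot infer volume format of '%s'; supported formats: %s",
               path, paste(SUPPORTED_FORMATS, collapse = ", ")))
}

sidecar_path <- function(path) paste0(path, ".meta.json")

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) return(NULL)
  jsonlite::read_json(sp, simplifyVector = TRUE)
}

write_sidecar <- function(path, meta) {
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
}

require_spacing <- function(meta, path) {
  if (is.null(meta) || is.null(meta$spacing_um))
    stop(sprintf("missing voxel size metadata for '%s': key 'spacing_um' not found", path))
  as.numeric(meta$spacing_um)
}

#' Load a 3D gray-value volume
#'
#' Reads a volume from multi-page TIFF, a directory of numbered 2D TIFF
#' slices, NIfTI (`.nii` / `.nii.gz`), or raw binary with a JSON sidecar.
#' Voxel spacing comes from the NIfTI header (`pixdim`, millimeters) or from
#' the sidecar file `<path>.meta.json` (key `spacing_um`) for the other
#' formats; a missing spacing is an error naming the missing key.
#'
#' @param path file (or, for slice stacks, directory) to read.
#' @param format_hint optional format name, one of `"tiff"`, `"tiff_dir"`,
#'   `"nifti"`, `"raw"`; by default inferred from the path.
#' @return A [gray_volume()].
#' @seealso [save_volume()], [load_mask()]
#' @export
load_volume <- function(path, format_hint = NULL) {
  fmt <- detect_format(path, format_hint)
  if (fmt != "tiff_dir" && !file.exists(path))
    stop(sprintf("cannot read '%s': file not found", path))
  switch(fmt,
    tiff = load_tiff(path),
    tiff_dir = load_tiff_dir(path),
    nifti = load_nifti(path),
    raw = load_raw(path))
}

#' Save a 3D volume
#'
#' Writes a [gray_volume()] or [binary_volume()] so that [load_volume()] /
#' [load_mask()] recover it. Binary volumes are stored as 8-bit 0/1.
#' Gray TIFF data are stored as 16-bit integers when all values are
#' integers in `[0, 65535]`, otherwise as 32-bit floats with an affine
#' rescaling recorded in the sidecar; NIfTI stores doubles; raw stores the
#' dtype named in its sidecar.
#'
#' @param vol a [gray_volume()] or [binary_volume()].
#' @param path destination file (for `"tiff_dir"`, a directory).
#' @param format_hint optional format name (see [load_volume()]); an
#'   unsupported name is an error listing the supported formats.
#' @return `path`, invisibly.
#' @export
save_volume <- function(vol, path, format_hint = NULL) {
  if (!inherits(vol, c("gray_volume", "binary_volume")))
    stop("`vol` must be a gray_volume or binary_volume")
  if (!is.null(format_hint) && !format_hint %in% SUPPORTED_FORMATS)
    stop(sprintf("unsupported format '%s'; supported formats: %s",
                 format_hint, paste(SUPPORTED_FORMATS, collapse = ", ")))
  fmt <- detect_format(path, format_hint)
  if (fmt != "tiff_dir" && !dir.exists(dirname(path)))
    stop(sprintf("parent directory '%s' does not exist", dirname(path)))
  binary <- inherits(vol, "binary_volume")
  spacing <- if (binary) NULL else vol$spacing_um
  switch(fmt,
    tiff = save_tiff(vol$data, path, spacing, binary),
    tiff_dir = save_tiff_dir(vol$data, path, spacing, binary),
    nifti = save_nifti(vol$data, path, spacing, binary),
    raw = save_raw(vol$data, path, spacing, binary))
  invisible(path)
}

#' Load a binary mask volume
#'
#' Like [load_volume()] but returns a [binary_volume()]; any nonzero voxel
#' maps to 1 (so masks stored as 0/255 load as 0/1).
#'
#' @inheritParams load_volume
#' @return A [binary_volume()].
#' @export
load_mask <- function(path, format_hint = NULL) {
  fmt <- detect_format(path, format_hint)
  if (fmt != "tiff_dir" && !file.exists(path))
    stop(sprintf("cannot read '%s': file not found", path))
  ## masks carry no spacing, so bypass the gray-volume spacing requirement
  dat <- switch(fmt,
    nifti = {
      img <- RNifti::readNifti(path)
      aperm(array(as.numeric(img), dim(img)), c(3L, 2L, 1L))
    },
    tiff = read_tiff_array(path)$arr,
    tiff_dir = read_tiff_dir_array(path)$arr,
    raw = read_raw_array(path)$arr)
  binary_volume(array(as.integer(dat != 0), dim(dat)))
}

## ---- TIFF ----

## slices along z; each slice is an (ny, nx) matrix
save_tiff_slices <- function(data, spacing, binary) {
  dm <- dim(data)
  meta <- list(axis_order = "zyx")
  if (!is.null(spacing)) meta$spacing_um <- spacing
  if (binary) {
    slices <- lapply(seq_len(dm[1L]), function(z) data[z, , , drop = TRUE] / 255)
    bits <- 8L
    meta$tiff_encoding <- list(kind = "uint8")
  } else if (all(data == round(data)) && min(data) >= 0 && max(data) <= 65535) {
    slices <- lapply(seq_len(dm[1L]), function(z) data[z, , , drop = TRUE] / 65535)
    bits <- 16L
    meta$tiff_encoding <- list(kind = "uint16")
  } else {
    lo <- min(data); hi <- max(data)
    scale <- if (hi > lo) hi - lo else 1
    slices <- lapply(seq_len(dm[1L]), function(z) (data[z, , , drop = TRUE] - lo) / scale)
    bits <- 32L
    meta$tiff_encoding <- list(kind = "float_scaled", offset = lo, scale = scale)
  }
  ## a 1x1xn volume yields scalar "slices"; keep them as 1x1 matrices
  slices <- lapply(slices, function(s) if (is.matrix(s)) s else matrix(s, dm[2L], dm[3L]))
  list(slices = slices, bits = bits, meta = meta)
}

## slices are read normalized to [0, 1]; the sidecar's encoding entry
## says how to map them back to gray values
decode_tiff_slices <- function(slices, meta) {
  arr <- array(0, c(length(slices), nrow(slices[[1L]]), ncol(slices[[1L]])))
  for (z in seq_along(slices)) arr[z, , ] <- slices[[z]]
  enc <- meta$tiff_encoding
  if (is.null(enc)) return(arr)
  switch(enc$kind,
         uint8 = round(arr * 255),
         uint16 = round(arr * 65535),
         float_scaled = arr * enc$scale + enc$offset,
         arr)
}

save_tiff <- function(data, path, spacing, binary) {
  enc <- save_tiff_slices(data, spacing, binary)
  tiff::writeTIFF(enc$slices, path, bits.per.sample = enc$bits)
  write_sidecar(path, enc$meta)
}

read_tiff_array <- function(path) {
  slices <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(slices)) slices <- list(slices)
  slices <- lapply(slices, function(s) if (is.matrix(s)) s else matrix(s, 1L, 1L))
  meta <- read_sidecar(path)
  list(arr = decode_tiff_slices(slices, if (is.null(meta)) list() else meta),
       meta = meta)
}

load_tiff <- function(path) {
  td <- read_tiff_array(path)
  gray_volume(td$arr, require_spacing(td$meta, path))
}

save_tiff_dir <- function(data, path, spacing, binary) {
  if (!dir.exists(path)) dir.create(path, recursive = FALSE)
  enc <- save_tiff_slices(data, spacing, binary)
  for (z in seq_along(enc$slices)) {
    tiff::writeTIFF(enc$slices[[z]],
                    file.path(path, sprintf("slice_%04d.tif", z - 1L)),
                    bits.per.sample = enc$bits)
  }
  write_sidecar(file.path(path, "volume"), enc$meta)
}

read_tiff_dir_array <- function(path) {
  files <- sort(list.files(path, pattern = "\\.tiff?$", full.names = TRUE))
  if (length(files) == 0L) stop(sprintf("no TIFF slices found in '%s'", path))
  slices <- lapply(files, function(f) {
    s <- tiff::readTIFF(f)
    if (is.matrix(s)) s else matrix(s, 1L, 1L)
  })
  meta <- read_sidecar(file.path(path, "volume"))
  list(arr = decode_tiff_slices(slices, if (is.null(meta)) list() else meta),
       meta = meta)
}

load_tiff_dir <- function(path) {
  td <- read_tiff_dir_array(path)
  gray_volume(td$arr, require_spacing(td$meta, file.path(path, "volume")))
}

## ---- NIfTI ----

save_nifti <- function(data, path, spacing, binary) {
  img <- aperm(data, c(3L, 2L, 1L))   # NIfTI stores x fastest
  if (binary) storage.mode(img) <- "integer"
  nim <- RNifti::asNifti(img)
  sp <- if (is.null(spacing)) 1000 else spacing
  nim <- RNifti::`pixdim<-`(nim, rep(sp / 1000, 3L))
  RNifti::writeNifti(nim, path, datatype = if (binary) "uint8" else "double")
}

load_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) stop(sprintf("'%s' is not a 3D NIfTI volume", path))
  spacing_mm <- RNifti::pixdim(img)[1L]
  if (!is.finite(spacing_mm) || spacing_mm <= 0)
    stop(sprintf("missing voxel size metadata for '%s': key 'spacing_um' (pixdim) not usable", path))
  gray_volume(aperm(array(as.numeric(img), dim(img)), c(3L, 2L, 1L)),
              spacing_mm * 1000)
}

## ---- raw + sidecar ----

RAW_DTYPES <- list(
  uint8   = list(what = "integer", size = 1L, signed = FALSE),
  int16   = list(what = "integer", size = 2L, signed = TRUE),
  int32   = list(what = "integer", size = 4L, signed = TRUE),
  float32 = list(what = "double",  size = 4L, signed = TRUE),
  float64 = list(what = "double",  size = 8L, signed = TRUE))

save_raw <- function(data, path, spacing, binary) {
  dtype <- if (binary) "uint8" else "float64"
  spec <- RAW_DTYPES[[dtype]]
  con <- file(path, "wb"); on.exit(close(con))
  vals <- as.vector(data)
  if (spec$what == "integer") {
    writeBin(as.integer(vals), con, size = spec$size, endian = "little")
  } else {
    writeBin(as.double(vals), con, size = spec$size, endian = "little")
  }
  meta <- list(dtype = dtype, shape = dim(data), axis_order = "zyx",
               endian = "little")
  if (!is.null(spacing)) meta$spacing_um <- spacing
  write_sidecar(path, meta)
}

read_raw_array <- function(path) {
  meta <- read_sidecar(path)
  if (is.null(meta))
    stop(sprintf("raw volume '%s' requires a sidecar '%s' declaring dtype, shape and spacing_um",
                 path, sidecar_path(path)))
  for (key in c("dtype", "shape"))
    if (is.null(meta[[key]]))
      stop(sprintf("sidecar for '%s' is missing key '%s'", path, key))
  spec <- RAW_DTYPES[[meta$dtype]]
  if (is.null(spec))
    stop(sprintf("unknown raw dtype '%s'; supported: %s", meta$dtype,
                 paste(names(RAW_DTYPES), collapse = ", ")))
  shape <- as.integer(meta$shape)
  n <- prod(shape)
  con <- file(path, "rb"); on.exit(close(con))
  vals <- readBin(con, what = spec$what, n = n, size = spec$size,
                  signed = spec$signed, endian = "little")
  if (length(vals) != n)
    stop(sprintf("raw file '%s' holds %d values but sidecar shape needs %d",
                 path, length(vals), n))
  list(arr = array(as.double(vals), shape), meta = meta)
}

load_raw <- function(path) {
  rd <- read_raw_array(path)
  gray_volume(rd$arr, require_spacing(rd$meta, path))
}
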