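# I/O for scalar images, label maps and vector fields.
#
# Two on-disk formats: NIfTI-1 (.nii / .nii.gz) through RNifti, and
# MetaImage (.mha, single-file, uncompressed, LOCAL data) through a small
# codec below -- the MetaImage header is a plain key = value text block
# followed by a raw array, with channels interleaved per voxel and the
# first index fastest. Only axis-aligned geometries (identity direction
# cosines) are accepted; vector fields carry 3 components in mm and are
# stored as 32-bit floats.

io_format <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) return("nifti")
  if (grepl("\\.mha$", path, ignore.case = TRUE)) return("mha")
  stop("unsupported image format (use .nii, .nii.gz or .mha): ", path,
       call. = FALSE)
}

check_identity_direction <- function(mat, path) {
  R <- mat[1:3, 1:3]
  sp <- diag(R)
  if (any(sp <= 0) || max(abs(R - diag(sp))) > 1e-6 * max(abs(sp)))
    stop("non-axis-aligned orientation in ", path,
         ": only identity direction cosines are supported", call. = FALSE)
  sp
}

nifti_write <- function(arr, grid, path, datatype) {
  img <- RNifti::asNifti(arr, datatype = datatype)
  # pixdim must be set through a reference before the xform, or writeNifti
  # falls back to unit voxels
  img <- RNifti::asNifti(img, reference = list(
    pixdim = c(-1, grid$spacing, 1, 1, 1, 1)))
  m <- diag(4)
  diag(m)[1:3] <- grid$spacing
  m[1:3, 4] <- grid$origin
  RNifti::`qform<-`(img, structure(m, code = 2L)) -> img
  RNifti::`sform<-`(img, structure(m, code = 2L)) -> img
  RNifti::writeNifti(img, path)
  invisible(path)
}

nifti_read <- function(path) {
  img <- RNifti::readNifti(path)
  x <- RNifti::xform(img)
  sp <- check_identity_direction(x, path)
  arr <- array(as.vector(as.array(img)), dim(img))   # drop nifti attributes
  list(arr = arr, spacing = as.numeric(sp), origin = as.numeric(x[1:3, 4]))
}

mha_type <- c(MET_UCHAR = "integer", MET_SHORT = "integer", MET_INT = "integer",
              MET_FLOAT = "double", MET_DOUBLE = "double")
mha_size <- c(MET_UCHAR = 1L, MET_SHORT = 2L, MET_INT = 4L,
              MET_FLOAT = 4L, MET_DOUBLE = 8L)

mha_write <- function(arr, grid, path, channels = 1L, element = "MET_FLOAT") {
  hdr <- c("ObjectType = Image",
           "NDims = 3",
           "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           "CompressedData = False",
           "TransformMatrix = 1 0 0 0 1 0 0 0 1",
           paste("Offset =", paste(grid$origin, collapse = " ")),
           paste("ElementSpacing =", paste(grid$spacing, collapse = " ")),
           paste("DimSize =", paste(grid$shape, collapse = " ")),
           paste("ElementNumberOfChannels =", channels),
           paste("ElementType =", element),
           "ElementDataFile = LOCAL")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  # interleave channels: disk order is (channel, i, j, k) with channel fastest
  if (channels > 1L) arr <- aperm(arr, c(4, 1, 2, 3))
  writeBin(as.vector(arr), con,
           size = mha_size[[element]],
           endian = "little")
  invisible(path)
}

mha_read <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L)
      stop("mha: header ended before ElementDataFile in ", path, call. = FALSE)
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  if (!identical(hdr[["ElementDataFile"]], "LOCAL"))
    stop("mha: only single-file LOCAL data is supported", call. = FALSE)
  if (identical(tolower(hdr[["CompressedData"]]), "true"))
    stop("mha: compressed data is not supported", call. = FALSE)
  num <- function(key, default = NULL) {
    if (is.null(hdr[[key]])) return(default)
    as.numeric(strsplit(hdr[[key]], "\\s+")[[1]])
  }
  shape <- as.integer(num("DimSize"))
  spacing <- num("ElementSpacing")
  if (is.null(spacing))
    stop("mha: missing ElementSpacing in ", path, call. = FALSE)
  origin <- num("Offset", c(0, 0, 0))
  tm <- num("TransformMatrix", c(1, 0, 0, 0, 1, 0, 0, 0, 1))
  if (max(abs(matrix(tm, 3, 3) - diag(3))) > 1e-6)
    stop("non-axis-aligned orientation in ", path,
         ": only identity direction cosines are supported", call. = FALSE)
  channels <- as.integer(num("ElementNumberOfChannels", 1))
  et <- hdr[["ElementType"]]
  if (is.null(et) || is.na(mha_size[et]))
    stop("mha: unsupported ElementType in ", path, call. = FALSE)
  n <- prod(shape) * channels
  raw <- readBin(con, what = mha_type[[et]], n = n, size = mha_size[[et]],
                 endian = "little")
  if (length(raw) != n)
    stop("mha: truncated data block in ", path, call. = FALSE)
  arr <- if (channels > 1L)
    aperm(array(raw, c(channels, shape)), c(2, 3, 4, 1))
  else
    array(raw, shape)
  list(arr = arr, spacing = spacing, origin = origin)
}

#' Write / read a 3-D scalar image
#'
#' @param image a [scalar_image()] (or [label_map()] for the label variants).
#' @param path file path ending in `.nii`, `.nii.gz` or `.mha`.
#' @return `read_image` returns a `scalar_image`; writers return the path,
#'   invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "scalar_image"))
  switch(io_format(path),
         nifti = nifti_write(image$values, image$grid, path, "double"),
         mha = mha_write(image$values, image$grid, path,
                         element = "MET_DOUBLE"))
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  r <- switch(io_format(path), nifti = nifti_read(path), mha = mha_read(path))
  if (length(dim(r$arr)) != 3L)
    stop("read_image: ", path, " is not a 3-D scalar image", call. = FALSE)
  scalar_image(grid3d(dim(r$arr), r$spacing, r$origin), r$arr)
}

#' @rdname write_image
#' @export
write_labels <- function(image, path) {
  stopifnot(inherits(image, "label_map"))
  switch(io_format(path),
         nifti = nifti_write(image$labels, image$grid, path, "int"),
         mha = mha_write(image$labels, image$grid, path, element = "MET_INT"))
}

#' @rdname write_image
#' @export
read_labels <- function(path) {
  r <- switch(io_format(path), nifti = nifti_read(path), mha = mha_read(path))
  if (length(dim(r$arr)) != 3L)
    stop("read_labels: ", path, " is not a 3-D label map", call. = FALSE)
  label_map(grid3d(dim(r$arr), r$spacing, r$origin), round(r$arr))
}

#' Write / read a displacement vector field
#'
#' Fields are stored as 3-component vector images in mm (pull-back
#' convention): a 5-D NIfTI volume (`nx x ny x nz x 1 x 3`) or a 3-channel
#' MetaImage, 32-bit floats. Reading anything that does not carry exactly 3
#' components per voxel is a `component count` error.
#'
#' @param field a [displacement_field()].
#' @param path file path ending in `.nii`, `.nii.gz` or `.mha`.
#' @return `read_field` returns a `displacement_field`; `write_field`
#'   returns the path, invisibly.
#' @export
write_field <- function(field, path) {
  stopifnot(inherits(field, "displacement_field"))
  switch(io_format(path),
         nifti = nifti_write(array(field$u, c(field$grid$shape, 1L, 3L)),
                             field$grid, path, "float"),
         mha = mha_write(field$u, field$grid, path, channels = 3L,
                         element = "MET_FLOAT"))
}

#' @rdname write_field
#' @export
read_field <- function(path) {
  r <- switch(io_format(path), nifti = nifti_read(path), mha = mha_read(path))
  d <- dim(r$arr)
  if (length(d) == 5L && d[4] == 1L) {
    r$arr <- array(r$arr, c(d[1:3], d[5]))
    d <- dim(r$arr)
  }
  if (length(d) != 4L || d[4] != 3L)
    stop("read_field: wrong component count in ", path,
         " (need 3 vector components per voxel)", call. = FALSE)
  displacement_field(grid3d(d[1:3], r$spacing, r$origin), r$arr)
}
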