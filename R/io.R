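#' Read a 3D volume from NIfTI or MetaImage
#'
#' Supports NIfTI-1 (`.nii`, `.nii.gz`) and MetaImage (`.mha`, `.mhd` with a
#' sidecar `.raw`). Spacing is taken from the stored affine/header; the
#' volume's mask flag is set automatically when every stored value is 0 or 1.
#' Only axis-aligned geometries are interpreted: the affine's rotation part is
#' reduced to its column norms (voxel spacing) and translation (origin).
#'
#' @param path file to read.
#' @return a [volume3d].
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    stop_propnet(sprintf("file not found: %s", path), "propnet_format_error")
  ext <- volume_format(path)
  parsed <- switch(ext,
    nifti = read_nifti_raw(path),
    meta  = read_metaimage(path),
    stop_propnet(sprintf("unsupported volume format: %s", path),
                 "propnet_format_error"))
  data <- parsed$data
  nd <- length(dim(data))
  if (nd != 3L)
    stop_propnet(sprintf("expected a 3D volume, got %dD", nd),
                 "propnet_dim_error")
  volume3d(data, spacing = parsed$spacing, origin = parsed$origin,
           is_mask = all(data %in% c(0, 1)))
}

#' Write a 3D volume to NIfTI or MetaImage
#'
#' The output format follows the file extension. Data are stored as 64-bit
#' floats so that read/write round-trips are bit-exact.
#'
#' @param v a [volume3d].
#' @param path output file (`.nii`, `.nii.gz`, `.mha`, or `.mhd`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  assert_volume(v)
  switch(volume_format(path),
    nifti = write_nifti_raw(v$data, v$spacing, v$origin, path),
    meta  = write_metaimage(v$data, v$spacing, v$origin, path),
    stop_propnet(sprintf("unsupported volume format: %s", path),
                 "propnet_format_error"))
  invisible(path)
}

volume_format <- function(path) {
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) return("nifti")
  if (grepl("\\.(mha|mhd)$", lower)) return("meta")
  "unknown"
}

read_nifti_raw <- function(path) {
  img <- RNifti::readNifti(path, internal = FALSE)
  data <- as.array(img)
  attributes(data) <- list(dim = dim(img))
  xf <- tryCatch(RNifti::xform(img), error = function(e) NULL)
  if (!is.null(xf) && isTRUE(attr(xf, "code") > 0)) {
    spacing <- sqrt(colSums(unclass(xf)[1:3, 1:3]^2))
    origin <- unclass(xf)[1:3, 4]
  } else {
    spacing <- RNifti::pixdim(img)[seq_len(min(3L, length(dim(img))))]
    origin <- c(0, 0, 0)
  }
  spacing[spacing == 0] <- 1
  list(data = data, spacing = abs(spacing[1:3]), origin = origin)
}

write_nifti_raw <- function(data, spacing, origin, path) {
  img <- RNifti::asNifti(data, datatype = "double")
  m <- diag(c(spacing, 1))
  m[1:3, 4] <- origin
  RNifti::sform(img) <- structure(m, code = 2L)
  RNifti::writeNifti(img, path)
}

# --- MetaImage (.mha / .mhd + .raw) -----------------------------------------
# The MetaImage header is a short list of "Key = value" ASCII lines followed by
# raw binary voxel data (inline for .mha, in a sidecar file for .mhd). No R
# package in this stack reads it, and the format is simple enough to support
# directly.

meta_types <- list(
  MET_DOUBLE = list(what = "double", size = 8L),
  MET_FLOAT  = list(what = "double", size = 4L),
  MET_UCHAR  = list(what = "integer", size = 1L, signed = FALSE),
  MET_CHAR   = list(what = "integer", size = 1L, signed = TRUE),
  MET_SHORT  = list(what = "integer", size = 2L, signed = TRUE),
  MET_USHORT = list(what = "integer", size = 2L, signed = FALSE),
  MET_INT    = list(what = "integer", size = 4L, signed = TRUE)
)

read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L)
      stop_propnet("MetaImage header has no ElementDataFile entry",
                   "propnet_format_error")
    kv <- regmatches(line, regexec("^\\s*([A-Za-z0-9]+)\\s*=\\s*(.*)$", line))[[1]]
    if (length(kv) != 3L)
      stop_propnet(sprintf("malformed MetaImage header line: %s", line),
                   "propnet_format_error")
    header[[kv[2]]] <- trimws(kv[3])
    if (kv[2] == "ElementDataFile") break
  }
  ndims <- as.integer(header$NDims %||% "3")
  dims <- as.integer(strsplit(header$DimSize, "\\s+")[[1]])
  if (length(dims) != ndims)
    stop_propnet("DimSize does not match NDims", "propnet_format_error")
  type <- meta_types[[header$ElementType %||% "MET_DOUBLE"]]
  if (is.null(type))
    stop_propnet(sprintf("unsupported MetaImage element type: %s",
                         header$ElementType), "propnet_format_error")
  if (identical(tolower(header$CompressedData %||% "false"), "true"))
    stop_propnet("compressed MetaImage data are not supported",
                 "propnet_format_error")
  endian <- if (identical(tolower(header$ByteOrderMSB %||% "false"), "true"))
    "big" else "little"
  n <- prod(dims)
  if (identical(header$ElementDataFile, "LOCAL")) {
    raw_con <- con
  } else {
    raw_path <- file.path(dirname(path), header$ElementDataFile)
    if (!file.exists(raw_path))
      stop_propnet(sprintf("MetaImage data file not found: %s", raw_path),
                   "propnet_format_error")
    raw_con <- file(raw_path, "rb")
    on.exit(close(raw_con), add = TRUE)
  }
  vals <- readBin(raw_con, what = type$what, n = n, size = type$size,
                  signed = type$signed %||% TRUE, endian = endian)
  if (length(vals) < n)
    stop_propnet("MetaImage data are truncated", "propnet_format_error")
  spacing <- as.numeric(strsplit(header$ElementSpacing %||%
                                   paste(rep("1", ndims), collapse = " "),
                                 "\\s+")[[1]])
  origin <- as.numeric(strsplit(header$Offset %||% header$Position %||%
                                  paste(rep("0", ndims), collapse = " "),
                                "\\s+")[[1]])
  list(data = array(as.double(vals), dim = dims),
       spacing = spacing, origin = origin)
}

write_metaimage <- function(data, spacing, origin, path) {
  local <- grepl("\\.mha$", tolower(path))
  data_file <- if (local) "LOCAL" else paste0(sub("\\.mhd$", "",
                                                  basename(path)), ".raw")
  header <- c(
    "ObjectType = Image",
    sprintf("NDims = %d", length(dim(data))),
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "ByteOrderMSB = False",
    "CompressedData = False",
    sprintf("TransformMatrix = %s",
            paste(as.integer(diag(length(dim(data)))), collapse = " ")),
    sprintf("Offset = %s", paste(format(origin, scientific = FALSE), collapse = " ")),
    sprintf("ElementSpacing = %s",
            paste(format(spacing, scientific = FALSE), collapse = " ")),
    sprintf("DimSize = %s", paste(dim(data), collapse = " ")),
    "ElementType = MET_DOUBLE",
    sprintf("ElementDataFile = %s", data_file)
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con)
  if (local) {
    writeBin(as.double(data), con, size = 8L, endian = "little")
  } else {
    raw_con <- file(file.path(dirname(path), data_file), "wb")
    on.exit(close(raw_con), add = TRUE)
    writeBin(as.double(data), raw_con, size = 8L, endian = "little")
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and write dense displacement fields
#'
#' Displacement fields are serialized as 4D NIfTI volumes whose last axis holds
#' the (ux, uy, uz) components, in voxel units of the network grid.
#'
#' @param field a [displacement_field].
#' @param path NIfTI file path.
#' @return `read_field` returns a [displacement_field]; `write_field` returns
#'   `path` invisibly.
#' @export
write_field <- function(field, path) {
  if (!inherits(field, "displacement_field"))
    stop_propnet("`field` must be a displacement_field", "propnet_type_error")
  img <- RNifti::asNifti(field$u, datatype = "double")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_field
#' @export
read_field <- function(path) {
  img <- RNifti::readNifti(path)
  data <- as.array(img)
  attributes(data) <- list(dim = dim(img))
  if (length(dim(data)) != 4L || dim(data)[4] != 3L)
    stop_propnet("a displacement field file must be 4D with 3 components",
                 "propnet_dim_error")
  displacement_field(data)
}
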