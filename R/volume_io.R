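#' CT volume container
#'
#' A minimal container for a 3D grid of integer Hounsfield-unit voxels with
#' voxel spacing (mm) and a physical origin. Values below the CT floor of
#' -2048 HU are clamped with a warning; such values occur as padding in some
#' scanner exports and carry no anatomical information.
#'
#' @param data 3D integer array of HU values.
#' @param spacing Numeric length-3, mm per voxel along (x, y, z); all > 0.
#' @param origin Numeric length-3, physical coordinate of voxel (1, 1, 1).
#' @return An object of class `ct_volume`: a list with elements `data`,
#'   `spacing`, `origin`.
#' @export
ct_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L)
    stop("ct_volume: `data` must be a 3D array, got ",
         length(dim(data)), " dimensions")
  if (any(dim(data) < 1L)) stop("ct_volume: all dimensions must be >= 1")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("ct_volume: `spacing` must be 3 positive numbers")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("ct_volume: `origin` must be 3 finite numbers")
  storage.mode(data) <- "integer"
  if (anyNA(data)) stop("ct_volume: NA voxels are not allowed")
  nlow <- sum(data < HU_FLOOR)
  if (nlow > 0L) {
    warning("ct_volume: ", nlow, " voxel(s) below ", HU_FLOOR,
            " HU clamped to the CT floor")
    data[data < HU_FLOOR] <- HU_FLOOR
  }
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat("<ct_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm, HU range [", min(x$data), ", ", max(x$data), "]\n", sep = "")
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$data)

#' Crop box
#'
#' An axis-aligned box of voxel indices, 1-based and inclusive on both ends
#' (`lo[i] <= hi[i]`), tied to the shape of the parent volume it indexes.
#'
#' @param lo,hi Integer length-3 inclusive start/end indices.
#' @param parent_shape Integer length-3 shape of the parent volume.
#' @return An object of class `crop_box`.
#' @export
crop_box <- function(lo, hi, parent_shape) {
  lo <- as.integer(lo); hi <- as.integer(hi)
  parent_shape <- as.integer(parent_shape)
  if (length(lo) != 3L || length(hi) != 3L || length(parent_shape) != 3L)
    stop("crop_box: lo, hi, parent_shape must have length 3")
  if (any(lo < 1L) || any(hi > parent_shape) || any(lo > hi))
    stop("crop_box: need 1 <= lo <= hi <= parent_shape componentwise")
  structure(list(lo = lo, hi = hi, parent_shape = parent_shape),
            class = "crop_box")
}

box_shape <- function(box) box$hi - box$lo + 1L

#' Expand a crop box by a voxel margin
#'
#' Grows a box by `R` voxels on every side, clamped to the parent volume
#' bounds. Used to carve the working subvolume around a seed surface so that
#' a quasi-sphere of radius `R` always fits.
#'
#' @param box A [crop_box()].
#' @param R Non-negative integer margin in voxels.
#' @param parent_shape Optional shape override (defaults to the box's own).
#' @return A [crop_box()].
#' @export
expand_box <- function(box, R, parent_shape = box$parent_shape) {
  stopifnot(inherits(box, "crop_box"))
  R <- as.integer(R)
  if (R < 0L) stop("expand_box: R must be >= 0")
  crop_box(pmax(1L, box$lo - R), pmin(as.integer(parent_shape), box$hi + R),
           parent_shape)
}

#' Crop a volume or mask to a box
#'
#' @param vol A `ct_volume` or a 3D array (e.g. a logical mask).
#' @param box A [crop_box()] valid for `vol`.
#' @return Same type as `vol`, restricted to the box (origin shifted for
#'   `ct_volume`).
#' @export
crop <- function(vol, box) {
  stopifnot(inherits(box, "crop_box"))
  arr <- if (inherits(vol, "ct_volume")) vol$data else vol
  if (!identical(as.integer(dim(arr)), box$parent_shape))
    stop("crop: box parent_shape does not match the volume shape")
  out <- arr[box$lo[1]:box$hi[1], box$lo[2]:box$hi[2], box$lo[3]:box$hi[3],
             drop = FALSE]
  if (inherits(vol, "ct_volume"))
    ct_volume(out, vol$spacing, vol$origin + (box$lo - 1L) * vol$spacing)
  else out
}

#' Paste a cropped array back into its parent
#'
#' Inverse of [crop()] for arrays: writes `sub` into `parent` at the box
#' position and returns the modified parent.
#'
#' @param parent 3D array.
#' @param sub 3D array with the box's shape.
#' @param box The [crop_box()] `sub` was cropped with.
#' @return The parent array with the subregion replaced.
#' @export
uncrop <- function(parent, sub, box) {
  stopifnot(inherits(box, "crop_box"))
  if (!identical(as.integer(dim(sub)), box_shape(box)))
    stop("uncrop: sub shape does not match box shape")
  parent[box$lo[1]:box$hi[1], box$lo[2]:box$hi[2], box$lo[3]:box$hi[3]] <- sub
  parent
}

# bounding box of a set of voxels given as an n x 3 index matrix
bbox_of_voxels <- function(vox, parent_shape) {
  crop_box(apply(vox, 2L, min), apply(vox, 2L, max), parent_shape)
}

file_format <- function(path) {
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) "nifti"
  else if (grepl("\\.(mhd|mha)$", lower)) "metaimage"
  else stop("unsupported volume format: ", path,
            " (expected .nii, .nii.gz, .mhd or .mha)")
}

#' Read a CT volume or mask
#'
#' Reads NIfTI-1 (`.nii`, `.nii.gz`) via RNifti or MetaImage (`.mhd`,
#' `.mha`). Voxels below -2048 HU are clamped to the CT floor with a
#' warning. Only 3D images are accepted.
#'
#' @param path Path to an existing volume file.
#' @return A [ct_volume()].
#' @export
load_volume <- function(path) {
  if (!file.exists(path)) stop("load_volume: file not found: ", path)
  fmt <- file_format(path)
  if (fmt == "nifti") {
    img <- RNifti::readNifti(path, internal = FALSE)
    arr <- as.array(img)
    if (length(dim(arr)) != 3L)
      stop("load_volume: ", path, " is not a 3D image (dims: ",
           paste(dim(arr), collapse = "x"), ")")
    spacing <- RNifti::pixdim(img)[1:3]
    origin <- unname(RNifti::xform(img)[1:3, 4])
    ct_volume(array(as.integer(round(arr)), dim = dim(arr)), spacing, origin)
  } else {
    read_metaimage(path)
  }
}

#' Write a CT volume or mask
#'
#' Writes a [ct_volume()] (or a logical/integer mask array) as NIfTI-1 or
#' MetaImage depending on the file extension. Integer data round-trip
#' bit-exactly through [load_volume()]. Masks are stored as 0/1 integer
#' volumes.
#'
#' @param vol A [ct_volume()] or a 3D logical/integer array.
#' @param path Destination path ending in `.nii`, `.nii.gz`, `.mhd` or `.mha`.
#' @return Invisibly, `path`.
#' @export
save_volume <- function(vol, path) {
  if (!inherits(vol, "ct_volume")) {
    arr <- vol
    if (is.logical(arr)) { storage.mode(arr) <- "integer" }
    vol <- ct_volume(arr)
  }
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("save_volume: directory does not exist: ", dir)
  fmt <- file_format(path)
  if (fmt == "nifti") {
    arr <- vol$data
    attr(arr, "pixdim") <- vol$spacing
    img <- RNifti::asNifti(arr, datatype = "int16", internal = FALSE)
    m <- diag(c(vol$spacing, 1))
    m[1:3, 4] <- vol$origin
    RNifti::`qform<-`(img, structure(m, code = 2L)) -> img
    RNifti::writeNifti(img, path)
  } else {
    write_metaimage(vol, path)
  }
  invisible(path)
}

# --- MetaImage (.mhd/.mha): minimal key = value header + raw block ---------

meta_types <- c(MET_UCHAR = "uint8", MET_SHORT = "int16", MET_INT = "int32")
meta_sizes <- c(MET_UCHAR = 1L, MET_SHORT = 2L, MET_INT = 4L)

read_metaimage <- function(path) {
  raw_all <- readBin(path, "raw", n = file.size(path))
  # header = lines up to and including ElementDataFile
  nl <- which(raw_all == as.raw(10L))
  header_end <- NA_integer_
  hdr_lines <- character()
  start <- 1L
  for (p in nl) {
    line <- rawToChar(raw_all[start:(p - 1L)])
    line <- sub("\r$", "", line)
    hdr_lines <- c(hdr_lines, line)
    start <- p + 1L
    if (grepl("^\\s*ElementDataFile\\s*=", line)) { header_end <- p; break }
  }
  if (is.na(header_end)) stop("read_metaimage: no ElementDataFile key in ", path)
  kv <- strsplit(hdr_lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, function(x) paste(x[-1L], collapse = "="), ""))
  names(vals) <- keys
  get <- function(k, default = NULL) if (k %in% keys) vals[[k]] else default
  ndims <- as.integer(get("NDims", "3"))
  if (ndims != 3L) stop("read_metaimage: only 3D images supported, NDims=", ndims)
  dims <- as.integer(strsplit(get("DimSize"), "\\s+")[[1]])
  etype <- get("ElementType", "MET_SHORT")
  if (!etype %in% names(meta_types))
    stop("read_metaimage: unsupported ElementType ", etype)
  spacing <- as.numeric(strsplit(get("ElementSpacing", "1 1 1"), "\\s+")[[1]])
  origin <- as.numeric(strsplit(get("Offset", "0 0 0"), "\\s+")[[1]])
  msb <- toupper(get("ElementByteOrderMSB", "False")) == "TRUE"
  datafile <- get("ElementDataFile")
  if (identical(datafile, "LOCAL")) {
    payload <- raw_all[(header_end + 1L):length(raw_all)]
  } else {
    rawpath <- file.path(dirname(path), datafile)
    if (!file.exists(rawpath))
      stop("read_metaimage: raw data file not found: ", rawpath)
    payload <- readBin(rawpath, "raw", n = file.size(rawpath))
  }
  n <- prod(dims)
  what <- if (etype == "MET_UCHAR") "integer" else "integer"
  vals_int <- readBin(payload, what = "integer", n = n,
                      size = meta_sizes[[etype]],
                      signed = etype != "MET_UCHAR",
                      endian = if (msb) "big" else "little")
  if (length(vals_int) < n)
    stop("read_metaimage: raw block too short in ", path)
  ct_volume(array(vals_int, dim = dims), spacing, origin)
}

write_metaimage <- function(vol, path) {
  arr <- vol$data
  rng <- range(arr)
  etype <- if (rng[1] >= -32768 && rng[2] <= 32767) "MET_SHORT" else "MET_INT"
  mha <- grepl("\\.mha$", tolower(path))
  datafile <- if (mha) "LOCAL"
              else paste0(sub("\\.mhd$", "", basename(path),
                              ignore.case = TRUE), ".raw")
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    paste("DimSize =", paste(dim(arr), collapse = " ")),
    paste("ElementSpacing =", paste(format(vol$spacing, trim = TRUE),
                                    collapse = " ")),
    paste("Offset =", paste(format(vol$origin, trim = TRUE), collapse = " ")),
    paste("ElementType =", etype),
    paste("ElementDataFile =", datafile))
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(charToRaw(paste0(paste(hdr, collapse = "\n"), "\n")), con)
  payload_con <- con
  if (!mha) {
    close(con)
    on.exit()
    payload_con <- file(file.path(dirname(path), datafile), "wb")
    on.exit(close(payload_con), add = TRUE)
  }
  writeBin(as.integer(arr), payload_con, size = meta_sizes[[etype]],
           endian = "little")
  invisible(path)
}
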