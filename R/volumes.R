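# Voxel containers and geometry. A scalar_volume is a 3-D grid with
# spacing/origin metadata and a tracked physical unit; a voi_mask is a
# binary grid with a label on the same kind of geometry. Units are carried
# through every transform and mismatches raise rather than coerce.

.VOL_UNITS <- c("counts", "MBq/mL", "mGy/s", "mGy/s per MBq")

#' Scalar voxel volume with tracked unit
#'
#' @param values 3-D numeric array.
#' @param spacing Voxel spacing in mm, length 3, all `> 0`.
#' @param origin World coordinates (mm) of the center of voxel (1,1,1).
#' @param unit One of `"counts"`, `"MBq/mL"`, `"mGy/s"`,
#'   `"mGy/s per MBq"`.
#' @return An object of class `scalar_volume`.
#' @export
scalar_volume <- function(values, spacing, origin = c(0, 0, 0),
                          unit = "mGy/s") {
  values <- as.array(values)
  if (length(dim(values)) != 3L) {
    .stop("'values' must be a 3-D array", "volume_geometry_error")
  }
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    .stop("'spacing' must be 3 positive finite numbers (mm)",
          "volume_geometry_error")
  }
  if (length(origin) != 3L || any(!is.finite(origin))) {
    .stop("'origin' must be 3 finite numbers (mm)", "volume_geometry_error")
  }
  unit <- match.arg(unit, .VOL_UNITS)
  structure(list(values = values, spacing = spacing, origin = origin,
                 unit = unit),
            class = "scalar_volume")
}

#' @export
print.scalar_volume <- function(x, ...) {
  cat(sprintf("scalar_volume %s, %s mm spacing, unit [%s]\n",
              paste(dim(x$values), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"), x$unit))
  cat(sprintf("  range %.4g .. %.4g, origin (%s) mm\n",
              min(x$values), max(x$values),
              paste(signif(x$origin, 4), collapse = ", ")))
  invisible(x)
}

#' Binary volume-of-interest mask
#'
#' @param values 3-D array coercible to logical; at least one voxel set.
#' @param label VOI label (e.g. `"LK"`, `"RK"`, `"L"`, `"S"`, `"L2L4"`,
#'   `"L1L5"`, `"T9L5"`, `"HUMERUS"`, `"BACKGROUND"`).
#' @param spacing,origin Grid geometry as in [scalar_volume()].
#' @return An object of class `voi_mask`.
#' @export
voi_mask <- function(values, label, spacing, origin = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L) {
    .stop("'values' must be a 3-D array", "volume_geometry_error")
  }
  mode(values) <- "logical"
  if (!any(values)) .stop("empty VOI mask", "empty_voi_error")
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    .stop("'spacing' must be 3 positive finite numbers (mm)",
          "volume_geometry_error")
  }
  structure(list(values = values, label = as.character(label),
                 spacing = spacing, origin = origin),
            class = "voi_mask")
}

#' @export
print.voi_mask <- function(x, ...) {
  cat(sprintf("voi_mask '%s' %s, %d voxels set\n", x$label,
              paste(dim(x$values), collapse = "x"), sum(x$values)))
  invisible(x)
}

voxel_volume_ml <- function(x) prod(x$spacing) / 1000  # mm^3 -> mL

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

# Trilinear interpolation of volume `vol` at world coordinates given by the
# grid of `target` (a scalar_volume or voi_mask). Values outside `vol` take
# `outside`. Dose maps are interpolated; masks never are.
resample_trilinear <- function(vol, target, outside = 0) {
  dims <- dim(vol$values)
  td <- dim(target$values)
  # world coords of target voxel centers, converted to source voxel index
  ix <- (target$origin[1L] + (seq_len(td[1L]) - 1) * target$spacing[1L] -
           vol$origin[1L]) / vol$spacing[1L] + 1
  iy <- (target$origin[2L] + (seq_len(td[2L]) - 1) * target$spacing[2L] -
           vol$origin[2L]) / vol$spacing[2L] + 1
  iz <- (target$origin[3L] + (seq_len(td[3L]) - 1) * target$spacing[3L] -
           vol$origin[3L]) / vol$spacing[3L] + 1
  out <- array(outside, dim = td)
  gx <- expand.grid(x = ix, y = iy, z = iz)
  x0 <- floor(gx$x); y0 <- floor(gx$y); z0 <- floor(gx$z)
  fx <- gx$x - x0; fy <- gx$y - y0; fz <- gx$z - z0
  ok <- x0 >= 1 & y0 >= 1 & z0 >= 1 &
    (x0 + 1) <= dims[1L] & (y0 + 1) <= dims[2L] & (z0 + 1) <= dims[3L]
  # clamp exact upper-edge points onto the last cell
  edge <- gx$x <= dims[1L] + 1e-9 & gx$y <= dims[2L] + 1e-9 &
    gx$z <= dims[3L] + 1e-9 & gx$x >= 1 - 1e-9 & gx$y >= 1 - 1e-9 &
    gx$z >= 1 - 1e-9
  hi <- edge & !ok
  if (any(hi)) {
    x0[hi] <- pmin(pmax(x0[hi], 1L), dims[1L] - 1L)
    y0[hi] <- pmin(pmax(y0[hi], 1L), dims[2L] - 1L)
    z0[hi] <- pmin(pmax(z0[hi], 1L), dims[3L] - 1L)
    fx[hi] <- gx$x[hi] - x0[hi]; fy[hi] <- gx$y[hi] - y0[hi]
    fz[hi] <- gx$z[hi] - z0[hi]
    ok <- ok | hi
  }
  v <- vol$values
  idx <- function(a, b, cc) ((cc - 1) * dims[2L] + (b - 1)) * dims[1L] + a
  w <- which(ok)
  if (length(w)) {
    x0w <- x0[w]; y0w <- y0[w]; z0w <- z0[w]
    fxw <- fx[w]; fyw <- fy[w]; fzw <- fz[w]
    out[w] <-
      v[idx(x0w,     y0w,     z0w)]     * (1 - fxw) * (1 - fyw) * (1 - fzw) +
      v[idx(x0w + 1, y0w,     z0w)]     * fxw       * (1 - fyw) * (1 - fzw) +
      v[idx(x0w,     y0w + 1, z0w)]     * (1 - fxw) * fyw       * (1 - fzw) +
      v[idx(x0w + 1, y0w + 1, z0w)]     * fxw       * fyw       * (1 - fzw) +
      v[idx(x0w,     y0w,     z0w + 1)] * (1 - fxw) * (1 - fyw) * fzw +
      v[idx(x0w + 1, y0w,     z0w + 1)] * fxw       * (1 - fyw) * fzw +
      v[idx(x0w,     y0w + 1, z0w + 1)] * (1 - fxw) * fyw       * fzw +
      v[idx(x0w + 1, y0w + 1, z0w + 1)] * fxw       * fyw       * fzw
  }
  scalar_volume(out, spacing = target$spacing, origin = target$origin,
                unit = vol$unit)
}

# ---- file I/O ----------------------------------------------------------

#' Read or write voxel volumes (NIfTI or MetaImage)
#'
#' NIfTI (`.nii`, `.nii.gz`) goes through the RNifti package with the
#' `double` datatype, so values round-trip exactly; spacing is stored in
#' `pixdim` and the origin in the sform. MetaImage (`.mhd` + `.raw`) is a
#' plain-text key=value header next to a raw little-endian block
#' (`MET_DOUBLE`/`MET_FLOAT`/`MET_UCHAR`), written uncompressed.
#' Geometry round-trips bit-exactly in both formats. The physical unit is
#' not stored by either format and must be supplied on read.
#'
#' @param x A [scalar_volume()] or [voi_mask()].
#' @param path Output/input file path; format chosen by extension.
#' @param unit Unit to attach on read (see [scalar_volume()]).
#' @return `write_volume()` returns `path` invisibly; `read_volume()` a
#'   `scalar_volume`; `read_mask()` a `voi_mask`.
#' @export
write_volume <- function(x, path) {
  if (!inherits(x, "scalar_volume") && !inherits(x, "voi_mask")) {
    .stop("'x' must be a scalar_volume or voi_mask", "volume_geometry_error")
  }
  vals <- x$values
  if (is.logical(vals)) { mode(vals) <- "integer" }
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::asNifti(vals + 0)
    RNifti::pixdim(img) <- x$spacing
    aff <- diag(c(x$spacing, 1))
    aff[1:3, 4] <- x$origin
    img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
    img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
    RNifti::writeNifti(img, path, datatype = "double")
  } else if (grepl("\\.mhd$", path)) {
    write_metaimage(vals + 0, x$spacing, x$origin, path,
                    element_type = if (inherits(x, "voi_mask")) "MET_UCHAR"
                                   else "MET_DOUBLE")
  } else {
    .stop(sprintf("unsupported volume format: %s", path), "volume_io_error")
  }
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path, unit = "mGy/s") {
  g <- read_volume_raw(path)
  scalar_volume(g$values, spacing = g$spacing, origin = g$origin, unit = unit)
}

#' @rdname write_volume
#' @param label VOI label to attach on read.
#' @export
read_mask <- function(path, label) {
  g <- read_volume_raw(path)
  voi_mask(g$values != 0, label = label, spacing = g$spacing,
           origin = g$origin)
}

read_volume_raw <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::readNifti(path)
    xf <- RNifti::xform(img)
    list(values = array(as.numeric(img), dim = dim(img)),
         spacing = as.numeric(RNifti::pixdim(img)[1:3]),
         origin = as.numeric(xf[1:3, 4]))
  } else if (grepl("\\.mhd$", path)) {
    read_metaimage(path)
  } else {
    .stop(sprintf("unsupported volume format: %s", path), "volume_io_error")
  }
}

# minimal MetaImage (.mhd + .raw) support: 3-D, uncompressed, little-endian
write_metaimage <- function(values, spacing, origin, path,
                            element_type = "MET_DOUBLE") {
  stopifnot(element_type %in% c("MET_DOUBLE", "MET_FLOAT", "MET_UCHAR"))
  raw_name <- sub("\\.mhd$", ".raw", basename(path))
  hdr <- c("ObjectType = Image",
           "NDims = 3",
           "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           "CompressedData = False",
           sprintf("TransformMatrix = %s",
                   paste(c(1, 0, 0, 0, 1, 0, 0, 0, 1), collapse = " ")),
           sprintf("Offset = %.17g %.17g %.17g",
                   origin[1L], origin[2L], origin[3L]),
           sprintf("ElementSpacing = %.17g %.17g %.17g",
                   spacing[1L], spacing[2L], spacing[3L]),
           sprintf("DimSize = %d %d %d", dim(values)[1L], dim(values)[2L],
                   dim(values)[3L]),
           sprintf("ElementType = %s", element_type),
           sprintf("ElementDataFile = %s", raw_name))
  writeLines(hdr, path)
  con <- file(file.path(dirname(path), raw_name), "wb")
  on.exit(close(con))
  v <- as.vector(values)
  switch(element_type,
         MET_DOUBLE = writeBin(as.numeric(v), con, size = 8L,
                               endian = "little"),
         MET_FLOAT = writeBin(as.numeric(v), con, size = 4L,
                              endian = "little"),
         MET_UCHAR = writeBin(as.integer(v), con, size = 1L,
                              endian = "little"))
  invisible(path)
}

read_metaimage <- function(path) {
  lines <- readLines(path, warn = FALSE)
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[[`, character(1L), 1L)
  vals <- vapply(kv, function(x) paste(x[-1L], collapse = " "), character(1L))
  get <- function(k, default = NULL) {
    i <- match(k, keys)
    if (is.na(i)) default else vals[i]
  }
  dims <- as.integer(strsplit(get("DimSize"), "\\s+")[[1L]])
  spacing <- as.numeric(strsplit(get("ElementSpacing", "1 1 1"),
                                 "\\s+")[[1L]])
  origin <- as.numeric(strsplit(get("Offset", "0 0 0"), "\\s+")[[1L]])
  etype <- get("ElementType", "MET_DOUBLE")
  if (!identical(get("CompressedData", "False"), "False")) {
    .stop("compressed MetaImage is not supported", "volume_io_error")
  }
  raw_path <- file.path(dirname(path), get("ElementDataFile"))
  n <- prod(dims)
  con <- file(raw_path, "rb")
  on.exit(close(con))
  v <- switch(etype,
              MET_DOUBLE = readBin(con, "numeric", n, size = 8L,
                                   endian = "little"),
              MET_FLOAT = readBin(con, "numeric", n, size = 4L,
                                  endian = "little"),
              MET_UCHAR = as.numeric(readBin(con, "integer", n, size = 1L,
                                             signed = FALSE,
                                             endian = "little")),
              .stop(sprintf("unsupported ElementType %s", etype),
                    "volume_io_error"))
  list(values = array(v, dim = dims), spacing = spacing, origin = origin)
}
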