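#' Image stacks with physical voxel spacing
#'
#' An `image_stack` bundles a 3D grayscale volume with its anisotropic voxel
#' spacing in micrometres. Axis order is fixed to (z, y, x), with z the
#' acquisition (sample-translation) axis; all downstream measurements are in
#' physical units, so spacing is mandatory.
#'
#' @param voxels 3D numeric array, axis order (z, y, x); finite, non-negative.
#' @param spacing numeric length-3, voxel spacing (dz, dy, dx) in micrometres.
#' @return An `image_stack` object.
#' @export
image_stack <- function(voxels, spacing) {
  if (length(dim(voxels)) != 3L) stop("voxels must be a 3D array (z, y, x)")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("spacing must be three positive micrometre values (dz, dy, dx)")
  }
  if (any(!is.finite(voxels))) stop("voxel intensities must be finite")
  if (any(voxels < 0)) stop("voxel intensities must be non-negative")
  structure(
    list(voxels = voxels, spacing = as.numeric(spacing)),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<image_stack> %d x %d x %d voxels (z,y,x), spacing %.3g x %.3g x %.3g um\n",
    d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]
  ))
  cat(sprintf("  physical extent: %.3g x %.3g x %.3g mm, intensity range [%.4g, %.4g]\n",
              d[1] * x$spacing[1] / 1000, d[2] * x$spacing[2] / 1000,
              d[3] * x$spacing[3] / 1000, min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$voxels)

sidecar_path <- function(path) paste0(sub("\\.tiff?$", "", path, ignore.case = TRUE), ".json")

#' Write a stack as 16-bit multi-page TIFF plus a spacing sidecar
#'
#' Voxel values must lie in \[0, 1\] (abstract grayscale levels); they are
#' stored as 16-bit samples. Values already on the 16-bit grid round-trip
#' bit-exactly. Spacing is recorded in a sidecar JSON
#' (`{"spacing_um": [dz, dy, dx]}`) next to the TIFF.
#'
#' @param stack an [image_stack()].
#' @param path output TIFF path; the sidecar is written with extension `.json`.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  v <- stack$voxels
  if (min(v) < 0 || max(v) > 1) {
    stop("write_stack stores 16-bit levels; intensities must lie in [0, 1]")
  }
  pages <- lapply(seq_len(dim(v)[1]), function(iz) v[iz, , ])
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "LZW")
  jsonlite::write_json(list(spacing_um = stack$spacing), sidecar_path(path),
                       auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF stack with spacing metadata
#'
#' Spacing is resolved with precedence: explicit `spacing` argument, then the
#' sidecar JSON, then TIFF resolution tags. If no source provides it, this is
#' an error: all folliculometric measurements are in physical units.
#'
#' @param path TIFF path.
#' @param spacing optional explicit (dz, dy, dx) micrometres; wins over metadata.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, spacing = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (any(vapply(pages, function(p) length(dim(p)) != 2L, logical(1)))) {
    stop("non-grayscale TIFF pages are not supported")
  }
  nz <- length(pages)
  d <- dim(pages[[1]])
  v <- array(0, c(nz, d[1], d[2]))
  for (iz in seq_len(nz)) v[iz, , ] <- pages[[iz]]
  if (is.null(spacing)) {
    sp <- sidecar_path(path)
    if (file.exists(sp)) {
      spacing <- as.numeric(jsonlite::read_json(sp, simplifyVector = TRUE)$spacing_um)
    } else {
      info <- attr(pages[[1]], "info")
      if (!is.null(info$x.resolution) && info$x.resolution > 0) {
        # TIFF resolution is pixels per unit; only in-plane, no z — insufficient
        spacing <- NULL
      }
    }
  }
  if (is.null(spacing)) {
    stop("no voxel spacing available: pass spacing= or provide a sidecar JSON ",
         "({\"spacing_um\": [dz, dy, dx]})")
  }
  image_stack(v, spacing)
}

#' Reslice a stack so another axis becomes the viewing (z) axis
#'
#' Swaps the z axis with the named axis, permuting the spacing consistently,
#' so every voxel keeps its physical coordinates. Reslicing twice along the
#' same axis restores the original orientation.
#'
#' @param stack an [image_stack()].
#' @param axis `"x"`, `"y"` or `"z"` (z is the identity).
#' @return An [image_stack()].
#' @export
reslice <- function(stack, axis = c("x", "y", "z")) {
  axis <- match.arg(axis)
  i <- AXIS_IDX[[axis]]
  perm <- 1:3
  perm[c(1L, i)] <- perm[c(i, 1L)]
  image_stack(aperm(stack$voxels, perm), stack$spacing[perm])
}

#' Maximum intensity projection
#'
#' @param stack an [image_stack()].
#' @param axis projection axis (`"z"` collapses planes into a (y, x) image).
#' @return 2D matrix of per-pixel maxima along the axis.
#' @export
max_intensity_projection <- function(stack, axis = c("z", "y", "x")) {
  axis <- match.arg(axis)
  i <- AXIS_IDX[[axis]]
  apply(stack$voxels, setdiff(1:3, i), max)
}
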