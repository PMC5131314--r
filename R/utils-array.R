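# Low-level 3D array helpers shared by the phantom and segmentation stages.
# All volumes use axis order (z, y, x) and spacing (dz, dy, dx) micrometres.

AXIS_IDX <- c(z = 1L, y = 2L, x = 3L)

# Shift a 3D array by one step along an axis, zero-filling (or `fill`) the
# vacated face. Used for 6-neighbourhood morphology and boundary extraction.
shift3d <- function(a, axis, by, fill = FALSE) {
  d <- dim(a)
  out <- array(fill, d)
  src <- dst <- lapply(d, seq_len)
  if (by > 0) {
    dst[[axis]] <- (by + 1):d[axis]
    src[[axis]] <- 1:(d[axis] - by)
  } else {
    dst[[axis]] <- 1:(d[axis] + by)
    src[[axis]] <- (1 - by):d[axis]
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# 6-connected binary dilation/erosion, repeated `r` times.
dilate6 <- function(mask, r = 1L) {
  for (i in seq_len(r)) {
    acc <- mask
    for (ax in 1:3) {
      acc <- acc | shift3d(mask, ax, 1L) | shift3d(mask, ax, -1L)
    }
    mask <- acc
  }
  mask
}

erode6 <- function(mask, r = 1L) {
  for (i in seq_len(r)) {
    acc <- mask
    for (ax in 1:3) {
      acc <- acc & shift3d(mask, ax, 1L, fill = TRUE) &
        shift3d(mask, ax, -1L, fill = TRUE)
    }
    mask <- acc
  }
  mask
}

close6 <- function(mask, r = 1L) {
  if (r <= 0L) return(mask)
  erode6(dilate6(mask, r), r)
}

# Fill enclosed cavities: background 6-components not touching the border.
fill_holes3d <- function(mask) {
  bg <- cpp_label3d(!mask, 6L)
  d <- dim(mask)
  border <- unique(c(
    bg[1, , ], bg[d[1], , ], bg[, 1, ], bg[, d[2], ], bg[, , 1], bg[, , d[3]]
  ))
  border <- border[border > 0L]
  hole <- bg > 0L & !(bg %in% border)
  mask | hole
}

# Truncated, renormalized 1D Gaussian kernel (sigma in samples).
gauss_kernel <- function(sigma, halfwidth = NULL) {
  if (sigma <= 0) return(1)
  if (is.null(halfwidth)) halfwidth <- max(1L, ceiling(3 * sigma))
  x <- (-halfwidth):halfwidth
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Centroid of a logical mask in physical micrometres (voxel centres).
mask_centroid_um <- function(mask, spacing) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty mask has no centroid")
  (colMeans(idx) - 0.5) * spacing
}

# Principal axis lengths (sqrt eigenvalues of the coordinate covariance),
# physical units; returns a sorted descending length-3 vector. Components
# beyond `max_n` voxels are subsampled deterministically (shape statistics
# converge long before that).
principal_axis_sd_um <- function(mask, spacing, max_n = 2e5) {
  lin <- which(mask)
  if (length(lin) < 2L) return(c(0, 0, 0))
  if (length(lin) > max_n) {
    lin <- lin[unique(as.integer(seq(1L, length(lin), length.out = max_n)))]
  }
  d <- dim(mask)
  iz <- (lin - 1L) %% d[1] + 1L
  iy <- ((lin - 1L) %/% d[1]) %% d[2] + 1L
  ix <- (lin - 1L) %/% (d[1] * d[2]) + 1L
  xyz <- cbind(iz * spacing[1], iy * spacing[2], ix * spacing[3])
  ev <- eigen(cov(xyz), symmetric = TRUE, only.values = TRUE)$values
  sqrt(pmax(ev, 0))
}
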