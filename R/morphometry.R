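# Folliculometric measurements on segmented follicles. All quantities are in
# physical units: volumes in mm^3, lengths in micrometres.

#' Follicle volume from a segmented whole-follicle mask
#'
#' Volume is the voxel count times the voxel volume, i.e. the full 3D
#' integral over the segmented follicle, so shape irregularities in every
#' plane contribute (unlike two-caliper histology estimates).
#'
#' @param whole_mask logical 3D mask of the filled follicle.
#' @param spacing (dz, dy, dx) micrometres.
#' @return volume in mm^3.
#' @export
follicle_volume <- function(whole_mask, spacing) {
  n <- sum(whole_mask)
  if (n == 0L) stop("empty mask has no volume")
  n * prod(spacing) * 1e-9
}

#' Equivalent spherical diameter from a volume
#'
#' The diameter of the sphere with the same volume, d = (6V/pi)^(1/3),
#' the convention used to compare volumetric measurements with
#' diameter-based histology.
#'
#' @param volume_mm3 volume in mm^3.
#' @return diameter in micrometres.
#' @export
equivalent_diameter <- function(volume_mm3) {
  if (any(volume_mm3 <= 0)) stop("volume must be positive")
  (6 * volume_mm3 / pi)^(1 / 3) * 1000
}

#' Equatorial plane of a follicle
#'
#' The z-plane with the maximum follicle cross-section area; ties go to the
#' lowest index. 2D measurements (asymmetry, wall thickness) are made in
#' this plane to avoid off-equator over/under-estimation.
#'
#' @param whole_mask logical 3D mask.
#' @return 1-based z-plane index.
#' @export
equatorial_plane <- function(whole_mask) {
  if (!any(whole_mask)) stop("empty mask has no equatorial plane")
  counts <- apply(whole_mask, 1L, sum)
  which.max(counts)
}

# second-moment ellipse of a set of in-plane pixels; returns axis sd's
# (descending) in physical units with the pixel-footprint correction
plane_moment_axes <- function(py, px, dy, dx) {
  Y <- py * dy
  X <- px * dx
  C <- cov(cbind(Y, X)) * (length(Y) - 1) / length(Y)
  raw_ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(raw_ev) < 1e-9 * max(raw_ev)) {
    stop("degenerate (collinear) cross-section")
  }
  C <- C + diag(c(dy^2, dx^2)) / 12 # square-pixel footprint moments
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  sqrt(pmax(ev, 0))
}

#' Equatorial asymmetry (major/minor axis ratio)
#'
#' Fits the second-moment ellipse to the equatorial cross-section in
#' physical (anisotropy-corrected) coordinates and returns the major/minor
#' axis ratio (>= 1). A sphere gives 1; the parameter shrinks towards 1 as
#' follicles mature.
#'
#' @param whole_mask logical 3D mask.
#' @param spacing (dz, dy, dx) micrometres.
#' @return ratio >= 1.
#' @export
equatorial_asymmetry <- function(whole_mask, spacing) {
  iz <- equatorial_plane(whole_mask)
  idx <- which(whole_mask[iz, , ], arr.ind = TRUE)
  if (nrow(idx) < 5L) stop("equatorial cross-section has fewer than 5 pixels")
  ax <- plane_moment_axes(idx[, 1], idx[, 2], spacing[2], spacing[3])
  if (ax[2] <= 0) stop("degenerate (collinear) equatorial cross-section")
  ax[1] / ax[2]
}

# in-plane boundary pixel coordinates (y, x integer matrix) of a 3D logical
# volume restricted to plane iz
plane_pixels <- function(vol, iz) {
  which(vol[iz, , ], arr.ind = TRUE)
}

#' Thecal wall thickness distribution in the equatorial plane
#'
#' The analysis plane is the equatorial plane of the whole-follicle mask.
#' For every pixel on the outer edge of the theca in that plane, the sample
#' is the shortest (Euclidean, physical-unit) distance to any inner-edge
#' pixel in the same plane, so each follicle yields a full thickness
#' distribution rather than a single caliper value.
#'
#' Distances are measured between pixel centres; since a boundary pixel's
#' centre sits on average half an in-plane pixel inside its surface, one
#' in-plane pixel (half per edge) is added to the reported samples as a
#' discretization correction. `samples_sq_um2` keeps the raw centre-to-centre
#' squared distances (comparable bitwise against an all-pairs search).
#'
#' @param mask_set a `follicle_masks` object (see [extract_shell_masks()]).
#' @param spacing (dz, dy, dx) micrometres.
#' @return a `thickness_distribution`: samples (um), raw squared samples,
#'   plane index, n, mean, sd and quartiles.
#' @export
theca_thickness_distribution <- function(mask_set, spacing) {
  iz <- equatorial_plane(mask_set$whole)
  outer <- plane_pixels(mask_set$outer_boundary, iz)
  inner <- plane_pixels(mask_set$inner_boundary, iz)
  if (nrow(outer) == 0L || nrow(inner) == 0L) {
    stop("theca boundary empty in the equatorial plane (plane ", iz, ")")
  }
  sq <- cpp_nearest_boundary_sq(outer, inner, spacing[2], spacing[3])
  edge_corr <- (spacing[2] + spacing[3]) / 2
  samples <- sqrt(sq) + edge_corr
  structure(list(
    samples_um = samples, samples_sq_um2 = sq, edge_correction_um = edge_corr,
    plane = iz,
    n = length(samples), mean = mean(samples), sd = stats::sd(samples),
    quantiles = stats::quantile(samples, c(0.25, 0.5, 0.75))
  ), class = "thickness_distribution")
}

#' @export
print.thickness_distribution <- function(x, ...) {
  cat(sprintf(
    "<thickness_distribution> n = %d (plane %d): mean %.1f um, sd %.1f um, IQR [%.1f-%.1f] um\n",
    x$n, x$plane, x$mean, x$sd, x$quantiles[1], x$quantiles[3]))
  invisible(x)
}

#' Two-orthogonal-caliper diameter estimate (histology convention)
#'
#' Reproduces the conventional histological measurement: the longest chord
#' through the centroid of the equatorial cross-section, then a second chord
#' through the first chord's midpoint and perpendicular to it; the average of
#' the two is the diameter estimate. Implemented for comparison with the
#' volumetric equivalent diameter; its bias grows with follicle asymmetry.
#'
#' @param whole_mask logical 3D mask.
#' @param spacing (dz, dy, dx) micrometres.
#' @param angular_tol_deg half-width of the angular window used to emulate
#'   the caliper through the centroid.
#' @return diameter estimate in micrometres.
#' @export
orthogonal_diameter_estimate <- function(whole_mask, spacing, angular_tol_deg = 2) {
  iz <- equatorial_plane(whole_mask)
  m2 <- whole_mask[iz, , ]
  idx <- which(m2, arr.ind = TRUE)
  if (nrow(idx) < 5L) stop("degenerate equatorial cross-section")
  dy <- spacing[2]; dx <- spacing[3]
  Y <- idx[, 1] * dy; X <- idx[, 2] * dx
  cy <- mean(Y); cx <- mean(X)
  # boundary pixels: any 4-neighbour outside
  inb <- function(i, j) i >= 1 & i <= nrow(m2) & j >= 1 & j <= ncol(m2)
  is_b <- vapply(seq_len(nrow(idx)), function(k) {
    i <- idx[k, 1]; j <- idx[k, 2]
    any(!c(inb(i - 1, j) && m2[i - 1, j], inb(i + 1, j) && m2[i + 1, j],
           inb(i, j - 1) && m2[i, j - 1], inb(i, j + 1) && m2[i, j + 1]))
  }, logical(1))
  by <- Y[is_b] - cy; bx <- X[is_b] - cx
  ang <- atan2(by, bx) %% (2 * pi)
  rad <- sqrt(by^2 + bx^2)
  tol <- angular_tol_deg * pi / 180
  thetas <- seq(0, pi, length.out = 181)[-181]
  ang_dist <- function(a, b) {
    d <- abs(a - b) %% (2 * pi)
    pmin(d, 2 * pi - d)
  }
  best <- -Inf; best_ends <- NULL
  for (th in thetas) {
    iA <- ang_dist(ang, th) <= tol
    iB <- ang_dist(ang, th + pi) <= tol
    if (!any(iA) || !any(iB)) next
    rA <- max(rad[iA]); rB <- max(rad[iB])
    if (rA + rB > best) {
      best <- rA + rB
      kA <- which(iA)[which.max(rad[iA])]
      kB <- which(iB)[which.max(rad[iB])]
      best_ends <- rbind(c(by[kA] + cy, bx[kA] + cx), c(by[kB] + cy, bx[kB] + cx))
    }
  }
  if (!is.finite(best)) stop("no chord through the centroid found")
  mid <- colMeans(best_ends)
  u <- (best_ends[1, ] - best_ends[2, ]) / best
  perp <- c(-u[2], u[1])
  # span of mask pixels within half a pixel of the perpendicular line
  dseg <- abs((Y - mid[1]) * u[1] + (X - mid[2]) * u[2]) # distance along chord dir = off-line
  on_line <- dseg <= 0.6 * max(dy, dx)
  if (!any(on_line)) stop("perpendicular chord found no pixels")
  t <- (Y[on_line] - mid[1]) * perp[1] + (X[on_line] - mid[2]) * perp[2]
  second <- max(t) - min(t) + mean(c(dy, dx)) # pixel-centre span + one pixel footprint
  (best + second) / 2
}

#' COC diameter at its middle plane
#'
#' The maximal-cross-section plane of the COC mask is taken as its
#' equatorial (middle) plane; the diameter is the equivalent-circle diameter
#' of that cross-section, 2*sqrt(area/pi).
#'
#' @param coc_mask logical 3D mask of one COC.
#' @param spacing (dz, dy, dx) micrometres.
#' @return diameter in micrometres.
#' @export
coc_diameter <- function(coc_mask, spacing) {
  if (!any(coc_mask)) stop("empty COC mask")
  iz <- equatorial_plane(coc_mask)
  area <- sum(coc_mask[iz, , ]) * spacing[2] * spacing[3]
  2 * sqrt(area / pi)
}

#' Measure one follicle
#'
#' Computes every folliculometric quantity available for a follicle mask
#' set: volume, equivalent diameter, equatorial plane and asymmetry, wall
#' thickness distribution, COC diameter (when a COC is detected), the
#' two-caliper comparison estimate, and the developmental stage. Fields that
#' cannot be computed (solid follicle without a resolvable wall, absent COC)
#' are NA, never zero.
#'
#' @param stack the intensity [image_stack()] (used for COC detection); may
#'   be NULL to skip COC detection.
#' @param mask_set a `follicle_masks` object.
#' @param thresholds a [stage_thresholds()].
#' @param coc_params parameters passed to [detect_cocs()].
#' @return a one-row data.frame (class `follicle_measurement`) with
#'   unit-suffixed columns; the thickness distribution object is attached as
#'   attribute `"thickness"`.
#' @export
measure_follicle <- function(stack, mask_set, thresholds = stage_thresholds(),
                             coc_params = list()) {
  spacing <- mask_set$spacing
  vol <- follicle_volume(mask_set$whole, spacing)
  d <- equivalent_diameter(vol)
  iz <- equatorial_plane(mask_set$whole)
  asym <- tryCatch(equatorial_asymmetry(mask_set$whole, spacing),
                   error = function(e) NA_real_)
  thick <- tryCatch(theca_thickness_distribution(mask_set, spacing),
                    error = function(e) NULL)
  orth <- tryCatch(orthogonal_diameter_estimate(mask_set$whole, spacing),
                   error = function(e) NA_real_)
  coc_d <- NA_real_
  if (!is.null(stack)) {
    cocs <- do.call(detect_cocs, c(list(stack = stack, mask_set = mask_set), coc_params))
    if (length(cocs$accepted) > 0) {
      coc_d <- coc_diameter(cocs$accepted[[1]], spacing)
    }
  }
  ctr <- mask_centroid_um(mask_set$whole, spacing)
  out <- data.frame(
    follicle_id = mask_set$follicle_id,
    voxel_count = sum(mask_set$whole),
    volume_mm3 = vol,
    equivalent_diameter_um = d,
    equatorial_plane = iz,
    asymmetry = asym,
    asymmetry_minor_major = 1 / asym,
    thickness_mean_um = if (is.null(thick)) NA_real_ else thick$mean,
    thickness_sd_um = if (is.null(thick)) NA_real_ else thick$sd,
    thickness_n = if (is.null(thick)) NA_integer_ else thick$n,
    coc_diameter_um = coc_d,
    orthogonal_diameter_um = orth,
    stage = as.character(classify_stage(d, thresholds)),
    centroid_z_um = ctr[1], centroid_y_um = ctr[2], centroid_x_um = ctr[3]
  )
  attr(out, "thickness") <- thick
  class(out) <- c("follicle_measurement", class(out))
  out
}
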