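# Synthetic cleared-ovary SPIM phantom generator.
#
# A phantom scene is painted back-to-front into a (z, y, x) voxel grid:
# background, blood-vessel tubes, then per follicle the concentric regions
# outer -> inner: bright thecal shell, dark delamination gap, granulosa
# lining, dark antral lumen, and an optional bright cumulus-oophorus complex
# (COC) attached to the inner wall. The imaging model then applies the
# light-sheet point spread (thin at the beam waist, thicker towards the FOV
# edge), lateral blur, and shot + read noise. A machine-readable ground-truth
# manifest is produced alongside for parameter-recovery experiments.

# region codes used while painting
RG_BACKGROUND <- 0L; RG_THECA <- 1L; RG_GAP <- 2L; RG_GRANULOSA <- 3L
RG_LUMEN <- 4L; RG_COC <- 5L; RG_VESSEL <- 6L

default_intensities <- function() {
  list(theca = 0.80, granulosa = 0.35, coc = 0.95, lumen = 0.02, gap = 0.02,
       vessel = 0.80, background = 0.08)
}

rot_about <- function(axis = c("z", "y", "x"), theta) {
  axis <- match.arg(axis)
  R <- diag(3)
  ij <- switch(axis, z = c(2L, 3L), y = c(1L, 3L), x = c(1L, 2L))
  R[ij, ij] <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  R
}

# Euler angles (radians) applied about the x, then y, then z axes; operates
# on (z, y, x)-ordered coordinate vectors.
rotation_matrix <- function(orientation) {
  if (is.matrix(orientation)) {
    stopifnot(all(dim(orientation) == c(3, 3)))
    return(orientation)
  }
  stopifnot(length(orientation) == 3)
  rot_about("z", orientation[3]) %*% rot_about("y", orientation[2]) %*%
    rot_about("x", orientation[1])
}

#' Describe one synthetic follicle
#'
#' Geometry is an ovoid (rotated ellipsoid) outer thecal surface; the wall
#' thickness may vary smoothly over the surface (a low-order angular field)
#' so that per-follicle thickness distributions are non-degenerate. When the
#' wall thickness reaches the smallest semi-axis the follicle is solid
#' (primary/primordial morphology, no antrum).
#'
#' @param center physical centre (z, y, x), micrometres.
#' @param semi_axes outer semi-axes (a >= b >= c), micrometres.
#' @param orientation Euler angles (radians, about x, y, z) or a 3x3 rotation.
#' @param theca_thickness_base base wall thickness, micrometres.
#' @param theca_thickness_modulation amplitude in \[0, 1) of the smooth
#'   angular thickness variation.
#' @param gap_width delamination gap (dark band) width, micrometres.
#' @param granulosa_width granulosa lining width, micrometres.
#' @param coc optional `list(diameter =, direction =)`: COC diameter in
#'   micrometres (typically 40--110) and the unit (z, y, x) direction from the
#'   follicle centre to its wall anchor.
#' @return A `follicle_phantom` description.
#' @export
follicle_phantom <- function(center, semi_axes, orientation = c(0, 0, 0),
                             theca_thickness_base = 100,
                             theca_thickness_modulation = 0,
                             gap_width = 12, granulosa_width = 20,
                             coc = NULL) {
  semi_axes <- as.numeric(semi_axes)
  if (any(semi_axes <= 0)) stop("semi_axes must all be positive")
  if (is.unsorted(rev(semi_axes))) stop("semi_axes must be sorted descending (a >= b >= c)")
  if (theca_thickness_base <= 0) stop("theca_thickness_base must be positive")
  if (theca_thickness_modulation < 0 || theca_thickness_modulation >= 1) {
    stop("theca_thickness_modulation must lie in [0, 1)")
  }
  if (!is.null(coc)) {
    lumen_min <- min(semi_axes) - theca_thickness_base - gap_width - granulosa_width
    if (coc$diameter >= lumen_min) {
      stop("coc diameter must be smaller than the smallest inner-lumen semi-axis")
    }
    if (is.null(coc$direction)) coc$direction <- c(0, 0, 1)
    coc$direction <- coc$direction / sqrt(sum(coc$direction^2))
  }
  structure(list(center = as.numeric(center), semi_axes = semi_axes,
                 orientation = orientation,
                 theca_thickness_base = theca_thickness_base,
                 theca_thickness_modulation = theca_thickness_modulation,
                 gap_width = gap_width, granulosa_width = granulosa_width,
                 coc = coc),
            class = "follicle_phantom")
}

#' Describe one synthetic blood vessel (tube around a polyline)
#' @param polyline matrix with >= 2 rows of (z, y, x) micrometre points.
#' @param radius tube radius, micrometres.
#' @export
vessel_phantom <- function(polyline, radius = 25) {
  polyline <- as.matrix(polyline)
  if (nrow(polyline) < 2L) stop("vessel polyline needs at least 2 points")
  if (radius <= 0) stop("vessel radius must be positive")
  structure(list(polyline = polyline, radius = radius), class = "vessel_phantom")
}

#' Imaging model for the synthetic SPIM acquisition
#'
#' The light sheet is thinnest at the beam waist and broadens towards the
#' edge of the field of view, so the axial (z) blur grows with lateral
#' distance from the waist axis; the default waist thickness is 11 um with a
#' 16 um variant selectable, broadening to ~60 um at 3 mm. Lateral
#' resolution is ~6 um FWHM. Noise is shot noise (Poisson in detected
#' electrons, `photon_scale` electrons per unit intensity) plus Gaussian
#' read noise in electrons.
#'
#' @param voxel_spacing (dz, dy, dx) micrometres; default (16, 4, 4): ~16 um
#'   z-steps and a 10 mm FOV on a 2,560-pixel detector in-plane.
#' @param lateral_psf_fwhm in-plane PSF FWHM, micrometres.
#' @param sheet_waist_um light-sheet thickness (axial FWHM) at the waist.
#' @param sheet_edge_um sheet thickness at `sheet_edge_distance_um` from the waist axis.
#' @param sheet_edge_distance_um lateral distance at which `sheet_edge_um` applies.
#' @param photon_scale detected electrons per unit intensity level.
#' @param read_noise_sd read noise standard deviation, electrons.
#' @export
imaging_model <- function(voxel_spacing = c(16, 4, 4), lateral_psf_fwhm = 6,
                          sheet_waist_um = 11, sheet_edge_um = 60,
                          sheet_edge_distance_um = 3000,
                          photon_scale = 2000, read_noise_sd = 1.0) {
  if (any(voxel_spacing <= 0)) stop("voxel spacing must be positive")
  if (sheet_edge_um < sheet_waist_um) {
    stop("sheet_edge_um must be >= sheet_waist_um (sheet broadens off-waist)")
  }
  if (photon_scale <= 0) stop("photon_scale must be positive")
  structure(list(voxel_spacing = as.numeric(voxel_spacing),
                 lateral_psf_fwhm = lateral_psf_fwhm,
                 sheet_waist_um = sheet_waist_um, sheet_edge_um = sheet_edge_um,
                 sheet_edge_distance_um = sheet_edge_distance_um,
                 photon_scale = photon_scale, read_noise_sd = read_noise_sd),
            class = "imaging_model")
}

#' Declarative description of a synthetic ovary scene
#'
#' @param volume_shape voxel counts (nz, ny, nx).
#' @param follicles list of [follicle_phantom()].
#' @param vessels list of [vessel_phantom()].
#' @param egg_nests list of `list(center =, count =, diameter_range = c(70, 100))`
#'   primordial-follicle clusters near the cortex.
#' @param imaging an [imaging_model()].
#' @param background_level stromal background intensity level.
#' @param intensities named list of grayscale levels per tissue class.
#' @param seed integer; fully determines the generated stack.
#' @param overlap_tolerance_vox voxels of structure overlap tolerated before
#'   [build_phantom()] errors (discrete-follicle assumption).
#' @export
phantom_spec <- function(volume_shape, follicles = list(), vessels = list(),
                         egg_nests = list(), imaging = imaging_model(),
                         background_level = 0.08,
                         intensities = default_intensities(),
                         seed = 1L, overlap_tolerance_vox = 0L) {
  stopifnot(length(volume_shape) == 3L, all(volume_shape >= 1))
  intensities <- utils::modifyList(default_intensities(), intensities)
  intensities$background <- background_level
  extent <- volume_shape * imaging$voxel_spacing
  for (f in follicles) {
    if (any(f$center - f$semi_axes[1] < 0) || any(f$center + f$semi_axes[1] > extent)) {
      stop("follicle at (", paste(round(f$center), collapse = ", "),
           ") does not fit inside the physical volume extent")
    }
  }
  for (v in vessels) {
    if (any(v$polyline < 0) || any(sweep(v$polyline, 2, extent) > 0)) {
      stop("vessel polyline leaves the physical volume extent")
    }
  }
  structure(list(volume_shape = as.integer(volume_shape), follicles = follicles,
                 vessels = vessels, egg_nests = egg_nests, imaging = imaging,
                 background_level = background_level, intensities = intensities,
                 seed = as.integer(seed),
                 overlap_tolerance_vox = as.integer(overlap_tolerance_vox)),
            class = "phantom_spec")
}

#' Voxelize a rotated ellipsoid on an anisotropic grid
#'
#' A voxel is set iff its physical centre lies inside the ellipsoid.
#'
#' @param center,semi_axes,orientation ellipsoid geometry, micrometres.
#' @param spacing (dz, dy, dx) micrometres.
#' @param shape voxel counts (nz, ny, nx).
#' @return logical 3D mask.
#' @export
voxelize_ellipsoid <- function(center, semi_axes, orientation = c(0, 0, 0),
                               spacing, shape) {
  semi_axes <- as.numeric(semi_axes)
  if (any(semi_axes <= 0)) stop("semi_axes must be positive")
  if (any(spacing <= 0)) stop("spacing must be positive")
  extent <- shape * spacing
  if (any(center + semi_axes[1] < 0) || any(center - semi_axes[1] > extent)) {
    stop("ellipsoid lies entirely outside the volume")
  }
  cpp_voxelize_ellipsoid(as.numeric(center), semi_axes,
                         rotation_matrix(orientation), as.numeric(spacing),
                         as.integer(shape))
}

# run `code` under a private RNG stream; restores the caller's RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# analytic outer ellipsoid volume, mm^3
ellipsoid_volume_mm3 <- function(semi_axes) 4 / 3 * pi * prod(semi_axes) * 1e-9

# analytic major/minor axis ratio of the central z-plane cross-section of a
# rotated ellipsoid (Schur complement of the quadratic form)
ellipsoid_equatorial_ratio <- function(semi_axes, orientation) {
  R <- rotation_matrix(orientation)
  Q <- R %*% diag(1 / semi_axes^2) %*% t(R)
  A <- Q[2:3, 2:3] - tcrossprod(Q[2:3, 1]) / Q[1, 1]
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  sqrt(max(ev) / min(ev)) # axis length ~ 1/sqrt(eigenvalue)
}

# wall thickness along a world-frame unit direction (z, y, x)
follicle_thickness_at <- function(f, u_world, coefs) {
  R <- rotation_matrix(f$orientation)
  u <- as.numeric(t(R) %*% u_world)
  if (f$theca_thickness_modulation == 0) return(f$theca_thickness_base)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  fld <- 0.5 * (coefs[1] * 2 * ux * uy + coefs[2] * 2 * uy * uz +
                  coefs[3] * 2 * ux * uz + coefs[4] * (1.5 * uz^2 - 0.5))
  f$theca_thickness_base * (1 + f$theca_thickness_modulation * fld)
}

# outer radial extent of the ellipsoid along a world unit direction
ellipsoid_radius_at <- function(f, u_world) {
  R <- rotation_matrix(f$orientation)
  u <- as.numeric(t(R) %*% u_world)
  1 / sqrt(sum((u / f$semi_axes)^2))
}

#' Build a synthetic SPIM stack with ground truth
#'
#' Paints the scene (vessels, follicle shells, gaps, granulosa, lumens,
#' COCs, egg nests), applies the light-sheet PSF and the noise model, and
#' quantizes the result onto the 16-bit level grid. The same spec (including
#' its seed) always produces a bit-identical stack and manifest.
#'
#' @param spec a [phantom_spec()].
#' @param blur,noise logical switches for the imaging model stages.
#' @return `list(stack = image_stack, truth = phantom_truth)`; the truth
#'   carries a label volume aligned to the stack and one record per structure
#'   with analytic volume, equatorial axis ratio, wall-thickness field
#'   samples, COC diameter, and developmental stage.
#' @export
build_phantom <- function(spec, blur = TRUE, noise = TRUE) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, build_phantom_impl(spec, blur, noise))
}

build_phantom_impl <- function(spec, blur, noise) {
  shp <- spec$volume_shape
  sp <- spec$imaging$voxel_spacing
  region <- array(0L, shp)
  labels <- array(0L, shp)
  structures <- list()
  next_id <- 1L

  for (v in spec$vessels) {
    m <- cpp_voxelize_tube(v$polyline, v$radius, sp, shp)
    ov <- sum(m & labels != 0L)
    if (ov > spec$overlap_tolerance_vox) {
      stop("vessel overlaps an existing structure by ", ov, " voxels")
    }
    sel <- m & labels == 0L
    labels[sel] <- next_id
    region[sel] <- RG_VESSEL
    structures[[next_id]] <- list(
      id = next_id, class = "vessel", stage = NA_character_,
      center_um = mask_centroid_um(sel, sp),
      radius_um = v$radius, voxel_count = sum(sel),
      voxel_volume_mm3 = sum(sel) * prod(sp) * 1e-9,
      true_volume_mm3 = NA_real_, true_equatorial_ratio = NA_real_,
      true_mean_thickness_um = NA_real_, thickness_samples_um = NULL,
      true_coc_diameter_um = NA_real_, coc_center_um = NULL
    )
    next_id <- next_id + 1L
  }

  paint_follicle <- function(f, class, stage = NULL) {
    coefs <- stats::runif(4, -1, 1)
    res <- cpp_paint_follicle(
      region, labels, next_id, f$center, f$semi_axes,
      rotation_matrix(f$orientation), sp,
      c(f$theca_thickness_base, f$theca_thickness_modulation, coefs),
      f$gap_width, f$granulosa_width, spec$overlap_tolerance_vox
    )
    if (res$overlap > spec$overlap_tolerance_vox) {
      stop("follicle ", next_id, " overlaps an existing structure by ",
           res$overlap, " voxels")
    }
    vol <- ellipsoid_volume_mm3(f$semi_axes)
    d_um <- equivalent_diameter(vol)
    theta <- seq(0, 2 * pi, length.out = 361)[-361]
    tsamp <- vapply(theta, function(th) {
      follicle_thickness_at(f, c(0, sin(th), cos(th)), coefs)
    }, numeric(1))
    coc_d <- NA_real_; coc_center <- NULL
    if (!is.null(f$coc)) {
      u <- f$coc$direction
      r_in <- ellipsoid_radius_at(f, u) - follicle_thickness_at(f, u, coefs) -
        f$gap_width - f$granulosa_width
      coc_r <- f$coc$diameter / 2
      coc_center <- f$center + u * (r_in - coc_r)
      cm <- cpp_voxelize_ellipsoid(coc_center, rep(coc_r, 3), diag(3), sp, shp)
      sel <- cm & labels == next_id & (region == RG_GRANULOSA | region == RG_LUMEN)
      region[sel] <<- RG_COC
      coc_d <- f$coc$diameter
    }
    structures[[next_id]] <<- list(
      id = next_id, class = class,
      stage = if (is.null(stage)) as.character(classify_stage(d_um)) else stage,
      center_um = f$center, semi_axes_um = f$semi_axes,
      voxel_count = res$painted,
      voxel_volume_mm3 = res$painted * prod(sp) * 1e-9,
      true_volume_mm3 = vol,
      true_equivalent_diameter_um = d_um,
      true_equatorial_ratio = ellipsoid_equatorial_ratio(f$semi_axes, f$orientation),
      true_mean_thickness_um = mean(tsamp),
      thickness_samples_um = tsamp,
      true_coc_diameter_um = coc_d, coc_center_um = coc_center
    )
    next_id <<- next_id + 1L
  }

  for (f in spec$follicles) paint_follicle(f, "follicle")

  for (nest in spec$egg_nests) {
    drange <- if (is.null(nest$diameter_range)) c(70, 100) else nest$diameter_range
    placed <- matrix(numeric(0), 0, 4) # z, y, x, r
    nest_r <- 2.5 * mean(drange)
    for (k in seq_len(nest$count)) {
      d <- stats::runif(1, drange[1], drange[2])
      for (try in 1:200) {
        u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
        pos <- nest$center + u * stats::runif(1, 0, nest_r)
        ok <- nrow(placed) == 0 ||
          all(sqrt(colSums((t(placed[, 1:3, drop = FALSE]) - pos)^2)) >
                placed[, 4] + d / 2 + 16)
        if (ok) break
        if (try %% 50 == 0) nest_r <- nest_r * 1.3
      }
      placed <- rbind(placed, c(pos, d / 2))
      f <- follicle_phantom(pos, rep(d / 2, 3),
                            theca_thickness_base = d, # solid
                            gap_width = 0, granulosa_width = 0)
      paint_follicle(f, "egg_nest_member", stage = "primordial")
    }
  }

  lv <- spec$intensities
  lut <- c(lv$background, lv$theca, lv$gap, lv$granulosa, lv$lumen, lv$coc, lv$vessel)
  vox <- array(lut[region + 1L], dim(region))
  stack <- image_stack(vox, sp)
  if (blur) stack <- apply_lightsheet_psf(stack, spec$imaging)
  if (noise) stack <- apply_noise(stack, spec$imaging, seed = spec$seed + 1L)
  v <- pmin(pmax(stack$voxels, 0), 1)
  stack$voxels <- round(v * 65535) / 65535 # 16-bit level grid
  truth <- structure(list(structures = structures, labels = labels, spacing = sp,
                          seed = spec$seed),
                     class = "phantom_truth")
  list(stack = stack, truth = truth)
}

#' Apply the light-sheet point-spread function
#'
#' In-plane blur is an isotropic Gaussian at `lateral_psf_fwhm`. Axial blur
#' is a Gaussian per x-column whose FWHM interpolates linearly from the
#' waist thickness on the waist axis to the edge thickness at
#' `sheet_edge_distance_um`, clamped beyond; the waist axis runs along y at
#' the x-centre of the volume (the sheet propagation direction is x). Edge
#' effects are renormalized so constant regions stay constant.
#'
#' @param stack an [image_stack()].
#' @param imaging an [imaging_model()].
#' @return blurred [image_stack()].
#' @export
apply_lightsheet_psf <- function(stack, imaging) {
  sp <- stack$spacing
  v <- stack$voxels
  fwhm2sd <- 1 / (2 * sqrt(2 * log(2)))
  # lateral
  sig_y <- imaging$lateral_psf_fwhm * fwhm2sd / sp[2]
  sig_x <- imaging$lateral_psf_fwhm * fwhm2sd / sp[3]
  if (sig_y > 0.05) v <- conv_axis3(v, gauss_kernel(sig_y), 2L)
  if (sig_x > 0.05) v <- conv_axis3(v, gauss_kernel(sig_x), 3L)
  # axial, sigma depends on lateral distance from the waist axis
  if (imaging$sheet_edge_um == imaging$sheet_waist_um) {
    # spatially uniform sheet: one exact separable convolution
    s <- imaging$sheet_waist_um * fwhm2sd / sp[1]
    if (s > 0.05) v <- conv_axis3(v, gauss_kernel(s), 1L)
  } else {
    nx <- dim(v)[3]
    x_um <- ((seq_len(nx)) - 0.5) * sp[3]
    dist <- abs(x_um - mean(range(x_um)))
    frac <- pmin(dist / imaging$sheet_edge_distance_um, 1)
    fwhm <- imaging$sheet_waist_um + (imaging$sheet_edge_um - imaging$sheet_waist_um) * frac
    sig_z <- round(fwhm * fwhm2sd / sp[1], 1) # quantize to batch columns
    for (s in unique(sig_z)) {
      if (s <= 0.05) next
      idx <- which(sig_z == s)
      v[, , idx] <- conv_axis3(v[, , idx, drop = FALSE], gauss_kernel(s), 1L)
    }
  }
  image_stack(v, sp)
}

# separable 1D convolution along one axis of a 3D array, edge-renormalized
conv_axis3 <- function(a, kernel, axis) {
  if (length(kernel) == 1L) return(a * kernel)
  d <- dim(a)
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  dp <- dim(ap)
  n <- dp[1]
  h <- (length(kernel) - 1L) %/% 2L
  if (2L * h + 1L > n) {
    stop("blur kernel (", 2 * h + 1, " samples) wider than the stack extent (",
         n, ") along axis ", axis)
  }
  m <- matrix(ap, n, dp[2] * dp[3])
  acc <- matrix(0, n, ncol(m))
  normv <- numeric(n)
  for (j in seq_along(kernel)) {
    off <- j - h - 1L
    w <- kernel[j]
    dst <- max(1L, 1L - off):min(n, n - off)
    acc[dst, ] <- acc[dst, ] + w * m[dst + off, , drop = FALSE]
    normv[dst] <- normv[dst] + w
  }
  acc <- acc / normv
  dim(acc) <- dp
  aperm(acc, order(perm))
}

#' Apply shot and read noise
#'
#' Detected electrons are Poisson with mean `level * photon_scale`; Gaussian
#' read noise (sd in electrons) is added and the result referred back to the
#' level scale, so a constant level L acquires variance
#' `L / photon_scale + (read_noise_sd / photon_scale)^2`. Negative excursions
#' are clipped at zero. Seeded and reproducible.
#'
#' @param stack an [image_stack()]; intensities must be non-negative.
#' @param imaging an [imaging_model()].
#' @param seed integer RNG seed.
#' @return noisy [image_stack()].
#' @export
apply_noise <- function(stack, imaging, seed = 1L) {
  v <- stack$voxels
  if (any(v < 0)) stop("apply_noise requires non-negative intensities")
  s <- imaging$photon_scale
  with_seed(seed, {
    n <- length(v)
    e <- stats::rpois(n, lambda = as.numeric(v) * s)
    if (imaging$read_noise_sd > 0) e <- e + stats::rnorm(n, 0, imaging$read_noise_sd)
    out <- array(pmax(e, 0) / s, dim(v))
    image_stack(out, stack$spacing)
  })
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %s voxels, %d follicles, %d vessels, %d egg nests, seed %d\n",
              paste(x$volume_shape, collapse = " x "), length(x$follicles),
              length(x$vessels), length(x$egg_nests), x$seed))
  invisible(x)
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> %d structures, %s label volume\n",
              length(x$structures), paste(dim(x$labels), collapse = " x ")))
  invisible(x)
}

#' Flatten a ground-truth manifest to a data frame
#' @param truth a `phantom_truth` from [build_phantom()].
#' @export
truth_table <- function(truth) {
  rows <- lapply(truth$structures, function(s) {
    data.frame(
      id = s$id, class = s$class, stage = s$stage,
      center_z_um = s$center_um[1], center_y_um = s$center_um[2],
      center_x_um = s$center_um[3],
      true_volume_mm3 = s$true_volume_mm3,
      voxel_volume_mm3 = s$voxel_volume_mm3,
      true_equivalent_diameter_um =
        if (!is.null(s$true_equivalent_diameter_um)) s$true_equivalent_diameter_um else NA_real_,
      true_equatorial_ratio = s$true_equatorial_ratio,
      true_mean_thickness_um = s$true_mean_thickness_um,
      true_coc_diameter_um = s$true_coc_diameter_um
    )
  })
  do.call(rbind, rows)
}
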