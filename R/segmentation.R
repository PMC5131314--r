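# Automated follicle segmentation and shell decomposition, plus the
# manual-mask ingestion path used when segmentations are drawn by hand.

#' Segmentation parameters
#'
#' @param smooth_sigma_um Gaussian denoising sigma, micrometres.
#' @param threshold absolute intensity threshold for the bright thecal
#'   shell; NULL (default) uses a global Otsu threshold on the smoothed
#'   stack (phantom and cleared-tissue contrast are both near-bimodal).
#' @param close_radius_vox 6-connected morphological closing radius, voxels.
#' @param min_diameter_um minimum equivalent diameter retained.
#' @param split_touching split touching follicles with a distance-transform
#'   watershed (per connected component).
#' @param split_tolerance_um watershed merge tolerance (micrometres of
#'   inscribed-radius difference); lobes shallower than this are not split.
#' @param rind_depth_um depth of the outer rind (from the follicle surface
#'   inwards) searched for the bright thecal shell.
#' @param elongation_threshold principal-axis ratio above which a component
#'   is classed a blood vessel.
#' @export
seg_params <- function(smooth_sigma_um = 5, threshold = NULL,
                       close_radius_vox = 1L, min_diameter_um = 40,
                       split_touching = TRUE, split_tolerance_um = 60,
                       rind_depth_um = 160, elongation_threshold = 4) {
  structure(list(smooth_sigma_um = smooth_sigma_um, threshold = threshold,
                 close_radius_vox = as.integer(close_radius_vox),
                 min_diameter_um = min_diameter_um,
                 split_touching = split_touching,
                 split_tolerance_um = split_tolerance_um,
                 rind_depth_um = rind_depth_um,
                 elongation_threshold = elongation_threshold),
            class = "seg_params")
}

#' Integer label volume aligned to an image stack
#'
#' @param labels 3D integer array; 0 = background.
#' @param spacing (dz, dy, dx) micrometres.
#' @param class_map named character vector mapping label ids to
#'   `"follicle"` or `"vessel"`; defaults to all-follicle.
#' @export
label_volume <- function(labels, spacing, class_map = NULL) {
  if (length(dim(labels)) != 3L) stop("labels must be a 3D array")
  ids <- setdiff(sort(unique(as.integer(labels))), 0L)
  if (length(ids) && min(ids) < 0L) stop("labels must be non-negative")
  if (is.null(class_map)) {
    class_map <- setNames(rep("follicle", length(ids)), as.character(ids))
  }
  structure(list(labels = labels, spacing = as.numeric(spacing),
                 class_map = class_map),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  n <- length(x$class_map)
  cat(sprintf("<label_volume> %s voxels, %d labels (%d follicle, %d vessel)\n",
              paste(dim(x$labels), collapse = " x "), n,
              sum(x$class_map == "follicle"), sum(x$class_map == "vessel")))
  invisible(x)
}

label_ids <- function(lv, class = NULL) {
  ids <- as.integer(names(lv$class_map))
  if (is.null(class)) ids else ids[lv$class_map == class]
}

# global Otsu threshold on a numeric volume via EBImage (single histogram)
otsu_threshold <- function(v) {
  EBImage::otsu(EBImage::Image(matrix(as.numeric(v), nrow = 1L)),
                range = range(v), levels = 256L)
}

# bounding box (z0, z1, y0, y1, x0, x1) of a mask, padded and clamped
mask_bbox <- function(mask, pad = 1L) {
  d <- dim(mask)
  idx <- which(mask, arr.ind = TRUE)
  lo <- pmax(apply(idx, 2, min) - pad, 1L)
  hi <- pmin(apply(idx, 2, max) + pad, d)
  c(lo[1], hi[1], lo[2], hi[2], lo[3], hi[3])
}

crop_bbox <- function(a, bb) a[bb[1]:bb[2], bb[3]:bb[4], bb[5]:bb[6], drop = FALSE]

#' Segment follicles in a stack
#'
#' Detection pipeline: Gaussian denoising, global Otsu (or absolute)
#' thresholding of the bright thecal shells, 6-connected morphological
#' closing, 3D filling of enclosed lumens, 26-connected component
#' labelling, an optional distance-transform watershed split of touching
#' follicles, and a minimum-size filter. Deterministic for fixed input and
#' parameters; the parameter object is attached to the result as attribute
#' `"params"`.
#'
#' @param stack an [image_stack()].
#' @param params a [seg_params()].
#' @return a [label_volume()]; empty (no labels) when nothing is detected.
#' @export
segment_follicles <- function(stack, params = seg_params()) {
  v <- stack$voxels
  sp <- stack$spacing
  if (mean(v >= 0.9999) > 0.2) {
    warning("stack appears saturated (>20% of voxels at the intensity ceiling)")
  }
  empty <- function() {
    lv <- label_volume(array(0L, dim(v)), sp)
    attr(lv, "params") <- params
    lv
  }
  if (diff(range(v)) < 1e-6) return(empty())
  sm <- v
  for (ax in 1:3) {
    sig <- params$smooth_sigma_um / (2 * sqrt(2 * log(2))) / sp[ax]
    if (sig > 0.05) sm <- conv_axis3(sm, gauss_kernel(sig), ax)
  }
  thr <- if (is.null(params$threshold)) otsu_threshold(sm) else params$threshold
  bin <- sm > thr
  if (!any(bin)) return(empty())
  bin <- close6(bin, params$close_radius_vox)
  filled <- fill_holes3d(bin)
  lab <- cpp_label3d(filled, 26L)
  if (params$split_touching) lab <- split_touching(lab, filled, sp, params)
  # size filter on equivalent diameter
  counts <- tabulate(lab)
  vox_mm3 <- prod(sp) * 1e-9
  keep <- which(counts > 0 &
                  equivalent_diameter(pmax(counts, 1) * vox_mm3) >= params$min_diameter_um)
  relab <- integer(length(counts))
  relab[keep] <- seq_along(keep)
  out <- array(0L, dim(lab))
  nz <- lab > 0L
  out[nz] <- relab[lab[nz]]
  lv <- label_volume(out, sp)
  attr(lv, "params") <- params
  lv
}

# watershed split of touching follicles, applied per connected component on
# its cropped distance transform; seeds are the lumen/interior EDT maxima
split_touching <- function(lab, mask, spacing, params) {
  nlab <- max(lab)
  if (nlab == 0L) return(lab)
  next_id <- nlab + 1L
  for (id in seq_len(nlab)) {
    m <- lab == id
    if (!any(m)) next
    bb <- mask_bbox(m, pad = 1L)
    mc <- crop_bbox(m, bb)
    edt <- cpp_edt3d(mc, spacing)
    # quick rejection: a component splits only if it has at least two
    # distance-transform plateaus deeper than the merge tolerance
    peaks <- cpp_label3d(mc & edt >= max(edt) - params$split_tolerance_um, 26L)
    if (max(peaks) < 2L) next
    ws <- EBImage::watershed(edt, tolerance = params$split_tolerance_um, ext = 1L)
    ws <- as.array(ws)
    k <- max(ws)
    if (k > 1L) {
      sub <- lab[bb[1]:bb[2], bb[3]:bb[4], bb[5]:bb[6]]
      for (j in 2:k) {
        sub[ws == j] <- next_id
        next_id <- next_id + 1L
      }
      lab[bb[1]:bb[2], bb[3]:bb[4], bb[5]:bb[6]] <- sub
    }
  }
  lab
}

#' Reclassify elongated components as blood vessels
#'
#' Blood vessels extend through the stack while follicles appear and
#' disappear over few planes; components whose longest/second-longest
#' principal-axis ratio (physical units) exceeds the threshold are classed
#' as vessels. Single-voxel components have an undefined ratio and stay
#' follicles.
#'
#' @param lv a [label_volume()].
#' @param elongation_threshold axis-ratio threshold (default 4).
#' @return the [label_volume()] with an updated class map.
#' @export
discriminate_vessels <- function(lv, elongation_threshold = 4) {
  for (id in label_ids(lv)) {
    m <- lv$labels == id
    ax <- principal_axis_sd_um(m, lv$spacing)
    ratio <- if (ax[2] <= 0) 1 else ax[1] / ax[2]
    lv$class_map[[as.character(id)]] <-
      if (ratio > elongation_threshold) "vessel" else "follicle"
  }
  lv
}

#' Decompose one follicle into theca, gap, granulosa and lumen masks
#'
#' The bright thecal shell is thresholded (per-follicle Otsu restricted to
#' the outer rind, compensating inter-follicle intensity variation); the
#' dark delamination band inside it is the gap; the remaining interior
#' (granulosa lining plus antrum) is the lumen. Boundary voxel sets use
#' face (6-) adjacency: outer boundary voxels touch the exterior, inner
#' boundary voxels touch the interior. All masks are cropped to the
#' follicle bounding box; `origin_vox` gives the 0-based offset into the
#' full volume.
#'
#' @param stack an [image_stack()].
#' @param lv a [label_volume()].
#' @param follicle_id label id to decompose.
#' @param params a [seg_params()].
#' @return a `follicle_masks` object.
#' @export
extract_shell_masks <- function(stack, lv, follicle_id, params = seg_params()) {
  m <- lv$labels == follicle_id
  if (!any(m)) stop("no voxels carry label ", follicle_id)
  sp <- lv$spacing
  bb <- mask_bbox(m, pad = 1L)
  whole <- crop_bbox(m, bb)
  v <- crop_bbox(stack$voxels, bb)
  depth <- cpp_edt3d(whole, sp) # distance to exterior, 0 outside
  rind <- whole & depth <= params$rind_depth_um
  thr <- otsu_threshold(v[rind])
  shell0 <- whole & rind & v >= thr
  if (!any(shell0)) stop("follicle ", follicle_id, ": no bright shell voxels found")
  # keep shell components near the follicle surface (the segmentation mask
  # may carry a 1-2 voxel blur halo, so pure surface contact is too strict);
  # interior bright blobs (granulosa, COC) sit deeper and are excluded
  comp <- cpp_label3d(shell0, 26L)
  halo_tol <- 3 * max(sp)
  near_surface <- depth <= halo_tol
  ids <- setdiff(unique(comp[near_surface & shell0]), 0L)
  theca <- array(comp %in% ids, dim(comp))
  # interior = non-theca voxels not connected to the crop border; the dark
  # halo ring outside the shell joins the exterior component
  ncomp <- cpp_label3d(!theca, 6L)
  d <- dim(theca)
  border_ids <- setdiff(unique(c(ncomp[1, , ], ncomp[d[1], , ], ncomp[, 1, ],
                                 ncomp[, d[2], ], ncomp[, , 1], ncomp[, , d[3]])), 0L)
  exterior <- array(ncomp %in% border_ids, d)
  interior <- !theca & !exterior
  if (sum(interior) < 0.05 * sum(whole)) {
    if (max(depth) > params$rind_depth_um + 2 * max(sp)) {
      stop("follicle ", follicle_id, ": thecal shell is not closed ",
           "(interior leaks to the exterior)")
    }
    stop("follicle ", follicle_id, ": solid (no resolvable lumen)")
  }
  outer_b <- theca & dilate6(exterior)
  inner_b <- theca & dilate6(interior)
  gap <- array(FALSE, dim(whole))
  granulosa <- array(FALSE, dim(whole))
  if (sum(interior) > 8L) {
    ithr <- otsu_threshold(v[interior])
    bright <- interior & v >= ithr
    dark <- interior & !bright
    if (any(dark)) {
      dcomp <- cpp_label3d(dark, 6L)
      near_theca <- dilate6(theca)
      gap_ids <- setdiff(unique(dcomp[dark & near_theca]), 0L)
      # a dark component is the delamination gap only if it hugs the shell;
      # the antrum also touches the wall when no gap exists, so require the
      # component to stay thin relative to the follicle. One distance
      # transform over all dark voxels serves every component: components
      # are 6-disconnected, so their depths are independent.
      dedt <- cpp_edt3d(dark, sp)
      comp_depth <- tapply(dedt[dark], dcomp[dark], max)
      thin <- as.integer(names(comp_depth))[
        comp_depth <= 0.15 * min(max(depth), params$rind_depth_um) + max(sp)]
      gap <- array(dcomp %in% intersect(gap_ids, thin), dim(whole))
    }
    granulosa <- bright
  }
  lumen <- interior & !gap
  structure(list(
    follicle_id = follicle_id, origin_vox = c(bb[1], bb[3], bb[5]) - 1L,
    spacing = sp, whole = whole, theca = theca, gap = gap,
    granulosa = granulosa, lumen = lumen,
    outer_boundary = outer_b, inner_boundary = inner_b, intensity = v
  ), class = "follicle_masks")
}

#' @export
print.follicle_masks <- function(x, ...) {
  cat(sprintf(
    "<follicle_masks> id %s: whole %d, theca %d, gap %d, lumen %d voxels (crop %s)\n",
    x$follicle_id, sum(x$whole), sum(x$theca), sum(x$gap), sum(x$lumen),
    paste(dim(x$whole), collapse = " x ")))
  invisible(x)
}

#' Detect cumulus-oophorus complexes in a follicle lumen
#'
#' COCs appear as bright, compact blobs protruding into the fluid-filled
#' lumen and attached to the inner follicle wall. Candidate blobs are the
#' brightest lumen voxels (a second Otsu separates them from the granulosa
#' lining); blobs within the diameter band and attached to the wall
#' (face-adjacent to granulosa, gap or theca after 1-voxel dilation) are
#' eligible; the largest is accepted, others are reported as candidates.
#' Detached bright blobs floating mid-lumen are never accepted.
#'
#' @param stack an [image_stack()] (full volume; cropped internally).
#' @param mask_set a `follicle_masks`.
#' @param diameter_band accepted COC equivalent-diameter band, micrometres.
#' @return `list(accepted = <0 or 1 masks>, candidates = <masks>)`, each mask
#'   cropped like the mask set.
#' @export
detect_cocs <- function(stack, mask_set, diameter_band = c(25, 150)) {
  v <- mask_set$intensity
  sp <- mask_set$spacing
  lum_bright <- mask_set$granulosa # bright interior: lining + any COC
  if (sum(lum_bright) < 8L) return(list(accepted = list(), candidates = list()))
  thr <- otsu_threshold(v[lum_bright])
  cand <- lum_bright & v >= thr
  if (!any(cand)) return(list(accepted = list(), candidates = list()))
  # the COC must be distinctly brighter than the granulosa lining; if the
  # second threshold merely bisects the lining's own noise, there is no COC
  gran_vals <- v[lum_bright & !cand]
  if (length(gran_vals) > 8L) {
    guard <- mean(gran_vals) + 5 * stats::sd(gran_vals)
    if (mean(v[cand]) < guard) return(list(accepted = list(), candidates = list()))
  }
  comp <- cpp_label3d(cand, 26L)
  wall <- mask_set$theca | mask_set$gap | (lum_bright & !cand)
  accepted <- list(); candidates <- list(); acc_size <- 0L
  for (id in seq_len(max(comp))) {
    m <- comp == id
    n <- sum(m)
    d <- tryCatch(coc_diameter(m, sp), error = function(e) NA_real_)
    if (!is.finite(d) || d < diameter_band[1] || d > diameter_band[2]) next
    attached <- any(dilate6(m) & wall)
    if (!attached) {
      candidates <- c(candidates, list(m))
      next
    }
    if (n > acc_size) {
      if (acc_size > 0L) candidates <- c(candidates, accepted)
      accepted <- list(m); acc_size <- n
    } else {
      candidates <- c(candidates, list(m))
    }
  }
  list(accepted = accepted, candidates = candidates)
}

#' Adopt an externally supplied (manual) label volume
#'
#' @param labels path to an integer label TIFF (see [write_label_volume()])
#'   or a 3D integer array.
#' @param stack the [image_stack()] the labels belong to.
#' @return a [label_volume()], validated against the stack shape.
#' @export
ingest_manual_masks <- function(labels, stack) {
  if (is.character(labels)) labels <- read_label_volume(labels)
  if (!identical(dim(labels), dim(stack$voxels))) {
    stop("label volume shape (", paste(dim(labels), collapse = "x"),
         ") does not match the stack (", paste(dim(stack$voxels), collapse = "x"), ")")
  }
  label_volume(labels, stack$spacing)
}

#' Write / read integer label volumes as 16-bit multi-page TIFF
#' @param labels 3D integer array (values < 65536).
#' @param path TIFF path.
#' @export
write_label_volume <- function(labels, path) {
  if (max(labels) > 65535L) stop("labels exceed the 16-bit range")
  pages <- lapply(seq_len(dim(labels)[1]), function(iz) labels[iz, , ] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "LZW")
  invisible(path)
}

#' @rdname write_label_volume
#' @export
read_label_volume <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  nz <- length(pages)
  d <- dim(pages[[1]])
  out <- array(0L, c(nz, d[1], d[2]))
  for (iz in seq_len(nz)) out[iz, , ] <- as.integer(round(pages[[iz]] * 65535))
  out
}

#' Dice overlap coefficient between two masks
#' @param a,b logical arrays of identical shape.
#' @export
dice_coefficient <- function(a, b) {
  2 * sum(a & b) / (sum(a) + sum(b))
}

#' Flag primordial candidates among small solid detections
#'
#' Primordial follicles cluster in egg nests near the cortex. Small solid
#' detections (no resolvable wall) within the diameter band that have at
#' least `min_neighbors` similar detections within `neighbor_radius_um`
#' are re-staged as `"primordial"` (counting only; no shell metrics).
#'
#' @param measurements cohort measurement data.frame.
#' @param diameter_band micrometre band for candidates.
#' @param neighbor_radius_um clustering radius.
#' @param min_neighbors minimum similar neighbours.
#' @export
flag_primordial_candidates <- function(measurements, diameter_band = c(40, 100),
                                       neighbor_radius_um = 300,
                                       min_neighbors = 2L) {
  if (nrow(measurements) == 0L) return(measurements)
  solid <- is.na(measurements$thickness_mean_um) &
    measurements$equivalent_diameter_um >= diameter_band[1] &
    measurements$equivalent_diameter_um <= diameter_band[2]
  idx <- which(solid)
  if (length(idx) == 0L) return(measurements)
  P <- as.matrix(measurements[idx, c("centroid_z_um", "centroid_y_um", "centroid_x_um")])
  for (k in seq_along(idx)) {
    dists <- sqrt(colSums((t(P) - P[k, ])^2))
    if (sum(dists > 0 & dists <= neighbor_radius_um) >= min_neighbors) {
      measurements$stage[idx[k]] <- "primordial"
    }
  }
  measurements
}
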