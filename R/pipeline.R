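# Reproducible pipeline stages: simulate -> measure -> evaluate. Each run
# writes provenance (parameters, package version, seed) sufficient to
# reproduce it.

#' Serialize / load a phantom spec as YAML
#' @param spec a [phantom_spec()].
#' @param path YAML file path.
#' @export
write_phantom_spec <- function(spec, path) {
  ser <- list(
    volume_shape = spec$volume_shape,
    follicles = lapply(spec$follicles, function(f) {
      out <- f[c("center", "semi_axes", "orientation", "theca_thickness_base",
                 "theca_thickness_modulation", "gap_width", "granulosa_width")]
      if (!is.null(f$coc)) out$coc <- list(diameter = f$coc$diameter,
                                           direction = as.numeric(f$coc$direction))
      out
    }),
    vessels = lapply(spec$vessels, function(v) {
      list(polyline = apply(v$polyline, 1, as.numeric, simplify = FALSE),
           radius = v$radius)
    }),
    egg_nests = spec$egg_nests,
    imaging = unclass(spec$imaging),
    background_level = spec$background_level,
    intensities = spec$intensities,
    seed = spec$seed,
    overlap_tolerance_vox = spec$overlap_tolerance_vox
  )
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$volume_shape)) stop("invalid phantom spec: missing field volume_shape")
  img <- do.call(imaging_model, y$imaging)
  follicles <- lapply(y$follicles, function(f) do.call(follicle_phantom, f))
  vessels <- lapply(y$vessels, function(v) {
    vessel_phantom(do.call(rbind, v$polyline), v$radius)
  })
  phantom_spec(volume_shape = unlist(y$volume_shape), follicles = follicles,
               vessels = vessels, egg_nests = y$egg_nests, imaging = img,
               background_level = y$background_level %||% 0.08,
               intensities = y$intensities %||% default_intensities(),
               seed = y$seed %||% 1L,
               overlap_tolerance_vox = y$overlap_tolerance_vox %||% 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a phantom and write its stack, truth labels and manifest
#'
#' @param spec a [phantom_spec()] or path to a spec YAML.
#' @param out_dir output directory (created if needed): writes `stack.tiff`
#'   (+ spacing sidecar), `truth_labels.tiff`, `truth.json`,
#'   `provenance.json`.
#' @param blur,noise imaging-model switches.
#' @return `list(stack, truth, paths)`, invisibly when writing.
#' @export
simulate_phantom <- function(spec, out_dir = NULL, blur = TRUE, noise = TRUE) {
  if (is.character(spec)) spec <- read_phantom_spec(spec)
  res <- build_phantom(spec, blur = blur, noise = noise)
  if (is.null(out_dir)) return(res)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(stack = file.path(out_dir, "stack.tiff"),
                labels = file.path(out_dir, "truth_labels.tiff"),
                truth = file.path(out_dir, "truth.json"),
                spec = file.path(out_dir, "spec.yaml"),
                provenance = file.path(out_dir, "provenance.json"))
  write_stack(res$stack, paths$stack)
  write_label_volume(res$truth$labels, paths$labels)
  write_truth_manifest(res$truth, paths$truth)
  write_phantom_spec(spec, paths$spec)
  write_provenance(paths$provenance, seed = spec$seed,
                   config = paths$spec, stage = "simulate")
  res$paths <- paths
  invisible(res)
}

write_truth_manifest <- function(truth, path) {
  payload <- list(
    spacing_um = truth$spacing,
    seed = truth$seed,
    structures = lapply(truth$structures, function(s) {
      s$center_um <- as.numeric(s$center_um)
      if (!is.null(s$coc_center_um)) s$coc_center_um <- as.numeric(s$coc_center_um)
      s
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Read a ground-truth manifest written by [simulate_phantom()]
#' @param path truth.json path.
#' @export
read_truth_manifest <- function(path) {
  y <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  structure(list(structures = y$structures, labels = NULL,
                 spacing = as.numeric(y$spacing_um), seed = y$seed),
            class = "phantom_truth")
}

write_provenance <- function(path, seed, config, stage) {
  prov <- list(
    stage = stage,
    package = "folliculometry",
    version = as.character(utils::packageVersion("folliculometry")),
    r_version = R.version.string,
    seed = seed,
    config_file = config,
    config_md5 = if (is.character(config) && file.exists(config))
      unname(tools::md5sum(config)) else NA_character_,
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(prov, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

# measurement table with zero rows but the full column contract
empty_measurements <- function() {
  data.frame(follicle_id = integer(), voxel_count = integer(),
             volume_mm3 = numeric(), equivalent_diameter_um = numeric(),
             equatorial_plane = integer(), asymmetry = numeric(),
             asymmetry_minor_major = numeric(), thickness_mean_um = numeric(),
             thickness_sd_um = numeric(), thickness_n = integer(),
             coc_diameter_um = numeric(), orthogonal_diameter_um = numeric(),
             stage = character(), centroid_z_um = numeric(),
             centroid_y_um = numeric(), centroid_x_um = numeric())
}

# volume/shape-only measurement used when the wall cannot be decomposed
measure_whole_only <- function(whole, id, origin, spacing, thresholds) {
  vol <- follicle_volume(whole, spacing)
  d <- equivalent_diameter(vol)
  ctr <- mask_centroid_um(whole, spacing) + origin * spacing
  data.frame(
    follicle_id = id, voxel_count = sum(whole), volume_mm3 = vol,
    equivalent_diameter_um = d,
    equatorial_plane = equatorial_plane(whole) + origin[1],
    asymmetry = tryCatch(equatorial_asymmetry(whole, spacing),
                         error = function(e) NA_real_),
    asymmetry_minor_major = NA_real_,
    thickness_mean_um = NA_real_, thickness_sd_um = NA_real_,
    thickness_n = NA_integer_,
    coc_diameter_um = NA_real_,
    orthogonal_diameter_um = tryCatch(
      orthogonal_diameter_estimate(whole, spacing), error = function(e) NA_real_),
    stage = as.character(classify_stage(d, thresholds)),
    centroid_z_um = ctr[1], centroid_y_um = ctr[2], centroid_x_um = ctr[3]
  )
}

#' Measure every follicle in a stack
#'
#' Runs segmentation (or adopts supplied manual labels), discriminates
#' blood vessels, decomposes each follicle into shell masks, measures all
#' folliculometric quantities, flags primordial candidates, and computes
#' cohort statistics and the inverse log-volume regressions. With
#' `out_dir`, writes `measurements.csv`, `cohort_summary.csv`,
#' `report.txt`, `regressions.json` and `provenance.json`.
#'
#' @param stack an [image_stack()] or path to a stack TIFF.
#' @param labels optional manual [label_volume()], array, or label TIFF path.
#' @param params a [seg_params()].
#' @param thresholds a [stage_thresholds()].
#' @param out_dir optional output directory.
#' @param spacing explicit spacing override when `stack` is a path.
#' @return list with `labels` (label_volume), `measurements` (data.frame),
#'   `summary` (per-stage table), `regressions` (list of `folli_regression`).
#' @export
measure_stack <- function(stack, labels = NULL, params = seg_params(),
                          thresholds = stage_thresholds(), out_dir = NULL,
                          spacing = NULL) {
  if (is.character(stack)) stack <- read_stack(stack, spacing = spacing)
  lv <- if (is.null(labels)) {
    segment_follicles(stack, params)
  } else if (inherits(labels, "label_volume")) {
    labels
  } else {
    ingest_manual_masks(labels, stack)
  }
  lv <- discriminate_vessels(lv, params$elongation_threshold)
  rows <- list()
  for (id in label_ids(lv, "follicle")) {
    row <- tryCatch({
      ms <- extract_shell_masks(stack, lv, id, params)
      r <- measure_follicle(stack, ms, thresholds)
      r$equatorial_plane <- r$equatorial_plane + ms$origin_vox[1]
      r$centroid_z_um <- r$centroid_z_um + ms$origin_vox[1] * lv$spacing[1]
      r$centroid_y_um <- r$centroid_y_um + ms$origin_vox[2] * lv$spacing[2]
      r$centroid_x_um <- r$centroid_x_um + ms$origin_vox[3] * lv$spacing[3]
      attr(r, "thickness") <- NULL
      class(r) <- "data.frame"
      r
    }, error = function(e) {
      m <- lv$labels == id
      bb <- mask_bbox(m, pad = 0L)
      measure_whole_only(crop_bbox(m, bb), id, c(bb[1], bb[3], bb[5]) - 1L,
                         lv$spacing, thresholds)
    })
    rows <- c(rows, list(row))
  }
  meas <- if (length(rows)) do.call(rbind, rows) else empty_measurements()
  meas <- flag_primordial_candidates(meas)
  summ <- cohort_volume_summary(meas)
  regressions <- list()
  with_thick <- meas[is.finite(meas$thickness_mean_um), , drop = FALSE]
  if (nrow(with_thick) >= 3L) {
    regressions$thickness_vs_logvolume <-
      loglinear_regression(with_thick$volume_mm3, with_thick$thickness_mean_um)
  }
  with_asym <- meas[is.finite(meas$asymmetry), , drop = FALSE]
  if (nrow(with_asym) >= 3L) {
    regressions$asymmetry_vs_logvolume <-
      loglinear_regression(with_asym$volume_mm3, with_asym$asymmetry)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(meas, file.path(out_dir, "measurements.csv"), row.names = FALSE)
    utils::write.csv(summ, file.path(out_dir, "cohort_summary.csv"), row.names = FALSE)
    writeLines(cohort_report_text(meas, summ, regressions),
               file.path(out_dir, "report.txt"))
    jsonlite::write_json(
      lapply(regressions, function(r) r[c("family", "coefficients", "n",
                                          "r_squared", "adj_r_squared",
                                          "residual_sd")]),
      file.path(out_dir, "regressions.json"), auto_unbox = TRUE, digits = NA)
    pfile <- file.path(out_dir, "params.yaml")
    yaml::write_yaml(unclass(params), pfile)
    write_provenance(file.path(out_dir, "provenance.json"), seed = NA,
                     config = pfile, stage = "measure")
  }
  list(labels = lv, measurements = meas, summary = summ, regressions = regressions)
}

cohort_report_text <- function(meas, summ, regressions) {
  lines <- c("Folliculometric cohort report", "=============================", "")
  lines <- c(lines, sprintf("Follicles measured: %d", nrow(meas)),
             sprintf("Stages: %s", paste(sprintf("%s = %d",
               names(table(meas$stage)), table(meas$stage)), collapse = ", ")), "")
  if (nrow(summ)) {
    lines <- c(lines, "Per-stage volume (mean [Q1-Q3]):",
               sprintf("  %-10s n=%-3d %s", summ$stage, summ$n, summ$formatted), "")
  }
  for (nm in names(regressions)) {
    r <- regressions[[nm]]
    lines <- c(lines, sprintf("%s: slope = %.4g, R^2 = %.3f (n = %d)",
                              nm, r$coefficients[["slope"]], r$r_squared, r$n))
  }
  lines
}

#' Compare measurements against a phantom ground truth
#'
#' Measured follicles are matched to truth structures by nearest centroid
#' (greedy on the global minimum distance; injective). Per matched pair the
#' relative errors of volume, equivalent diameter, asymmetry ratio, mean
#' wall thickness and COC diameter are reported, plus the Dice overlap when
#' both label volumes are given, staging agreement, and COC recall.
#'
#' @param measurements measurement data.frame from [measure_stack()].
#' @param truth a `phantom_truth` (or path to `truth.json`).
#' @param measured_labels optional [label_volume()] for Dice computation.
#' @param truth_labels optional truth label array (defaults to
#'   `truth$labels` when present).
#' @param max_match_um centroid distance cap for a valid match.
#' @return list with `matches` (data.frame), `unmatched_truth` ids and a
#'   `summary` list of aggregate recovery metrics.
#' @export
evaluate_recovery <- function(measurements, truth, measured_labels = NULL,
                              truth_labels = NULL, max_match_um = 200) {
  if (is.character(truth)) truth <- read_truth_manifest(truth)
  if (is.null(truth_labels)) truth_labels <- truth$labels
  tr <- Filter(function(s) s$class %in% c("follicle", "egg_nest_member"),
               truth$structures)
  if (length(tr) == 0L || nrow(measurements) == 0L) {
    return(list(matches = data.frame(), unmatched_truth = vapply(tr, `[[`, 0L, "id"),
                summary = list(n_matched = 0L)))
  }
  tc <- t(vapply(tr, function(s) as.numeric(s$center_um), numeric(3)))
  mc <- as.matrix(measurements[, c("centroid_z_um", "centroid_y_um", "centroid_x_um")])
  D <- outer(seq_len(nrow(tc)), seq_len(nrow(mc)), Vectorize(function(i, j) {
    sqrt(sum((tc[i, ] - mc[j, ])^2))
  }))
  matches <- list()
  while (TRUE) {
    k <- which.min(D)
    if (!length(k) || !is.finite(D[k]) || min(D, na.rm = TRUE) > max_match_um) break
    i <- (k - 1) %% nrow(D) + 1
    j <- (k - 1) %/% nrow(D) + 1
    s <- tr[[i]]
    # manifests loaded from JSON may carry nulls where in-memory truth has NA
    num <- function(x) {
      if (is.null(x) || length(x) != 1L) return(NA_real_)
      suppressWarnings(as.numeric(x))
    }
    m <- measurements[j, ]
    dice <- NA_real_
    if (!is.null(measured_labels) && !is.null(truth_labels)) {
      dice <- dice_coefficient(truth_labels == s$id,
                               measured_labels$labels == m$follicle_id)
    }
    matches[[length(matches) + 1L]] <- data.frame(
      truth_id = s$id, measured_id = m$follicle_id,
      centroid_dist_um = D[k],
      true_volume_mm3 = num(s$true_volume_mm3), volume_mm3 = m$volume_mm3,
      volume_rel_err = abs(m$volume_mm3 - num(s$true_volume_mm3)) /
        num(s$true_volume_mm3),
      true_diameter_um = num(s$true_equivalent_diameter_um),
      diameter_um = m$equivalent_diameter_um,
      true_asymmetry = num(s$true_equatorial_ratio),
      asymmetry = m$asymmetry,
      asymmetry_rel_err = abs(m$asymmetry - num(s$true_equatorial_ratio)) /
        num(s$true_equatorial_ratio),
      true_thickness_um = num(s$true_mean_thickness_um),
      thickness_mean_um = m$thickness_mean_um,
      true_coc_um = num(s$true_coc_diameter_um),
      coc_um = m$coc_diameter_um,
      true_stage = s$stage, stage = m$stage,
      dice = dice
    )
    D[i, ] <- Inf
    D[, j] <- Inf
  }
  matches <- if (length(matches)) do.call(rbind, matches) else data.frame()
  unmatched <- setdiff(vapply(tr, function(s) s$id, 0L),
                       if (nrow(matches)) matches$truth_id else integer())
  coc_truth <- nrow(matches) && any(is.finite(matches$true_coc_um) &
                                      matches$true_coc_um >= 40)
  summary <- list(
    n_truth = length(tr), n_matched = nrow(matches),
    max_volume_rel_err = if (nrow(matches)) max(matches$volume_rel_err) else NA_real_,
    stage_accuracy = if (nrow(matches))
      mean(matches$stage == matches$true_stage) else NA_real_,
    min_dice = if (nrow(matches) && any(is.finite(matches$dice)))
      min(matches$dice, na.rm = TRUE) else NA_real_,
    coc_recall = if (isTRUE(coc_truth)) {
      sel <- is.finite(matches$true_coc_um) & matches$true_coc_um >= 40
      mean(is.finite(matches$coc_um[sel]))
    } else NA_real_,
    coc_max_rel_err = if (isTRUE(coc_truth)) {
      sel <- is.finite(matches$true_coc_um) & matches$true_coc_um >= 40 &
        is.finite(matches$coc_um)
      if (any(sel)) max(abs(matches$coc_um[sel] - matches$true_coc_um[sel]) /
                          matches$true_coc_um[sel]) else NA_real_
    } else NA_real_
  )
  list(matches = matches, unmatched_truth = unmatched, summary = summary)
}

#' Reference phantom scenes
#'
#' `cohort_phantom_spec()` is a 10-follicle scene spanning the primary,
#' antral and Graafian stages (equivalent diameters 74 um to 1.25 mm) with
#' wall thicknesses decreasing from ~120 um (antral) to ~90 um (large
#' Graafian) and COCs of 50--110 um on the larger follicles, in a
#' 150 x 520 x 520 voxel volume at (16, 4, 4) um spacing.
#' `demo_phantom_spec()` is a smaller scene that adds blood vessels and a
#' primordial egg nest.
#'
#' @param seed integer seed stored in the spec.
#' @export
cohort_phantom_spec <- function(seed = 1L) {
  f <- list(
    follicle_phantom(c(150, 150, 150), c(37, 37, 37), theca_thickness_base = 40,
                     gap_width = 0, granulosa_width = 0),
    follicle_phantom(c(150, 150, 400), c(48, 44, 40), orientation = c(0.3, 0.2, 0.5),
                     theca_thickness_base = 45, gap_width = 0, granulosa_width = 0),
    follicle_phantom(c(300, 1500, 300), c(82, 75, 68), orientation = c(0, 0, 0.7),
                     theca_thickness_base = 30, theca_thickness_modulation = 0.15,
                     gap_width = 8, granulosa_width = 12),
    follicle_phantom(c(300, 1800, 700), c(118, 110, 103), orientation = c(0.4, 0.1, 1.1),
                     theca_thickness_base = 45, theca_thickness_modulation = 0.15,
                     gap_width = 10, granulosa_width = 15),
    follicle_phantom(c(1900, 300, 300), c(172, 160, 149), orientation = c(0.2, 0.5, 0.3),
                     theca_thickness_base = 60, theca_thickness_modulation = 0.15,
                     gap_width = 10, granulosa_width = 18,
                     coc = list(diameter = 50, direction = c(0, 0.6, 0.8))),
    follicle_phantom(c(2000, 300, 1000), c(243, 230, 219), orientation = c(0.9, 0.2, 0.4),
                     theca_thickness_base = 95, theca_thickness_modulation = 0.15,
                     gap_width = 12, granulosa_width = 20,
                     coc = list(diameter = 80, direction = c(0.3, -0.7, 0.65))),
    follicle_phantom(c(2050, 1750, 350), c(315, 300, 286), orientation = c(0.1, 0.8, 0.2),
                     theca_thickness_base = 120, theca_thickness_modulation = 0.15,
                     gap_width = 12, granulosa_width = 20,
                     coc = list(diameter = 95, direction = c(-0.4, 0.5, 0.77))),
    follicle_phantom(c(600, 500, 500), c(416, 400, 385), orientation = c(0.5, 0.3, 0.9),
                     theca_thickness_base = 110, theca_thickness_modulation = 0.15,
                     gap_width = 12, granulosa_width = 20,
                     coc = list(diameter = 100, direction = c(0.2, 0.9, 0.39))),
    follicle_phantom(c(600, 520, 1550), c(515, 500, 486), orientation = c(0.2, 0.6, 1.3),
                     theca_thickness_base = 100, theca_thickness_modulation = 0.15,
                     gap_width = 12, granulosa_width = 20,
                     coc = list(diameter = 105, direction = c(0.5, -0.6, 0.62))),
    follicle_phantom(c(1700, 1350, 1350), c(638, 625, 613), orientation = c(1.0, 0.4, 0.6),
                     theca_thickness_base = 90, theca_thickness_modulation = 0.15,
                     gap_width = 12, granulosa_width = 20,
                     coc = list(diameter = 110, direction = c(-0.3, -0.5, 0.81)))
  )
  phantom_spec(volume_shape = c(150L, 520L, 520L), follicles = f, seed = seed)
}

#' @rdname cohort_phantom_spec
#' @export
demo_phantom_spec <- function(seed = 1L) {
  f <- list(
    follicle_phantom(c(500, 400, 400), c(172, 160, 149), orientation = c(0.2, 0.5, 0.3),
                     theca_thickness_base = 60, theca_thickness_modulation = 0.15,
                     gap_width = 10, granulosa_width = 18,
                     coc = list(diameter = 55, direction = c(0, 0.6, 0.8))),
    follicle_phantom(c(500, 400, 950), c(118, 110, 103), orientation = c(0.4, 0.1, 1.1),
                     theca_thickness_base = 45, theca_thickness_modulation = 0.15,
                     gap_width = 10, granulosa_width = 15),
    follicle_phantom(c(1000, 900, 500), c(243, 230, 219), orientation = c(0.9, 0.2, 0.4),
                     theca_thickness_base = 95, theca_thickness_modulation = 0.15,
                     gap_width = 12, granulosa_width = 20,
                     coc = list(diameter = 80, direction = c(0.3, -0.7, 0.65)))
  )
  v <- list(
    vessel_phantom(rbind(c(60, 120, 60), c(400, 150, 400), c(900, 100, 700),
                         c(1440, 150, 1100)), radius = 25),
    vessel_phantom(rbind(c(80, 1200, 100), c(700, 1200, 600), c(1400, 1200, 1150)),
                   radius = 35)
  )
  nests <- list(list(center = c(350, 1000, 1000), count = 5,
                     diameter_range = c(70, 100)))
  phantom_spec(volume_shape = c(96L, 320L, 320L), follicles = f, vessels = v,
               egg_nests = nests, seed = seed)
}
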