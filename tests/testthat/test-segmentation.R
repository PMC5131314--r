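test_that("uniform stack segments to zero labels", {
  st <- image_stack(array(0.3, c(10, 20, 20)), c(16, 4, 4))
  lv <- segment_follicles(st)
  expect_s3_class(lv, "label_volume")
  expect_equal(max(lv$labels), 0L)
})

test_that("noiseless disjoint follicles are each recovered with Dice >= 0.95", {
  spec <- phantom_spec(
    c(60L, 200L, 200L),
    list(
      follicle_phantom(c(250, 200, 200), c(90, 80, 75), theca_thickness_base = 35,
                       gap_width = 8, granulosa_width = 12),
      follicle_phantom(c(250, 200, 600), c(120, 110, 100), theca_thickness_base = 45,
                       gap_width = 10, granulosa_width = 15),
      follicle_phantom(c(650, 550, 400), c(150, 140, 130), theca_thickness_base = 55,
                       theca_thickness_modulation = 0.15,
                       gap_width = 10, granulosa_width = 18)
    ),
    seed = 4L
  )
  res <- build_phantom(spec, blur = FALSE, noise = FALSE)
  lv <- segment_follicles(res$stack)
  expect_equal(length(folliculometry:::label_ids(lv)), 3L)
  tt <- truth_table(res$truth)
  for (k in seq_len(nrow(tt))) {
    truth_mask <- res$truth$labels == tt$id[k]
    ctr <- round(c(tt$center_z_um[k] / 16, tt$center_y_um[k] / 4,
                   tt$center_x_um[k] / 4))
    id <- lv$labels[ctr[1], ctr[2], ctr[3]]
    expect_gt(id, 0L)
    expect_gte(dice_coefficient(truth_mask, lv$labels == id), 0.95)
  }
})

test_that("segmentation on a noisy blurred phantom keeps Dice >= 0.9 (d >= 100 um)", {
  res <- demo_build()
  out <- demo_measured()
  ev <- evaluate_recovery(out$measurements, res$truth, measured_labels = out$labels)
  m <- ev$matches
  big <- is.finite(m$true_diameter_um) & m$true_diameter_um >= 100
  expect_true(all(m$dice[big] >= 0.9))
})

test_that("segmentation is deterministic for fixed input and params", {
  res <- demo_build()
  a <- segment_follicles(res$stack)
  b <- segment_follicles(res$stack)
  expect_identical(a$labels, b$labels)
})

test_that("elongated tubes are reclassified as vessels, spheres stay follicles", {
  # synthetic label volume: a straight tube spanning z and a sphere
  sp <- c(16, 4, 4)
  sh <- c(60L, 100L, 100L)
  tube <- folliculometry:::cpp_voxelize_tube(rbind(c(8, 200, 60), c(952, 200, 340)),
                                             20, sp, sh)
  ball <- voxelize_ellipsoid(c(480, 250, 120), c(60, 60, 60), spacing = sp, shape = sh)
  lab <- array(0L, sh)
  lab[tube] <- 1L
  lab[ball] <- 2L
  lv <- label_volume(lab, sp)
  lv <- discriminate_vessels(lv)
  expect_equal(unname(lv$class_map[["1"]]), "vessel")
  expect_equal(unname(lv$class_map[["2"]]), "follicle")
})

test_that("single-voxel components have undefined elongation and stay follicles", {
  lab <- array(0L, c(5, 5, 5)); lab[3, 3, 3] <- 1L
  lv <- discriminate_vessels(label_volume(lab, c(16, 4, 4)))
  expect_equal(unname(lv$class_map[["1"]]), "follicle")
})

test_that("phantom vessels and follicles are classified 100% correctly", {
  res <- demo_build()
  out <- demo_measured()
  lv <- out$labels
  tt <- truth_table(res$truth)
  for (k in seq_len(nrow(tt))) {
    ctr <- round(c(tt$center_z_um[k] / 16, tt$center_y_um[k] / 4, tt$center_x_um[k] / 4))
    id <- lv$labels[ctr[1], ctr[2], ctr[3]]
    if (id == 0 || tt$class[k] == "vessel") {
      # a vessel must never be picked up as a follicle label
      if (tt$class[k] == "vessel" && id > 0) {
        expect_equal(unname(lv$class_map[[as.character(id)]]), "vessel")
      }
    } else {
      expect_equal(unname(lv$class_map[[as.character(id)]]), "follicle")
    }
  }
})

test_that("shell decomposition of a concentric spherical shell finds both boundaries", {
  ms <- shell_masks()
  sp <- ms$spacing
  # boundary radii: outer ~500 um, inner ~400 um within one in-plane voxel
  ctr <- folliculometry:::mask_centroid_um(ms$whole, sp)
  radius_of <- function(bmask) {
    iz <- equatorial_plane(ms$whole)
    px <- which(bmask[iz, , ], arr.ind = TRUE)
    r <- sqrt(((px[, 1] - 0.5) * sp[2] - ctr[2])^2 + ((px[, 2] - 0.5) * sp[3] - ctr[3])^2)
    mean(r)
  }
  expect_equal(radius_of(ms$outer_boundary), 500, tolerance = 0.01)
  expect_equal(radius_of(ms$inner_boundary), 400, tolerance = 0.012)
})

test_that("mask-set partition and boundary adjacency invariants hold", {
  for (ms in list(shell_masks())) {
    expect_true(all(ms$theca | !ms$theca)) # masks share a shape
    expect_true(!any(ms$theca & ms$lumen))
    expect_true(!any(ms$theca & ms$gap))
    expect_true(!any(ms$gap & ms$lumen))
    union <- ms$theca | ms$gap | ms$lumen
    expect_true(all(union == (ms$whole & union) | !ms$whole))
    # boundary sets are theca subsets with the right adjacency
    expect_true(all(ms$theca[ms$outer_boundary]))
    expect_true(all(ms$theca[ms$inner_boundary]))
    expect_true(any(ms$inner_boundary))
    expect_true(any(ms$outer_boundary))
    interior_or_gap <- ms$gap | ms$lumen
    expect_true(all((folliculometry:::dilate6(interior_or_gap) & ms$theca)[ms$inner_boundary] |
                      !ms$inner_boundary[ms$inner_boundary]))
  }
})

test_that("noiseless shell boundaries lie within one voxel of the analytic surfaces", {
  ms <- shell_masks()
  sp <- ms$spacing
  ctr <- folliculometry:::mask_centroid_um(ms$whole, sp)
  for (b in list(list(m = ms$outer_boundary, r = 500),
                 list(m = ms$inner_boundary, r = 400))) {
    idx <- which(b$m, arr.ind = TRUE)
    pos <- sweep(sweep(idx, 2, 0.5), 2, sp, `*`)
    r <- sqrt(colSums((t(pos) - ctr)^2))
    expect_lt(max(abs(r - b$r)), max(sp) + 1e-9) # Hausdorff bound, one voxel
  }
})

test_that("COC detection: attached blob accepted, detached blob only a candidate", {
  b <- shell_build() # has no COC
  lv <- ingest_manual_masks(b$truth$labels, b$stack)
  ms <- extract_shell_masks(b$stack, lv, 1L)
  expect_length(detect_cocs(b$stack, ms)$accepted, 0L)
  # paint an attached bright blob at the inner wall and a detached one mid-lumen
  v <- b$stack$voxels
  sp <- b$stack$spacing
  paint_ball <- function(v, ctr, r, level) {
    m <- voxelize_ellipsoid(ctr, rep(r, 3), spacing = sp, shape = dim(v))
    v[m] <- level
    v
  }
  ctr <- c(640, 600, 600)
  v2 <- paint_ball(v, ctr + c(0, 0, 320), 40, 0.95)  # touching granulosa lining
  v2 <- paint_ball(v2, ctr, 30, 0.95)                # floating mid-lumen
  st2 <- image_stack(v2, sp)
  ms2 <- extract_shell_masks(st2, lv, 1L)
  res <- detect_cocs(st2, ms2)
  expect_length(res$accepted, 1L)
  expect_gte(length(res$candidates), 1L)
  expect_equal(coc_diameter(res$accepted[[1]], sp), 80, tolerance = 0.1)
})

test_that("phantom COCs are recovered with centroid close to truth", {
  res <- demo_build()
  out <- demo_measured()
  ev <- evaluate_recovery(out$measurements, res$truth, measured_labels = out$labels)
  m <- ev$matches
  has_coc <- is.finite(m$true_coc_um)
  expect_true(any(has_coc))
  expect_true(all(is.finite(m$coc_um[has_coc])))
  expect_true(all(abs(m$coc_um[has_coc] - m$true_coc_um[has_coc]) /
                    m$true_coc_um[has_coc] <= 0.1))
})

test_that("manual-mask ingestion round-trips and matches truth-mask measurements", {
  b <- shell_build()
  lv <- ingest_manual_masks(b$truth$labels, b$stack)
  expect_identical(lv$labels, b$truth$labels)
  out_manual <- measure_stack(b$stack, labels = b$truth$labels)
  out_lv <- measure_stack(b$stack, labels = lv)
  expect_identical(out_manual$measurements, out_lv$measurements)
})

test_that("mismatched manual-mask shape errors", {
  b <- shell_build()
  expect_error(ingest_manual_masks(array(0L, c(2, 2, 2)), b$stack), "shape")
})

test_that("label TIFF round-trips integer labels exactly", {
  lab <- array(sample(0:7, 4 * 6 * 6, TRUE), c(4, 6, 6))
  path <- file.path(withr::local_tempdir(), "lab.tiff")
  write_label_volume(lab, path)
  expect_identical(read_label_volume(path), lab)
})

test_that("touching spheres are split by the watershed stage", {
  sp <- c(8, 8, 8)
  sh <- c(80L, 80L, 40L)
  # barely touching: centres 242 um apart for radii 130 + 120 um, so the
  # contact neck is thin (as after closing two abutting follicles)
  a <- voxelize_ellipsoid(c(200, 300, 160), c(130, 130, 130), spacing = sp, shape = sh)
  b <- voxelize_ellipsoid(c(442, 300, 160), c(120, 120, 120), spacing = sp, shape = sh)
  lab <- folliculometry:::cpp_label3d(a | b, 26L)
  expect_equal(max(lab), 1L) # they touch: one 26-connected component
  split <- folliculometry:::split_touching(lab, a | b, sp, seg_params(split_tolerance_um = 60))
  expect_equal(max(split), 2L)
  # an isolated sphere is never split
  solo <- folliculometry:::cpp_label3d(a, 26L)
  expect_equal(max(folliculometry:::split_touching(solo, a, sp, seg_params())), 1L)
})

test_that("egg-nest members are flagged as primordial candidates", {
  out <- demo_measured()
  expect_gte(sum(out$measurements$stage == "primordial"), 3L)
  # primordial candidates carry no shell metrics
  expect_true(all(is.na(out$measurements$thickness_mean_um[
    out$measurements$stage == "primordial"])))
})
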