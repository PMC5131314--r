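test_that("voxelized sphere volume matches the analytic value within 3%", {
  sp <- c(16, 4, 4)
  m <- voxelize_ellipsoid(c(400, 400, 400), c(100, 100, 100),
                          spacing = sp, shape = c(50, 200, 200))
  v <- sum(m) * prod(sp) * 1e-9
  expect_lt(abs(v - 4 / 3 * pi * 0.1^3) / (4 / 3 * pi * 0.1^3), 0.03)
})

test_that("central cross-section of an axis-aligned 2:1 ellipsoid has ratio 2", {
  sp <- c(16, 4, 4)
  # long axis rotated into the y direction -> in-plane 2:1 ellipse
  m <- voxelize_ellipsoid(c(400, 400, 400), c(100, 50, 50),
                          orientation = c(pi / 2, 0, 0),
                          spacing = sp, shape = c(50, 200, 200))
  iz <- equatorial_plane(m)
  px <- which(m[iz, , ], arr.ind = TRUE)
  # pixel extents: (index span + 1) pixels cover the full axis
  span_y <- (diff(range(px[, 1])) + 1) * sp[2]
  span_x <- (diff(range(px[, 2])) + 1) * sp[3]
  expect_equal(span_y / span_x, 2, tolerance = 0.05)
})

test_that("voxel-count volume converges to (4/3) pi abc under grid refinement", {
  semi <- c(120, 90, 70)
  orient <- c(0.5, 0.3, 0.8)
  target <- 4 / 3 * pi * prod(semi) * 1e-9
  errs <- vapply(list(c(16, 8, 8), c(8, 4, 4), c(4, 2, 2)), function(sp) {
    shape <- ceiling(320 / sp)
    m <- voxelize_ellipsoid(c(160, 160, 160), semi, orient, sp, shape)
    abs(sum(m) * prod(sp) * 1e-9 - target) / target
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 0.01)
})

test_that("degenerate voxelization inputs error", {
  expect_error(voxelize_ellipsoid(c(0, 0, 0), c(0, 0, 0), spacing = c(1, 1, 1),
                                  shape = c(4, 4, 4)), "positive")
  expect_error(voxelize_ellipsoid(c(1e5, 1e5, 1e5), c(10, 10, 10),
                                  spacing = c(1, 1, 1), shape = c(4, 4, 4)),
               "outside")
})

test_that("empty scene yields uniform background at the requested level", {
  spec <- phantom_spec(c(24L, 40L, 40L), background_level = 0.2, seed = 3L)
  res <- build_phantom(spec)
  expect_equal(mean(res$stack$voxels), 0.2, tolerance = 0.01)
  expect_equal(length(res$truth$structures), 0L)
})

test_that("same spec and seed give bit-identical stacks and manifests", {
  a <- build_phantom(demo_phantom_spec(seed = 11))
  b <- build_phantom(demo_phantom_spec(seed = 11))
  expect_identical(a$stack$voxels, b$stack$voxels)
  expect_identical(a$truth$labels, b$truth$labels)
  expect_identical(truth_table(a$truth), truth_table(b$truth))
})

test_that("noiseless constant-thickness follicle: manifest matches voxel truth", {
  b <- shell_build()
  s <- b$truth$structures[[1]]
  expect_equal(s$voxel_count, sum(b$truth$labels == s$id))
  expect_equal(s$voxel_volume_mm3, s$true_volume_mm3, tolerance = 0.01)
  expect_true(all(s$thickness_samples_um == 100))
})

test_that("manifest volume is truth-consistent for diameters >= 70 um", {
  tt <- truth_table(demo_build()$truth)
  tt <- tt[tt$class != "vessel", ]
  rel <- abs(tt$voxel_volume_mm3 - tt$true_volume_mm3) / tt$true_volume_mm3
  expect_true(all(rel < 0.03))
})

test_that("pre-noise intensity ordering: theca > granulosa > background > lumen", {
  spec <- demo_phantom_spec(seed = 2)
  res <- build_phantom(spec, blur = FALSE, noise = FALSE)
  v <- res$stack$voxels
  lab <- res$truth$labels
  iv <- spec$intensities
  expect_gt(iv$theca, iv$granulosa)
  expect_gt(iv$granulosa, iv$background)
  expect_gt(iv$background, iv$lumen)
  expect_gt(iv$coc, iv$granulosa)
  # realized voxels follow the spec levels
  expect_equal(sort(unique(as.numeric(v[lab == 0]))),
               sort(unique(c(round(iv$background * 65535) / 65535))))
})

test_that("uniform-thickness blur equals a single separable convolution", {
  img <- imaging_model(voxel_spacing = c(4, 4, 4), sheet_waist_um = 20,
                       sheet_edge_um = 20, lateral_psf_fwhm = 6)
  set.seed(9)
  v <- array(runif(30 * 30 * 30), c(30, 30, 30))
  st <- image_stack(v, c(4, 4, 4))
  got <- apply_lightsheet_psf(st, img)$voxels
  fwhm2sd <- 1 / (2 * sqrt(2 * log(2)))
  kz <- folliculometry:::gauss_kernel(20 * fwhm2sd / 4)
  kl <- folliculometry:::gauss_kernel(6 * fwhm2sd / 4)
  ref <- folliculometry:::conv_axis3(
    folliculometry:::conv_axis3(
      folliculometry:::conv_axis3(v, kl, 2L), kl, 3L), kz, 1L)
  expect_equal(got, ref, tolerance = 1e-12)
})

test_that("axial spot width grows off-waist with the sheet-thickness ratio", {
  img <- imaging_model(voxel_spacing = c(2, 4, 16))
  sh <- c(201, 9, 400) # x extent 6.4 mm; waist at x centre
  v <- array(0, sh)
  v[101, 5, 200] <- 1          # on the waist axis
  v[101, 5, 13] <- 1           # ~3 mm lateral offset
  v[101, 5, 105] <- 1          # ~1.5 mm lateral offset
  b <- apply_lightsheet_psf(image_stack(v, c(2, 4, 16)), img)$voxels
  sd_of <- function(ix) {
    p <- b[, 5, ix]
    sqrt(sum(p * ((1:201 - 101) * 2)^2) / sum(p))
  }
  w <- sd_of(200); mid <- sd_of(105); e <- sd_of(13)
  expect_true(w < mid && mid < e) # monotone broadening
  expect_equal(e / w, 60 / 11, tolerance = 0.10)
})

test_that("blur conserves intensity and a constant volume stays constant", {
  img <- imaging_model(voxel_spacing = c(8, 8, 8))
  set.seed(10)
  v <- array(runif(24 * 24 * 24), c(24, 24, 24))
  st <- image_stack(v, c(8, 8, 8))
  # edge renormalization perturbs the margins only: total conserved to ~0.1%
  expect_equal(sum(apply_lightsheet_psf(st, img)$voxels), sum(v), tolerance = 1e-3)
  cst <- image_stack(array(0.4, c(24, 24, 24)), c(8, 8, 8))
  expect_equal(apply_lightsheet_psf(cst, img)$voxels,
               array(0.4, c(24, 24, 24)), tolerance = 1e-12)
})

test_that("blur errors when the kernel exceeds the stack extent", {
  img <- imaging_model(voxel_spacing = c(2, 4, 4), sheet_waist_um = 60)
  st <- image_stack(array(0.1, c(12, 8, 8)), c(2, 4, 4))
  expect_error(apply_lightsheet_psf(st, img), "wider")
})

test_that("noise moments follow the electron-referred shot + read model", {
  img <- imaging_model(photon_scale = 2000, read_noise_sd = 1.0)
  L <- 0.5
  st <- image_stack(array(L, c(50, 50, 50)), c(16, 4, 4))
  out <- apply_noise(st, img, seed = 21)$voxels
  expect_equal(mean(out), L, tolerance = 0.005)
  expect_equal(var(as.numeric(out)), L / 2000 + (1 / 2000)^2, tolerance = 0.03)
})

test_that("noise is seeded, near-noiseless in the high-photon limit, and validates input", {
  img <- imaging_model(photon_scale = 1e8, read_noise_sd = 0)
  st <- rand_stack(c(8, 8, 8), seed = 1)
  out <- apply_noise(st, img, seed = 5)$voxels
  expect_equal(out, st$voxels, tolerance = 1e-3)
  img2 <- imaging_model()
  a <- apply_noise(st, img2, seed = 9)$voxels
  b <- apply_noise(st, img2, seed = 9)$voxels
  expect_identical(a, b)
  bad <- st; bad$voxels[1] <- -1
  expect_error(apply_noise(structure(bad, class = "image_stack"), img2, 1),
               "non-negative")
})

test_that("overlapping follicles beyond tolerance abort the build", {
  spec <- phantom_spec(
    c(30L, 80L, 80L),
    list(follicle_phantom(c(240, 160, 140), c(60, 60, 60), theca_thickness_base = 20),
         follicle_phantom(c(240, 160, 180), c(60, 60, 60), theca_thickness_base = 20)),
    seed = 1L
  )
  expect_error(build_phantom(spec), "overlap")
})

test_that("phantom spec YAML round-trips and rebuilds identically", {
  spec <- demo_phantom_spec(seed = 13)
  path <- file.path(withr::local_tempdir(), "spec.yaml")
  write_phantom_spec(spec, path)
  spec2 <- read_phantom_spec(path)
  a <- build_phantom(spec, blur = FALSE, noise = FALSE)
  b <- build_phantom(spec2, blur = FALSE, noise = FALSE)
  expect_identical(a$stack$voxels, b$stack$voxels)
})
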