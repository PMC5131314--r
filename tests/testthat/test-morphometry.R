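test_that("volume is voxel count times voxel volume, in mm^3", {
  m <- array(FALSE, c(3, 3, 3)); m[2, 2, 2] <- TRUE
  expect_equal(follicle_volume(m, c(16, 4, 4)), 2.56e-7)
  expect_error(follicle_volume(array(FALSE, c(2, 2, 2)), c(16, 4, 4)), "empty")
})

test_that("voxelized sphere d=500 um has volume within 3% of the analytic value", {
  m <- voxelize_ellipsoid(c(400, 400, 400), c(250, 250, 250),
                          spacing = c(16, 4, 4), shape = c(50, 200, 200))
  expect_equal(follicle_volume(m, c(16, 4, 4)), 6.545e-2, tolerance = 0.03)
})

test_that("rotated-ellipsoid volume is within 3% of (4/3) pi abc", {
  semi <- c(210, 150, 120)
  m <- voxelize_ellipsoid(c(400, 400, 400), semi, orientation = c(0.7, 0.4, 1.1),
                          spacing = c(16, 4, 4), shape = c(50, 200, 200))
  expect_equal(follicle_volume(m, c(16, 4, 4)), 4 / 3 * pi * prod(semi) * 1e-9,
               tolerance = 0.03)
})

test_that("equivalent diameter: closed form, exact inverse, monotone", {
  expect_equal(equivalent_diameter(pi / 6 * 1e-3), 100)
  d <- c(74, 212.5, 980)
  v <- pi / 6 * (d / 1000)^3
  expect_equal(equivalent_diameter(v), d)
  expect_true(all(diff(equivalent_diameter(sort(stats::runif(10, 1e-5, 1)))) > 0))
  expect_error(equivalent_diameter(0), "positive")
})

test_that("equatorial plane is the max-area plane with low-index ties", {
  m <- voxelize_ellipsoid(c(520, 400, 400), c(150, 150, 150),
                          spacing = c(16, 4, 4), shape = c(65, 200, 200))
  expect_equal(equatorial_plane(m), 33L) # centre plane: z = 520 um = (33 - 0.5) * 16
  tie <- array(FALSE, c(5, 4, 4))
  tie[2, 1:2, 1] <- TRUE; tie[4, 1:2, 1] <- TRUE; tie[3, 1, 1] <- TRUE
  expect_equal(equatorial_plane(tie), 2L)
  # brute-force argmax oracle on a random blob
  set.seed(12)
  blob <- array(stats::runif(8 * 10 * 10) > 0.6, c(8, 10, 10))
  counts <- vapply(1:8, function(k) sum(blob[k, , ]), numeric(1))
  expect_equal(equatorial_plane(blob), which.max(counts))
})

test_that("asymmetry: sphere 1.00 +/- 2%, in-plane 2:1 ellipsoid 2.00 +/- 3%", {
  sp <- c(16, 4, 4)
  s <- voxelize_ellipsoid(c(600, 600, 600), c(400, 400, 400),
                          spacing = sp, shape = c(75, 300, 300))
  expect_equal(equatorial_asymmetry(s, sp), 1, tolerance = 0.02)
  e <- voxelize_ellipsoid(c(400, 400, 400), c(200, 100, 100),
                          orientation = c(pi / 2, 0, 0), spacing = sp,
                          shape = c(50, 200, 200))
  expect_equal(equatorial_asymmetry(e, sp), 2, tolerance = 0.03)
})

test_that("asymmetry is invariant (<2%) under in-plane rotation", {
  sp <- c(16, 4, 4)
  vals <- vapply(seq(0, pi / 2, length.out = 7), function(th) {
    m <- voxelize_ellipsoid(c(400, 400, 400), c(200, 100, 100),
                            orientation = c(pi / 2, 0, th), spacing = sp,
                            shape = c(50, 200, 200))
    equatorial_asymmetry(m, sp)
  }, numeric(1))
  expect_lt((max(vals) - min(vals)) / min(vals), 0.02)
})

test_that("asymmetry rejects tiny or degenerate cross-sections", {
  m <- array(FALSE, c(3, 10, 10)); m[2, 3, 3:4] <- TRUE
  expect_error(equatorial_asymmetry(m, c(16, 4, 4)), "fewer than 5")
  m2 <- array(FALSE, c(3, 12, 12)); m2[2, 3, 2:9] <- TRUE # collinear row
  expect_error(equatorial_asymmetry(m2, c(16, 4, 4)), "degenerate")
})

test_that("concentric-circle annulus yields constant thickness within one pixel", {
  ms <- shell_masks()
  td <- theca_thickness_distribution(ms, ms$spacing)
  expect_equal(td$mean, 100, tolerance = 0.04)
  expect_lte(td$sd, 4)
  expect_gte(min(td$samples_um), 100 - 8)
  expect_lte(max(td$samples_um), 100 + 8)
})

test_that("thickness samples equal the all-pairs brute force bitwise", {
  set.seed(31)
  for (rep in 1:20) {
    # random elliptical annuli rendered as one-plane masks
    a <- stats::runif(1, 200, 480); b <- stats::runif(1, 0.6, 1) * a
    t0 <- stats::runif(1, 40, 120)
    th <- stats::runif(1, 0, pi)
    sh <- c(3L, 256L, 256L)
    outer <- voxelize_ellipsoid(c(24, 512, 512), c(500, a, b),
                                orientation = c(0, 0, th), spacing = c(16, 4, 4),
                                shape = sh)
    inner <- voxelize_ellipsoid(c(24, 512, 512), c(500, a - t0, max(b - t0, 20)),
                                orientation = c(0, 0, th), spacing = c(16, 4, 4),
                                shape = sh)
    ring <- outer & !inner
    iz <- 2L
    opx <- which((ring & !folliculometry:::erode6(ring))[iz, , ], arr.ind = TRUE)
    ipx <- which((inner | folliculometry:::dilate6(inner))[iz, , ] & ring[iz, , ],
                 arr.ind = TRUE)
    if (nrow(opx) == 0 || nrow(ipx) == 0) next
    fast <- folliculometry:::cpp_nearest_boundary_sq(opx, ipx, 4, 4)
    expect_identical(fast, brute_nearest_sq(opx, ipx, 4, 4))
  }
})

test_that("thickness sample count equals the outer-boundary pixel count", {
  ms <- shell_masks()
  td <- theca_thickness_distribution(ms, ms$spacing)
  iz <- equatorial_plane(ms$whole)
  expect_equal(td$n, sum(ms$outer_boundary[iz, , ]))
  expect_equal(td$plane, iz)
})

test_that("orthogonal caliper estimate: circle exact, ellipse averages the axes", {
  sp <- c(16, 4, 4)
  circ <- voxelize_ellipsoid(c(400, 400, 400), c(150, 150, 150),
                             spacing = sp, shape = c(50, 200, 200))
  expect_equal(orthogonal_diameter_estimate(circ, sp), 300, tolerance = 4 / 300)
  ell <- voxelize_ellipsoid(c(400, 400, 400), c(200, 100, 100),
                            orientation = c(pi / 2, 0, 0.5), spacing = sp,
                            shape = c(50, 200, 200))
  expect_equal(orthogonal_diameter_estimate(ell, sp), 300, tolerance = 4 / 300)
})

test_that("the caliper bias against the equivalent diameter grows with asymmetry", {
  sp <- c(16, 4, 4)
  ratios <- c(1, 1.5, 2, 2.8)
  bias <- vapply(ratios, function(r) {
    b <- 100
    m <- voxelize_ellipsoid(c(400, 400, 400), c(b * r, b, b),
                            orientation = c(pi / 2, 0, 0.4),
                            spacing = sp, shape = c(50, 250, 250))
    abs(orthogonal_diameter_estimate(m, sp) -
          equivalent_diameter(follicle_volume(m, sp)))
  }, numeric(1))
  expect_true(all(diff(bias) > 0))
})

test_that("COC diameter from the middle plane: sphere, single voxel, band", {
  sp <- c(16, 4, 4)
  coc <- voxelize_ellipsoid(c(200, 200, 200), c(40, 40, 40),
                            spacing = sp, shape = c(25, 100, 100))
  expect_equal(coc_diameter(coc, sp), 80, tolerance = 4 / 80)
  one <- array(FALSE, c(3, 3, 3)); one[2, 2, 2] <- TRUE
  expect_equal(coc_diameter(one, sp), 2 * sqrt(16 / pi))
  expect_error(coc_diameter(array(FALSE, c(2, 2, 2)), sp), "empty")
})

test_that("scale equivariance: volumes scale as s^3, lengths as s, asymmetry fixed", {
  ms <- shell_masks()
  sp <- ms$spacing
  s <- 2.5
  expect_equal(follicle_volume(ms$whole, sp * s), follicle_volume(ms$whole, sp) * s^3)
  td1 <- theca_thickness_distribution(ms, sp)
  td2 <- theca_thickness_distribution(ms, sp * s)
  expect_equal(td2$mean, td1$mean * s, tolerance = 1e-10)
  expect_equal(equatorial_asymmetry(ms$whole, sp * s),
               equatorial_asymmetry(ms$whole, sp), tolerance = 1e-10)
})

test_that("measure_follicle populates a consistent record", {
  b <- shell_build()
  lv <- ingest_manual_masks(b$truth$labels, b$stack)
  ms <- extract_shell_masks(b$stack, lv, 1L)
  r <- measure_follicle(b$stack, ms)
  expect_s3_class(r, "follicle_measurement")
  expect_equal(r$equivalent_diameter_um, equivalent_diameter(r$volume_mm3))
  expect_gte(r$asymmetry, 1)
  expect_equal(r$asymmetry * r$asymmetry_minor_major, 1)
  expect_equal(r$stage, "Graafian") # d = 1 mm
  expect_true(is.na(r$coc_diameter_um)) # no COC in this phantom
  expect_equal(r$thickness_mean_um, 100, tolerance = 0.04)
})
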