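# cortical and trabecular morphometry

test_that("segment_bone: threshold semantics, empty-mask error, noisy accuracy", {
  gt <- geometry_truth(c(0.9, 0.9), c(0.6, 0.6), 0, 0.006)
  cs <- gen_cross_section(gt, seed = 1, n_slices = 3)
  m <- segment_bone(cs$grid, sigma = 0)
  truthb <- cs$labels == 1L
  dice <- 2 * sum(m & truthb) / (sum(m) + sum(truthb))
  expect_gte(dice, 0.999)
  # 5% grayscale noise, sigma = 1 smoothing: Ct.Ar within 1% of closed form
  csn <- gen_cross_section(gt, seed = 2, n_slices = 3, noise_sd = 0.05)
  mn <- segment_bone(csn$grid, sigma = 1)
  ct_ar <- sum(mn) * 0.006^2 / dim(mn)[3]
  expect_equal(ct_ar, unname(gt$true_areas["Ct.Ar"]), tolerance = 0.01)
  empty <- voxel_grid(array(0, c(8, 8, 2)), 0.01)
  expect_error(segment_bone(empty, sigma = 0, threshold = 0.5),
               "no mineralized tissue")
})

test_that("label_compartments: disk, off-center voids, generated-grid agreement", {
  disk <- phantom_slices(function(x, y) x^2 + y^2 <= 0.45^2, 0.55, 0.01, 2)
  expect_warning(l <- label_compartments(disk), "no enclosed cavity")
  expect_equal(sum(l == 2L), 0L)
  expect_equal(sum(l == 3L), 0L)

  # annulus with three enclosed voids: largest becomes marrow, others pores
  ann <- phantom_slices(function(x, y) x^2 + y^2 <= 0.45^2, 0.55, 0.01, 2)
  ann[, , ][phantom_slices(function(x, y) (x - 0.1)^2 + y^2 <= 0.2^2,
                           0.55, 0.01, 2)] <- FALSE
  ann[, , ][phantom_slices(function(x, y) (x + 0.25)^2 + y^2 <= 0.05^2,
                           0.55, 0.01, 2)] <- FALSE
  ann[, , ][phantom_slices(function(x, y) x^2 + (y + 0.3)^2 <= 0.04^2,
                           0.55, 0.01, 2)] <- FALSE
  l2 <- label_compartments(ann)
  expect_gt(sum(l2 == 2L), sum(l2 == 3L) / 2)   # marrow is the largest void
  pore_components <- bonemech:::.label6(as.logical(l2 == 3L),
                                        as.integer(dim(l2)))
  expect_equal(max(pore_components), 2L)

  gt <- geometry_truth(c(0.9, 0.7), c(0.6, 0.45), 0.04, 0.006)
  cs <- gen_cross_section(gt, seed = 3, n_slices = 3)
  lab <- label_compartments(cs$labels %in% c(1L, 3L) &
                              !(cs$labels == 3L) | cs$labels == 1L)
  lab <- label_compartments(cs$labels == 1L)
  expect_gte(mean(lab == cs$labels), 0.999)
})

test_that("cortical_morphometry reproduces closed forms at 6 um voxels", {
  # filled ellipse a = 1.0, b = 0.5 mm
  ell <- phantom_slices(function(x, y) (x / 1)^2 + (y / 0.5)^2 <= 1,
                        1.1, 0.006, 2)
  suppressWarnings(l <- labels_from_mask(ell))
  cm <- cortical_morphometry(l, 0.006)
  expect_equal(cm$I_min, pi * 1 * 0.5^3 / 4, tolerance = 0.01)
  expect_equal(cm$I_max, pi * 1^3 * 0.5 / 4, tolerance = 0.01)
  expect_equal(cm$c, 0.5, tolerance = 0.01)
  expect_equal(cm$Ct.Ar, pi * 0.5, tolerance = 0.01)
  # principal angle: weak axis along x for this ellipse
  expect_lt(min(abs(cm$principal_angle - c(0, pi))), 0.05)

  # circular annulus: Ct.Th -> r_o - r_i
  gt <- geometry_truth(c(0.9, 0.9), c(0.6, 0.6), 0, 0.006)
  cs <- gen_cross_section(gt, seed = 1, n_slices = 3)
  cma <- cortical_morphometry(cs$labels, 0.006, cs$grid$calibration,
                              cs$grid$values)
  expect_equal(cma$Ct.Th, 0.3, tolerance = 0.05)
  expect_equal(cma$Ct.TMD, 1200, tolerance = 1e-6)   # uniform density
  expect_equal(cma$I_min, unname(gt$true_moments["I_min"]), tolerance = 0.01)
  expect_equal(cma$c, 0.9, tolerance = 0.01)
  # missing calibration -> absent, not zero
  cm0 <- cortical_morphometry(cs$labels, 0.006)
  expect_true(is.na(cm0$Ct.TMD))
})

test_that("morphometry invariants: rotation, scale law, porosity calibration-invariance", {
  gt <- geometry_truth(c(0.9, 0.6), c(0.6, 0.4), 0.03, 0.008)
  cs <- gen_cross_section(gt, seed = 5, n_slices = 3)
  cm <- cortical_morphometry(cs$labels, 0.008)
  rot <- aperm(cs$labels, c(2, 1, 3))[, dim(cs$labels)[1]:1, , drop = FALSE]
  cmr <- cortical_morphometry(rot, 0.008)
  expect_equal(cm$I_min, cmr$I_min, tolerance = 1e-10)
  expect_equal(cm$I_max, cmr$I_max, tolerance = 1e-10)
  expect_equal(cm$Ct.Ar, cmr$Ct.Ar, tolerance = 1e-12)
  expect_equal(cm$Ct.Po, cmr$Ct.Po, tolerance = 1e-12)
  dang <- abs(cm$principal_angle - cmr$principal_angle)
  expect_lt(min(abs(dang - pi / 2), abs(dang - pi / 2 - pi),
                abs(dang - pi / 2 + pi)), 1e-6)
  # scale law: voxel_size x2 -> areas x4, moments x16
  cm2 <- cortical_morphometry(cs$labels, 0.016)
  expect_equal(cm2$Ct.Ar / cm$Ct.Ar, 4, tolerance = 1e-12)
  expect_equal(cm2$I_min / cm$I_min, 16, tolerance = 1e-12)
  expect_identical(cm$Ct.Po, cm2$Ct.Po)
})

test_that("closed-form error shrinks with resolution", {
  err <- vapply(c(0.018, 0.006), function(vs) {
    ell <- phantom_slices(function(x, y) (x / 0.8)^2 + (y / 0.5)^2 <= 1,
                          0.9, vs, 1)
    cm <- cortical_morphometry(labels_from_mask(ell), vs)
    abs(cm$I_min / (pi * 0.8 * 0.5^3 / 4) - 1)
  }, 0)
  expect_lt(err[2], err[1])
  expect_lt(err[2], 0.01)
})

test_that("trabecular_morphometry: slabs, plate thickness oracle, torus topology", {
  # half bone, half marrow
  half <- array(FALSE, c(20, 20, 20))
  half[, , 1:10] <- TRUE
  tm <- trabecular_morphometry(labels_from_mask(half), voxel_size = 0.006)
  expect_equal(tm$BV_TV, 50)

  # plate 60 um thick bounded by marrow on both sides (10 voxels at 6 um)
  plate <- array(FALSE, c(30, 30, 40))
  plate[, , 16:25] <- TRUE
  tm2 <- trabecular_morphometry(labels_from_mask(plate), voxel_size = 0.006)
  expect_equal(tm2$Tb.Th, 60, tolerance = 0.10)
  # gap of 240 um bounded by bone slabs on both sides (40 voxels)
  gap <- array(TRUE, c(30, 30, 100))
  gap[, , 31:70] <- FALSE
  tmg <- trabecular_morphometry(labels_from_mask(gap), voxel_size = 0.006)
  expect_equal(tmg$Tb.Sp, 240, tolerance = 0.10)
  expect_equal(tm2$Tb.N, 1 / ((tm2$Tb.Th + tm2$Tb.Sp) / 1000),
               tolerance = 1e-12)
  # brute-force sphere-fitting oracle on a small version of the same grid
  small <- array(FALSE, c(12, 12, 16))
  small[, , 3:7] <- TRUE
  oracle <- brute_thickness(small)
  tm3 <- trabecular_morphometry(labels_from_mask(small),
                                voi = array(TRUE, dim(small)),
                                voxel_size = 1)
  expect_equal(tm3$Tb.Th / 1000, oracle, tolerance = 0.10)

  # solid torus: Euler characteristic 0 -> Conn.D = 1/volume
  tor <- array(FALSE, c(40, 40, 20))
  for (k in 1:20) for (j in 1:40) for (i in 1:40) {
    x <- i - 20.5; y <- j - 20.5; z <- k - 10.5
    tor[i, j, k] <- (sqrt(x^2 + y^2) - 12)^2 + z^2 <= 4^2
  }
  expect_equal(euler_characteristic(tor), 0L)
  tmt <- trabecular_morphometry(labels_from_mask(tor), voxel_size = 0.006)
  expect_equal(tmt$Conn.D, 1 / (length(tor) * 0.006^3), tolerance = 1e-12)

  # empty VOI
  none <- array(FALSE, c(6, 6, 6))
  expect_warning(tm0 <- trabecular_morphometry(labels_from_mask(none),
                                               voxel_size = 0.006),
                 "no bone")
  expect_equal(tm0$BV_TV, 0)
  expect_true(is.na(tm0$Tb.Th))
})

test_that("euler characteristic of simple solids", {
  cube <- array(TRUE, c(4, 4, 4))
  expect_equal(euler_characteristic(cube), 1L)
  shell <- array(TRUE, c(7, 7, 7))
  shell[3:5, 3:5, 3:5] <- FALSE   # hollow cube: chi = 2
  expect_equal(euler_characteristic(shell), 2L)
})
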