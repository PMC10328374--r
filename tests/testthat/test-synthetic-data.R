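# synthetic-data generators: determinism, closed forms, round trips

test_that("geometry truth carries closed-form areas, moments and c", {
  gt <- geometry_truth(c(0.9, 0.9), c(0.6, 0.6), 0, 0.006)
  expect_equal(unname(gt$true_moments["I_min"]), pi / 4 * (0.9^4 - 0.6^4),
               tolerance = 1e-12)
  expect_equal(unname(gt$true_moments["I_min"]),
               unname(gt$true_moments["I_max"]))
  expect_equal(unname(gt$true_areas["Tt.Ar"]), pi * 0.81, tolerance = 1e-12)
  # ellipse: weak axis along the short semi-axis direction
  ge <- geometry_truth(c(1.0, 0.5), c(0.5, 0.25), 0, 0.006)
  expect_equal(unname(ge$true_moments["I_min"]),
               pi / 4 * (1.0 * 0.5^3 - 0.5 * 0.25^3), tolerance = 1e-12)
  expect_equal(ge$true_c, 0.5)
  expect_error(geometry_truth(c(0.9, 0.7), c(0.95, 0.4)), "inside")
  expect_error(geometry_truth(pore_fraction = 0.6), "pore_fraction")
})

test_that("gen_cross_section meets the requested pore fraction and is deterministic", {
  gt <- geometry_truth(c(0.9, 0.7), c(0.6, 0.45), 0.05, 0.006)
  cs <- gen_cross_section(gt, seed = 11, n_slices = 3)
  pf <- sum(cs$labels == 3L) / sum(cs$labels %in% c(1L, 3L))
  expect_lt(abs(pf - 0.05), 0.005)
  cs2 <- gen_cross_section(gt, seed = 11, n_slices = 3)
  expect_identical(cs$grid$values, cs2$grid$values)
  expect_identical(cs$labels, cs2$labels)
  # label conservation: every voxel is exactly one of the four classes
  expect_equal(sum(cs$labels %in% 0:3), length(cs$labels))
  # too-coarse voxels are rejected
  expect_error(gen_cross_section(geometry_truth(voxel_size = 0.12)),
               "coarse")
})

test_that("gen_bending_curve: triangle work, truth sidecar, determinism, noise gate", {
  bt <- bending_truth(stiffness = 110, yield_force = 18, ultimate_force = 18,
                      post_yield_displacement = 0, noise_sd = 0)
  g <- gen_bending_curve(bt, seed = 1)
  # pure linear-to-fracture: area under curve = F^2 / 2K
  d <- g$curve$displacement; f <- g$curve$force
  upto <- d <= g$truth$failure_displacement
  work <- sum(diff(d[upto]) * (head(f[upto], -1) + tail(f[upto], -1)) / 2)
  # trapezoid on the 0.5 um displacement grid truncates at most one sample
  expect_equal(work, 18^2 / (2 * 110), tolerance = 5e-3)
  expect_equal(g$truth$pyd_criterion, 0)
  g2 <- gen_bending_curve(bt, seed = 1)
  expect_identical(g$curve, g2$curve)
  expect_error(bending_truth(yield_force = 10, noise_sd = 1.5),
               "unidentifiable")
})

test_that("bending extraction recovers generator truth within 2% (noise free)", {
  bt <- bending_truth(stiffness = 110, yield_force = 15, ultimate_force = 18,
                      post_yield_displacement = 0.15, noise_sd = 0)
  g <- gen_bending_curve(bt, seed = 2)
  fp <- extract_flexural(g$curve, bending_config(preload = 0))
  expect_equal(fp$stiffness, 110, tolerance = 0.02)
  expect_equal(fp$max_force, 18, tolerance = 0.02)
  expect_equal(fp$post_yield_displacement, g$truth$pyd_criterion,
               tolerance = 0.02)
  expect_equal(fp$yield_force, g$truth$yield_force_criterion,
               tolerance = 0.03)
  expect_equal(fp$work_to_fracture, g$truth$work_to_fracture,
               tolerance = 0.02)
})

test_that("gen_indentation_curve: protocol shape and Oliver-Pharr round trip", {
  tr <- indentation_truth(reduced_modulus = 70, hardness = 0.9,
                          creep_amplitude = 0, noise_sd = 0)
  g <- gen_indentation_curve(tr, seed = 1)
  seg <- segment_indent(g$curve$time, g$curve$depth, g$curve$load,
                        load_rate = 100)
  hold <- seg[seg$segment == "hold", ]
  expect_equal(diff(range(hold$time)), 30, tolerance = 0.5 / 30)
  expect_true(all(abs(hold$load - 1000) < 1e-6))
  res <- analyze_indent(g$curve)
  expect_equal(res$E_r, 70, tolerance = 0.01)
  expect_equal(res$H, 0.9, tolerance = 0.01)
  expect_error(gen_indentation_curve(tr, seed = 1, m = 2.5), "\\[1.2, 2.2\\]")
  g2 <- gen_indentation_curve(tr, seed = 1)
  expect_identical(g$curve, g2$curve)
})

test_that("gen_raman_spectrum matches analytic band integrals and FWHM", {
  one <- data.frame(center = 960, height = 100, sigma = 6,
                    shape = "gaussian", stringsAsFactors = FALSE)
  st <- spectrum_truth(bands = one, baseline_coeffs = numeric(0),
                       noise_sd = 0)
  g <- gen_raman_spectrum(st, step = 1, seed = 1)
  expect_equal(band_fwhm(g$spectrum), 2 * sqrt(2 * log(2)) * 6,
               tolerance = 5e-3)
  # trapezoid areas equal closed-form profile integrals within 0.1%
  st2 <- spectrum_truth(baseline_coeffs = numeric(0), noise_sd = 0)
  g2 <- gen_raman_spectrum(st2, step = 1, seed = 1)
  for (w in list(c(410, 460), c(930, 980), c(1215, 1300))) {
    expect_equal(band_area(g2$spectrum, w[1], w[2]),
                 bonemech:::band_profile_area(st2$bands, w[1], w[2]),
                 tolerance = 1e-3)
  }
  expect_error(gen_raman_spectrum(st, step = 3), "step")
  expect_identical(gen_raman_spectrum(st2, seed = 4)$spectrum,
                   gen_raman_spectrum(st2, seed = 4)$spectrum)
})

test_that("gen_cohort: large-sample means, zero-variance hierarchy, determinism", {
  sp <- cohort_spec(n_per_group = c("C57Bl/6J" = 1000, "TallyHO" = 1000),
                    seed = 5)
  co <- gen_cohort(sp)
  oc <- default_outcomes()
  for (i in seq_len(nrow(oc))) {
    for (g in c("C57Bl/6J", "TallyHO")) {
      sel <- co$mice$genotype == g
      mu <- if (g == "TallyHO") oc$diabetic_mean[i] else oc$control_mean[i]
      sdv <- if (g == "TallyHO") oc$diabetic_sd[i] else oc$control_sd[i]
      z <- abs(mean(co$mice[[oc$outcome[i]]][sel]) - mu) / (sdv / sqrt(1000))
      expect_lt(z, 3)
    }
  }
  expect_identical(gen_cohort(sp), gen_cohort(sp))
  co0 <- gen_cohort(cohort_spec(
    hierarchy_cv = c(mouse = 0, quadrant = 0, region = 0, residual = 0),
    seed = 3))
  spread <- tapply(co0$tissue$E_s_GPa,
                   paste(co0$tissue$mouse, co0$tissue$quadrant,
                         co0$tissue$region),
                   function(x) diff(range(x)))
  expect_true(all(spread == 0))
})

test_that("truth sidecars round-trip through JSON", {
  tmp <- withr::local_tempdir()
  bt <- bending_truth()
  p <- file.path(tmp, "b1.csv")
  writeLines("x", p)
  write_truth_sidecar(bt, p)
  back <- read_truth_sidecar(p)
  expect_equal(back$stiffness, bt$stiffness)
  expect_equal(back$span, bt$span)
})
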