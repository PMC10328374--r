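# three-point-bending property extraction

make_line_curve <- function(K = 100, dmax = 0.3, rate = 0.05, hz = 100) {
  d <- seq(0, dmax, by = rate / hz)
  fd_curve(d, K * d)
}

test_that("preprocess_curve zeroes displacement at the preload crossing", {
  cv <- make_line_curve(K = 100)
  pc <- preprocess_curve(cv, bending_config(preload = 2))
  expect_equal(pc$displacement[1], 0)
  expect_equal(pc$force[1], 2)
  # origin shifted by preload/K = 0.02 mm
  expect_equal(max(cv$displacement) - max(pc$displacement), 0.02,
               tolerance = 1e-9)
  # curve already starting at the preload: only the origin shifts
  d <- seq(0, 0.3, by = 5e-4)
  cv2 <- fd_curve(d, 2 + 100 * d)
  pc2 <- preprocess_curve(cv2, bending_config(preload = 2))
  expect_equal(pc2$force, cv2$force)
  expect_equal(pc2$displacement, cv2$displacement)
  low <- fd_curve(d, rep(1.5, length(d)))
  expect_error(preprocess_curve(low, bending_config(preload = 2)),
               "invalid test")
})

test_that("bending_stiffness: exact slope, noise robustness, concavity bound", {
  expect_equal(bending_stiffness(make_line_curve(K = 110)), 110,
               tolerance = 1e-9)
  # bilinear with 1% force noise: within 2%
  set.seed(42)
  d <- seq(0, 0.3, by = 5e-4)
  f <- pmin(110 * d, 15 + 10 * (d - 15 / 110))
  fn <- f + rnorm(length(f), 0, 0.01 * max(f))
  expect_equal(bending_stiffness(fd_curve(d, fn)), 110, tolerance = 0.02)
  # concave-down curve: windowed max slope >= secant at peak
  fc <- 20 * sqrt(d)
  K <- bending_stiffness(fd_curve(d, fc))
  expect_gte(K, max(fc) / max(d))
  short <- fd_curve(seq(0, 0.02, length.out = 21),
                    c(seq(1, 0.2, length.out = 4), rep(0.1, 17)))
  expect_error(bending_stiffness(short), "fewer than 5")
})

test_that("yield_point: linear, elastic-perfectly-plastic algebra, warning path", {
  cfg <- bending_config(preload = 0)
  lin <- make_line_curve(K = 110, dmax = 0.2)
  expect_warning(y <- yield_point(lin, 110, cfg), "never met")
  expect_equal(y$displacement, max(lin$displacement))
  # elastic-perfectly-plastic: plateau F_p -> d_y = F_p / (0.9 K)
  d <- seq(0, 0.4, by = 5e-4)
  f <- pmin(110 * d, 16.5)
  ep <- fd_curve(d, f)
  y2 <- yield_point(ep, 110, cfg)
  expect_equal(y2$displacement, 16.5 / (0.9 * 110), tolerance = 0.01)
})

test_that("failure_point: drop detection and fallback", {
  d <- seq(0, 0.3, by = 5e-4)
  f <- 100 * d
  f[d > 0.25] <- 0.5
  fp <- failure_point(fd_curve(d, f), bending_config())
  expect_equal(fp$displacement, max(d[d <= 0.25]), tolerance = 1e-9)
  expect_warning(failure_point(make_line_curve(), bending_config()),
                 "no failure drop")
  bt <- bending_truth(noise_sd = 0)
  g <- gen_bending_curve(bt, seed = 9)
  got <- failure_point(g$curve, bending_config(preload = 0), warn = FALSE)
  expect_equal(got$displacement, g$truth$failure_displacement,
               tolerance = 0.001 / g$truth$failure_displacement)
})

test_that("extract_flexural assembles properties and flags irregular curves", {
  # linear curve to 18 N at K = 110: W = F^2/2K, moment = F L / 4
  d <- seq(0, 18 / 110, length.out = 200)
  f <- 110 * d
  f <- c(f, 0.1)                       # terminal drop
  d <- c(d, max(d) + 5e-4)
  fp <- extract_flexural(fd_curve(d, f), bending_config(preload = 0))
  expect_equal(fp$work_to_fracture, 18^2 / (2 * 110), tolerance = 0.02)
  expect_equal(fp$max_moment, 18 * 7 / 4, tolerance = 1e-9)
  expect_equal(fp$post_yield_displacement, 0, tolerance = 1e-9)
  expect_false(fp$irregular)
  # non-monotone force before 50% of peak -> irregular, PYD/work withheld
  f2 <- f
  f2[30:40] <- f2[30:40] - 3
  fp2 <- extract_flexural(fd_curve(d, pmax(f2, 0)),
                          bending_config(preload = 0))
  expect_true(fp2$irregular)
  expect_true(is.na(fp2$post_yield_displacement))
  expect_true(is.na(fp2$work_to_fracture))
})

test_that("property extraction is invariant to prepending a zero-force toe", {
  bt <- bending_truth(noise_sd = 0)
  g <- gen_bending_curve(bt, seed = 4)
  base <- g$curve
  cfg <- bending_config(preload = 0.5)
  toe <- fd_curve(c(seq(0, 0.02, by = 5e-4), base$displacement + 0.0205),
                  c(rep(0, 41), base$force))
  shifted <- fd_curve(base$displacement, base$force)
  p1 <- extract_flexural(shifted, cfg)
  p2 <- extract_flexural(toe, cfg)
  expect_equal(p1$stiffness, p2$stiffness, tolerance = 1e-6)
  expect_equal(p1$max_force, p2$max_force, tolerance = 1e-9)
  expect_equal(p1$post_yield_displacement, p2$post_yield_displacement,
               tolerance = 0.02)
  expect_equal(p1$work_to_fracture, p2$work_to_fracture, tolerance = 0.02)
})

test_that("tissue_modulus implements the beam equation exactly", {
  # E -> K -> E identity
  E <- 20000; I <- 0.1; L <- 7
  K <- 48 * E * I / L^3
  expect_equal(K, 279.9, tolerance = 1e-3)
  expect_equal(tissue_modulus(K, I, L), E, tolerance = 1e-12)
  # worked value from group means
  expect_equal(tissue_modulus(110.79, 0.15, 7), 110.79 * 343 / (48 * 0.15),
               tolerance = 1e-12)
  expect_equal(tissue_modulus(110.79, 0.15, 7), 5277.91, tolerance = 1e-5)
  expect_error(tissue_modulus(110, 0, 7), "> 0")
})

test_that("mass_adjust removes the strain-specific mass trend", {
  set.seed(1)
  n <- 200
  strain <- rep(c("a", "b"), each = n)
  mass <- c(rnorm(n, 34, 3), rnorm(n, 39, 5))
  y <- ifelse(strain == "a", 2 + 0.05 * mass, 5 + 0.12 * mass) +
    rnorm(2 * n, 0, 0.1)
  adj <- mass_adjust(y, mass, strain)
  for (s in c("a", "b"))
    expect_lt(abs(cor(adj[strain == s], mass[strain == s])), 0.1)
  # zero slope -> adjusted equals observed
  y0 <- rnorm(2 * n)
  adj0 <- mass_adjust(y0, mass, strain)
  for (s in c("a", "b")) {
    b <- coef(lm(y0[strain == s] ~ mass[strain == s]))[2]
    manual <- y0[strain == s] - b * (mass[strain == s] - mean(mass))
    expect_equal(adj0[strain == s], manual, tolerance = 1e-12)
  }
  # constant mass within a strain: warning, unchanged
  mass2 <- c(rep(30, n), rnorm(n, 39, 5))
  expect_warning(adj2 <- mass_adjust(y0, mass2, strain), "constant")
  expect_equal(adj2[strain == "a"], y0[strain == "a"])
})
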