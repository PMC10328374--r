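#' Ground-truth description of an elliptical cortical cross-section
#'
#' Defines an elliptical annulus (cortex) with optional spherical intracortical
#' pores. Closed-form areas and principal second moments of area are attached
#' so voxelized renderings can be checked against analytic values.
#'
#' Closed forms for outer semi-axes (a, b) and inner semi-axes (ai, bi):
#' Tt.Ar = pi*a*b, Ma.Ar = pi*ai*bi, annulus area = pi*(a*b - ai*bi),
#' I about the axis through the centroid along x: pi/4*(a*b^3 - ai*bi^3),
#' along y: pi/4*(a^3*b - ai^3*bi). c is the extreme-fiber distance from the
#' weak (I_min) principal axis.
#'
#' @param outer_semi_axes length-2 numeric, outer semi-axes (a, b) in mm
#' @param inner_semi_axes length-2 numeric, inner semi-axes in mm, strictly
#'   inside the outer ellipse
#' @param pore_fraction target cortical porosity, pore/(pore+bone), in [0, 0.5)
#' @param voxel_size isotropic voxel size in mm (default 0.006, i.e. 6 um)
#' @return object of class `geometry_truth` with the requested fields plus
#'   `true_areas` (Tt.Ar, Ct.Ar, Ma.Ar in mm^2), `true_moments` (I_min, I_max
#'   in mm^4) and `true_c` (mm)
#' @export
geometry_truth <- function(outer_semi_axes = c(0.9, 0.7),
                           inner_semi_axes = c(0.6, 0.45),
                           pore_fraction = 0,
                           voxel_size = 0.006) {
  a <- outer_semi_axes[1]; b <- outer_semi_axes[2]
  ai <- inner_semi_axes[1]; bi <- inner_semi_axes[2]
  if (any(c(a, b, ai, bi) <= 0)) stop_bonemech("semi-axes must be positive")
  if (ai >= a || bi >= b)
    stop_bonemech("inner semi-axes must be strictly inside the outer ellipse")
  if (pore_fraction < 0 || pore_fraction >= 0.5)
    stop_bonemech("pore_fraction must be in [0, 0.5)")
  if (voxel_size <= 0) stop_bonemech("voxel_size must be positive")

  Ix <- pi / 4 * (a * b^3 - ai * bi^3)  # bending about the x-directed axis
  Iy <- pi / 4 * (a^3 * b - ai^3 * bi)
  I_min <- min(Ix, Iy); I_max <- max(Ix, Iy)
  # extreme fiber distance from the weak axis: the weak axis is x-directed
  # when Ix <= Iy, and the farthest fiber is then at |y| = b
  true_c <- if (Ix <= Iy) b else a
  annulus <- pi * (a * b - ai * bi)
  structure(list(
    outer_semi_axes = c(a, b), inner_semi_axes = c(ai, bi),
    pore_fraction = pore_fraction, voxel_size = voxel_size,
    true_areas = c(Tt.Ar = pi * a * b,
                   Ct.Ar = annulus * (1 - pore_fraction),
                   Ma.Ar = pi * ai * bi),
    true_moments = c(I_min = I_min, I_max = I_max),
    true_c = true_c
  ), class = "geometry_truth")
}

#' Ground-truth parameters of a three-point-bending test
#'
#' @param stiffness elastic bending stiffness K in N/mm
#' @param yield_force force at the elastic/post-yield kink in N
#' @param ultimate_force peak force in N (>= yield_force)
#' @param post_yield_displacement displacement from the kink to failure in mm
#' @param span support span L in mm
#' @param noise_sd additive force noise SD in N (must stay below 10% of the
#'   yield force, otherwise the properties are unidentifiable)
#' @return object of class `bending_truth`
#' @export
bending_truth <- function(stiffness = 110, yield_force = 15,
                          ultimate_force = 18, post_yield_displacement = 0.15,
                          span = 7, noise_sd = 0) {
  if (stiffness <= 0) stop_bonemech("stiffness must be positive")
  if (yield_force <= 0) stop_bonemech("yield_force must be positive")
  if (ultimate_force < yield_force)
    stop_bonemech("ultimate_force must be >= yield_force")
  if (post_yield_displacement < 0)
    stop_bonemech("post_yield_displacement must be >= 0")
  if (noise_sd >= 0.1 * yield_force)
    stop_bonemech("noise_sd >= 10% of yield_force: properties unidentifiable")
  structure(list(stiffness = stiffness, yield_force = yield_force,
                 ultimate_force = ultimate_force,
                 post_yield_displacement = post_yield_displacement,
                 span = span, noise_sd = noise_sd),
            class = "bending_truth")
}

#' Ground-truth parameters of a nanoindentation test
#'
#' @param reduced_modulus target contact (reduced) modulus E_r in GPa
#' @param hardness target hardness H in GPa
#' @param max_load peak load in uN (protocol default 1000 uN)
#' @param load_rate loading/unloading rate in uN/s (protocol default 100)
#' @param hold_time hold duration at peak load in s (protocol default 30)
#' @param creep_amplitude depth creep amplitude during the hold, nm
#' @param noise_sd additive load noise SD in uN
#' @return object of class `indentation_truth`
#' @export
indentation_truth <- function(reduced_modulus = 70, hardness = 0.9,
                              max_load = 1000, load_rate = 100,
                              hold_time = 30, creep_amplitude = 0,
                              noise_sd = 0) {
  if (reduced_modulus <= 0) stop_bonemech("reduced_modulus must be positive")
  if (hardness <= 0) stop_bonemech("hardness must be positive")
  if (max_load <= 0) stop_bonemech("max_load must be positive")
  if (load_rate <= 0) stop_bonemech("load_rate must be positive")
  if (hold_time < 0) stop_bonemech("hold_time must be >= 0")
  structure(list(reduced_modulus = reduced_modulus, hardness = hardness,
                 max_load = max_load, load_rate = load_rate,
                 hold_time = hold_time, creep_amplitude = creep_amplitude,
                 noise_sd = noise_sd),
            class = "indentation_truth")
}

#' Default Raman band set for cortical bone
#'
#' Characteristic mineral and organic matrix bands: nu2 PO4 (~430), nu1 PO4
#' (~960), nu1 CO3 (~1070), amide III envelope (~1245), CH2 wag (~1450), the
#' pentosidine-associated band (~1495) and the amide I pair (1660/1690).
#'
#' @return data.frame with columns center, height, sigma, shape
#' @export
default_bands <- function() {
  data.frame(
    center = c(430, 960, 1070, 1245, 1450, 1495, 1660, 1690),
    height = c(30, 100, 16, 24, 30, 9, 34, 20),
    sigma  = c(8, 7.3, 8, 19, 12, 8, 13, 9),
    shape  = c("gaussian", "gaussian", "gaussian", "gaussian",
               "gaussian", "gaussian", "gaussian", "gaussian"),
    stringsAsFactors = FALSE
  )
}

#' Ground-truth description of a Raman bone spectrum
#'
#' The analytic metric values (`true_metrics`) are computed from the band
#' parameters alone: band areas by exact profile integrals over the metric
#' windows, the nu1 PO4 FWHM by root finding on the noiseless band sum, and
#' the intensity ratios from the noiseless band sum at the named wavenumbers.
#'
#' @param bands data.frame(center, height, sigma, shape); shape is
#'   "gaussian" or "lorentzian" (sigma = HWHM for lorentzian)
#' @param baseline_coeffs polynomial coefficients (intercept first) in the
#'   scaled variable x/1000 for the additive fluorescence baseline
#' @param noise_sd additive Gaussian noise SD in counts
#' @return object of class `spectrum_truth` with a `true_metrics` element
#'   (mineral_matrix, carbonate_phosphate, crystallinity, collagen_maturity,
#'   pen_ratio) and `true_fwhm` (cm^-1)
#' @export
spectrum_truth <- function(bands = default_bands(),
                           baseline_coeffs = c(240, 25, -10),
                           noise_sd = 1) {
  stopifnot(is.data.frame(bands),
            all(c("center", "height", "sigma", "shape") %in% names(bands)))
  if (any(bands$center < 280 | bands$center > 2000))
    stop_bonemech("band centers must lie within 280-2000 cm^-1")
  if (any(bands$sigma <= 0)) stop_bonemech("band widths must be positive")
  tm <- analytic_metrics(bands)
  structure(list(bands = bands, baseline_coeffs = baseline_coeffs,
                 noise_sd = noise_sd,
                 true_metrics = tm$metrics, true_fwhm = tm$fwhm),
            class = "spectrum_truth")
}

# noiseless, baseline-free band-sum profile
band_profile <- function(bands, x) {
  y <- numeric(length(x))
  for (i in seq_len(nrow(bands))) {
    if (bands$shape[i] == "gaussian") {
      y <- y + bands$height[i] * exp(-(x - bands$center[i])^2 /
                                       (2 * bands$sigma[i]^2))
    } else {
      y <- y + bands$height[i] /
        (1 + ((x - bands$center[i]) / bands$sigma[i])^2)
    }
  }
  y
}

# exact integral of the band sum over [lo, hi]
band_profile_area <- function(bands, lo, hi) {
  tot <- 0
  for (i in seq_len(nrow(bands))) {
    h <- bands$height[i]; c0 <- bands$center[i]; s <- bands$sigma[i]
    if (bands$shape[i] == "gaussian") {
      tot <- tot + h * s * sqrt(2 * pi) *
        (pnorm((hi - c0) / s) - pnorm((lo - c0) / s))
    } else {
      tot <- tot + h * s * (atan((hi - c0) / s) - atan((lo - c0) / s))
    }
  }
  tot
}

analytic_metrics <- function(bands) {
  f <- function(x) band_profile(bands, x)
  # FWHM of the nu1 PO4 band: peak within 930-980, half-max crossings of the
  # noiseless profile found by root bracketing
  opt <- optimise(f, c(930, 980), maximum = TRUE)
  pk_x <- opt$maximum; pk <- opt$objective
  half <- pk / 2
  g <- function(x) f(x) - half
  left <- uniroot(g, c(pk_x - 120, pk_x), tol = 1e-10)$root
  right <- uniroot(g, c(pk_x, pk_x + 120), tol = 1e-10)$root
  fwhm <- right - left
  metrics <- c(
    mineral_matrix = band_profile_area(bands, 410, 460) /
      band_profile_area(bands, 1215, 1300),
    carbonate_phosphate = band_profile_area(bands, 1050, 1100) /
      band_profile_area(bands, 930, 980),
    crystallinity = 1 / fwhm,
    collagen_maturity = f(1660) / f(1690),
    pen_ratio = f(1495) / f(1450)
  )
  list(metrics = metrics, fwhm = fwhm)
}
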