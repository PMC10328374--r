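#' Construct a force-displacement curve
#'
#' @param displacement non-decreasing displacement in mm
#' @param force force in N
#' @param sampling_rate sampling rate in Hz (default 100, typical for a
#'   200-N load cell on an electrically actuated frame)
#' @return object of class `fd_curve`
#' @export
fd_curve <- function(displacement, force, sampling_rate = 100) {
  if (length(displacement) != length(force))
    stop_bonemech("displacement and force must have equal length")
  if (length(force) < 20L) stop_bonemech("curve needs >= 20 samples")
  if (any(diff(displacement) < -1e-12))
    stop_bonemech("displacement must be non-decreasing")
  structure(list(displacement = as.numeric(displacement),
                 force = as.numeric(force),
                 sampling_rate = sampling_rate),
            class = "fd_curve")
}

#' Three-point-bending configuration
#'
#' @param span support span L in mm (default 7)
#' @param preload compressive preload in N used for displacement zeroing
#'   (default 2)
#' @param yield_secant_fraction yield when the secant stiffness F/d falls
#'   below (1 - fraction) * K (default 0.10)
#' @param failure_drop_fraction failure at the first sample-to-sample force
#'   drop exceeding this fraction of peak force (default 0.10)
#' @return object of class `bending_config`
#' @export
bending_config <- function(span = 7, preload = 2,
                           yield_secant_fraction = 0.10,
                           failure_drop_fraction = 0.10) {
  if (span <= 0) stop_bonemech("span must be positive")
  if (preload < 0) stop_bonemech("preload must be >= 0")
  structure(list(span = span, preload = preload,
                 yield_secant_fraction = yield_secant_fraction,
                 failure_drop_fraction = failure_drop_fraction),
            class = "bending_config")
}

#' Generate a synthetic three-point-bending curve
#'
#' Piecewise force-displacement record: linear ramp at stiffness K to the
#' yield kink, linear hardening to the ultimate force over 40% of the
#' post-yield displacement, linear softening to failure, then a terminal
#' force drop; additive i.i.d. Gaussian noise. Sampled at the displacement
#' rate/sampling rate of the standard murine protocol (0.05 mm/s, 100 Hz).
#'
#' The attached ground truth reports both the kink parameters and the
#' *criterion* yield point: the point where the secant stiffness of the
#' noiseless curve falls to 90% of K, which is what any secant-offset
#' analysis measures on a bilinear curve (on a kinked curve the criterion
#' point lies slightly beyond the kink).
#'
#' @param truth a [bending_truth()]
#' @param seed integer seed
#' @param rate displacement rate mm/s (default 0.05)
#' @param sampling_rate Hz (default 100)
#' @param yield_secant_fraction secant reduction defining the criterion
#'   yield recorded in the truth (default 0.10)
#' @return list with `curve` (an `fd_curve`) and `truth` (the input truth
#'   plus criterion yield displacement/force, failure point, analytic
#'   post-yield displacement and work to fracture)
#' @export
gen_bending_curve <- function(truth, seed = 1L, rate = 0.05,
                              sampling_rate = 100,
                              yield_secant_fraction = 0.10) {
  stopifnot(inherits(truth, "bending_truth"))
  K <- truth$stiffness
  Fy <- truth$yield_force
  Fu <- truth$ultimate_force
  pyd <- truth$post_yield_displacement
  d_k <- Fy / K
  d_u <- d_k + 0.4 * pyd
  d_f <- d_k + pyd
  F_end <- if (pyd > 0) 0.85 * Fu else Fu
  node_d <- c(0, d_k, d_u, d_f)
  node_f <- c(0, Fy, Fu, F_end)
  if (pyd == 0) { node_d <- c(0, d_k); node_f <- c(0, Fy) }

  step <- rate / sampling_rate
  disp <- seq(0, d_f + 2 * step, by = step)
  force <- approx(node_d, node_f, xout = pmin(disp, d_f), rule = 2)$y
  force[disp > d_f] <- 0.02 * Fu       # terminal drop after fracture

  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  if (truth$noise_sd > 0)
    force <- force + rnorm(length(force), 0, truth$noise_sd)

  # criterion yield on the noiseless curve: F(d)/d = (1 - q) K
  q <- yield_secant_fraction
  if (pyd > 0) {
    s_h <- (Fu - Fy) / (d_u - d_k)     # hardening slope
    d_y <- (Fy - s_h * d_k) / ((1 - q) * K - s_h)
    if (d_y > d_u) {                   # criterion met on the softening leg
      s_s <- (F_end - Fu) / (d_f - d_u)
      d_y <- (Fu - s_s * d_u) / ((1 - q) * K - s_s)
      d_y <- min(d_y, d_f)
    }
    F_yc <- approx(node_d, node_f, xout = d_y)$y
  } else {
    d_y <- d_k; F_yc <- Fy
  }
  # analytic work to fracture: trapezoids over the exact nodes
  nd <- node_d; nf <- node_f
  work <- sum(diff(nd) * (head(nf, -1) + tail(nf, -1)) / 2)
  tr <- truth
  tr$yield_displacement <- d_y
  tr$yield_force_criterion <- F_yc
  tr$failure_displacement <- d_f
  tr$pyd_criterion <- d_f - d_y
  tr$work_to_fracture <- work
  tr$max_force <- Fu
  list(curve = fd_curve(disp, force, sampling_rate), truth = tr)
}

#' Zero a bending curve at the preload crossing
#'
#' Displacement is re-zeroed at the first crossing of the preload force
#' (linear interpolation); samples before the crossing are discarded and the
#' interpolated crossing becomes the first sample at force = preload.
#'
#' @param curve an [fd_curve()]
#' @param config a [bending_config()]
#' @return zeroed `fd_curve`
#' @export
preprocess_curve <- function(curve, config = bending_config()) {
  stopifnot(inherits(curve, "fd_curve"))
  f <- curve$force; d <- curve$displacement
  pre <- config$preload
  if (max(f) <= pre) stop_bonemech("invalid test: force never reaches preload")
  i <- which(f >= pre)[1]
  if (i == 1L) {
    d0 <- d[1]
    keep <- seq_along(d)
    nd <- d[keep] - d0; nf <- f[keep]
  } else {
    # linear interpolation of the crossing between samples i-1 and i
    w <- (pre - f[i - 1]) / (f[i] - f[i - 1])
    d0 <- d[i - 1] + w * (d[i] - d[i - 1])
    nd <- c(0, d[i:length(d)] - d0)
    nf <- c(pre, f[i:length(f)])
  }
  structure(list(displacement = nd, force = nf,
                 sampling_rate = curve$sampling_rate),
            class = "fd_curve")
}

#' Bending stiffness by maximum sliding-window regression
#'
#' K is the maximum least-squares slope over a sliding window covering 20%
#' of the samples between the start of the (preprocessed) curve and the peak
#' force; robust to toe regions and deterministic.
#'
#' @param curve preprocessed [fd_curve()]
#' @param window_fraction window width as a fraction of pre-peak samples
#' @return stiffness K in N/mm
#' @export
bending_stiffness <- function(curve, window_fraction = 0.2) {
  d <- curve$displacement; f <- curve$force
  ipk <- which.max(f)
  n <- ipk
  w <- max(5L, ceiling(window_fraction * n))
  if (n < 5L) stop_bonemech("fewer than 5 pre-peak samples")
  if (w > n) w <- n
  # O(n) sliding OLS slope via cumulative sums
  cx <- cumsum(d[1:n]); cy <- cumsum(f[1:n])
  cxx <- cumsum(d[1:n]^2); cxy <- cumsum(d[1:n] * f[1:n])
  starts <- 1:(n - w + 1L)
  sx <- cx[starts + w - 1L] - c(0, cx)[starts]
  sy <- cy[starts + w - 1L] - c(0, cy)[starts]
  sxx <- cxx[starts + w - 1L] - c(0, cxx)[starts]
  sxy <- cxy[starts + w - 1L] - c(0, cxy)[starts]
  denom <- w * sxx - sx^2
  slope <- ifelse(denom > 0, (w * sxy - sx * sy) / denom, -Inf)
  max(slope)
}

#' Yield point by secant-stiffness reduction
#'
#' First sample where the secant stiffness F/d falls below
#' (1 - yield_secant_fraction) * K. If the criterion is never met before the
#' failure point, yield is placed at failure (post-yield displacement 0)
#' with a warning.
#'
#' @param curve preprocessed [fd_curve()]
#' @param K bending stiffness from [bending_stiffness()]
#' @param config a [bending_config()]
#' @return list(displacement, force)
#' @export
yield_point <- function(curve, K, config = bending_config()) {
  d <- curve$displacement; f <- curve$force
  fail <- failure_point(curve, config, warn = FALSE)
  upto <- d <= fail$displacement + 1e-12
  sec <- ifelse(d > 0, f / d, K)
  crit <- (1 - config$yield_secant_fraction) * K
  # the secant is noise-dominated near the origin; only consider samples
  # carrying at least a quarter of the peak force
  loaded <- f >= 0.25 * max(f)
  cand <- which(sec < crit & d > 0 & upto & loaded)
  if (length(cand) == 0L) {
    warning("yield criterion never met before failure: PYD = 0")
    return(list(displacement = fail$displacement, force = fail$force))
  }
  i <- cand[1]
  list(displacement = d[i], force = f[i])
}

#' Failure point by instantaneous force drop
#'
#' First sample-to-sample force drop exceeding `failure_drop_fraction` of
#' the peak force; if no such drop exists the last sample is returned with a
#' warning.
#'
#' @param curve preprocessed [fd_curve()]
#' @param config a [bending_config()]
#' @param warn warn when no drop is found
#' @return list(displacement, force)
#' @export
failure_point <- function(curve, config = bending_config(), warn = TRUE) {
  d <- curve$displacement; f <- curve$force
  drops <- -diff(f)
  thr <- config$failure_drop_fraction * max(f)
  i <- which(drops > thr)
  if (length(i) == 0L) {
    if (warn) warning("no failure drop detected: using last sample")
    n <- length(d)
    return(list(displacement = d[n], force = f[n]))
  }
  list(displacement = d[i[1]], force = f[i[1]])
}

#' Extract whole-bone flexural properties
#'
#' Assembles stiffness, peak force/moment, yield, failure, post-yield
#' displacement and work to fracture (trapezoidal integral of force over
#' displacement up to failure) from a raw curve. A curve with non-monotone
#' force before 50% of peak is flagged irregular and its PYD/work are
#' reported NA (the exclusion rule for specimens that moved during testing).
#'
#' @param curve raw [fd_curve()]
#' @param config a [bending_config()]
#' @param I_min optional minimum second moment of area (mm^4) for the tissue
#'   modulus via the beam equation
#' @return named list of properties (forces N, displacements mm, moments
#'   N*mm, modulus MPa)
#' @export
extract_flexural <- function(curve, config = bending_config(), I_min = NULL) {
  pc <- preprocess_curve(curve, config)
  K <- bending_stiffness(pc)
  fail <- failure_point(pc, config, warn = FALSE)
  yld <- suppressWarnings(yield_point(pc, K, config))
  f <- pc$force; d <- pc$displacement
  ipk <- which.max(f)
  max_force <- f[ipk]
  # irregularity: force drops > 2% of peak before half of peak force
  pre <- f[seq_len(ipk)]
  half <- which(pre >= 0.5 * max_force)[1]
  irregular <- half > 2 && any(diff(pre[seq_len(half)]) < -0.02 * max_force)
  upto <- d <= fail$displacement + 1e-12
  dd <- d[upto]; ff <- f[upto]
  work <- sum(diff(dd) * (head(ff, -1) + tail(ff, -1)) / 2)
  pyd <- fail$displacement - yld$displacement
  E <- if (!is.null(I_min)) tissue_modulus(K, I_min, config$span) else NA_real_
  list(stiffness = K, max_force = max_force,
       max_moment = max_force * config$span / 4,
       yield_displacement = yld$displacement, yield_force = yld$force,
       failure_displacement = fail$displacement,
       post_yield_displacement = if (irregular) NA_real_ else pyd,
       work_to_fracture = if (irregular) NA_real_ else work,
       tissue_modulus = E, irregular = irregular)
}

#' Tissue elastic modulus from bending stiffness (beam equation)
#'
#' E = K L^3 / (48 I_min): the prismatic-beam relation between structural
#' bending stiffness at midspan and tissue modulus. K in N/mm, L in mm,
#' I_min in mm^4 give E in MPa.
#'
#' @param K bending stiffness N/mm
#' @param I_min minimum second moment of area mm^4
#' @param L span mm
#' @return tissue modulus E in MPa
#' @export
tissue_modulus <- function(K, I_min, L) {
  if (any(c(K, I_min, L) <= 0)) stop_bonemech("K, I_min and L must be > 0")
  K * L^3 / (48 * I_min)
}

#' Body-mass adjustment of an outcome
#'
#' For each mouse i in strain s the adjusted value is
#' y_i - b_s * (m_i - m_bar), with b_s the strain-specific OLS slope of the
#' outcome on body mass and m_bar the grand-mean body mass over both
#' strains, so adjusted group means are comparable at a common mass.
#'
#' @param y outcome values
#' @param mass body masses (g)
#' @param strain strain labels (factor or character)
#' @param reference_mass mass at which to report (default grand mean)
#' @return adjusted outcome vector
#' @export
mass_adjust <- function(y, mass, strain, reference_mass = NULL) {
  stopifnot(length(y) == length(mass), length(y) == length(strain))
  strain <- as.factor(strain)
  if (any(table(strain) < 3L))
    stop_bonemech("need >= 3 mice per strain for the slope")
  mbar <- reference_mass %||% mean(mass)
  adj <- y
  for (s in levels(strain)) {
    i <- strain == s
    if (sd(mass[i]) == 0) {
      warning("constant body mass in strain ", s, ": adjusted = observed")
      next
    }
    b <- coef(lm(y[i] ~ mass[i]))[2]
    adj[i] <- y[i] - b * (mass[i] - mbar)
  }
  adj
}
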