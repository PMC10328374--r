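#' Indenter tip area function
#'
#' Projected contact area A(h_c) = C0 h_c^2 + C1 h_c + C2 h_c^(1/2) +
#' C3 h_c^(1/4) + C4 h_c^(1/8) + C5 h_c^(1/16), the standard polynomial form
#' for a calibrated Berkovich tip. C0 = 24.5 is the ideal Berkovich value.
#'
#' @param coefficients numeric length 6 (C0..C5); depths in nm, area in nm^2
#' @param valid_range depth range (nm) over which the fit is trusted
#' @return object of class `area_function`; callable via [evaluate_area()]
#' @export
area_function <- function(coefficients = c(24.5, 0, 0, 0, 0, 0),
                          valid_range = c(0, Inf)) {
  coefficients <- c(coefficients, rep(0, 6))[1:6]
  structure(list(coefficients = coefficients, valid_range = valid_range),
            class = "area_function")
}

#' @rdname area_function
#' @export
berkovich_area_function <- function() area_function()

#' Evaluate a tip area function
#'
#' @param af an [area_function()]
#' @param h_c contact depth(s) in nm
#' @return projected area(s) in nm^2
#' @export
evaluate_area <- function(af, h_c) {
  stopifnot(inherits(af, "area_function"))
  cf <- af$coefficients
  A <- cf[1] * h_c^2 + cf[2] * h_c + cf[3] * h_c^(1 / 2) +
    cf[4] * h_c^(1 / 4) + cf[5] * h_c^(1 / 8) + cf[6] * h_c^(1 / 16)
  if (any(A <= 0)) stop_bonemech("area function non-positive at requested depth")
  A
}

#' Oliver-Pharr indenter constants
#'
#' Standard constants for a diamond Berkovich tip: geometry factor
#' epsilon = 0.75, correction beta = 1.0, indenter modulus 1141 GPa,
#' indenter Poisson ratio 0.07, and a default sample Poisson ratio of 0.3
#' (cortical bone).
#'
#' @param epsilon unload geometry factor in `[0.7, 0.8]`
#' @param beta tip shape correction
#' @param E_indenter indenter Young's modulus, GPa
#' @param nu_indenter indenter Poisson ratio
#' @param nu_sample sample Poisson ratio
#' @return object of class `indenter_constants`
#' @export
indenter_constants <- function(epsilon = 0.75, beta = 1.0,
                               E_indenter = 1141, nu_indenter = 0.07,
                               nu_sample = 0.3) {
  if (epsilon < 0.7 || epsilon > 0.8)
    stop_bonemech("epsilon must lie in [0.7, 0.8]")
  if (any(c(beta, E_indenter) <= 0))
    stop_bonemech("constants must be positive")
  structure(list(epsilon = epsilon, beta = beta, E_indenter = E_indenter,
                 nu_indenter = nu_indenter, nu_sample = nu_sample),
            class = "indenter_constants")
}

# unit note: with depth in nm and load in uN, S [uN/nm] / sqrt(A [nm^2])
# carries uN/nm^2 = 10^3 GPa, and P/A carries the same factor.
UN_PER_NM2_TO_GPA <- 1000

# forward contact solution: target E_r (GPa), H (GPa), P_max (uN) ->
# contact area, stiffness, depths, for a given area function and constants
contact_forward <- function(E_r, H, P_max, af = berkovich_area_function(),
                            constants = indenter_constants()) {
  A <- P_max / (H / UN_PER_NM2_TO_GPA)                   # nm^2
  S <- 2 * constants$beta / sqrt(pi) * (E_r / UN_PER_NM2_TO_GPA) * sqrt(A)
  # invert the area function for h_c (monotone on the valid range)
  cf <- af$coefficients
  if (all(cf[-1] == 0)) {
    h_c <- sqrt(A / cf[1])
  } else {
    h_c <- uniroot(function(h) evaluate_area(af, h) - A,
                   c(1e-3, 1e6), tol = 1e-10)$root
  }
  h_max <- h_c + constants$epsilon * P_max / S
  list(A = A, S = S, h_c = h_c, h_max = h_max)
}

#' Generate a synthetic nanoindentation curve
#'
#' Three-segment load-hold-unload record consistent with the Oliver-Pharr
#' contact model: loading with P proportional to h^2 (a modelling choice:
#' the loading-curve shape is not constrained by the contact analysis),
#' a constant-load hold with logarithmic depth creep, and a power-law unload
#' P = alpha (h - h_f)^m whose slope at peak equals the contact stiffness
#' implied by the requested reduced modulus.
#'
#' @param truth an [indentation_truth()]
#' @param af [area_function()] describing the (true) tip
#' @param seed integer seed
#' @param m unload exponent, must lie in `[1.2, 2.2]` (default 1.5)
#' @param dt sample spacing in s (default 0.05)
#' @param constants [indenter_constants()]
#' @return list with `curve` (data.frame time, depth, load, segment) and
#'   `truth` (input truth plus the implied S, h_c, h_max, alpha, h_f, m)
#' @export
gen_indentation_curve <- function(truth, af = berkovich_area_function(),
                                  seed = 1L, m = 1.5, dt = 0.05,
                                  constants = indenter_constants()) {
  stopifnot(inherits(truth, "indentation_truth"))
  if (m < 1.2 || m > 2.2)
    stop_bonemech("unload exponent m must lie in [1.2, 2.2]")
  fw <- contact_forward(truth$reduced_modulus, truth$hardness,
                        truth$max_load, af, constants)
  P_max <- truth$max_load
  t_load <- P_max / truth$load_rate
  t_hold <- truth$hold_time
  creep <- truth$creep_amplitude
  total_creep <- if (t_hold > 0) creep * log1p(t_hold) else 0
  h_le <- fw$h_max - total_creep       # depth at end of loading
  if (h_le <= 0) stop_bonemech("creep amplitude inconsistent with depth scale")

  tl <- seq(0, t_load, by = dt)
  Pl <- truth$load_rate * tl
  hl <- h_le * sqrt(Pl / P_max)

  th <- if (t_hold > 0) seq(dt, t_hold, by = dt) else numeric(0)
  Ph <- rep(P_max, length(th))
  hh <- h_le + creep * log1p(th)

  # unload at load_rate down to zero load
  h_f <- fw$h_max - m * P_max / fw$S
  alpha <- P_max / (fw$h_max - h_f)^m
  tu <- seq(dt, t_load, by = dt)
  Pu <- pmax(P_max - truth$load_rate * tu, 0)
  hu <- h_f + (Pu / alpha)^(1 / m)

  tt <- c(tl, t_load + th, t_load + t_hold + tu)
  depth <- c(hl, hh, hu)
  load <- c(Pl, Ph, Pu)
  seg <- c(rep("load", length(tl)), rep("hold", length(th)),
           rep("unload", length(tu)))

  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  if (truth$noise_sd > 0)
    load <- load + rnorm(length(load), 0, truth$noise_sd)

  tr <- truth
  tr[c("S", "h_c", "h_max", "A")] <- fw[c("S", "h_c", "h_max", "A")]
  tr$alpha <- alpha; tr$h_f <- h_f; tr$m <- m
  list(curve = data.frame(time = tt, depth = depth, load = load,
                          segment = seg, stringsAsFactors = FALSE),
       truth = tr)
}

#' Segment a raw indentation record into load / hold / unload
#'
#' The hold is the contiguous region where |dP/dt| < 1% of the nominal load
#' rate; loading precedes it, unloading follows. Without a hold, the split
#' is at peak load.
#'
#' @param time,depth,load numeric vectors (s, nm, uN)
#' @param load_rate nominal loading rate in uN/s (default 100)
#' @return data.frame(time, depth, load, segment)
#' @export
segment_indent <- function(time, depth, load, load_rate = 100) {
  n <- length(time)
  stopifnot(length(depth) == n, length(load) == n, n >= 10L)
  dPdt <- c(diff(load) / diff(time), NA)
  flat <- abs(dPdt) < 0.01 * load_rate
  ipk <- which.max(load)
  # hold: longest flat run containing loads near the maximum
  seg <- rep("load", n)
  near_max <- load > 0.95 * max(load)
  hold_idx <- which(flat & near_max)
  if (length(hold_idx) > 1L) {
    runs <- split(hold_idx, cumsum(c(1, diff(hold_idx) != 1)))
    run <- runs[[which.max(lengths(runs))]]
    seg[run[1]:(tail(run, 1) + 1L)] <- "hold"
    if (tail(run, 1) + 2L <= n) seg[(tail(run, 1) + 2L):n] <- "unload"
  } else {
    if (ipk < n) seg[(ipk + 1L):n] <- "unload"
  }
  if (!any(seg == "unload")) stop_bonemech("no unload segment")
  data.frame(time = time, depth = depth, load = load, segment = seg,
             stringsAsFactors = FALSE)
}

#' Fit the Oliver-Pharr unloading power law
#'
#' Least-squares fit of P = alpha (h - h_f)^m over the portion of the unload
#' between `fit_range[1]` and `fit_range[2]` of the peak load (default
#' 20%-95%, avoiding initial creep contamination and final tip-off). The
#' contact stiffness is the analytic slope at peak depth,
#' S = m alpha (h_max - h_f)^(m-1), and the contact depth is
#' h_c = h_max - epsilon P_max / S.
#'
#' @param curve segmented indent data.frame (from [segment_indent()] or
#'   [gen_indentation_curve()])
#' @param fit_range fraction-of-peak-load window used in the fit
#' @param constants [indenter_constants()]
#' @return list(alpha, h_f, m, S, h_c, h_max, P_max)
#' @export
fit_unloading <- function(curve, fit_range = c(0.20, 0.95),
                          constants = indenter_constants()) {
  un <- curve[curve$segment == "unload", ]
  if (nrow(un) < 10L) stop_bonemech("unload segment has < 10 samples")
  hold <- curve[curve$segment == "hold", ]
  P_max <- if (nrow(hold) > 0) mean(hold$load) else max(curve$load)
  h_max <- max(c(un$depth, if (nrow(hold) > 0) max(hold$depth) else NULL))
  sel <- un$load >= fit_range[1] * P_max & un$load <= fit_range[2] * P_max
  h <- un$depth[sel]; P <- un$load[sel]
  if (length(h) < 5L) stop_bonemech("too few samples in the fit range")

  # profile the residual depth h_f: for fixed h_f the model is linear in
  # log space, so a 1-D search over h_f is robust where a free 3-parameter
  # nls start can stall on the flat power-law SSE surface
  span <- max(h) - min(h)
  prof <- function(hf) {
    z <- log(h - hf)
    ft <- lm(log(P) ~ z)
    sum((P - exp(coef(ft)[1]) * (h - hf)^coef(ft)[2])^2)
  }
  opt <- optimise(prof, c(min(h) - 3 * span, min(h) - 1e-6 * span))
  hf0 <- opt$minimum
  fit0 <- lm(log(P) ~ log(h - hf0))
  start <- list(alpha = unname(exp(coef(fit0)[1])), h_f = hf0,
                m = unname(max(1.02, min(2.9, coef(fit0)[2]))))
  df <- data.frame(h = h, P = P)
  fit <- tryCatch(
    nls(P ~ alpha * (h - h_f)^m, data = df, start = start,
        control = nls.control(maxiter = 500, warnOnly = TRUE),
        lower = c(alpha = 1e-12, h_f = -Inf, m = 1.0),
        upper = c(alpha = Inf, h_f = min(h) - 1e-9, m = 3.0),
        algorithm = "port"),
    error = function(e) NULL)
  cf <- if (is.null(fit)) {
    c(alpha = start$alpha, h_f = start$h_f, m = start$m)
  } else coef(fit)
  if (cf["m"] < 1 || cf["m"] > 3)
    stop_bonemech("unloading exponent outside [1, 3]: indent flagged invalid")
  S <- cf["m"] * cf["alpha"] * (h_max - cf["h_f"])^(cf["m"] - 1)
  h_c <- h_max - constants$epsilon * P_max / S
  if (h_c <= 0 || h_c >= h_max)
    stop_bonemech("contact depth outside (0, h_max): indent flagged invalid")
  list(alpha = unname(cf["alpha"]), h_f = unname(cf["h_f"]),
       m = unname(cf["m"]), S = unname(S), h_c = unname(h_c),
       h_max = h_max, P_max = P_max)
}

#' Reduced modulus, sample modulus and hardness from an unloading fit
#'
#' E_r = sqrt(pi) S / (2 beta sqrt(A)), H = P_max / A, and the sample
#' modulus from 1/E_r = (1 - nu_s^2)/E_s + (1 - nu_i^2)/E_i.
#'
#' @param fit result of [fit_unloading()]
#' @param af [area_function()]
#' @param constants [indenter_constants()]
#' @return list(S, h_c, A, E_r, E_s, H) -- moduli GPa, A nm^2
#' @export
modulus_hardness <- function(fit, af = berkovich_area_function(),
                             constants = indenter_constants()) {
  A <- evaluate_area(af, fit$h_c)
  E_r <- sqrt(pi) * fit$S / (2 * constants$beta * sqrt(A)) * UN_PER_NM2_TO_GPA
  H <- fit$P_max / A * UN_PER_NM2_TO_GPA
  inv_Es <- 1 / E_r - (1 - constants$nu_indenter^2) / constants$E_indenter
  E_s <- (1 - constants$nu_sample^2) / inv_Es
  list(S = fit$S, h_c = fit$h_c, A = A, E_r = E_r, E_s = E_s, H = H)
}

#' Analyze one indentation curve end to end
#'
#' Convenience wrapper: segment (if needed), fit the unload, convert to
#' moduli and hardness.
#'
#' @param curve data.frame with time, depth, load (and optionally segment)
#' @param af [area_function()]
#' @param constants [indenter_constants()]
#' @param fit_range unload fit window as fraction of peak load
#' @param load_rate nominal load rate for segmentation, uN/s
#' @return list combining [fit_unloading()] and [modulus_hardness()] output
#' @export
analyze_indent <- function(curve, af = berkovich_area_function(),
                           constants = indenter_constants(),
                           fit_range = c(0.20, 0.95), load_rate = 100) {
  if (is.null(curve$segment))
    curve <- segment_indent(curve$time, curve$depth, curve$load, load_rate)
  fit <- fit_unloading(curve, fit_range, constants)
  c(fit[c("alpha", "h_f", "m")], modulus_hardness(fit, af, constants),
    list(P_max = fit$P_max, h_max = fit$h_max))
}

#' Calibrate a tip area function on fused-silica indents
#'
#' Given indentation curves on a calibration specimen of known modulus
#' (fused silica, E = 72 GPa, nu = 0.17), each unload fit yields a contact
#' stiffness and contact depth; the area each indent *must* have for the
#' target reduced modulus is A = pi S^2 / (4 beta^2 E_r^2). The C1..C5
#' deviation terms are then fit by least squares with C0 fixed at the ideal
#' Berkovich 24.5.
#'
#' @param curves list of segmented indent data.frames spanning a >= 3-fold
#'   depth range (at least 5 curves)
#' @param E_target calibration specimen Young's modulus, GPa (default 72)
#' @param nu_sample calibration specimen Poisson ratio (default 0.17)
#' @param constants [indenter_constants()] (nu_sample is overridden)
#' @param n_terms number of deviation terms C1..C5 to fit (default 2)
#' @return an [area_function()]
#' @export
calibrate_area_function <- function(curves, E_target = 72, nu_sample = 0.17,
                                    constants = indenter_constants(),
                                    n_terms = 2) {
  if (!is.list(curves) || length(curves) < 2L || !is.null(curves$load))
    stop_bonemech("need a list of >= 5 calibration curves")
  if (length(curves) < 5L) stop_bonemech("need >= 5 calibration curves")
  constants$nu_sample <- nu_sample
  E_r <- 1 / ((1 - nu_sample^2) / E_target +
                (1 - constants$nu_indenter^2) / constants$E_indenter)
  fits <- lapply(curves, fit_unloading, constants = constants)
  h_c <- vapply(fits, `[[`, 0, "h_c")
  S <- vapply(fits, `[[`, 0, "S")
  if (max(h_c) / min(h_c) < 3) {
    warning("depth range < 3-fold: fitting C0-C2 terms only")
    n_terms <- min(n_terms, 2)
  }
  A_req <- pi * S^2 / (4 * constants$beta^2 * (E_r / UN_PER_NM2_TO_GPA)^2)
  resid <- A_req - 24.5 * h_c^2
  basis <- cbind(h_c, sqrt(h_c), h_c^(1 / 4), h_c^(1 / 8), h_c^(1 / 16))
  k <- min(n_terms, 5, length(curves) - 1)
  cf <- rep(0, 5)
  if (k > 0) {
    B <- basis[, seq_len(k), drop = FALSE]
    cf[seq_len(k)] <- qr.solve(crossprod(B), crossprod(B, resid))
  }
  area_function(c(24.5, cf), valid_range = range(h_c))
}
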