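#' Default per-mouse outcome table for the two-genotype cohort
#'
#' Group means and SDs for the diabetic (TallyHO) and control (C57Bl/6J)
#' strains: cortical morphometry and whole-bone mechanics as reported for
#' body-mass-adjusted femoral data, trabecular microarchitecture of the
#' distal metaphysis, glycemia and body mass.
#'
#' @return data.frame(outcome, control_mean, control_sd, diabetic_mean,
#'   diabetic_sd)
#' @export
default_outcomes <- function() {
  d <- rbind(
    c("length_mm",        16.48, 0.20, 16.29, 0.30),
    c("Tt.Ar",             2.06, 0.11,  1.48, 0.07),
    c("Ma.Ar",             1.20, 0.08,  0.62, 0.06),
    c("Ct.Ar",             0.86, 0.04,  0.86, 0.04),
    c("Ct.Th",             0.19, 0.01,  0.25, 0.01),
    c("I_min",             0.15, 0.02,  0.11, 0.01),
    c("I_max",             0.34, 0.04,  0.20, 0.02),
    c("c",                 0.66, 0.03,  0.59, 0.02),
    c("Ct.Po",             0.24, 0.30,  1.43, 1.06),
    c("Ct.TMD",         1159.99, 24.29, 1227.20, 17.97),
    c("BV_TV",             9.38, 1.06,  3.43, 1.10),
    c("Tb.Sp",           236.50, 19.01, 354.50, 37.20),
    c("Tb.Th",            36.37, 1.18,  34.93, 7.30),
    c("Tb.N",              4.11, 0.27,  2.85, 0.29),
    c("Conn.D",          128.10, 28.65, 50.61, 28.85),
    c("SMI",               2.34, 0.08,  2.79, 0.33),
    c("Tb.TMD",          947.19, 8.22, 969.26, 9.70),
    c("max_moment",       32.68, 2.12, 34.68, 2.96),
    c("stiffness",       110.79, 11.70, 111.63, 21.61),
    c("post_yield_displacement", 0.17, 0.03, 0.11, 0.02),
    c("work_to_fracture",  4.01, 0.74,  3.38, 0.27),
    c("HbA1c",             5.00, 0.39,  9.90, 1.70),
    c("body_mass",        33.80, 3.30, 38.80, 7.40))
  data.frame(outcome = d[, 1],
             control_mean = as.numeric(d[, 2]),
             control_sd = as.numeric(d[, 3]),
             diabetic_mean = as.numeric(d[, 4]),
             diabetic_sd = as.numeric(d[, 5]),
             stringsAsFactors = FALSE)
}

#' Default tissue-level (indentation and Raman) outcome table
#'
#' Control means chosen at realistic values for hydrated murine cortical
#' bone; diabetic effects follow the reported group contrasts: +22%
#' indentation modulus and hardness, +10% mineral:matrix, +0.41%
#' crystallinity, +19% pentosidine ratio, no difference in
#' carbonate:phosphate or collagen maturity.
#'
#' @return data.frame(outcome, control_mean, diabetic_mean)
#' @export
default_tissue_outcomes <- function() {
  data.frame(
    outcome = c("E_s_GPa", "H_GPa", "mineral_matrix", "carbonate_phosphate",
                "crystallinity", "collagen_maturity", "pen_ratio"),
    control_mean = c(24.0, 0.85, 0.70, 0.175, 0.0580, 1.65, 0.30),
    diabetic_mean = c(24.0 * 1.22, 0.85 * 1.22, 0.70 * 1.10,
                      0.175, 0.0580 * 1.0041, 1.65, 0.30 * 1.19),
    stringsAsFactors = FALSE)
}

#' Cohort simulation specification
#'
#' States the simulated world: group sizes (8 diabetic vs 5 control mice by
#' default, the post-exclusion study sizes), per-outcome genotype means and
#' SDs, strain-specific body-mass/outcome slopes, weekly glucose
#' trajectories over the 16-week observation period, and the variance
#' components (as coefficients of variation) of the
#' mouse/quadrant/region/replicate sampling hierarchy for tissue-level
#' measures.
#'
#' @param n_per_group named integer vector c(control, diabetic)
#' @param outcomes per-mouse outcome table (see [default_outcomes()])
#' @param tissue_outcomes tissue outcome table
#'   (see [default_tissue_outcomes()])
#' @param mass_outcome_slopes named list strain -> named numeric of slopes
#'   (outcome units per gram); defaults encode the strong body-mass
#'   relationships of the minimum moment of inertia and post-yield
#'   displacement
#' @param glucose_trajectory_params list per strain: baseline (mg/dL),
#'   drift (mg/dL per week), between_sd, within_sd
#' @param hierarchy_cv coefficients of variation c(mouse, quadrant, region,
#'   residual) for tissue-level outcomes
#' @param region_modulus_factor multiplicative endosteal deficit applied to
#'   modulus and hardness (default 0.82, i.e. endosteal tissue ~18-20%
#'   softer)
#' @param n_weeks weeks of glucose follow-up (default 16)
#' @param points_per_region indents/spectra per cortex region (default 3)
#' @param seed integer seed
#' @return object of class `cohort_spec`
#' @export
cohort_spec <- function(n_per_group = c("C57Bl/6J" = 5, "TallyHO" = 8),
                        outcomes = default_outcomes(),
                        tissue_outcomes = default_tissue_outcomes(),
                        mass_outcome_slopes = list(
                          "C57Bl/6J" = c(I_min = 0.0014,
                                         post_yield_displacement = 0.0070),
                          "TallyHO" = c(I_min = 0.0010,
                                        post_yield_displacement = 0.0025)),
                        glucose_trajectory_params = list(
                          "C57Bl/6J" = list(baseline = 165, drift = 0,
                                            between_sd = 12, within_sd = 15),
                          "TallyHO" = list(baseline = 250, drift = 12.5,
                                           between_sd = 90, within_sd = 45)),
                        hierarchy_cv = c(mouse = 0.06, quadrant = 0.03,
                                         region = 0.04, residual = 0.05),
                        region_modulus_factor = 0.82,
                        n_weeks = 16, points_per_region = 3, seed = 1L) {
  if (any(n_per_group < 2)) stop_bonemech("n_per_group must be >= 2")
  if (any(outcomes$control_sd < 0) || any(outcomes$diabetic_sd < 0))
    stop_bonemech("outcome SDs must be >= 0")
  if (any(hierarchy_cv < 0)) stop_bonemech("variance components must be >= 0")
  structure(list(n_per_group = n_per_group, outcomes = outcomes,
                 tissue_outcomes = tissue_outcomes,
                 mass_outcome_slopes = mass_outcome_slopes,
                 glucose_trajectory_params = glucose_trajectory_params,
                 hierarchy_cv = hierarchy_cv,
                 region_modulus_factor = region_modulus_factor,
                 n_weeks = n_weeks, points_per_region = points_per_region,
                 seed = seed),
            class = "cohort_spec")
}

#' Generate a synthetic two-genotype cohort
#'
#' Per-mouse outcomes are drawn from genotype-specific normals with the
#' body-mass covariation partitioned out of the stated SD (so the marginal
#' SD matches the stated value); weekly glucose follows the per-strain
#' trajectory;
#' tissue-level records carry nested mouse/quadrant/region random effects
#' plus replicate noise. Deterministic in `(spec$seed)`.
#'
#' @param spec a [cohort_spec()]
#' @return object of class `cohort_table`: list(mice, glucose, tissue)
#' @export
gen_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(as.integer(spec$seed))

  strains <- names(spec$n_per_group)
  control <- strains[1]
  mice <- data.frame(
    mouse = sprintf("m%02d", seq_len(sum(spec$n_per_group))),
    genotype = rep(strains, spec$n_per_group),
    stringsAsFactors = FALSE)
  oc <- spec$outcomes
  get_par <- function(outc, strain, what) {
    i <- match(outc, oc$outcome)
    col <- if (strain == control) paste0("control_", what)
    else paste0("diabetic_", what)
    oc[[col]][i]
  }
  # body mass first (covariate for the sloped outcomes)
  mice$body_mass <- NA_real_
  for (s in strains) {
    i <- mice$genotype == s
    mice$body_mass[i] <- rnorm(sum(i), get_par("body_mass", s, "mean"),
                               get_par("body_mass", s, "sd"))
  }
  for (o in setdiff(oc$outcome, "body_mass")) {
    mice[[o]] <- NA_real_
    for (s in strains) {
      i <- mice$genotype == s
      mu <- get_par(o, s, "mean"); sdv <- get_par(o, s, "sd")
      b <- spec$mass_outcome_slopes[[s]][o]
      b <- if (is.null(b) || is.na(b)) 0 else unname(b)
      m_sd <- get_par("body_mass", s, "sd")
      resid_var <- sdv^2 - b^2 * m_sd^2
      if (resid_var < 0) { b <- sdv / m_sd; resid_var <- 0 }
      mm <- get_par("body_mass", s, "mean")
      mice[[o]][i] <- mu + b * (mice$body_mass[i] - mm) +
        rnorm(sum(i), 0, sqrt(resid_var))
    }
  }

  # weekly glucose trajectories
  gl <- list()
  for (r in seq_len(nrow(mice))) {
    p <- spec$glucose_trajectory_params[[mice$genotype[r]]]
    base <- rnorm(1, p$baseline, p$between_sd)
    wk <- seq_len(spec$n_weeks)
    gl[[r]] <- data.frame(
      mouse = mice$mouse[r], genotype = mice$genotype[r], week = wk,
      glucose = base + p$drift * (wk - 1) + rnorm(spec$n_weeks, 0, p$within_sd),
      stringsAsFactors = FALSE)
  }
  glucose <- do.call(rbind, gl)

  # nested tissue-level records (vectorized over the full hierarchy)
  toc <- spec$tissue_outcomes
  cv <- spec$hierarchy_cv
  quadrants <- c("AL", "PM")
  regions <- c("endosteal", "intracortical", "periosteal")
  grid <- expand.grid(point = seq_len(spec$points_per_region),
                      region = regions, quadrant = quadrants,
                      mouse_idx = seq_len(nrow(mice)),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$region <- as.character(grid$region)
  grid$quadrant <- as.character(grid$quadrant)
  n_rows <- nrow(grid)
  mouse_key <- grid$mouse_idx
  quad_key <- match(paste(grid$mouse_idx, grid$quadrant),
                    unique(paste(grid$mouse_idx, grid$quadrant)))
  reg_key <- match(paste(grid$mouse_idx, grid$quadrant, grid$region),
                   unique(paste(grid$mouse_idx, grid$quadrant, grid$region)))
  tissue <- data.frame(mouse = mice$mouse[mouse_key],
                       genotype = mice$genotype[mouse_key],
                       quadrant = grid$quadrant, region = grid$region,
                       microstructure = ifelse(runif(n_rows) < 0.7,
                                               "lamellar", "non_lamellar"),
                       point = grid$point, stringsAsFactors = FALSE)
  is_diab <- tissue$genotype != control
  for (j in seq_len(nrow(toc))) {
    mu <- ifelse(is_diab, toc$diabetic_mean[j], toc$control_mean[j])
    u_m <- rnorm(max(mouse_key), 0, cv["mouse"])[mouse_key]
    u_q <- rnorm(max(quad_key), 0, cv["quadrant"])[quad_key]
    u_r <- rnorm(max(reg_key), 0, cv["region"])[reg_key]
    eps <- rnorm(n_rows, 0, cv["residual"])
    vals <- mu * (1 + u_m + u_q + u_r + eps)
    if (toc$outcome[j] %in% c("E_s_GPa", "H_GPa"))
      vals <- vals * ifelse(tissue$region == "endosteal",
                            spec$region_modulus_factor, 1)
    tissue[[toc$outcome[j]]] <- vals
  }
  structure(list(mice = mice, glucose = glucose, tissue = tissue,
                 spec = spec, control = control,
                 diabetic = setdiff(strains, control)),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table> %d mice (%s), %d glucose records, %d tissue records\n",
              nrow(x$mice),
              paste(sprintf("%s n=%d", names(table(x$mice$genotype)),
                            table(x$mice$genotype)), collapse = ", "),
              nrow(x$glucose), nrow(x$tissue)))
  invisible(x)
}
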