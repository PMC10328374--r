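#' Pipeline configuration
#'
#' Assembles (and validates) every knob of the end-to-end pipeline into one
#' structure that can round-trip through a JSON config file. Unknown keys
#' are rejected.
#'
#' @param seed master seed for simulation
#' @param n_per_group named group sizes (default 5 control / 8 diabetic)
#' @param n_slices axial slices per simulated cross-section
#' @param voxel_size mm (default 0.006)
#' @param points_per_region indents/spectra per cortex region
#' @param bending list(span_mm, preload_N, yield_secant_fraction,
#'   failure_drop_fraction)
#' @param indenter list(epsilon, beta, E_indenter, nu_indenter, nu_sample,
#'   max_load_uN, load_rate_uN_s, hold_s)
#' @param raman list(rcf_radius, rcf_iterations, step)
#' @param stats list(diabetic_glucose_threshold)
#' @param log_level one of "quiet", "info"
#' @return object of class `pipeline_config`
#' @export
pipeline_config <- function(seed = 1L,
                            n_per_group = c("C57Bl/6J" = 5, "TallyHO" = 8),
                            n_slices = 4L,
                            voxel_size = 0.006,
                            points_per_region = 3L,
                            bending = list(span_mm = 7, preload_N = 2,
                                           yield_secant_fraction = 0.10,
                                           failure_drop_fraction = 0.10),
                            indenter = list(epsilon = 0.75, beta = 1.0,
                                            E_indenter = 1141,
                                            nu_indenter = 0.07,
                                            nu_sample = 0.3,
                                            max_load_uN = 1000,
                                            load_rate_uN_s = 100,
                                            hold_s = 30),
                            raman = list(rcf_radius = 450,
                                         rcf_iterations = 3, step = 1),
                            stats = list(diabetic_glucose_threshold = 250),
                            log_level = "info") {
  cfg <- list(seed = as.integer(seed), n_per_group = n_per_group,
              n_slices = as.integer(n_slices), voxel_size = voxel_size,
              points_per_region = as.integer(points_per_region),
              bending = bending, indenter = indenter, raman = raman,
              stats = stats, log_level = log_level)
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  known <- c("seed", "n_per_group", "n_slices", "voxel_size",
             "points_per_region", "bending", "indenter", "raman", "stats",
             "log_level")
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    stop_bonemech("unknown config field(s): ", paste(extra, collapse = ", "))
  miss <- setdiff(known, names(cfg))
  if (length(miss))
    stop_bonemech("missing config field(s): ", paste(miss, collapse = ", "))
  if (cfg$voxel_size <= 0) stop_bonemech("config field voxel_size must be > 0")
  if (length(cfg$n_per_group) != 2)
    stop_bonemech("config field n_per_group must name two genotypes")
  invisible(TRUE)
}

#' Read / write a pipeline configuration as JSON
#'
#' @param path JSON file path
#' @return `read_config` returns a `pipeline_config`
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$n_per_group)) raw$n_per_group <- unlist(raw$n_per_group)
  cfg <- modifyList(unclass(pipeline_config()), raw)
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

#' @rdname read_config
#' @param config a `pipeline_config`
#' @export
write_config <- function(config, path) {
  out <- unclass(config)
  out$n_per_group <- as.list(out$n_per_group)   # keep genotype names in JSON
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Provenance hash of a configuration
#'
#' Deterministic 64-bit hash of the canonical JSON serialization; changes
#' iff the configuration changes.
#'
#' @param config a `pipeline_config`
#' @return hex string
#' @export
config_hash <- function(config) {
  fnv1a64(jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA))
}

log_msg <- function(cfg, ...) {
  if (identical(cfg$log_level, "info")) message("[bonemech] ", ...)
}

# geometry truths per genotype: ellipse semi-axes reproducing the group
# mean total/marrow areas, pore fraction from the porosity means
genotype_geometry <- function(genotype, voxel_size) {
  if (genotype == "C57Bl/6J")
    geometry_truth(outer_semi_axes = c(0.95, 0.690),
                   inner_semi_axes = c(0.72, 0.530),
                   pore_fraction = 0.0024, voxel_size = voxel_size)
  else
    geometry_truth(outer_semi_axes = c(0.80, 0.589),
                   inner_semi_axes = c(0.54, 0.366),
                   pore_fraction = 0.0143, voxel_size = voxel_size)
}

#' Simulate a full synthetic study directory
#'
#' Generates the cohort table plus per-modality raw files (voxel-grid CSVs,
#' bending CSVs, indentation CSVs, Raman two-column spectra) with
#' `.truth.json` sidecars, under one directory.
#'
#' @param config a [pipeline_config()]
#' @param outdir output directory (created)
#' @return invisible list of written paths by modality
#' @export
run_simulate <- function(config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("cohort", "geometry", "bending", "indent", "raman"))
    dir.create(file.path(outdir, d), showWarnings = FALSE)
  hash <- config_hash(config)
  spec <- cohort_spec(n_per_group = config$n_per_group,
                      points_per_region = config$points_per_region,
                      seed = config$seed)
  cohort <- gen_cohort(spec)
  mice <- cohort$mice
  write.csv(mice, file.path(outdir, "cohort", "mice.csv"), row.names = FALSE)
  write.csv(cohort$glucose, file.path(outdir, "cohort", "glucose.csv"),
            row.names = FALSE)
  write.csv(cohort$tissue, file.path(outdir, "cohort", "tissue_truth.csv"),
            row.names = FALSE)

  written <- list(cohort = file.path(outdir, "cohort",
                                     c("mice.csv", "glucose.csv",
                                       "tissue_truth.csv")))
  ic <- indenter_constants(config$indenter$epsilon, config$indenter$beta,
                           config$indenter$E_indenter,
                           config$indenter$nu_indenter,
                           config$indenter$nu_sample)
  for (r in seq_len(nrow(mice))) {
    m <- mice$mouse[r]
    seed_m <- config$seed * 1000L + r
    # geometry
    gt <- genotype_geometry(mice$genotype[r], config$voxel_size)
    cs <- gen_cross_section(gt, seed = seed_m, n_slices = config$n_slices)
    gp <- file.path(outdir, "geometry", paste0(m, ".csv"))
    write_voxel_csv(cs$grid, gp)
    write_truth_sidecar(cs$truth, gp)
    written$geometry <- c(written$geometry, gp)
    # bending
    bt <- bending_truth(stiffness = max(20, mice$stiffness[r]),
                        yield_force = 15, ultimate_force = 18,
                        post_yield_displacement =
                          max(0.01, mice$post_yield_displacement[r]),
                        span = config$bending$span_mm, noise_sd = 0.05)
    bc <- gen_bending_curve(bt, seed = seed_m)
    bp <- file.path(outdir, "bending", paste0(m, ".csv"))
    write_bending_csv(bc$curve, bp)
    write_truth_sidecar(bc$truth, bp)
    written$bending <- c(written$bending, bp)
  }
  # tissue-level raw records (one indent curve + one spectrum per row)
  tis <- cohort$tissue
  manifest <- tis[c("mouse", "genotype", "quadrant", "region",
                    "microstructure", "point")]
  manifest$indent_file <- sprintf("%s_%s_%s_p%d.csv", tis$mouse,
                                  tis$quadrant, tis$region, tis$point)
  manifest$spectrum_file <- sprintf("%s_%s_%s_p%d.txt", tis$mouse,
                                    tis$quadrant, tis$region, tis$point)
  for (r in seq_len(nrow(tis))) {
    seed_r <- config$seed * 100000L + r
    E_s <- tis$E_s_GPa[r]
    E_r <- 1 / ((1 - ic$nu_sample^2) / E_s +
                  (1 - ic$nu_indenter^2) / ic$E_indenter)
    it <- indentation_truth(reduced_modulus = E_r, hardness = tis$H_GPa[r],
                            max_load = config$indenter$max_load_uN,
                            load_rate = config$indenter$load_rate_uN_s,
                            hold_time = config$indenter$hold_s,
                            noise_sd = 2)
    icv <- gen_indentation_curve(it, seed = seed_r, constants = ic)
    ip <- file.path(outdir, "indent", manifest$indent_file[r])
    write_indent_csv(icv$curve, ip)
    write_truth_sidecar(icv$truth, ip)
    # spectrum whose analytic metrics match the tissue row
    st <- tissue_row_spectrum_truth(tis[r, ])
    sp_path <- file.path(outdir, "raman", manifest$spectrum_file[r])
    sp <- gen_raman_spectrum(st, step = config$raman$step, seed = seed_r)
    write_spectrum_txt(sp$spectrum, sp_path)
    write_truth_sidecar(st, sp_path)
    written$indent <- c(written$indent, ip)
    written$raman <- c(written$raman, sp_path)
  }
  write.csv(manifest, file.path(outdir, "cohort", "manifest.csv"),
            row.names = FALSE)
  jsonlite::write_json(list(config = unclass(config), config_hash = hash),
                       file.path(outdir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_msg(config, "simulated study in ", outdir, " (config ", hash, ")")
  invisible(written)
}

# bend the default band set so its analytic metrics hit a tissue row's
# mineral_matrix / crystallinity / collagen_maturity / carbonate_phosphate
tissue_row_spectrum_truth <- function(row) {
  b <- default_bands()
  ref <- analytic_metrics(b)$metrics
  # scale the nu2 PO4 band for mineral:matrix, nu1 CO3 for carb:phos,
  # the 1690 band for collagen maturity, 1495 for PEN; width of nu1 PO4
  # for crystallinity
  b$height[b$center == 430] <- b$height[b$center == 430] *
    row$mineral_matrix / ref["mineral_matrix"]
  b$height[b$center == 1070] <- b$height[b$center == 1070] *
    row$carbonate_phosphate / ref["carbonate_phosphate"]
  b$sigma[b$center == 960] <- b$sigma[b$center == 960] *
    ref["crystallinity"] / row$crystallinity
  b$height[b$center == 1690] <- b$height[b$center == 1690] *
    ref["collagen_maturity"] / row$collagen_maturity
  b$height[b$center == 1495] <- b$height[b$center == 1495] *
    row$pen_ratio / ref["pen_ratio"]
  spectrum_truth(bands = b, noise_sd = 1)
}

#' Run one pipeline stage
#'
#' Stages: `geometry` (voxel grids -> morphometry CSV), `bending` (curves ->
#' flexural CSV), `indent` (indent curves -> per-indent moduli CSV), `raman`
#' (spectra -> metrics CSV), `stats` (merged outputs -> study report).
#' Idempotent: rerunning without input changes rewrites identical outputs.
#'
#' @param stage stage name
#' @param config a [pipeline_config()]
#' @param outdir study directory produced by [run_simulate()] (or populated
#'   with instrument exports in the same layout)
#' @return path of the stage output, invisibly
#' @export
run_stage <- function(stage, config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- c("geometry", "bending", "indent", "raman", "stats")
  if (!stage %in% stages)
    stop_bonemech("unknown stage '", stage, "'; expected one of: ",
                  paste(stages, collapse = ", "))
  fn <- switch(stage, geometry = stage_geometry, bending = stage_bending,
               indent = stage_indent, raman = stage_raman,
               stats = stage_stats)
  out <- fn(config, outdir)
  log_msg(config, "stage ", stage, " -> ", out)
  invisible(out)
}

require_inputs <- function(paths, what) {
  bad <- paths[!file.exists(paths)]
  if (length(bad))
    stop_bonemech("missing ", what, " input(s): ",
                  paste(bad, collapse = ", "),
                  " -- run the simulate stage or provide instrument exports")
  paths
}

stage_geometry <- function(config, outdir) {
  files <- sort(Sys.glob(file.path(outdir, "geometry", "*.csv")))
  if (!length(files)) require_inputs(file.path(outdir, "geometry", "*.csv"),
                                     "voxel grid")
  rows <- lapply(files, function(f) {
    g <- read_voxel_csv(f)
    mask <- segment_bone(g, sigma = 0.8)
    labs <- label_compartments(mask)
    cm <- cortical_morphometry(labs, g$voxel_size, g$calibration, g$values)
    cm$per_slice <- NULL
    data.frame(mouse = sub("\\.csv$", "", basename(f)),
               as.data.frame(cm), check.names = FALSE,
               stringsAsFactors = FALSE)
  })
  out <- file.path(outdir, "morphometry.csv")
  write.csv(do.call(rbind, rows), out, row.names = FALSE)
  out
}

stage_bending <- function(config, outdir) {
  files <- sort(Sys.glob(file.path(outdir, "bending", "*.csv")))
  if (!length(files)) require_inputs(file.path(outdir, "bending", "*.csv"),
                                     "bending curve")
  bc <- bending_config(config$bending$span_mm, 0,
                       config$bending$yield_secant_fraction,
                       config$bending$failure_drop_fraction)
  morph <- file.path(outdir, "morphometry.csv")
  imin <- NULL
  if (file.exists(morph)) {
    md <- read.csv(morph, check.names = FALSE)
    imin <- setNames(md$I_min, md$mouse)
  }
  rows <- lapply(files, function(f) {
    m <- sub("\\.csv$", "", basename(f))
    cv <- read_bending_csv(f)
    fp <- extract_flexural(cv, bc, I_min = unname(imin[m]))
    data.frame(mouse = m, as.data.frame(fp[names(fp) != "irregular"]),
               irregular = fp$irregular, stringsAsFactors = FALSE)
  })
  out <- file.path(outdir, "flexural.csv")
  write.csv(do.call(rbind, rows), out, row.names = FALSE)
  out
}

stage_indent <- function(config, outdir) {
  man_path <- require_inputs(file.path(outdir, "cohort", "manifest.csv"),
                             "manifest")
  man <- read.csv(man_path, stringsAsFactors = FALSE)
  ic <- indenter_constants(config$indenter$epsilon, config$indenter$beta,
                           config$indenter$E_indenter,
                           config$indenter$nu_indenter,
                           config$indenter$nu_sample)
  rows <- lapply(seq_len(nrow(man)), function(r) {
    f <- file.path(outdir, "indent", man$indent_file[r])
    require_inputs(f, "indent curve")
    cv <- read_indent_csv(f)
    res <- analyze_indent(cv, constants = ic,
                          load_rate = config$indenter$load_rate_uN_s)
    data.frame(man[r, c("mouse", "genotype", "quadrant", "region",
                        "microstructure", "point")],
               E_r_GPa = res$E_r, E_s_GPa = res$E_s, H_GPa = res$H,
               stringsAsFactors = FALSE)
  })
  out <- file.path(outdir, "indent_results.csv")
  write.csv(do.call(rbind, rows), out, row.names = FALSE)
  out
}

stage_raman <- function(config, outdir) {
  man_path <- require_inputs(file.path(outdir, "cohort", "manifest.csv"),
                             "manifest")
  man <- read.csv(man_path, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(man)), function(r) {
    f <- file.path(outdir, "raman", man$spectrum_file[r])
    require_inputs(f, "spectrum")
    sp <- read_spectrum_txt(f)
    sp <- truncate_spectrum(sp, 280, 2000)
    corr <- rcf_baseline(sp, config$raman$rcf_radius,
                         config$raman$rcf_iterations)$corrected
    mt <- compute_metrics(corr)
    data.frame(man[r, c("mouse", "genotype", "quadrant", "region",
                        "microstructure", "point")],
               as.data.frame(mt[c("mineral_matrix", "carbonate_phosphate",
                                  "crystallinity", "collagen_maturity",
                                  "pen_ratio", "pen_snr_flag")]),
               stringsAsFactors = FALSE)
  })
  out <- file.path(outdir, "raman_metrics.csv")
  write.csv(do.call(rbind, rows), out, row.names = FALSE)
  out
}

stage_stats <- function(config, outdir) {
  mice <- read.csv(require_inputs(file.path(outdir, "cohort", "mice.csv"),
                                  "cohort"), check.names = FALSE,
                   stringsAsFactors = FALSE)
  glucose <- read.csv(file.path(outdir, "cohort", "glucose.csv"),
                      stringsAsFactors = FALSE)
  control <- "C57Bl/6J"
  if (!control %in% mice$genotype) control <- sort(unique(mice$genotype))[1]
  # inclusion rule on the study-end window (the repeated glucose checks at
  # euthanasia, final three weeks), then lifetime-average glucose
  late <- glucose[glucose$week > max(glucose$week) - 3, ]
  mice <- diabetic_inclusion_filter(
    mice, late, config$stats$diabetic_glucose_threshold,
    diabetic_strain = setdiff(unique(mice$genotype), control))
  mice$lifetime_glucose <- vapply(mice$mouse, function(m)
    lifetime_average_glucose(glucose$glucose[glucose$mouse == m])$mean, 0)

  # measured morphometry/flexural replace the cohort truth columns when the
  # corresponding stages have run
  morph <- file.path(outdir, "morphometry.csv")
  if (file.exists(morph)) {
    md <- read.csv(morph, check.names = FALSE, stringsAsFactors = FALSE)
    keep <- intersect(names(md), c("Tt.Ar", "Ct.Ar", "Ma.Ar", "Ct.Th",
                                   "I_min", "I_max", "c", "Ct.Po", "Ct.TMD"))
    for (k in keep) mice[[k]] <- md[[k]][match(mice$mouse, md$mouse)]
  }
  flex <- file.path(outdir, "flexural.csv")
  if (file.exists(flex)) {
    fd <- read.csv(flex, stringsAsFactors = FALSE)
    for (k in c("stiffness", "max_moment", "post_yield_displacement",
                "work_to_fracture"))
      mice[[k]] <- fd[[k]][match(mice$mouse, fd$mouse)]
  }

  whole_bone <- intersect(
    c("Tt.Ar", "Ma.Ar", "Ct.Ar", "Ct.Th", "I_min", "I_max", "c", "Ct.Po",
      "Ct.TMD", "max_moment", "stiffness", "post_yield_displacement",
      "work_to_fracture"), names(mice))
  adjusted <- mice
  can_adjust <- all(table(mice$genotype) >= 3L)
  if (!can_adjust)
    log_msg(config, "fewer than 3 mice per strain: ",
            "reporting unadjusted outcomes")
  for (o in whole_bone) {
    ok <- !is.na(mice[[o]])
    if (!can_adjust || sum(ok) < nrow(mice)) next
    adjusted[[o]] <- mass_adjust(mice[[o]], mice$body_mass, mice$genotype)
  }
  trab <- intersect(c("BV_TV", "Tb.Sp", "Tb.Th", "Tb.N", "Conn.D", "SMI",
                      "Tb.TMD"), names(mice))
  tab2 <- group_comparison(adjusted, c(whole_bone, trab), "genotype",
                           control)

  # tissue-level mixed models
  ind_path <- file.path(outdir, "indent_results.csv")
  ram_path <- file.path(outdir, "raman_metrics.csv")
  tissue <- if (file.exists(ind_path)) read.csv(ind_path,
                                                stringsAsFactors = FALSE)
  else read.csv(file.path(outdir, "cohort", "tissue_truth.csv"),
                stringsAsFactors = FALSE)
  if (file.exists(ram_path)) {
    rm_ <- read.csv(ram_path, stringsAsFactors = FALSE)
    key <- c("mouse", "quadrant", "region", "point")
    tissue <- merge(tissue, rm_[c(key, "mineral_matrix",
                                  "carbonate_phosphate", "crystallinity",
                                  "collagen_maturity", "pen_ratio")],
                    by = key)
  }
  tissue <- tissue[tissue$mouse %in% mice$mouse, ]
  lmm_out <- list()
  for (o in intersect(c("E_s_GPa", "H_GPa", "mineral_matrix",
                        "carbonate_phosphate", "crystallinity",
                        "collagen_maturity", "pen_ratio"), names(tissue))) {
    fit <- tryCatch(fit_lmm(tissue, o,
                            fixed = c("genotype", "quadrant", "region",
                                      "microstructure")),
                    error = function(e) NULL)
    if (is.null(fit)) next
    lmm_out[[o]] <- list(fixed = fit$fixed, varcomp = fit$varcomp,
                         singular = fit$singular,
                         qq_correlation = fit$qq_correlation,
                         levene_p = fit$levene_p,
                         tukey_genotype = tukey_hsd(fit, "genotype"),
                         tukey_region = tukey_hsd(fit, "region"))
  }

  # glucose-metric regressions (Table-4-like)
  per_mouse <- stats::aggregate(
    tissue[setdiff(names(tissue),
                   c("mouse", "genotype", "quadrant", "region",
                     "microstructure", "point", "pen_snr_flag"))],
    by = list(mouse = tissue$mouse), FUN = mean)
  mg <- merge(mice, per_mouse, by = "mouse")
  cor_rows <- list()
  for (o in intersect(c("max_moment", "stiffness",
                        "post_yield_displacement", "work_to_fracture",
                        "E_s_GPa", "H_GPa", "mineral_matrix",
                        "carbonate_phosphate", "crystallinity",
                        "collagen_maturity"), names(mg))) {
    for (pred in c("lifetime_glucose", "HbA1c")) {
      lr <- tryCatch(linreg(mg[[pred]], mg[[o]]), error = function(e) NULL)
      if (is.null(lr)) next
      cor_rows[[length(cor_rows) + 1]] <-
        data.frame(outcome = o, predictor = pred, r = lr$r, R2 = lr$R2,
                   p = lr$p, stringsAsFactors = FALSE)
    }
  }
  report <- list(
    provenance = list(config_hash = config_hash(config),
                      seed = config$seed,
                      package_version =
                        as.character(utils::packageVersion("bonemech")),
                      n_mice = nrow(mice)),
    group_comparison = tab2,
    mixed_models = lmm_out,
    glucose_correlations = do.call(rbind, cor_rows))
  out <- file.path(outdir, "report.json")
  jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  write.csv(tab2, file.path(outdir, "group_comparison.csv"),
            row.names = FALSE)
  out
}

#' Run the full pipeline
#'
#' Simulate (unless the directory already holds raw data), run every stage,
#' and write the study report.
#'
#' @param config a [pipeline_config()]
#' @param outdir study directory
#' @param simulate force (re)simulation (default: simulate when no cohort
#'   is present)
#' @return report path, invisibly
#' @export
run_full <- function(config, outdir, simulate = NA) {
  have <- file.exists(file.path(outdir, "cohort", "mice.csv"))
  if (is.na(simulate)) simulate <- !have
  if (simulate) run_simulate(config, outdir)
  for (s in c("geometry", "bending", "indent", "raman", "stats"))
    run_stage(s, config, outdir)
  invisible(file.path(outdir, "report.json"))
}
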