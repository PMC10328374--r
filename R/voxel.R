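#' Construct a voxel grid
#'
#' A 3-D scalar field with an isotropic voxel size and an optional affine
#' mineral-density calibration mapping grayscale to mg HA/cm^3.
#'
#' @param values 3-D numeric array (a matrix is promoted to a single slice)
#' @param voxel_size isotropic voxel edge length in mm
#' @param calibration optional `c(intercept, slope)`: density = intercept +
#'   slope * grayscale, in mg HA/cm^3
#' @return object of class `voxel_grid`
#' @export
voxel_grid <- function(values, voxel_size, calibration = NULL) {
  if (is.matrix(values)) dim(values) <- c(dim(values), 1L)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop_bonemech("values must be a 3-D array")
  if (length(values) == 0L) stop_bonemech("grid is empty")
  if (!is.numeric(voxel_size) || voxel_size <= 0)
    stop_bonemech("voxel_size must be positive")
  if (!is.null(calibration) && length(calibration) != 2L)
    stop_bonemech("calibration must be c(intercept, slope)")
  structure(list(values = values, voxel_size = voxel_size,
                 calibration = calibration),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<voxel_grid> %d x %d x %d voxels, %.1f um isotropic%s\n",
              d[1], d[2], d[3], x$voxel_size * 1000,
              if (is.null(x$calibration)) "" else ", density-calibrated"))
  invisible(x)
}

#' Write / read a voxel grid as plain-text CSV
#'
#' Slices are stacked row-wise; a header line carries the dimensions, voxel
#' size and calibration so the grid round-trips exactly.
#'
#' @param grid a `voxel_grid`
#' @param path output file
#' @return `read_voxel_csv` returns a `voxel_grid`
#' @export
write_voxel_csv <- function(grid, path) {
  d <- dim(grid$values)
  cal <- grid$calibration %||% c(NA_real_, NA_real_)
  hdr <- sprintf("# voxel_grid nx=%d ny=%d nz=%d voxel_size=%.17g cal0=%.17g cal1=%.17g",
                 d[1], d[2], d[3], grid$voxel_size, cal[1], cal[2])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  m <- matrix(grid$values, nrow = d[1])
  write.table(m, con, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_voxel_csv
#' @param path input file
#' @export
read_voxel_csv <- function(path) {
  hdr <- readLines(path, n = 1L)
  kv <- regmatches(hdr, gregexpr("[a-z_0-9]+=[-+0-9.eginfaNA]+", hdr))[[1]]
  vals <- setNames(as.numeric(sub(".*=", "", kv)), sub("=.*", "", kv))
  m <- as.matrix(read.csv(path, header = FALSE, skip = 1L))
  arr <- array(as.numeric(m), dim = c(vals["nx"], vals["ny"], vals["nz"]))
  cal <- if (is.na(vals["cal0"])) NULL else unname(c(vals["cal0"], vals["cal1"]))
  voxel_grid(arr, unname(vals["voxel_size"]), cal)
}

#' Generate a voxelized cortical cross-section with known geometry
#'
#' Renders the elliptical annulus described by a [geometry_truth()] on an
#' isotropic voxel grid, carves non-overlapping spherical pores fully inside
#' the cortex until the requested pore fraction is met, and returns the grid
#' together with per-voxel ground-truth labels.
#'
#' @param truth a [geometry_truth()]
#' @param seed integer seed; the generator is a pure function of
#'   `(truth, seed)`
#' @param n_slices number of axial slices (default 6)
#' @param bone_value,background_value grayscale levels for bone and
#'   non-bone voxels
#' @param density mean calibrated tissue mineral density assigned to bone
#'   voxels (mg HA/cm^3); stored via the grid calibration
#' @param noise_sd grayscale noise SD added to every voxel
#' @return list with `grid` (a `voxel_grid`), `labels` (integer array, 0 =
#'   background, 1 = bone, 2 = marrow, 3 = pore) and `truth`
#' @export
gen_cross_section <- function(truth, seed = 1L, n_slices = 6L,
                              bone_value = 1, background_value = 0,
                              density = 1200, noise_sd = 0) {
  stopifnot(inherits(truth, "geometry_truth"))
  vs <- truth$voxel_size
  a <- truth$outer_semi_axes[1]; b <- truth$outer_semi_axes[2]
  ai <- truth$inner_semi_axes[1]; bi <- truth$inner_semi_axes[2]
  thick <- min(a - ai, b - bi)
  if (thick / vs < 3)
    stop_bonemech("voxel size too coarse to resolve cortex ",
                  "(< 3 voxels across thickness)")
  margin <- 4 * vs
  nx <- as.integer(ceiling(2 * (a + margin) / vs))
  ny <- as.integer(ceiling(2 * (b + margin) / vs))
  cx <- nx * vs / 2; cy <- ny * vs / 2
  xs <- (seq_len(nx) - 0.5) * vs - cx
  ys <- (seq_len(ny) - 0.5) * vs - cy
  X <- matrix(xs, nx, ny)
  Y <- matrix(ys, nx, ny, byrow = TRUE)
  r_out <- (X / a)^2 + (Y / b)^2
  r_in <- (X / ai)^2 + (Y / bi)^2
  slice_lab <- matrix(0L, nx, ny)
  slice_lab[r_out <= 1] <- 1L         # bone (annulus for now)
  slice_lab[r_in <= 1] <- 2L          # marrow

  labels <- array(rep(slice_lab, n_slices), dim = c(nx, ny, n_slices))

  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))

  if (truth$pore_fraction > 0)
    labels <- carve_pores(labels, slice_lab, truth, xs, ys, vs, n_slices)

  values <- array(background_value, dim = dim(labels))
  values[labels == 1L] <- bone_value
  if (noise_sd > 0) values <- values + rnorm(length(values), 0, noise_sd)
  # affine calibration mapping background_value -> 0, bone_value -> density
  slope <- density / (bone_value - background_value)
  cal <- c(-background_value * slope, slope)
  list(grid = voxel_grid(values, vs, calibration = cal),
       labels = labels, truth = truth)
}

# place non-overlapping spheres fully inside the cortex until the pore
# fraction pore/(pore+bone) reaches the target (within half a percent,
# relative); pore radii default to the 12-30 um scale seen in murine cortex
carve_pores <- function(labels, slice_lab, truth, xs, ys, vs, n_slices) {
  target <- truth$pore_fraction
  cortex_n <- sum(slice_lab == 1L) * n_slices
  target_n <- target * cortex_n           # pore voxels wanted
  a <- truth$outer_semi_axes[1]; b <- truth$outer_semi_axes[2]
  ai <- truth$inner_semi_axes[1]; bi <- truth$inner_semi_axes[2]
  nz <- n_slices
  placed <- matrix(numeric(0), ncol = 4)  # x, y, z, r
  n_pore <- 0
  r_lo <- max(2 * vs, 0.012); r_hi <- max(r_lo, 0.030)
  guard <- 0
  while (n_pore < target_n && guard < 20000) {
    guard <- guard + 1
    deficit <- target_n - n_pore
    r <- runif(1, r_lo, r_hi)
    # when close to target, pick the radius that fills the deficit
    r_fit <- (3 * deficit * vs^3 / (4 * pi))^(1 / 3)
    if (r_fit < r_hi) r <- max(r_lo, r_fit)
    # sample a center with the whole sphere inside the annulus and the slab
    th <- runif(1, 0, 2 * pi)
    u <- runif(1)
    px <- cos(th); py <- sin(th)
    # radial scaling: between inner and outer ellipse with sphere margin
    s_out <- 1 / sqrt((px / (a - r))^2 + (py / (b - r))^2)
    s_in <- 1 / sqrt((px / (ai + r))^2 + (py / (bi + r))^2)
    if (s_out <= s_in) next
    s <- s_in + u * (s_out - s_in)
    cx <- px * s; cy <- py * s
    cz <- if (nz * vs >= 2 * r) runif(1, r, nz * vs - r)
    else nz * vs / 2                 # thin slab: allow truncation in z
    if (nrow(placed) > 0) {
      dd <- sqrt((placed[, 1] - cx)^2 + (placed[, 2] - cy)^2 +
                   (placed[, 3] - cz)^2)
      if (any(dd < placed[, 4] + r)) next
    }
    ix <- which(abs(xs - cx) <= r)
    iy <- which(abs(ys - cy) <= r)
    if (!length(ix) || !length(iy)) next
    added <- 0L
    for (k in seq_len(nz)) {
      zk <- (k - 0.5) * vs
      dz2 <- (zk - cz)^2
      if (dz2 > r^2) next
      rr <- sqrt(r^2 - dz2)
      for (j in iy) {
        dy2 <- (ys[j] - cy)^2
        if (dy2 > rr^2) next
        for (i in ix) {
          if ((xs[i] - cx)^2 + dy2 <= rr^2 && labels[i, j, k] == 1L) {
            labels[i, j, k] <- 3L
            added <- added + 1L
          }
        }
      }
    }
    if (added > 0L) {
      placed <- rbind(placed, c(cx, cy, cz, r))
      n_pore <- n_pore + added
    }
  }
  labels
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}
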