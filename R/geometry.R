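#' Segment mineralized tissue from a voxel grid
#'
#' Gaussian smoothing (separable, sigma in voxels) followed by a global
#' threshold, the standard noise-robust segmentation for micro-CT cortical
#' analysis.
#'
#' @param grid a [voxel_grid()]
#' @param sigma Gaussian SD in voxels (0 disables smoothing)
#' @param threshold grayscale threshold; voxels with smoothed value >=
#'   threshold are bone
#' @return logical array of the same dimensions (TRUE = mineralized)
#' @export
segment_bone <- function(grid, sigma = 0.8, threshold) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (sigma < 0) stop_bonemech("sigma must be >= 0")
  v <- grid$values
  if (missing(threshold))
    threshold <- (max(v) + min(v)) / 2
  if (sigma > 0) v <- gaussian_smooth3(v, sigma)
  mask <- v >= threshold
  if (!any(mask)) stop_bonemech("no mineralized tissue")
  mask
}

# separable Gaussian smoothing with reflected boundaries
gaussian_smooth3 <- function(arr, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  d <- dim(arr)
  conv_axis <- function(a, axis) {
    perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 2, 1))
    b <- aperm(a, perm)
    db <- dim(b)
    m <- matrix(b, nrow = db[1])
    n <- nrow(m)
    idx <- seq_len(n)
    out <- matrix(0, n, ncol(m))
    for (o in -r:r) {
      src <- idx + o
      src[src < 1] <- 1 - (src[src < 1] - 1)       # reflect
      src[src > n] <- 2 * n - src[src > n] + 1
      src <- pmin(pmax(src, 1L), n)                # clamp tiny axes
      out <- out + k[o + r + 1] * m[src, , drop = FALSE]
    }
    array(out, dim = db) |> aperm(order(perm))
  }
  for (ax in 1:3) if (d[ax] > 1) arr <- conv_axis(arr, ax)
  arr
}

#' Label bone, marrow, pore and background compartments
#'
#' Background = non-bone components touching the grid boundary; marrow = the
#' largest enclosed non-bone cavity; pores = all other enclosed non-bone
#' components. Connectivity is 6-connected.
#'
#' @param mask logical array from [segment_bone()]
#' @return integer array: 0 background, 1 bone, 2 marrow, 3 pore
#' @export
label_compartments <- function(mask) {
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1)))
  if (is.matrix(mask)) dim(mask) <- c(dim(mask), 1L)
  d <- dim(mask)
  lab_bg <- array(.label6(as.logical(!mask), as.integer(d)), dim = d)
  out <- array(0L, dim = d)
  out[mask] <- 1L
  ncomp <- max(lab_bg)
  if (ncomp > 0) {
    # components touching a lateral (x/y) face are exterior background; the
    # z faces are section cuts through the shaft, so the marrow column that
    # reaches them is still an enclosed cavity
    faces <- unique(c(
      lab_bg[1, , ], lab_bg[d[1], , ],
      lab_bg[, 1, ], lab_bg[, d[2], ]))
    faces <- faces[faces > 0]
    enclosed <- setdiff(seq_len(ncomp), faces)
    if (length(enclosed) == 0L) {
      warning("no enclosed cavity: marrow area is 0")
    } else {
      sizes <- tabulate(lab_bg[lab_bg > 0L], nbins = ncomp)
      marrow <- enclosed[which.max(sizes[enclosed])]
      out[lab_bg == marrow] <- 2L
      pores <- setdiff(enclosed, marrow)
      if (length(pores)) out[array(lab_bg %in% pores, dim = d)] <- 3L
    }
  }
  out
}

# per-slice area centroid + second moments of area about the centroid,
# slice-averaged; returns I_min, I_max (mm^4), principal angle (rad) and the
# principal directions
section_moments <- function(labels, voxel_size) {
  d <- dim(labels)
  va <- voxel_size^2
  Ixx <- Iyy <- Ixy <- 0
  nsl <- 0L
  axes <- NULL
  for (k in seq_len(d[3])) {
    idx <- which(labels[, , k] == 1L, arr.ind = TRUE)
    if (nrow(idx) == 0L) next
    nsl <- nsl + 1L
    x <- (idx[, 1] - 0.5) * voxel_size
    y <- (idx[, 2] - 0.5) * voxel_size
    x <- x - mean(x); y <- y - mean(y)
    # voxel self-moment s^4/12 accounts for the finite voxel footprint
    self <- nrow(idx) * voxel_size^4 / 12
    Ixx <- Ixx + sum(y^2) * va + self   # moment about x-directed axis
    Iyy <- Iyy + sum(x^2) * va + self
    Ixy <- Ixy + sum(x * y) * va
  }
  if (nsl == 0L) stop_bonemech("no bone voxels present")
  Ixx <- Ixx / nsl; Iyy <- Iyy / nsl; Ixy <- Ixy / nsl
  J <- matrix(c(Ixx, -Ixy, -Ixy, Iyy), 2, 2)
  e <- eigen(J, symmetric = TRUE)
  # eigen returns decreasing eigenvalues: [I_max, I_min]
  I_max <- e$values[1]; I_min <- e$values[2]
  v_min <- e$vectors[, 2]  # direction n with n' J n = I_min
  # the I_min bending axis is the line through the centroid along v_min
  angle <- atan2(v_min[2], v_min[1])
  if (angle < 0) angle <- angle + pi
  list(I_min = I_min, I_max = I_max, principal_angle = angle, v_min = v_min)
}

#' Cortical morphometry of a labelled cross-section
#'
#' Areas by voxel counting averaged over slices; principal second moments of
#' area from the per-slice inertia tensor about the bone-area centroid;
#' `c` = extreme-fiber distance from the weak (I_min) principal axis; cortical
#' porosity from pore/(pore+bone) voxel counts; Ct.Th by the
#' maximal-inscribed-sphere (local thickness) method; Ct.TMD as the mean
#' calibrated density over bone voxels.
#'
#' @param labels integer label array from [label_compartments()] (or generator
#'   truth labels)
#' @param voxel_size isotropic voxel size in mm
#' @param calibration optional `c(intercept, slope)` density calibration;
#'   when absent Ct.TMD is NA (absent, not zero)
#' @param values optional grayscale array (needed for Ct.TMD)
#' @return named list with Tt.Ar, Ct.Ar, Ma.Ar (mm^2), Ct.Th (mm), I_min,
#'   I_max (mm^4), principal_angle (rad), c (mm), Ct.Po (%), Ct.TMD
#'   (mg HA/cm^3), plus `per_slice` areas
#' @export
cortical_morphometry <- function(labels, voxel_size, calibration = NULL,
                                 values = NULL) {
  if (is.matrix(labels)) dim(labels) <- c(dim(labels), 1L)
  d <- dim(labels)
  nz <- d[3]
  va <- voxel_size^2
  n_bone <- sum(labels == 1L)
  if (n_bone == 0L) stop_bonemech("no bone voxels present")
  n_marrow <- sum(labels == 2L)
  n_pore <- sum(labels == 3L)
  per_slice <- data.frame(
    slice = seq_len(nz),
    Ct.Ar = vapply(seq_len(nz), function(k) sum(labels[, , k] == 1L) * va, 0),
    Ma.Ar = vapply(seq_len(nz), function(k) sum(labels[, , k] == 2L) * va, 0),
    Po.Ar = vapply(seq_len(nz), function(k) sum(labels[, , k] == 3L) * va, 0))
  Ct.Ar <- n_bone * va / nz
  Ma.Ar <- n_marrow * va / nz
  Po.Ar <- n_pore * va / nz
  Tt.Ar <- Ct.Ar + Ma.Ar + Po.Ar

  mom <- section_moments(labels, voxel_size)

  # extreme-fiber distance from the I_min axis (perpendicular distance)
  idx <- which(labels == 1L, arr.ind = TRUE)
  x <- (idx[, 1] - 0.5) * voxel_size
  y <- (idx[, 2] - 0.5) * voxel_size
  x <- x - mean(x); y <- y - mean(y)
  v <- mom$v_min
  cdist <- max(abs(x * (-v[2]) + y * v[1]))

  # cortical thickness: local thickness of the bone phase (pores count as
  # bone for the envelope, matching the standard treatment of the cortex
  # as a solid shell for Ct.Th)
  shell <- labels == 1L | labels == 3L
  th <- local_thickness_mm(shell, voxel_size, average_over = labels == 1L)

  Ct.TMD <- NA_real_
  if (!is.null(calibration) && !is.null(values)) {
    if (is.matrix(values)) dim(values) <- c(dim(values), 1L)
    Ct.TMD <- calibration[1] + calibration[2] * mean(values[labels == 1L])
  }

  list(Tt.Ar = Tt.Ar, Ct.Ar = Ct.Ar, Ma.Ar = Ma.Ar, Ct.Th = th,
       I_min = mom$I_min, I_max = mom$I_max,
       principal_angle = mom$principal_angle, c = cdist,
       Ct.Po = 100 * n_pore / (n_pore + n_bone), Ct.TMD = Ct.TMD,
       per_slice = per_slice)
}

# mean local thickness (mm) of a phase; `average_over` restricts the mean
local_thickness_mm <- function(phase, voxel_size, average_over = phase) {
  d <- dim(phase)
  edt <- .edt3d_sq(as.logical(phase), as.integer(d))
  th <- array(.local_thickness(as.logical(phase), as.integer(d), edt), dim = d)
  mean(th[average_over]) * voxel_size
}

#' Trabecular morphometry within a volume of interest
#'
#' BV/TV by voxel counting; Tb.Th and Tb.Sp by the maximal-inscribed-sphere
#' local-thickness method on the bone and marrow phases; Tb.N = 1/(Tb.Th +
#' Tb.Sp); Conn.D = max(0, 1 - Euler characteristic)/VOI volume with the
#' Euler characteristic computed on the cubical complex of the bone phase.
#'
#' @param labels integer label array (1 = bone; anything else is marrow
#'   space inside the VOI)
#' @param voi logical array, TRUE inside the volume of interest
#' @param voxel_size isotropic voxel size in mm
#' @param calibration optional density calibration `c(intercept, slope)`
#' @param values optional grayscale array for Tb.TMD
#' @return named list: BV_TV (%), Tb.Th (um), Tb.Sp (um), Tb.N (1/mm),
#'   Conn.D (1/mm^3), Tb.TMD (mg HA/cm^3 or NA)
#' @export
trabecular_morphometry <- function(labels, voi = NULL, voxel_size,
                                   calibration = NULL, values = NULL) {
  if (is.matrix(labels)) dim(labels) <- c(dim(labels), 1L)
  d <- dim(labels)
  if (is.null(voi)) voi <- array(TRUE, dim = d)
  bone <- labels == 1L & voi
  n_voi <- sum(voi)
  if (n_voi == 0L) stop_bonemech("empty VOI")
  bvtv <- 100 * sum(bone) / n_voi
  vol <- n_voi * voxel_size^3

  if (sum(bone) == 0L) {
    warning("VOI contains no bone: thickness metrics undefined")
    return(list(BV_TV = 0, Tb.Th = NA_real_, Tb.Sp = NA_real_,
                Tb.N = NA_real_, Conn.D = 0, Tb.TMD = NA_real_))
  }
  marrow <- !bone & voi
  # voxels outside the VOI are treated as continuation of the phase so VOI
  # boundaries do not clip the fitted spheres
  tbth <- local_thickness_mm(bone | !voi, voxel_size, average_over = bone) * 1000
  tbsp <- if (sum(marrow) == 0L) NA_real_ else
    local_thickness_mm(marrow | !voi, voxel_size, average_over = marrow) * 1000
  tbn <- if (is.na(tbsp)) NA_real_ else 1 / ((tbth + tbsp) / 1000)

  chi <- euler_characteristic(bone)
  connd <- max(0, 1 - chi) / vol

  tbtmd <- NA_real_
  if (!is.null(calibration) && !is.null(values)) {
    if (is.matrix(values)) dim(values) <- c(dim(values), 1L)
    tbtmd <- calibration[1] + calibration[2] * mean(values[bone])
  }
  list(BV_TV = bvtv, Tb.Th = tbth, Tb.Sp = tbsp, Tb.N = tbn,
       Conn.D = connd, Tb.TMD = tbtmd)
}

#' Euler characteristic of a voxel set
#'
#' Computed on the cubical complex of the occupied voxels: chi = V - E + F -
#' C where vertices/edges/faces are counted once regardless of how many
#' cubes share them.
#'
#' @param mask logical 3-D array
#' @return integer Euler characteristic
#' @export
euler_characteristic <- function(mask) {
  if (is.matrix(mask)) dim(mask) <- c(dim(mask), 1L)
  d <- dim(mask)
  # pad with FALSE; voxel i sits at padded index i + 1
  p <- array(FALSE, dim = d + 2L)
  p[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  # a cell with span s (1 = the cell lies between voxels along that axis)
  # is present if any incident voxel is occupied; incident voxels are the
  # 2^sum(s) offsets over the spanned axes
  count_cells <- function(span) {
    slice <- function(ax, off)
      if (span[ax] == 1L) (1L + off):(d[ax] + 1L + off) else 2L:(d[ax] + 1L)
    acc <- NULL
    for (ox in 0:span[1]) for (oy in 0:span[2]) for (oz in 0:span[3]) {
      blk <- p[slice(1, ox), slice(2, oy), slice(3, oz), drop = FALSE]
      acc <- if (is.null(acc)) blk else (acc | blk)
    }
    sum(acc)
  }
  V <- count_cells(c(1L, 1L, 1L))
  E <- count_cells(c(0L, 1L, 1L)) + count_cells(c(1L, 0L, 1L)) +
    count_cells(c(1L, 1L, 0L))
  Fc <- count_cells(c(1L, 0L, 0L)) + count_cells(c(0L, 1L, 0L)) +
    count_cells(c(0L, 0L, 1L))
  C <- sum(mask)
  as.integer(V - E + Fc - C)
}
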