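# shared fixtures and independent oracles

# voxelize a set of z-slices for simple phantoms: predicate(x, y) in mm,
# centered grid; returns logical array
phantom_slices <- function(predicate, halfwidth, voxel, n_slices = 3) {
  n <- ceiling(2 * halfwidth / voxel)
  xs <- (seq_len(n) - 0.5) * voxel - n * voxel / 2
  sl <- outer(xs, xs, predicate)
  array(rep(sl, n_slices), dim = c(n, n, n_slices))
}

labels_from_mask <- function(mask) {
  # bone-only labels (no marrow/pores) for closed-form phantoms
  out <- array(0L, dim = dim(mask))
  out[mask] <- 1L
  out
}

# brute-force maximal-inscribed-sphere thickness oracle (tiny grids only):
# thickness(p) = 2 * max radius r such that some sphere of radius r inside
# the phase contains p
brute_thickness <- function(mask) {
  d <- dim(mask)
  idx <- which(mask, arr.ind = TRUE)
  # radius of largest sphere centered at each voxel: distance to nearest
  # background voxel center
  bg <- which(!mask, arr.ind = TRUE)
  th <- array(0, dim = d)
  r <- numeric(nrow(idx))
  for (i in seq_len(nrow(idx))) {
    dd <- sqrt((bg[, 1] - idx[i, 1])^2 + (bg[, 2] - idx[i, 2])^2 +
                 (bg[, 3] - idx[i, 3])^2)
    r[i] <- min(dd)
  }
  for (i in seq_len(nrow(idx))) {
    cover <- (idx[, 1] - idx[i, 1])^2 + (idx[, 2] - idx[i, 2])^2 +
      (idx[, 3] - idx[i, 3])^2 <= r[i]^2 + 1e-9
    th[idx[cover, , drop = FALSE]] <- pmax(th[idx[cover, , drop = FALSE]],
                                           2 * r[i])
  }
  mean(th[mask])
}

# independent exact WMW oracle: enumerate all group labelings of the
# observed values and count rank-sum configurations at least as extreme
wmw_enumeration_oracle <- function(x, y) {
  nx <- length(x)
  vals <- c(x, y)
  r <- rank(vals)
  obs <- sum(r[seq_len(nx)])
  combos <- utils::combn(length(vals), nx)
  sums <- apply(combos, 2, function(ix) sum(r[ix]))
  lo <- mean(sums <= obs + 1e-9)
  hi <- mean(sums >= obs - 1e-9)
  min(1, 2 * min(lo, hi))
}

# protocol-faithful Raman point spectrum: ten accumulations averaged
protocol_spectrum <- function(truth, seed) {
  accs <- lapply(1:10, function(k)
    gen_raman_spectrum(truth, step = 1, seed = seed * 100 + k)$spectrum)
  average_accumulations(accs)
}

silica_E_r <- function(constants = indenter_constants(nu_sample = 0.17)) {
  1 / ((1 - constants$nu_sample^2) / 72 +
         (1 - constants$nu_indenter^2) / constants$E_indenter)
}
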