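# Virtual MRI phantom generation: partial-volume capsule voxelization of an
# RSA, seeded water noise inside a soil cylinder scaled to a target SNR, and
# the Weierstrass (Gaussian) transform, plus the matching SNR meter.

#' Voxelize a root system into a partial-volume signal grid
#'
#' Each root segment is treated as a capsule: a tube whose radius
#' interpolates linearly between the two node radii, with hemispherical
#' caps. Per voxel, the occupied volume fraction is estimated with a regular
#' `supersampling^3` sub-grid of sample points tested against the union of
#' all capsules (max-of-memberships, so overlaps at branch junctions are not
#' double counted). The result is deterministic — no Monte Carlo.
#'
#' @param rsa A valid [root_system()].
#' @param voxel_size Isotropic voxel size in cm (default 0.05).
#' @param shape,origin Grid shape (3 integers) and corner (cm). When `NULL`
#'   both are derived from the RSA bounding box plus `margin`. If the given
#'   grid does not cover the RSA, the signal is clipped with a warning.
#' @param supersampling Sub-grid points per voxel edge (>= 1, default 4).
#' @param margin Margin (cm) added around the RSA for the automatic grid.
#' @return A [volume_grid()] with values in \[0, 1\] (occupied volume
#'   fraction per voxel).
#' @export
voxelize <- function(rsa, voxel_size = 0.05, shape = NULL, origin = NULL,
                     supersampling = 4L, margin = 0.3) {
  validate_root_system(rsa)
  if (!is_scalar(voxel_size) || voxel_size <= 0)
    stop_parameter("voxel_size must be a positive scalar")
  if (!is_count(supersampling) || supersampling < 1)
    stop_parameter("supersampling must be a positive integer")
  s <- as.integer(supersampling)

  segs <- to_segments(rsa)
  if (is.null(shape) || is.null(origin)) {
    if (!nrow(segs)) {
      shape <- shape %||% c(8L, 8L, 8L)
      origin <- origin %||% c(0, 0, 0)
    } else {
      pts <- rbind(as.matrix(segs[, c("x0", "y0", "z0")]),
                   as.matrix(segs[, c("x1", "y1", "z1")]))
      pad <- max(segs$radius) + margin
      lo <- apply(pts, 2L, min) - pad
      hi <- apply(pts, 2L, max) + pad
      origin <- origin %||% lo
      shape <- shape %||% pmax(1L, ceiling((hi - origin) / voxel_size))
    }
  }
  shape <- as.integer(shape)
  nx <- shape[1L]; ny <- shape[2L]; nz <- shape[3L]
  vals <- array(0, dim = shape)
  if (!nrow(segs))
    return(volume_grid(vals, voxel_size, origin))

  sub_size <- voxel_size / s
  nxs <- nx * s; nys <- ny * s
  counts <- integer(nx * ny * nz)
  clipped <- FALSE
  acc <- vector("list", nrow(segs))

  for (k in seq_len(nrow(segs))) {
    p0 <- c(segs$x0[k], segs$y0[k], segs$z0[k])
    p1 <- c(segs$x1[k], segs$y1[k], segs$z1[k])
    r0 <- segs$radius0[k]; r1 <- segs$radius1[k]
    r <- max(r0, r1)
    lo <- pmin(p0, p1) - r
    hi <- pmax(p0, p1) + r
    i0 <- floor((lo - origin) / voxel_size) + 1
    i1 <- ceiling((hi - origin) / voxel_size)
    if (any(i1 < 1) || any(i0 > shape)) { clipped <- TRUE; next }
    if (any(i0 < 1) || any(i1 > shape)) clipped <- TRUE
    i0 <- pmax(i0, 1); i1 <- pmin(i1, shape)
    # sub-grid indices covered by the bounding box, per axis
    sx <- ((i0[1L] - 1) * s + 1):(i1[1L] * s)
    sy <- ((i0[2L] - 1) * s + 1):(i1[2L] * s)
    sz <- ((i0[3L] - 1) * s + 1):(i1[3L] * s)
    cx <- origin[1L] + (sx - 0.5) * sub_size
    cy <- origin[2L] + (sy - 0.5) * sub_size
    cz <- origin[3L] + (sz - 0.5) * sub_size
    nxl <- length(sx); nyl <- length(sy); nzl <- length(sz)
    px <- rep(cx, times = nyl * nzl)
    py <- rep(rep(cy, each = nxl), times = nzl)
    pz <- rep(cz, each = nxl * nyl)
    d <- p1 - p0
    len2 <- sum(d * d)
    t <- clamp01(((px - p0[1L]) * d[1L] + (py - p0[2L]) * d[2L] +
                  (pz - p0[3L]) * d[3L]) / len2)
    dx <- px - (p0[1L] + t * d[1L])
    dy <- py - (p0[2L] + t * d[2L])
    dz <- pz - (p0[3L] + t * d[3L])
    # radius interpolates linearly between the node radii along the axis
    rad <- r0 + t * (r1 - r0)
    inside <- (dx * dx + dy * dy + dz * dz) <= rad * rad
    if (!any(inside)) next
    gsx <- rep(sx, times = nyl * nzl)[inside]
    gsy <- rep(rep(sy, each = nxl), times = nzl)[inside]
    gsz <- rep(sz, each = nxl * nyl)[inside]
    acc[[k]] <- (gsz - 1) * (as.double(nxs) * nys) + (gsy - 1) * nxs + gsx
  }
  if (clipped)
    warning("voxelize: grid does not fully cover the root system; signal clipped")

  all_idx <- unlist(acc, use.names = FALSE)
  if (length(all_idx)) {
    u <- unique(all_idx)          # union over capsules at sub-grid resolution
    gsx <- (u - 1) %% nxs + 1
    rest <- (u - 1 - (gsx - 1)) / nxs
    gsy <- rest %% nys + 1
    gsz <- (rest - (gsy - 1)) / nys + 1
    vi <- ceiling(gsx / s); vj <- ceiling(gsy / s); vk <- ceiling(gsz / s)
    vox <- as.integer((vk - 1) * (nx * ny) + (vj - 1) * nx + vi)
    tab <- tabulate(vox, nbins = nx * ny * nz)
    vals <- array(pmin(1, tab / s^3), dim = shape)
  }
  volume_grid(vals, voxel_size, origin)
}

#' Water-noise configuration for the virtual MRI
#'
#' Defaults emulate the study conditions: a vertical soil cylinder of 1.5 cm
#' diameter around the plant axis, noise amplitude scaled to a
#' signal-to-noise ratio of 4.3, signed impulses at 2% density smoothed with
#' a 0.05 cm (one-voxel) Gaussian bandwidth.
#'
#' @param snr Target signal-to-noise ratio (> 0), as measured by
#'   [measure_snr()] after the Weierstrass transform.
#' @param cylinder_diameter Diameter (cm) of the noise cylinder.
#' @param cylinder_center Center of the cylinder in the plane perpendicular
#'   to its axis (cm, world coordinates, in ascending axis order).
#' @param cylinder_axis `"x"`, `"y"` or `"z"` (default; vertical).
#' @param impulse_density Fraction of cylinder voxels receiving a signed
#'   impulse, in (0, 1].
#' @param kernel_sigma Weierstrass (Gaussian) bandwidth in cm.
#' @param seed Integer seed for reproducible noise placement.
#' @return An object of class `noise_config`.
#' @export
noise_config <- function(snr = 4.3, cylinder_diameter = 1.5,
                         cylinder_center = c(0, 0), cylinder_axis = "z",
                         impulse_density = 0.02, kernel_sigma = 0.05,
                         seed = NULL) {
  if (!is_scalar(snr) || snr <= 0) stop_parameter("snr must be > 0")
  if (!is_scalar(cylinder_diameter) || cylinder_diameter <= 0)
    stop_parameter("cylinder_diameter must be > 0")
  if (!is_scalar(impulse_density) || impulse_density <= 0 || impulse_density > 1)
    stop_parameter("impulse_density must be in (0, 1]")
  if (!is_scalar(kernel_sigma) || kernel_sigma < 0)
    stop_parameter("kernel_sigma must be >= 0")
  if (!cylinder_axis %in% c("x", "y", "z"))
    stop_parameter("cylinder_axis must be one of x, y, z")
  structure(list(snr = snr, cylinder_diameter = cylinder_diameter,
                 cylinder_center = as.numeric(cylinder_center),
                 cylinder_axis = cylinder_axis,
                 impulse_density = impulse_density,
                 kernel_sigma = kernel_sigma, seed = seed),
            class = "noise_config")
}

#' Logical mask of a cylindrical region of a volume
#'
#' @param volume A [volume_grid()].
#' @param center Cylinder center in the perpendicular plane (cm, the two
#'   non-axis world coordinates in ascending axis order).
#' @param diameter Cylinder diameter in cm.
#' @param axis Cylinder axis, `"x"`, `"y"` or `"z"`; the cylinder spans the
#'   full grid along it.
#' @return Logical array of `dim(volume$values)`.
#' @export
cylinder_mask <- function(volume, center, diameter, axis = "z") {
  ax <- match(axis, c("x", "y", "z"))
  if (is.na(ax)) stop_parameter("axis must be x, y or z")
  others <- setdiff(1:3, ax)
  c1 <- axis_coords(volume, others[1L]) - center[1L]
  c2 <- axis_coords(volume, others[2L]) - center[2L]
  r2 <- (diameter / 2)^2
  plane <- outer(c1^2, c2^2, "+") <= r2
  d <- dim(volume$values)
  mask <- array(FALSE, d)
  # broadcast the perpendicular-plane disk along the cylinder axis
  perm <- order(c(others, ax))
  full <- array(rep(plane, d[ax]), dim = c(d[others], d[ax]))
  aperm(full, perm)
}

# Separable Gaussian smoothing of a 3D array, sigma in voxels,
# zero-padded boundaries, kernel truncated at 4 sigma and normalized.
gaussian_smooth_3d <- function(a, sigma_vox) {
  if (sigma_vox == 0) return(a)
  h <- max(1L, ceiling(4 * sigma_vox))
  g <- stats::dnorm(-h:h, sd = sigma_vox)
  g <- g / sum(g)
  for (ax in 1:3) {
    d <- dim(a)
    n <- d[1L]
    hh <- min(h, n - 1L)
    gg <- if (hh < h) { gt <- g[(h - hh + 1L):(h + hh + 1L)]; gt / sum(gt) } else g
    K <- Matrix::bandSparse(n, n, k = -hh:hh,
                            diagonals = lapply(-hh:hh, function(k)
                              rep(gg[k + hh + 1L], n - abs(k))))
    a <- array(as.matrix(K %*% matrix(a, n, prod(d) / n)), d)
    a <- aperm(a, c(2L, 3L, 1L))
  }
  a
}

# Binary dilation of a mask by r voxels (separable box, chebyshev ball).
dilate_mask <- function(mask, r) {
  if (r <= 0) return(mask)
  a <- array(as.numeric(mask), dim = dim(mask))
  for (ax in 1:3) {
    d <- dim(a)
    n <- d[1L]
    hh <- min(r, n - 1L)
    K <- Matrix::bandSparse(n, n, k = -hh:hh,
                            diagonals = lapply(-hh:hh, function(k)
                              rep(1, n - abs(k))))
    a <- array(as.matrix(K %*% matrix(a, n, prod(d) / n)), d)
    a <- aperm(a, c(2L, 3L, 1L))
  }
  a > 0
}

#' Seed water noise inside a soil cylinder
#'
#' Places signed unit impulses (random sign) at `impulse_density` of the
#' voxels inside the configured cylinder, then scales their amplitude so
#' that, after Gaussian smoothing at the configured `kernel_sigma`, the
#' measured SNR ([measure_snr()]) equals `config$snr`. The generator and the
#' meter share one SNR definition — peak smoothed clean signal in the
#' dilated region over smoothed-noise RMS in the region — making the target
#' SNR a closed-loop contract. Voxels outside the cylinder are unchanged.
#' The returned volume is the *unsmoothed* clean + noise field; apply
#' [weierstrass_transform()] with the same bandwidth to obtain the final
#' phantom.
#'
#' @param volume Clean signal [volume_grid()] (values in \[0, 1\]).
#' @param config A [noise_config()].
#' @return A [volume_grid()] with the noise added, carrying attributes
#'   `noise_amplitude`, `noise_mask_spec` and `noise_config`.
#' @export
seed_water_noise <- function(volume, config = noise_config()) {
  if (!inherits(volume, "volume_grid")) stop_parameter("volume must be a volume_grid")
  if (!inherits(config, "noise_config")) stop_parameter("config must be a noise_config")
  mask <- cylinder_mask(volume, config$cylinder_center,
                        config$cylinder_diameter, config$cylinder_axis)
  idx_in <- which(mask)
  if (!length(idx_in))
    stop_with("rsaeval_placement_error",
              "noise cylinder lies entirely outside the volume grid")
  n_imp <- max(1L, round(config$impulse_density * length(idx_in)))
  eps <- array(0, dim(volume$values))
  with_seed(config$seed, {
    at <- sample(idx_in, n_imp)
    eps[at] <- sample(c(-1, 1), n_imp, replace = TRUE)
  })
  sig_vox <- config$kernel_sigma / volume$voxel_size
  eps_s <- gaussian_smooth_3d(eps, sig_vox)
  rms <- sqrt(mean(eps_s[mask]^2))
  dil <- dilate_mask(mask, max(1L, ceiling(3 * sig_vox)))
  clean_s <- gaussian_smooth_3d(volume$values, sig_vox)
  peak <- max(clean_s[dil])
  if (peak <= 0)
    stop_with("rsaeval_placement_error",
              "no clean signal in the dilated noise region; SNR undefined")
  amp <- peak / (config$snr * rms)
  out <- volume_grid(volume$values + amp * eps, volume$voxel_size,
                     volume$origin)
  attr(out, "noise_amplitude") <- amp
  attr(out, "noise_config") <- config
  out
}

#' Weierstrass (Gaussian) transform of a volume
#'
#' Convolution with a normalized isotropic Gaussian kernel of standard
#' deviation `sigma` (cm; converted to voxels internally), truncated at 4
#' sigma, with zero padding at the boundary. `sigma = 0` is the identity.
#' The total mass of an interior-supported field is preserved.
#'
#' @param volume A [volume_grid()].
#' @param sigma Gaussian standard deviation in cm (>= 0).
#' @return Smoothed [volume_grid()].
#' @export
weierstrass_transform <- function(volume, sigma) {
  if (!is_scalar(sigma) || sigma < 0)
    stop_parameter("sigma must be a non-negative scalar")
  if (sigma == 0) return(volume)
  volume_grid(gaussian_smooth_3d(volume$values, sigma / volume$voxel_size),
              volume$voxel_size, volume$origin)
}

#' Measure the signal-to-noise ratio of a noisy volume
#'
#' SNR is defined as the peak clean signal within the dilated neighbourhood
#' of the region, divided by the root-mean-square of `noisy - clean` inside
#' the region. Pass the smoothed clean and smoothed noisy phantoms to
#' evaluate the SNR of the final (post-Weierstrass) data set.
#'
#' @param clean,noisy Congruent [volume_grid()]s.
#' @param region Logical mask array (as from [cylinder_mask()]).
#' @param dilate Dilation radius in voxels for the peak-signal neighbourhood
#'   (default 3).
#' @return SNR (dimensionless); `Inf` when `noisy` equals `clean` in the
#'   region.
#' @export
measure_snr <- function(clean, noisy, region, dilate = 3L) {
  if (!congruent_grids(clean, noisy))
    stop_parameter("clean and noisy grids are not congruent")
  if (!is.logical(region) || !identical(dim(region), dim(clean$values)))
    stop_parameter("region must be a logical array matching the grids")
  if (!any(region)) stop_parameter("region is empty")
  rms <- sqrt(mean((noisy$values[region] - clean$values[region])^2))
  peak <- max(clean$values[dilate_mask(region, dilate)])
  if (rms == 0) return(Inf)
  peak / rms
}

#' Generate a full virtual MRI phantom from a root system
#'
#' Composes [voxelize()], [seed_water_noise()] and
#' [weierstrass_transform()], and measures the achieved SNR of the smoothed
#' phantom with [measure_snr()].
#'
#' @param rsa A [root_system()].
#' @param voxel_size Voxel size in cm (default 0.05).
#' @param config A [noise_config()]; `NULL` skips noise.
#' @param supersampling Passed to [voxelize()].
#' @param ... Further arguments to [voxelize()] (`shape`, `origin`,
#'   `margin`).
#' @return A list with `clean` (raw signal), `clean_smoothed`, `noisy`
#'   (post-Weierstrass, `NULL` without noise), `mask` (noise region) and
#'   `snr` (measured; `NA` without noise).
#' @export
simulate_phantom <- function(rsa, voxel_size = 0.05, config = noise_config(),
                             supersampling = 4L, ...) {
  clean <- voxelize(rsa, voxel_size = voxel_size,
                    supersampling = supersampling, ...)
  if (is.null(config))
    return(list(clean = clean, clean_smoothed = NULL, noisy = NULL,
                mask = NULL, snr = NA_real_))
  seeded <- seed_water_noise(clean, config)
  noisy <- weierstrass_transform(seeded, config$kernel_sigma)
  clean_s <- weierstrass_transform(clean, config$kernel_sigma)
  mask <- cylinder_mask(clean, config$cylinder_center,
                        config$cylinder_diameter, config$cylinder_axis)
  snr <- measure_snr(clean_s, noisy, mask,
                     dilate = max(1L, ceiling(3 * config$kernel_sigma /
                                                voxel_size)))
  list(clean = clean, clean_smoothed = clean_s, noisy = noisy,
       mask = mask, snr = snr)
}
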