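# Volumetric mode: ROI spheres painted into a voxel grid, voxelwise fALFF,
# Gaussian smoothing and sphere-mean aggregation. ROI-level matrices are the
# default pipeline path; this mode exercises the imaging path (NIfTI I/O,
# smoothing) on the same synthetic signals.

#' Voxelisation geometry for a template
#'
#' Builds a regular grid covering all template spheres and assigns each ROI
#' its voxel indices (sphere of the template's radius around the MNI
#' coordinate).
#'
#' @param template a [roi_template()].
#' @param voxel_size isotropic voxel edge in mm (default 6; coarse grids
#'   keep synthetic volumes small).
#' @param margin_mm padding beyond the extreme coordinates (default 10).
#' @return A `roi_voxel_map`: list with `dim`, `origin_mm`, `voxel_size`,
#'   and `voxels` (per-ROI integer vectors of linear voxel indices).
#' @export
roi_voxel_map <- function(template, voxel_size = 6, margin_mm = 10) {
  stopifnot(inherits(template, "roi_template"))
  radius <- attr(template, "radius")
  xyz <- as.matrix(template[, c("x", "y", "z")])
  lo <- floor((apply(xyz, 2, min) - margin_mm) / voxel_size) * voxel_size
  hi <- apply(xyz, 2, max) + margin_mm
  dims <- pmax(ceiling((hi - lo) / voxel_size) + 1L, 2L)
  centers <- lapply(1:3, function(a) lo[a] + (seq_len(dims[a]) - 1) * voxel_size)
  voxels <- lapply(seq_len(nrow(xyz)), function(i) {
    rng <- lapply(1:3, function(a) {
      which(abs(centers[[a]] - xyz[i, a]) <= radius)
    })
    if (any(lengths(rng) == 0)) return(integer(0))
    g <- expand.grid(rng[[1]], rng[[2]], rng[[3]])
    d2 <- (centers[[1]][g[, 1]] - xyz[i, 1])^2 +
      (centers[[2]][g[, 2]] - xyz[i, 2])^2 +
      (centers[[3]][g[, 3]] - xyz[i, 3])^2
    keep <- d2 <= radius^2
    as.integer(g[keep, 1] + dims[1] * (g[keep, 2] - 1) +
                 dims[1] * dims[2] * (g[keep, 3] - 1))
  })
  structure(list(dim = as.integer(dims), origin_mm = lo,
                 voxel_size = voxel_size, voxels = voxels,
                 roi_names = template$name),
            class = "roi_voxel_map")
}

#' Paint an ROI recording into a 4D voxel grid
#'
#' Each ROI's time series is written into every voxel of its sphere;
#' independent white voxel noise can be added on top. Voxels belonging to no
#' sphere stay zero (and are excluded by the mask).
#'
#' @param recording a `subject_recording` (ROI-level).
#' @param vmap a [roi_voxel_map()] built from the same template.
#' @param voxel_noise_sigma white-noise sd added per voxel (default 0).
#' @return List with `data` (4D array x,y,z,t), `mask` (3D logical, voxels
#'   covered by at least one sphere) and `tr`.
#' @export
recording_to_volume <- function(recording, vmap, voxel_noise_sigma = 0) {
  stopifnot(inherits(recording, "subject_recording"),
            inherits(vmap, "roi_voxel_map"))
  nt <- nrow(recording$data)
  nvox <- prod(vmap$dim)
  flat <- matrix(0, nvox, nt)
  mask <- logical(nvox)
  for (i in seq_along(vmap$voxels)) {
    vox <- vmap$voxels[[i]]
    if (!length(vox)) next
    flat[vox, ] <- matrix(recording$data[, i], length(vox), nt, byrow = TRUE)
    mask[vox] <- TRUE
  }
  if (voxel_noise_sigma > 0)
    flat[mask, ] <- flat[mask, ] +
      rnorm(sum(mask) * nt, 0, voxel_noise_sigma)
  list(data = array(flat, c(vmap$dim, nt)),
       mask = array(mask, vmap$dim), tr = recording$tr)
}

#' Voxelwise fALFF map from a 4D volume
#'
#' Discards nothing (trim beforehand), detrends each masked voxel series and
#' computes fALFF voxelwise; unmasked voxels are NA.
#'
#' @param volume 4D array (x, y, z, t).
#' @param tr sampling interval, seconds.
#' @param mask 3D logical array (default: voxels with nonzero variance).
#' @param bands a [spectral_bands()].
#' @return 3D array of fALFF values (NA outside the mask).
#' @export
falff_volume <- function(volume, tr, mask = NULL, bands = spectral_bands(tr)) {
  assert_that(length(dim(volume)) == 4, "volume must be a 4D array")
  d <- dim(volume)
  flat <- matrix(volume, prod(d[1:3]), d[4])
  mask <- mask %||% array(apply(flat, 1, sd) > 0, d[1:3])
  assert_that(any(mask), "mask is empty")
  series <- detrend_linear(t(flat[as.vector(mask), , drop = FALSE]))
  f <- falff_columns(series, tr, bands)$falff
  out <- array(NA_real_, d[1:3])
  out[as.vector(mask)] <- f
  out
}

gaussian_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  half <- max(1L, ceiling(3 * sigma_vox))
  k <- exp(-((-half):half)^2 / (2 * sigma_vox^2))
  k / sum(k)
}

convolve_axis <- function(vol, kernel, axis) {
  if (length(kernel) == 1) return(vol)
  d <- dim(vol)
  perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  v <- aperm(vol, perm)
  dm <- dim(v)
  m <- matrix(v, dm[1], dm[2] * dm[3])
  half <- (length(kernel) - 1) / 2
  pad <- rbind(matrix(0, half, ncol(m)), m, matrix(0, half, ncol(m)))
  out <- apply(pad, 2, function(col)
    convolve(col, rev(kernel), type = "open")[(2 * half + 1):(2 * half + dm[1])])
  array(out, dm) |> aperm(order(perm))
}

#' Gaussian smoothing of a 3D map
#'
#' Separable Gaussian convolution with per-axis standard deviation
#' `fwhm / (2 * sqrt(2 * log(2)))`. Border voxels are renormalised by the
#' kernel mass actually inside the volume, so constant maps are preserved
#' exactly and a unit impulse away from the border reproduces the kernel
#' (total intensity conserved for interior-supported maps). `fwhm_mm = 0`
#' is the identity.
#'
#' @param volume 3D numeric array.
#' @param fwhm_mm kernel full width at half maximum in mm (study value: 6).
#' @param voxel_size isotropic voxel edge in mm.
#' @return Smoothed 3D array of the same dimensions.
#' @export
smooth_gaussian <- function(volume, fwhm_mm, voxel_size) {
  assert_that(length(dim(volume)) == 3, "expected a 3D array")
  assert_that(fwhm_mm >= 0, "fwhm must be >= 0")
  if (fwhm_mm == 0) return(volume)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size
  k <- gaussian_kernel_1d(sigma_vox)
  out <- volume
  norm <- array(1, dim(volume))
  for (axis in 1:3) {
    out <- convolve_axis(out, k, axis)
    norm <- convolve_axis(norm, k, axis)
  }
  out / norm
}

#' Aggregate a map (or pass through a matrix) to per-ROI means
#'
#' In volumetric mode, averages a 3D map over each ROI sphere; an ROI whose
#' sphere contains no finite voxels is flagged `NA` (missing, never a silent
#' zero). For an ROI-level vector or matrix this is an identity pass-through
#' with label alignment against the template.
#'
#' @param x 3D array (with `vmap` supplied), or a named per-ROI numeric
#'   vector / subjects x ROI matrix.
#' @param template a [roi_template()].
#' @param vmap a [roi_voxel_map()] (volumetric input only).
#' @return Per-ROI mean vector in template order (or the aligned matrix).
#' @export
roi_aggregate <- function(x, template, vmap = NULL) {
  stopifnot(inherits(template, "roi_template"))
  if (is.array(x) && length(dim(x)) == 3) {
    assert_that(!is.null(vmap), "volumetric aggregation needs a roi_voxel_map")
    vals <- vapply(vmap$voxels, function(vox) {
      v <- x[vox]
      v <- v[is.finite(v)]
      if (length(v) == 0) NA_real_ else mean(v)
    }, numeric(1))
    return(setNames(vals, template$name))
  }
  if (is.matrix(x)) {
    assert_that(all(template$name %in% colnames(x)),
                "matrix columns do not cover the template ROIs")
    return(x[, template$name, drop = FALSE])
  }
  assert_that(all(template$name %in% names(x)),
              "vector names do not cover the template ROIs")
  x[template$name]
}

#' Write / read a 4D recording as NIfTI
#'
#' Thin wrappers over RNifti for volumetric interchange; the voxel size and
#' TR are stored in the NIfTI header (`pixdim`).
#'
#' @param volume 4D array (x, y, z, t).
#' @param path output `.nii` / `.nii.gz` path.
#' @param voxel_size isotropic voxel edge, mm.
#' @param tr repetition time, seconds.
#' @return `path`, invisibly (write); list with `data` 4D array and `tr`
#'   (read).
#' @export
write_volume_nifti <- function(volume, path, voxel_size, tr) {
  img <- RNifti::asNifti(volume)
  RNifti::pixdim(img) <- c(rep(voxel_size, 3), tr)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  list(data = unclass(img)[, , , , drop = FALSE],
       tr = if (length(pd) >= 4) pd[4] else NA_real_)
}
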