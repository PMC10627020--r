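#' Gaussian kernel weights over gray-matter voxels around an electrode
#'
#' Weights each gray-matter voxel by a 3D isotropic Gaussian of width
#' `sigma` (mm) in the distance between the electrode position and the
#' voxel center (world mm, voxel centers from the affine). Voxels beyond
#' `trunc_k * sigma` carry zero weight; the remaining weights are
#' normalized to sum 1.
#'
#' @param electrode_xyz Numeric length-3 position in world mm.
#' @param zmap A `zmap` (only `gm_mask` and `affine` are used).
#' @param sigma Kernel width (sd) in mm.
#' @param trunc_k Truncation radius in units of sigma. The default of 6
#'   discards less than 1e-7 of the 3D kernel mass, keeping truncated and
#'   untruncated weighted averages equal to well below 1e-6; a radius of
#'   4 sigma, in contrast, loses ~1e-3 of the mass of a 3D Gaussian.
#' @param label Electrode name used in error messages.
#' @return List with `idx` (indices into the GM voxel set, in
#'   `which(gm_mask)` order), `weights` (summing to 1), `sigma`.
#' @export
gaussian_weights <- function(electrode_xyz, zmap, sigma, trunc_k = 6,
                             label = "electrode") {
  check_scalar(sigma, "sigma")
  gm_xyz <- voxel_to_world(mask_indices(zmap$gm_mask), zmap$affine)
  d2 <- rowSums(sweep(gm_xyz, 2, as.numeric(electrode_xyz))^2)
  sel <- which(d2 <= (trunc_k * sigma)^2)
  if (length(sel) == 0L)
    stop(sprintf("no gray-matter voxel within %g mm (= %g sigma) of %s at sigma = %g mm",
                 trunc_k * sigma, trunc_k, label, sigma), call. = FALSE)
  w <- exp(-d2[sel] / (2 * sigma^2))
  list(idx = sel, weights = w / sum(w), sigma = sigma)
}

# Distances (mm) from each electrode (rows of exyz) to each GM voxel center,
# plus the GM z vector. Precomputed once per sigma sweep.
.electrode_gm_geometry <- function(zmap, exyz) {
  gm_xyz <- voxel_to_world(mask_indices(zmap$gm_mask), zmap$affine)
  exyz <- as.matrix(exyz)
  d2 <- outer(rowSums(exyz^2), rowSums(gm_xyz^2), "+") - 2 * exyz %*% t(gm_xyz)
  list(d2 = pmax(d2, 0), z = zmap$z[zmap$gm_mask])
}

# Weighted fMRI z per electrode from a precomputed geometry at one sigma.
# Electrodes with no GM voxel in the truncation radius get NA.
.weighted_z_at_sigma <- function(geom, sigma, trunc_k) {
  W <- exp(-geom$d2 / (2 * sigma^2))
  W[geom$d2 > (trunc_k * sigma)^2] <- 0
  tot <- rowSums(W)
  out <- as.vector(W %*% geom$z) / tot
  out[tot == 0] <- NA_real_
  out
}

#' Kernel-weighted fMRI z-score at each electrode
#'
#' Applies [gaussian_weights()] per electrode and returns the weighted
#' average of the gray-matter z-scores. Electrodes with no gray matter
#' within the truncation radius are dropped with a warning.
#'
#' @param zmap A `zmap`.
#' @param electrodes Data frame with `electrode` (or `name`), `x`, `y`, `z`.
#' @param sigma Kernel width in mm.
#' @param trunc_k Truncation radius in units of sigma.
#' @return Named numeric vector of weighted fMRI z-scores (dropped
#'   electrodes omitted).
#' @export
weighted_zscores <- function(zmap, electrodes, sigma, trunc_k = 6) {
  if (nrow(electrodes) == 0L) stop("no electrodes supplied", call. = FALSE)
  nm <- if ("electrode" %in% names(electrodes)) electrodes$electrode else electrodes$name
  geom <- .electrode_gm_geometry(zmap, electrodes[, c("x", "y", "z")])
  out <- .weighted_z_at_sigma(geom, sigma, trunc_k)
  names(out) <- nm
  if (anyNA(out)) {
    warning(sprintf("dropping %d electrode(s) with no gray matter within %g sigma: %s",
                    sum(is.na(out)), trunc_k,
                    paste(nm[is.na(out)], collapse = ", ")), call. = FALSE)
    out <- out[!is.na(out)]
  }
  if (length(out) == 0L)
    stop("all electrodes dropped: no gray matter in any truncation radius",
         call. = FALSE)
  out
}

#' Correlation between ECoG and weighted fMRI z-scores at one kernel width
#'
#' Pearson correlation across electrodes between the ECoG band z-scores and
#' the kernel-weighted fMRI z-scores, the explained variance r-squared, and
#' the least-squares slope of fMRI z on ECoG z.
#'
#' @param ecog_z,fmri_z Numeric vectors, one value per electrode (>= 3).
#' @param method `"pearson"` (default) or `"spearman"` (rank correlation;
#'   the slope is still the least-squares slope on the raw values).
#' @return List with `r`, `r2`, `slope`, `n`.
#' @export
correlation_at_sigma <- function(ecog_z, fmri_z, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(ecog_z) != length(fmri_z))
    stop("z-score vectors differ in length", call. = FALSE)
  if (length(ecog_z) < 3L)
    stop("need at least 3 electrodes to correlate", call. = FALSE)
  if (stats::sd(ecog_z) == 0 || stats::sd(fmri_z) == 0)
    stop("zero variance in a z-score vector", call. = FALSE)
  r <- stats::cor(ecog_z, fmri_z, method = method)
  slope <- stats::cov(ecog_z, fmri_z) / stats::var(ecog_z)
  list(r = r, r2 = r^2, slope = slope, n = length(ecog_z))
}

#' Fit the explained-variance versus kernel-width curve
#'
#' The central estimator: for every kernel width on `sigma_grid`, computes
#' the Gaussian-kernel weighted fMRI z-score at each task-responsive
#' electrode and correlates it, across electrodes, with the ECoG band
#' z-scores. The resulting r-squared curve is summarized by two kernel
#' widths:
#'
#' * `peak_sigma` — the width maximizing explained variance (ties resolve
#'   to the smallest width; a peak on the first or last grid point sets
#'   `peak_on_boundary`), and
#' * `concavity_sigma` — the point of maximum downwards concavity of the
#'   curve (see [concavity_sigma()]), where further smoothing stops paying
#'   off: the spatial-specificity measure.
#'
#' Only electrodes with a significant band response (positive or negative)
#' enter the correlation, and the electrode set is held fixed across the
#' whole sweep.
#'
#' @param zmap A `zmap`.
#' @param electrodes An electrode response table from
#'   [ecog_band_responses()], already restricted to one band.
#' @param sigma_grid Kernel widths in mm; strictly increasing, >= 5 values.
#'   Default `seq(1, 20, by = 0.25)`.
#' @param trunc_k Kernel truncation radius in units of sigma.
#' @param only_significant Restrict to electrodes flagged significant
#'   (default `TRUE`).
#' @param method Correlation method, see [correlation_at_sigma()].
#' @param concavity_stencil_mm Central-difference half-width used when
#'   locating the concavity point of the fitted curve (see
#'   [concavity_sigma()]). The default of 2 mm — half the emulated voxel
#'   size — suppresses the sub-voxel curvature noise that raw one-step
#'   second differences amplify, while leaving curvature at anatomically
#'   meaningful scales untouched.
#' @return A `kernel_curve` object: per-sigma `r`, `r2`, `slope`, the
#'   summary widths described above, flags, `n_electrodes`, `band`.
#' @export
fit_kernel_curve <- function(zmap, electrodes,
                             sigma_grid = seq(1, 20, by = 0.25),
                             trunc_k = 6, only_significant = TRUE,
                             method = "pearson", concavity_stencil_mm = 2) {
  if (length(sigma_grid) < 5L)
    stop("sigma_grid needs at least 5 values", call. = FALSE)
  if (any(diff(sigma_grid) <= 0) || any(sigma_grid <= 0))
    stop("sigma_grid must be positive and strictly increasing", call. = FALSE)
  band <- if ("band" %in% names(electrodes)) unique(electrodes$band) else NA_character_
  if (length(band) > 1L)
    stop("electrode table mixes bands; filter to one band first", call. = FALSE)
  el <- electrodes
  if (only_significant && "significant" %in% names(el))
    el <- el[el$significant, , drop = FALSE]
  if (nrow(el) < 3L)
    stop(sprintf("need at least 3 %selectrodes, got %d",
                 if (only_significant) "significant " else "", nrow(el)),
         call. = FALSE)

  geom <- .electrode_gm_geometry(zmap, el[, c("x", "y", "z")])
  keep <- rep(TRUE, nrow(el))
  n_drop <- 0L
  # fix the electrode set: drop electrodes unreachable at the smallest sigma
  w0 <- .weighted_z_at_sigma(geom, sigma_grid[1], trunc_k)
  if (anyNA(w0)) {
    keep <- !is.na(w0)
    n_drop <- sum(!keep)
    warning(sprintf("dropping %d electrode(s) with no gray matter at sigma = %g mm",
                    n_drop, sigma_grid[1]), call. = FALSE)
    geom$d2 <- geom$d2[keep, , drop = FALSE]
    el <- el[keep, , drop = FALSE]
    if (nrow(el) < 3L) stop("fewer than 3 usable electrodes", call. = FALSE)
  }

  ns <- length(sigma_grid)
  r <- r2 <- slope <- numeric(ns)
  for (i in seq_len(ns)) {
    fz <- .weighted_z_at_sigma(geom, sigma_grid[i], trunc_k)
    cs <- correlation_at_sigma(el$z_score, fz, method = method)
    r[i] <- cs$r; r2[i] <- cs$r2; slope[i] <- cs$slope
  }

  peak_i <- which.max(r2)              # which.max takes the first maximum
  obj <- structure(
    list(sigma = sigma_grid, r = r, r2 = r2, slope = slope,
         n_electrodes = nrow(el), n_dropped = n_drop, band = band,
         method = method, trunc_k = trunc_k,
         electrodes = el$electrode,
         peak_sigma = sigma_grid[peak_i], peak_r2 = r2[peak_i],
         peak_slope = slope[peak_i],
         peak_on_boundary = peak_i == 1L || peak_i == ns,
         concavity_stencil_mm = concavity_stencil_mm),
    class = "kernel_curve"
  )
  cc <- concavity_sigma(obj, stencil_mm = concavity_stencil_mm)
  obj$concavity_sigma <- cc$sigma
  obj$concavity_r2 <- cc$r2
  obj$concavity_flag <- cc$flag
  obj$d2r2 <- cc$d2
  obj
}

#' Point of maximum downwards concavity of an r-squared curve
#'
#' Computes the discrete second derivative of `r2` over the uniform sigma
#' grid by central differences and returns the sigma at its most negative
#' (interior) value — the kernel width after which the gain in explained
#' variance from further smoothing tapers off. Ties (second derivative
#' equal within tolerance) resolve to the smallest sigma. If the second
#' derivative is nowhere negative, the curve has no downwards concavity
#' and `NA` is returned with a flag.
#'
#' @param curve A `kernel_curve`, or a list/data frame with `sigma` and
#'   `r2` components.
#' @param stencil_mm Half-width, in mm, of the central-difference stencil:
#'   `d2[i] = (r2[i+k] - 2 r2[i] + r2[i-k]) / (k h)^2` with
#'   `k = round(stencil_mm / h)`. The default `NULL` uses one grid step
#'   (`k = 1`), the plain discrete second derivative. Estimators working
#'   on noisy curves should widen the stencil: differentiation amplifies
#'   curve noise by `1/(k h)^2`, and curvature features narrower than the
#'   voxel size are not physically meaningful (see [fit_kernel_curve()]).
#' @param tol Absolute tolerance for ties and the no-concavity decision.
#' @return List with `sigma` (mm or `NA`), `r2` at that sigma, `flag`
#'   (`"ok"`, `"no_concavity"`), and `d2` (second derivative at the
#'   evaluable grid points, named by sigma).
#' @export
concavity_sigma <- function(curve, stencil_mm = NULL, tol = 1e-10) {
  sg <- curve$sigma; r2 <- curve$r2
  if (length(sg) < 5L) stop("need at least 5 grid points", call. = FALSE)
  h <- diff(sg)
  if (max(h) - min(h) > 1e-8 * mean(h))
    stop("sigma grid must be uniformly spaced for the second derivative",
         call. = FALSE)
  h <- mean(h)
  n <- length(sg)
  k <- if (is.null(stencil_mm)) 1L else max(1L, as.integer(round(stencil_mm / h)))
  if (n < 2L * k + 1L)
    stop("sigma grid too short for the requested stencil", call. = FALSE)
  interior <- (1L + k):(n - k)
  d2 <- (r2[interior + k] - 2 * r2[interior] + r2[interior - k]) / (k * h)^2
  names(d2) <- sg[interior]
  dmin <- min(d2)
  if (dmin >= -tol)
    return(list(sigma = NA_real_, r2 = NA_real_, flag = "no_concavity", d2 = d2))
  i <- which(d2 <= dmin + tol)[1]      # ties -> smallest sigma
  list(sigma = sg[interior][i], r2 = r2[interior][i], flag = "ok", d2 = d2)
}
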