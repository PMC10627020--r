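#' Simulate a 4D BOLD series from a synthetic truth field
#'
#' The spatial amplitude map is the ground-truth activation field blurred by
#' an isotropic Gaussian of width `sigma_true` (gray-matter restricted,
#' mass conserving, see [gm_blur()]). Every voxel's time series is
#'
#'   `baseline + amplitude * map * (boxcar (x) HRF) + drift + noise`
#'
#' with a linear drift plus one slow cosine (120 s period) scaled by
#' `drift_amplitude`, and two temporal noise components: spatially white
#' (thermal) noise of sd `bold_noise_sd`, and spatially correlated
#' (physiological) noise of sd `bold_phys_sd` whose correlation length is
#' `sigma_true` — fluctuations of neurovascular origin pass through the
#' same vascular point-spread as the evoked signal, and dominate thermal
#' noise at typical 3T voxel sizes. Noise is temporally white: the slow
#' part of real BOLD autocorrelation is carried by the drift terms, which
#' the 45 s high-pass is responsible for removing.
#'
#' @param scene A [make_scene()] object.
#' @param truth A [make_truth()] object.
#' @param design A [make_design()] object; the default scanner protocol is
#'   `make_design(4, 5, 30)`.
#' @param tr Volume repetition time in seconds (emulated protocol: 0.608 s).
#' @param baseline Mean signal level (arbitrary units).
#' @param amplitude Peak task-related signal change, in the same units, at
#'   field value 1 (default 1, i.e. a 1% change on a baseline of 100 —
#'   typical for a 3T motor block design).
#' @param seed Integer seed; defaults to the truth's seed.
#'
#' @return A `bold_series`: list with `data` (4D array x,y,z,t), `affine`,
#'   `tr`, and the blurred `amplitude_map` used to generate it.
#' @export
simulate_bold <- function(scene, truth, design = make_design(4, 5, 30),
                          tr = 0.608, baseline = 100, amplitude = 1,
                          seed = truth$seed) {
  stopifnot(inherits(scene, "synthetic_scene"), inherits(truth, "synthetic_truth"))
  check_scalar(tr, "tr")
  total_s <- design_total_duration(design)
  n_vols <- floor(total_s / tr)
  if (n_vols < 2L) stop("task design too short for the requested TR", call. = FALSE)

  # The point spread shapes the activation pattern; the observed response
  # amplitude (percent signal change) does not shrink with its width, so
  # the blurred map is rescaled to peak 1 and `amplitude` sets the peak.
  amap <- gm_blur(truth$field, scene$gm_mask, scene$affine, truth$sigma_true)
  if (max(amap) > 0) amap <- amap / max(amap)
  reg <- build_regressor(design, tr = tr, n_vols = n_vols, center = FALSE)

  dims <- dim(scene$gm_mask)
  n_vox <- prod(dims)
  tt <- (seq_len(n_vols) - 1) * tr
  drift_amp <- truth$noise$drift_amplitude
  noise_sd <- truth$noise$bold_noise_sd
  phys_sd <- if (is.null(truth$noise$bold_phys_sd)) 0 else truth$noise$bold_phys_sd

  data <- with_seed(seed, {
    slope <- stats::runif(n_vox, -1, 1)
    cosamp <- stats::runif(n_vox, -1, 1)
    phase <- stats::runif(n_vox, 0, 2 * pi)
    # time x voxel matrix
    Y <- outer(reg$values, as.vector(amap) * amplitude) + baseline
    Y <- Y + drift_amp * (outer((tt - total_s / 2) / total_s, slope) +
                          cos(outer(2 * pi * tt / 120, rep(1, n_vox)) +
                              matrix(phase, n_vols, n_vox, byrow = TRUE)) *
                          matrix(cosamp, n_vols, n_vox, byrow = TRUE))
    if (noise_sd > 0)
      Y <- Y + matrix(stats::rnorm(n_vols * n_vox, sd = noise_sd), n_vols, n_vox)
    if (phys_sd > 0 && truth$sigma_true >= 1e-6) {
      Ks <- .gm_kernel(scene$gm_mask, scene$affine, truth$sigma_true,
                       normalize = "sd")
      E <- matrix(stats::rnorm(n_vols * sum(scene$gm_mask), sd = phys_sd),
                  nrow = sum(scene$gm_mask))
      Y[, as.vector(scene$gm_mask)] <- Y[, as.vector(scene$gm_mask)] +
        t(Ks %*% E)
    } else if (phys_sd > 0) {
      Y[, as.vector(scene$gm_mask)] <- Y[, as.vector(scene$gm_mask)] +
        matrix(stats::rnorm(n_vols * sum(scene$gm_mask), sd = phys_sd),
               n_vols, sum(scene$gm_mask))
    }
    array(t(Y), dim = c(dims, n_vols))
  })

  structure(
    list(data = data, affine = scene$affine, tr = tr, amplitude_map = amap),
    class = "bold_series"
  )
}

#' @export
print.bold_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("BOLD series: %d x %d x %d voxels, %d volumes, TR %g s\n",
              d[1], d[2], d[3], d[4], x$tr))
  invisible(x)
}
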