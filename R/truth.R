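#' Build the ground-truth neural activation field for a synthetic scene
#'
#' The activation field emulates the two spatial scales of a motor-task
#' response: focal hotspots (`n_foci` Gaussian bumps of width
#' `focus_width_mm`, e.g. the hand-knob representation) riding on a broad
#' activation region (`background$n` bumps of width `background$width_mm`,
#' the sensorimotor strip, mixed in with weight `background$frac`). Both
#' components are normalized to maximum 1 before mixing, and the sum is
#' renormalized. The broad component gives the field structure larger than
#' the electrode grid, so correlations do not collapse under heavy
#' smoothing; the hotspots carry the fine structure from which the
#' ground-truth point-spread width `sigma_true` is recoverable.
#'
#' Default band effects follow the physiology of a motor task: power in the
#' high-frequency broadband (HFB, 65-95 Hz) increases during movement while
#' alpha (8-12 Hz) and beta (13-30 Hz) power decrease.
#'
#' @param scene A [make_scene()] object.
#' @param n_foci Number of activation foci (>= 1).
#' @param focus_width_mm Gaussian width (sd, mm) of each activation bump.
#' @param sigma_true Ground-truth spatial blur (sd, mm) of the BOLD response
#'   relative to the neural field.
#' @param seed Integer seed for focus placement (and, by default, for the
#'   downstream simulators).
#' @param band_effects Named list of signed fractional band-power changes at
#'   field value 1 during movement, for `hfb`, `alpha`, `beta`.
#' @param noise Named list of measurement-noise parameters:
#'   * `ecog_noise_sd` — uV scale of the broadband ECoG process;
#'   * `bold_noise_sd` — per-voxel sd of spatially white (thermal) BOLD
#'     noise, in signal units;
#'   * `bold_phys_sd` — per-voxel sd of spatially correlated
#'     (physiological) BOLD noise; fluctuations of neurovascular origin
#'     share the vascular point-spread, so this component is smoothed at
#'     `sigma_true` and dominates thermal noise at typical 3T voxel sizes;
#'   * `drift_amplitude` — scale of the linear + slow cosine drift;
#'   * `electrode_jitter_mm` — per-axis sd of the tangential electrode
#'     localization error (clinical estimates put grid localization
#'     accuracy below 2 mm). ECoG is simulated at the true positions; the
#'     analysis sees the jittered, "measured" coordinates.
#' @param background Broad activation component: list with `n` (bump
#'   count), `width_mm` (Gaussian width) and `frac` (mixing weight in
#'   `[0, 1)`); `NULL` disables it.
#'
#' @return A `synthetic_truth`: list with `field` (3D array, zero outside
#'   GM, max 1), `foci` (world-mm matrix), `sigma_true`, `band_effects`,
#'   `noise`, `seed`.
#' @export
make_truth <- function(scene, n_foci = 6, focus_width_mm = 4, sigma_true = 4,
                       seed = 1,
                       band_effects = list(hfb = 0.5, alpha = -0.4, beta = -0.4),
                       noise = list(ecog_noise_sd = 1, bold_noise_sd = 0.55,
                                    bold_phys_sd = 2.15, drift_amplitude = 2,
                                    electrode_jitter_mm = 1.5),
                       background = list(n = 2, width_mm = 25, frac = 0.6)) {
  stopifnot(inherits(scene, "synthetic_scene"))
  n_foci <- check_count(n_foci, "n_foci")
  check_scalar(focus_width_mm, "focus_width_mm")
  check_scalar(sigma_true, "sigma_true")
  stopifnot(all(c("hfb", "alpha", "beta") %in% names(band_effects)))
  if (is.null(background)) background <- list(n = 0, width_mm = 1, frac = 0)
  stopifnot(background$frac >= 0, background$frac < 1)

  gm_ijk <- mask_indices(scene$gm_mask)
  gm_xyz <- voxel_to_world(gm_ijk, scene$affine)
  bump_sum <- function(centers, w) {
    v <- numeric(nrow(gm_xyz))
    for (i in seq_len(nrow(centers))) {
      d2 <- rowSums(sweep(gm_xyz, 2, centers[i, ])^2)
      v <- v + exp(-d2 / (2 * w^2))
    }
    v / max(v)
  }
  n_bg <- if (background$frac > 0) background$n else 0
  picks <- with_seed(seed,
                     sample.int(nrow(gm_xyz), n_foci + n_bg, replace = FALSE))
  foci <- gm_xyz[picks[seq_len(n_foci)], , drop = FALSE]
  vals <- (1 - background$frac) * bump_sum(foci, focus_width_mm)
  if (n_bg > 0) {
    bg_centers <- gm_xyz[picks[n_foci + seq_len(n_bg)], , drop = FALSE]
    vals <- vals + background$frac * bump_sum(bg_centers, background$width_mm)
  }
  vals <- vals / max(vals)

  field <- array(0, dim = dim(scene$gm_mask))
  field[scene$gm_mask] <- vals

  if (is.null(noise$electrode_jitter_mm)) noise$electrode_jitter_mm <- 0
  if (is.null(noise$bold_phys_sd)) noise$bold_phys_sd <- 0
  structure(
    list(field = field, foci = foci, focus_width_mm = focus_width_mm,
         background = background, sigma_true = sigma_true,
         band_effects = band_effects, noise = noise,
         seed = as.integer(seed)),
    class = "synthetic_truth"
  )
}

#' Measured electrode coordinates with seeded localization error
#'
#' Real grid coordinates come from CT-MR coregistration followed by
#' brain-shift correction, which projects the contacts onto the pial
#' surface; the residual localization error is therefore mostly tangential
#' to the surface. This returns the scene's true electrode table with
#' seeded in-plane (x, y) Gaussian jitter of per-axis sd
#' `truth$noise$electrode_jitter_mm` added — the coordinates the analysis
#' (and the written `*_electrodes.tsv`) should see, while the ECoG
#' simulator records from the true positions.
#'
#' @param scene A [make_scene()] object.
#' @param truth A [make_truth()] object.
#' @param seed Integer seed (default derived from the truth's seed).
#' @return Electrode data frame (`name`, `x`, `y`, `z`) with jitter applied.
#' @export
measured_electrodes <- function(scene, truth, seed = truth$seed + 3L) {
  el <- scene$electrodes
  sd_mm <- truth$noise$electrode_jitter_mm
  if (is.null(sd_mm) || sd_mm <= 0) return(el)
  jit <- with_seed(seed, matrix(stats::rnorm(2L * nrow(el), sd = sd_mm), ncol = 2L))
  el$x <- el$x + jit[, 1]
  el$y <- el$y + jit[, 2]
  el
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("Synthetic truth: %d foci (width %g mm), sigma_true %g mm; effects hfb %+g, alpha %+g, beta %+g\n",
              nrow(x$foci), x$focus_width_mm, x$sigma_true,
              x$band_effects$hfb, x$band_effects$alpha, x$band_effects$beta))
  invisible(x)
}

#' Gray-matter-restricted, mass-conserving Gaussian blur of a voxel field
#'
#' Blurs a scalar field defined on gray-matter voxels with an isotropic 3D
#' Gaussian, restricting both sources and targets to GM. The kernel is
#' renormalized per source over the GM targets it reaches, so the total
#' field mass over GM is preserved exactly: activity cannot leak into
#' voxels outside gray matter, mirroring how the kernel-weighted analysis
#' itself only samples GM.
#'
#' @param field 3D array (values outside the mask are ignored).
#' @param gm_mask 3D logical array, same dimensions.
#' @param affine 4x4 voxel-to-world transform.
#' @param sigma_mm Blur width (sd, mm); values below 1e-6 return the field
#'   unchanged on GM.
#' @param trunc_k Kernel truncation radius in units of sigma.
#' @return 3D array: blurred field on GM, zero outside.
#' @export
gm_blur <- function(field, gm_mask, affine, sigma_mm, trunc_k = 6) {
  stopifnot(identical(dim(field), dim(gm_mask)))
  check_scalar(sigma_mm, "sigma_mm", positive = FALSE)
  out <- array(0, dim = dim(field))
  vals <- field[gm_mask]
  if (sigma_mm < 1e-6) {
    out[gm_mask] <- vals
    return(out)
  }
  K <- .gm_kernel(gm_mask, affine, sigma_mm, trunc_k, normalize = "mass")
  out[gm_mask] <- as.vector(K %*% vals)
  out
}

# Gaussian kernel matrix between GM voxel centers, truncated at trunc_k
# sigma. normalize = "mass": columns sum to 1 (each source distributes unit
# mass; mass-conserving blur). normalize = "sd": rows have unit L2 norm
# (K %*% white noise keeps per-voxel sd, giving spatially correlated noise).
.gm_kernel <- function(gm_mask, affine, sigma_mm, trunc_k = 6,
                       normalize = c("mass", "sd")) {
  normalize <- match.arg(normalize)
  gm_xyz <- voxel_to_world(mask_indices(gm_mask), affine)
  sq <- rowSums(gm_xyz^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(gm_xyz)
  K <- exp(-pmax(d2, 0) / (2 * sigma_mm^2))
  K[d2 > (trunc_k * sigma_mm)^2] <- 0
  if (normalize == "mass") sweep(K, 2, colSums(K), "/")
  else K / sqrt(rowSums(K^2))
}
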