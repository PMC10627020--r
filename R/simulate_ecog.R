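#' Default analysis frequency bands
#'
#' High-frequency broadband (HFB, 65-95 Hz), alpha (8-12 Hz) and beta
#' (13-30 Hz), the bands whose task modulation is compared against BOLD.
#'
#' @return Data frame with columns `name`, `f_lo`, `f_hi` (Hz).
#' @export
default_bands <- function() {
  data.frame(name = c("hfb", "alpha", "beta"),
             f_lo = c(65, 8, 13),
             f_hi = c(95, 12, 30),
             stringsAsFactors = FALSE)
}

# Ground-truth field value at each electrode: nearest GM voxel center.
field_at_electrodes <- function(scene, truth) {
  gm_ijk <- mask_indices(scene$gm_mask)
  gm_xyz <- voxel_to_world(gm_ijk, scene$affine)
  vals <- truth$field[scene$gm_mask]
  exyz <- as.matrix(scene$electrodes[, c("x", "y", "z")])
  sq <- rowSums(gm_xyz^2)
  out <- numeric(nrow(exyz))
  for (i in seq_len(nrow(exyz))) {
    d2 <- sq - 2 * (gm_xyz %*% exyz[i, ]) + sum(exyz[i, ]^2)
    out[i] <- vals[which.min(d2)]
  }
  out
}

# 0/1 movement indicator sampled at times `t` (seconds).
movement_indicator <- function(design, t) {
  mov <- design[design$trial_type == "movement", , drop = FALSE]
  ind <- logical(length(t))
  for (i in seq_len(nrow(mov)))
    ind <- ind | (t >= mov$onset[i] & t < mov$onset[i] + mov$duration[i])
  ind
}

#' Simulate a multichannel ECoG recording for a synthetic scene
#'
#' Each channel is broadband noise with a 1/f-shaped power spectrum,
#' constructed in the frequency domain and decomposed into the three
#' analysis bands plus an out-of-band remainder. During movement blocks the
#' band components are rescaled so that the power in band *b* is multiplied
#' by `1 + band_effects[b] * field(electrode)`, giving exact control of the
#' expected band-power modulation at every electrode.
#'
#' @param scene A [make_scene()] object (one channel per electrode).
#' @param truth A [make_truth()] object.
#' @param design A [make_design()] object; the default ECoG protocol is
#'   `make_design(5, 6, 30)`.
#' @param fs Sampling rate in Hz; must exceed twice the top analysis
#'   frequency. The emulated clinical system samples at 512 Hz.
#' @param bands Band table as from [default_bands()].
#' @param spectral_slope Exponent of the 1/f^slope power spectrum.
#' @param seed Integer seed; defaults to the truth's seed.
#'
#' @return An `ecog_recording`: list with `samples` (channels x time matrix,
#'   uV), `fs`, `channel_names`, `reference` (`"raw"`).
#' @export
simulate_ecog <- function(scene, truth, design = make_design(5, 6, 30),
                          fs = 512, bands = default_bands(),
                          spectral_slope = 1, seed = truth$seed) {
  stopifnot(inherits(scene, "synthetic_scene"), inherits(truth, "synthetic_truth"))
  check_scalar(fs, "fs")
  for (b in seq_len(nrow(bands))) {
    if (fs < 2 * bands$f_hi[b])
      stop(sprintf("fs = %g Hz is below twice the upper edge of band '%s' (%g Hz)",
                   fs, bands$name[b], bands$f_hi[b]), call. = FALSE)
  }
  total_s <- design_total_duration(design)
  n <- floor(total_s * fs)
  if (nrow(design) == 0L || n < 1L)
    stop("task design has zero duration", call. = FALSE)

  t <- (seq_len(n) - 1) / fs
  moving <- movement_indicator(design, t)
  fvals <- field_at_electrodes(scene, truth)
  effects <- truth$band_effects

  k <- 0:(n - 1)
  freq <- fs * pmin(k, n - k) / n          # symmetric frequency axis
  shape <- ifelse(freq > 0, freq^(-spectral_slope / 2), 0)
  band_mask <- lapply(seq_len(nrow(bands)), function(b)
    freq >= bands$f_lo[b] & freq <= bands$f_hi[b])
  names(band_mask) <- bands$name
  in_any <- Reduce("|", band_mask)
  rest_mask <- freq > 0 & !in_any

  n_ch <- nrow(scene$electrodes)
  samples <- with_seed(seed, {
    out <- matrix(0, nrow = n_ch, ncol = n)
    for (ch in seq_len(n_ch)) {
      X <- stats::fft(stats::rnorm(n)) * shape
      comp <- lapply(band_mask, function(m) Re(stats::fft(X * m, inverse = TRUE)) / n)
      x_rest <- Re(stats::fft(X * rest_mask, inverse = TRUE)) / n
      base <- Reduce("+", comp) + x_rest
      scl <- truth$noise$ecog_noise_sd / stats::sd(base)
      sig <- x_rest * scl
      for (b in bands$name) {
        gain <- rep(1, n)
        gain[moving] <- sqrt(max(0, 1 + effects[[b]] * fvals[ch]))
        sig <- sig + comp[[b]] * scl * gain
      }
      out[ch, ] <- sig
    }
    out
  })

  structure(
    list(samples = samples, fs = fs,
         channel_names = scene$electrodes$name, reference = "raw"),
    class = "ecog_recording"
  )
}

#' @export
print.ecog_recording <- function(x, ...) {
  cat(sprintf("ECoG recording: %d channels x %d samples at %g Hz (%s reference)\n",
              nrow(x$samples), ncol(x$samples), x$fs, x$reference))
  invisible(x)
}
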