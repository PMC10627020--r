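#' Screen ECoG channels by signal variance
#'
#' Flags channels with pathological signal levels (flat or artifactual) by
#' comparing each channel's variance with the distribution of the variances
#' of all other channels: channel *c* is rejected when its variance lies
#' outside `mean +/- k_sd * sd` of the remaining channels' variances
#' (leave-one-out, single pass over the original set, so a gross outlier
#' cannot mask itself).
#'
#' @param rec An `ecog_recording`.
#' @param k_sd Rejection threshold in standard deviations (default 3).
#' @return List with `retained` and `rejected` channel names and a `report`
#'   data frame (`channel`, `variance`, `lower`, `upper`, `rejected`).
#' @export
reject_channels <- function(rec, k_sd = 3) {
  stopifnot(inherits(rec, "ecog_recording"))
  check_scalar(k_sd, "k_sd")
  n_ch <- nrow(rec$samples)
  if (n_ch < 4L)
    stop("channel screening needs at least 4 channels", call. = FALSE)
  v <- apply(rec$samples, 1, stats::var)
  lower <- upper <- numeric(n_ch)
  rejected <- logical(n_ch)
  for (c in seq_len(n_ch)) {
    others <- v[-c]
    m <- mean(others); s <- stats::sd(others)
    lower[c] <- m - k_sd * s
    upper[c] <- m + k_sd * s
    rejected[c] <- v[c] < lower[c] | v[c] > upper[c]
  }
  report <- data.frame(channel = rec$channel_names, variance = v,
                       lower = lower, upper = upper, rejected = rejected,
                       stringsAsFactors = FALSE)
  list(retained = rec$channel_names[!rejected],
       rejected = rec$channel_names[rejected],
       report = report)
}

#' Re-reference an ECoG recording to the common average
#'
#' Subtracts, at every sample, the mean across the retained channels from
#' each retained channel. The output contains the retained channels only.
#'
#' @param rec An `ecog_recording`.
#' @param retained Channel names to keep; defaults to all.
#' @return The re-referenced `ecog_recording` (`reference = "common_average"`).
#' @export
common_average_reference <- function(rec, retained = rec$channel_names) {
  stopifnot(inherits(rec, "ecog_recording"))
  if (length(retained) == 0L)
    stop("no channels retained for common-average referencing", call. = FALSE)
  idx <- match(retained, rec$channel_names)
  if (anyNA(idx))
    stop("unknown channel name(s): ", paste(retained[is.na(idx)], collapse = ", "),
         call. = FALSE)
  sub <- rec$samples[idx, , drop = FALSE]
  car <- colMeans(sub)
  rec$samples <- sweep(sub, 2, car)
  rec$channel_names <- retained
  rec$reference <- "common_average"
  rec
}

#' Tile analysis windows within task blocks
#'
#' Tiles non-overlapping windows of length `win_s` from the onset of each
#' block; windows crossing a block boundary or running past the end of the
#' recording are dropped, so every window lies wholly inside one condition.
#'
#' @param rec An `ecog_recording`.
#' @param design A `task_design`.
#' @param win_s Window length in seconds (default 2).
#' @return Data frame with columns `onset` (s), `start` (1-based sample),
#'   `n_samples`, `condition`.
#' @export
segment_windows <- function(rec, design, win_s = 2) {
  stopifnot(inherits(rec, "ecog_recording"))
  check_scalar(win_s, "win_s")
  n_win_samp <- round(win_s * rec$fs)
  n_total <- ncol(rec$samples)
  rows <- list()
  for (b in seq_len(nrow(design))) {
    onset <- design$onset[b]
    n_fit <- floor(design$duration[b] / win_s)
    if (n_fit < 1L) next
    for (k in seq_len(n_fit)) {
      w_on <- onset + (k - 1) * win_s
      start <- round(w_on * rec$fs) + 1L
      if (start + n_win_samp - 1L > n_total) next
      rows[[length(rows) + 1L]] <- data.frame(
        onset = w_on, start = start, n_samples = n_win_samp,
        condition = design$trial_type[b], stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    stop("no analysis windows fit inside the task blocks", call. = FALSE)
  do.call(rbind, rows)
}

#' Mean log power of a signal window in a frequency band
#'
#' Computes a single Hanning-tapered periodogram of the (demeaned) window
#' and averages the natural-log power spectral density over the frequency
#' bins falling inside the band, both edges inclusive. A 2 s window gives
#' the 0.5 Hz bin grid of the standard analysis, so the 65-95 Hz band
#' averages 61 bins.
#'
#' @param x Numeric vector, one analysis window.
#' @param fs Sampling rate in Hz.
#' @param f_lo,f_hi Band edges in Hz (inclusive).
#' @param psd_floor PSD values below this floor are clipped before the log
#'   (guards degenerate all-zero windows; a warning is raised).
#' @return Mean log-PSD over the band's bins (unitless up to an additive
#'   constant shared by all windows).
#' @export
band_log_power <- function(x, fs, f_lo, f_hi, psd_floor = 1e-30) {
  n <- length(x)
  check_scalar(fs, "fs")
  if (!(0 < f_lo && f_lo < f_hi)) stop("need 0 < f_lo < f_hi", call. = FALSE)
  if (f_hi >= fs / 2)
    stop(sprintf("band edge %g Hz is at or above Nyquist (%g Hz)", f_hi, fs / 2),
         call. = FALSE)
  if (fs / n > 0.5 + 1e-9)
    stop(sprintf("window of %d samples at %g Hz gives %.3g Hz bins; need <= 0.5 Hz",
                 n, fs, fs / n), call. = FALSE)
  logp <- .log_psd(matrix(x, ncol = 1), fs)
  sel <- .band_bins(n, fs, f_lo, f_hi)
  if (any(logp[sel, 1] <= log(psd_floor) + 1e-12))
    warning("zero-power bins floored before log", call. = FALSE)
  mean(pmax(logp[sel, 1], log(psd_floor)))
}

# Hanning-tapered log periodogram of each column of `xm` (samples x windows).
# Returns log-PSD for bins k = 0..n/2 (rows).
.log_psd <- function(xm, fs, psd_floor = 1e-30) {
  n <- nrow(xm)
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
  xm <- sweep(xm, 2, colMeans(xm)) * w
  X <- stats::mvfft(xm)
  nk <- floor(n / 2) + 1L
  psd <- (Mod(X[seq_len(nk), , drop = FALSE])^2) / (fs * sum(w^2))
  # one-sided: double interior bins
  interior <- seq(2L, nk - if (n %% 2 == 0) 1L else 0L)
  psd[interior, ] <- 2 * psd[interior, ]
  log(pmax(psd, psd_floor))
}

.band_bins <- function(n, fs, f_lo, f_hi) {
  freqs <- (seq_len(floor(n / 2) + 1L) - 1L) * fs / n
  which(freqs >= f_lo - 1e-9 & freqs <= f_hi + 1e-9)
}

#' Two-sample comparison of window band powers at one electrode
#'
#' Pooled-variance unpaired two-sample t-test of movement versus rest
#' window log powers, converted to a signed z-score through the two-sided
#' p-value and the standard-normal quantile. Significance is assessed at
#' `alpha_electrode` without multiple-comparison correction: the flag is
#' used only to select responsive electrodes, not as a study outcome.
#'
#' @param powers_movement,powers_rest Numeric vectors of per-window log
#'   band power (>= 2 each).
#' @param alpha_electrode Significance level (default 0.05).
#' @param welch Use Welch's unequal-variance t instead of the pooled test.
#' @param z_cap Cap on |z| (and the p-value floor it implies).
#' @return List with `t_stat`, `df`, `p_value`, `z_score`, `significant`.
#' @export
electrode_band_zscores <- function(powers_movement, powers_rest,
                                   alpha_electrode = 0.05, welch = FALSE,
                                   z_cap = Z_CAP) {
  n1 <- length(powers_movement); n2 <- length(powers_rest)
  if (n1 < 2L || n2 < 2L)
    stop("need at least 2 windows per condition", call. = FALSE)
  m1 <- mean(powers_movement); m2 <- mean(powers_rest)
  v1 <- stats::var(powers_movement); v2 <- stats::var(powers_rest)
  if (welch) {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  if (se == 0) {
    if (m1 == m2) {
      t_stat <- 0; z <- 0; p <- 1
    } else {
      warning("zero pooled variance with unequal means; z capped", call. = FALSE)
      t_stat <- sign(m1 - m2) * Inf
      z <- sign(m1 - m2) * z_cap
      p <- 0
    }
  } else {
    t_stat <- (m1 - m2) / se
    p <- 2 * stats::pt(-abs(t_stat), df = df)
    z <- t_to_z(t_stat, df, z_cap)
  }
  list(t_stat = t_stat, df = df, p_value = p, z_score = z,
       significant = p < alpha_electrode)
}

#' Per-electrode band z-scores for a referenced ECoG recording
#'
#' Runs the full electrode-level analysis: windows are tiled inside the
#' task blocks, per-window log band power is computed for each channel and
#' band, and movement versus rest powers are compared with
#' [electrode_band_zscores()]. Electrode coordinates are joined from the
#' electrodes table by channel name.
#'
#' @param rec A (typically common-average referenced) `ecog_recording`.
#' @param design A `task_design`.
#' @param electrodes Data frame with `name`, `x`, `y`, `z` (world mm).
#' @param bands Band table as from [default_bands()].
#' @param win_s Window length in seconds.
#' @param alpha_electrode Electrode-inclusion significance level.
#' @param welch Use Welch's t-test.
#' @return Data frame (one row per electrode x band): `electrode`, `band`,
#'   `t_stat`, `z_score`, `p_value`, `significant`, `x`, `y`, `z`.
#' @export
ecog_band_responses <- function(rec, design, electrodes,
                                bands = default_bands(), win_s = 2,
                                alpha_electrode = 0.05, welch = FALSE) {
  stopifnot(inherits(rec, "ecog_recording"))
  if (any(bands$f_hi >= rec$fs / 2))
    stop("band upper edge at or above Nyquist for this recording", call. = FALSE)
  wins <- segment_windows(rec, design, win_s)
  if (!any(wins$condition == "movement") || !any(wins$condition == "rest"))
    stop("need windows in both the movement and the rest condition", call. = FALSE)
  exyz <- electrodes[match(rec$channel_names, electrodes$name),
                     c("x", "y", "z"), drop = FALSE]
  n <- wins$n_samples[1]
  out <- vector("list", nrow(rec$samples) * nrow(bands))
  k <- 0L
  for (ch in seq_len(nrow(rec$samples))) {
    segs <- vapply(seq_len(nrow(wins)), function(w)
      rec$samples[ch, wins$start[w]:(wins$start[w] + n - 1L)], numeric(n))
    logp <- .log_psd(segs, rec$fs)
    for (b in seq_len(nrow(bands))) {
      sel <- .band_bins(n, rec$fs, bands$f_lo[b], bands$f_hi[b])
      bp <- colMeans(logp[sel, , drop = FALSE])
      res <- electrode_band_zscores(bp[wins$condition == "movement"],
                                    bp[wins$condition == "rest"],
                                    alpha_electrode = alpha_electrode,
                                    welch = welch)
      k <- k + 1L
      out[[k]] <- data.frame(
        electrode = rec$channel_names[ch], band = bands$name[b],
        t_stat = res$t_stat, z_score = res$z_score, p_value = res$p_value,
        significant = res$significant,
        x = exyz$x[ch], y = exyz$y[ch], z = exyz$z[ch],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
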