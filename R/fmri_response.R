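#' Gaussian-weighted running-line high-pass filter
#'
#' Removes slow trends from fMRI time series by Gaussian-weighted
#' least-squares straight-line fitting: at every time point a straight line
#' is fit to the series with Gaussian weights (sd `sigma_s` seconds)
#' centered there, the fitted value is subtracted, and the series mean is
#' added back. Weights are truncated at the series bounds and renormalized
#' implicitly by the weighted fit. Because the local-line fit reproduces
#' constants and straight lines exactly, those survive only through the
#' restored mean.
#'
#' @param y Numeric vector, or a time-by-series matrix filtered columnwise.
#' @param tr Sampling interval in seconds.
#' @param sigma_s Gaussian weight width in seconds (default 45 s).
#' @return Filtered series, same shape as `y`.
#' @export
highpass_gaussian_line <- function(y, tr, sigma_s = 45) {
  check_scalar(tr, "tr")
  check_scalar(sigma_s, "sigma_s")
  ym <- if (is.matrix(y)) y else matrix(y, ncol = 1)
  n <- nrow(ym)
  if (n < 3L) stop("series must have at least 3 samples", call. = FALSE)
  S <- .runline_smoother(n, tr, sigma_s)
  out <- ym - S %*% ym
  out <- sweep(out, 2, colMeans(ym), "+")
  if (is.matrix(y)) out else as.vector(out)
}

# Smoother matrix of the Gaussian-weighted local linear fit: row i gives the
# weights producing the fitted value at time i.
.runline_smoother <- function(n, tr, sigma_s) {
  t <- (seq_len(n) - 1) * tr
  D <- outer(t, t, "-")                 # D[i, j] = t_i - t_j
  W <- exp(-D^2 / (2 * sigma_s^2))
  S0 <- rowSums(W)
  S1 <- rowSums(W * (-D))               # sum_j w (t_j - t_i)
  S2 <- rowSums(W * D^2)
  # fitted value at t_i: sum_j w_ij [S2 - (t_j - t_i) S1] / (S0 S2 - S1^2)
  num <- W * (S2 - (-D) * S1)
  num / (S0 * S2 - S1^2)
}

#' Canonical double-gamma hemodynamic response function
#'
#' Samples the standard double-gamma HRF — a gamma density peaking near
#' 5-6 s minus 1/6 of a gamma density peaking near 15-16 s (the
#' post-stimulus undershoot) — on a grid of spacing `dt` over `length_s`
#' seconds, normalized to unit sum so convolution preserves boxcar mass.
#'
#' @param dt Sampling interval in seconds.
#' @param peak_delay,undershoot_delay Gamma shape parameters (rate 1, s).
#' @param ratio Undershoot amplitude relative to the peak.
#' @param length_s Kernel support in seconds.
#' @return Numeric vector of kernel samples at `seq(0, length_s, by = dt)`.
#' @export
canonical_hrf <- function(dt, peak_delay = 6, undershoot_delay = 16,
                          ratio = 1 / 6, length_s = 32) {
  check_scalar(dt, "dt")
  t <- seq(0, length_s, by = dt)
  h <- stats::dgamma(t, shape = peak_delay, rate = 1) -
    ratio * stats::dgamma(t, shape = undershoot_delay, rate = 1)
  h / sum(h)
}

#' Build the task regressor for the block-design GLM
#'
#' Samples a boxcar (1 during movement blocks, 0 otherwise) on a fine time
#' grid, convolves it with the canonical HRF, reads it out at the volume
#' acquisition times `(i - 1) * tr`, and (optionally) mean-centers it.
#'
#' @param design A `task_design`.
#' @param tr Volume repetition time in seconds.
#' @param n_vols Number of volumes.
#' @param dt Internal convolution grid spacing in seconds.
#' @param center Mean-center the sampled regressor (default `TRUE`, as used
#'   in the GLM; the simulator uses the uncentered version).
#' @param hrf_params Optional named list overriding [canonical_hrf()]
#'   arguments (`peak_delay`, `undershoot_delay`, `ratio`, `length_s`).
#' @return An `fmri_regressor`: list with `values` (length `n_vols`),
#'   `values_raw` (uncentered), `boxcar_highres`, `conv_highres`, `dt`,
#'   `tr`, `hrf_params`.
#' @export
build_regressor <- function(design, tr, n_vols, dt = 0.1, center = TRUE,
                            hrf_params = list()) {
  check_scalar(tr, "tr")
  n_vols <- check_count(n_vols, "n_vols", min = 2L)
  if (nrow(design) == 0L) stop("empty task design", call. = FALSE)
  total_s <- design_total_duration(design)
  t_hi <- seq(0, total_s + 32, by = dt)
  box <- as.numeric(movement_indicator(design, t_hi))
  hrf <- do.call(canonical_hrf, c(list(dt = dt), hrf_params))
  conv <- stats::convolve(box, rev(hrf), type = "open")[seq_along(t_hi)]
  t_vol <- (seq_len(n_vols) - 1) * tr
  idx <- pmin(length(t_hi), round(t_vol / dt) + 1L)
  raw <- conv[idx]
  structure(
    list(values = if (center) raw - mean(raw) else raw,
         values_raw = raw, boxcar_highres = box, conv_highres = conv,
         dt = dt, tr = tr,
         hrf_params = utils::modifyList(
           list(peak_delay = 6, undershoot_delay = 16, ratio = 1 / 6,
                length_s = 32), hrf_params)),
    class = "fmri_regressor"
  )
}

#' Gray-matter-restricted voxelwise GLM z-map
#'
#' For each gray-matter voxel, high-pass filters the time series
#' ([highpass_gaussian_line()]) and fits ordinary least squares on an
#' intercept plus the task regressor; the regressor is passed through the
#' same filter so that design and data are treated identically. The
#' regressor t statistic (`df = n_vols - 2`) is converted to a signed
#' z-score through the two-sided p-value, capped at `+/- z_cap`. Voxels
#' outside the mask are `NA`; zero-variance voxels get `z = 0` and are
#' flagged.
#'
#' @param bold A `bold_series` (or 4D array with `affine`/`tr` attributes).
#' @param reg An `fmri_regressor` built for the same number of volumes.
#' @param gm_mask 3D logical array matching the spatial dimensions.
#' @param sigma_s High-pass width in seconds; `NULL` skips filtering.
#' @param z_cap Cap on |z|.
#' @return A `zmap`: list with `z` (3D array, `NA` off-mask), `gm_mask`,
#'   `affine`, `beta` (regressor coefficients on GM), `t_gm` and `df`
#'   (the underlying t statistics), and a `stats` list
#'   (`n_gm`, `max_z`, `min_z`, `pct_sig` at |z| > 1.96, `n_flagged`).
#' @export
glm_zmap <- function(bold, reg, gm_mask, sigma_s = 45, z_cap = Z_CAP) {
  stopifnot(inherits(bold, "bold_series"), inherits(reg, "fmri_regressor"))
  dims <- dim(bold$data)
  if (!identical(dims[1:3], dim(gm_mask)))
    stop("gray-matter mask dimensions do not match the BOLD volume", call. = FALSE)
  n_vols <- dims[4]
  if (length(reg$values) != n_vols)
    stop("regressor length does not match the number of volumes", call. = FALSE)
  x <- reg$values
  if (stats::sd(x) == 0) stop("constant task regressor", call. = FALSE)

  Y <- t(matrix(bold$data, nrow = prod(dims[1:3]))[gm_mask, , drop = FALSE])
  if (!is.null(sigma_s)) {
    Y <- highpass_gaussian_line(Y, bold$tr, sigma_s)
    x <- highpass_gaussian_line(x, bold$tr, sigma_s)
  }

  xc <- x - mean(x)
  sxx <- sum(xc^2)
  ym <- colMeans(Y)
  beta <- as.vector(crossprod(Y, xc)) / sxx
  fitted <- outer(xc, beta) + matrix(ym, n_vols, ncol(Y), byrow = TRUE)
  rss <- colSums((Y - fitted)^2)
  df <- n_vols - 2
  se <- sqrt(rss / df / sxx)
  # numerically degenerate voxels: variation below ~1e-8 of the signal
  # scale (flat series up to floating-point noise) are reported as z = 0
  zero_var <- colSums(sweep(Y, 2, ym)^2) <=
    n_vols * (1e-8 * (abs(ym) + 1))^2
  t_stat <- ifelse(se > 0, beta / se, ifelse(beta == 0, 0, sign(beta) * Inf))
  z <- vapply(t_stat, t_to_z, numeric(1), df = df, z_cap = z_cap)
  z[zero_var] <- 0

  zvol <- array(NA_real_, dim = dims[1:3])
  zvol[gm_mask] <- z
  structure(
    list(z = zvol, gm_mask = gm_mask, affine = bold$affine, beta = beta,
         t_gm = t_stat, df = df,
         stats = list(n_gm = sum(gm_mask), max_z = max(z), min_z = min(z),
                      pct_sig = 100 * mean(abs(z) > 1.96),
                      n_flagged = sum(zero_var))),
    class = "zmap"
  )
}

#' @export
print.zmap <- function(x, ...) {
  s <- x$stats
  cat(sprintf("GM z-map: %d voxels, z range [%.2f, %.2f], %.1f%% with |z| > 1.96\n",
              s$n_gm, s$min_z, s$max_z, s$pct_sig))
  invisible(x)
}
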