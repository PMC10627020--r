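#' Default run configuration
#'
#' All tunable parameters of the pipeline in one nested list. The analysis
#' defaults mirror the emulated study protocol: 2 s Hanning windows, 0.05
#' electrode-inclusion alpha, 45 s high-pass, kernel widths 1-20 mm in
#' 0.25 mm steps with truncation at 4 sigma. Synthetic-data defaults: 512
#' Hz ECoG sampling, TR 0.608 s, 4 mm voxels, an 8 x 8 grid at 10 mm
#' pitch, 4 movement / 5 rest 30 s blocks in the scanner session (4 min
#' 30 s) and 5 movement / 6 rest during the ECoG session (5 min 30 s);
#' rest blocks open and close both sessions.
#'
#' @param ... Named overrides merged into the defaults (nested lists are
#'   merged recursively).
#' @return A validated config list.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1L,
    bands = default_bands(),
    window_s = 2,
    alpha_electrode = 0.05,
    welch = FALSE,
    highpass_sigma_s = 45,
    sigma_grid = list(from = 1, to = 20, by = 0.25),
    trunc_k = 6,
    correlation = "pearson",
    concavity_stencil_mm = 2,
    synthetic = list(
      grid_shape = c(8, 8), pitch_mm = 10, voxel_mm = 4,
      sheet_thickness_mm = 8, margin_mm = 12,
      n_foci = 6, focus_width_mm = 4, sigma_true = 4,
      background = list(n = 2, width_mm = 25, frac = 0.6),
      band_effects = list(hfb = 0.5, alpha = -0.4, beta = -0.4),
      noise = list(ecog_noise_sd = 1, bold_noise_sd = 0.55, bold_phys_sd = 2.15,
                   drift_amplitude = 2, electrode_jitter_mm = 1.5),
      fs = 512, tr = 0.608,
      bold_baseline = 100, bold_amplitude = 1,
      design_ecog = c(5, 6, 30), design_bold = c(4, 5, 30)
    )
  )
  over <- list(...)
  if (length(over)) cfg <- utils::modifyList(cfg, over)
  validate_config(cfg)
}

#' Validate a run configuration
#'
#' @param config A config list as from [default_config()].
#' @return The config, invisibly normalized; errors on invalid entries.
#' @export
validate_config <- function(config) {
  stopifnot(is.list(config))
  check_scalar(config$window_s, "window_s")
  check_scalar(config$highpass_sigma_s, "highpass_sigma_s")
  check_scalar(config$trunc_k, "trunc_k")
  if (!(config$alpha_electrode > 0 && config$alpha_electrode < 1))
    stop("alpha_electrode must be in (0, 1)", call. = FALSE)
  g <- config$sigma_grid
  if (!(g$from > 0 && g$to > g$from && g$by > 0))
    stop("sigma_grid must satisfy 0 < from < to with by > 0", call. = FALSE)
  if (!all(c("name", "f_lo", "f_hi") %in% names(config$bands)))
    stop("bands must have columns name, f_lo, f_hi", call. = FALSE)
  if (any(config$bands$f_lo <= 0) || any(config$bands$f_hi <= config$bands$f_lo))
    stop("each band needs 0 < f_lo < f_hi", call. = FALSE)
  config
}

#' Read a serialized run configuration
#'
#' Reads a configuration written as JSON (as done for provenance by
#' [run_subject()]) back into the nested-list form used by the pipeline,
#' so a recorded run can be repeated exactly.
#'
#' @param path Path to a config JSON file.
#' @return A validated config list.
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$bands <- as.data.frame(cfg$bands, stringsAsFactors = FALSE)
  validate_config(cfg)
}

config_sigma_grid <- function(config) {
  g <- config$sigma_grid
  seq(g$from, g$to, by = g$by)
}

log_stage <- function(subject, stage, msg, log_con = NULL) {
  line <- sprintf("[%s] %s %s: %s", format(Sys.time(), "%H:%M:%S"),
                  subject, stage, msg)
  message(line)
  if (!is.null(log_con)) writeLines(line, log_con)
  invisible(line)
}

#' Run the full per-subject analysis over a subject directory
#'
#' Orchestrates the staged analysis on a BIDS-like subject tree: optional
#' synthetic data generation, ECoG electrode responses, the GM-restricted
#' GLM z-map, and the kernel-width correlation curve per band. Outputs are
#' written under `derivatives/<subject>/`, together with the serialized
#' configuration for provenance; re-running with the same config and seed
#' overwrites the outputs deterministically.
#'
#' @param root Dataset root directory.
#' @param subject Subject label (e.g. `"sub-01"`).
#' @param config Run configuration, see [default_config()].
#' @param stages Character vector among `"simulate"`, `"ecog"`, `"fmri"`,
#'   `"kernel"`; `"all"` expands to all four.
#' @param seed Seed for the simulate stage (default `config$seed`).
#' @return Invisibly, a list with the per-band `kernel_curve` objects
#'   (`NULL` for skipped bands), the `summary` data frame, and paths of
#'   all written files.
#' @export
run_subject <- function(root, subject, config = default_config(),
                        stages = "all", seed = config$seed) {
  config <- validate_config(config)
  if ("all" %in% stages) stages <- c("simulate", "ecog", "fmri", "kernel")
  p <- subject_paths(root, subject)
  dir.create(p$deriv, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(p$deriv, paste0(subject, "_log.txt"))
  log_con <- file(log_path, open = "a")
  on.exit(close(log_con))
  written <- character()

  if ("simulate" %in% stages) {
    t0 <- Sys.time()
    write_synthetic_subject(root, subject, config, seed = seed)
    log_stage(subject, "simulate",
              sprintf("synthetic data written (seed %d, %.1f s)", seed,
                      as.numeric(Sys.time() - t0, units = "secs")), log_con)
  }

  resp_path <- file.path(p$deriv, paste0(subject, "_electrodes_response.tsv"))
  if ("ecog" %in% stages) {
    t0 <- Sys.time()
    ec <- read_subject_ecog(root, subject)
    scr <- reject_channels(ec$rec)
    rec <- common_average_reference(ec$rec, scr$retained)
    resp <- ecog_band_responses(rec, ec$design, ec$electrodes,
                                bands = config$bands, win_s = config$window_s,
                                alpha_electrode = config$alpha_electrode,
                                welch = config$welch)
    write_tsv(resp, resp_path)
    written <- c(written, resp_path)
    log_stage(subject, "ecog",
              sprintf("%d channels kept (%d rejected), %d significant responses (%.1f s)",
                      length(scr$retained), length(scr$rejected),
                      sum(resp$significant),
                      as.numeric(Sys.time() - t0, units = "secs")), log_con)
  }

  zmap_path <- file.path(p$deriv, paste0(subject, "_zmap.nii.gz"))
  zsum_path <- file.path(p$deriv, paste0(subject, "_zmap_summary.tsv"))
  if ("fmri" %in% stages) {
    t0 <- Sys.time()
    fm <- read_subject_fmri(root, subject)
    reg <- build_regressor(fm$design, tr = fm$bold$tr, n_vols = dim(fm$bold$data)[4])
    zm <- glm_zmap(fm$bold, reg, fm$gm_mask, sigma_s = config$highpass_sigma_s)
    zout <- zm$z
    zout[is.na(zout)] <- 0
    write_nifti_vol(zout, zm$affine, zmap_path,
                    pixdim = abs(zm$affine[1, 1]))
    write_tsv(data.frame(n_gm = zm$stats$n_gm, max_z = zm$stats$max_z,
                         min_z = zm$stats$min_z, pct_sig = zm$stats$pct_sig),
              zsum_path)
    written <- c(written, zmap_path, zsum_path)
    log_stage(subject, "fmri",
              sprintf("z-map on %d GM voxels, z in [%.1f, %.1f] (%.1f s)",
                      zm$stats$n_gm, zm$stats$min_z, zm$stats$max_z,
                      as.numeric(Sys.time() - t0, units = "secs")), log_con)
  }

  curves <- list()
  summary_rows <- list()
  if ("kernel" %in% stages) {
    t0 <- Sys.time()
    resp <- read_tsv(resp_path)
    zm_file <- read_nifti_vol(zmap_path)
    gm <- read_nifti_vol(p$gm_mask)
    zvol <- zm_file$data
    gm_mask <- gm$data > 0.5
    zvol[!gm_mask] <- NA_real_
    zmap <- structure(list(z = zvol, gm_mask = gm_mask, affine = zm_file$affine),
                      class = "zmap")
    grid <- config_sigma_grid(config)
    for (b in config$bands$name) {
      el <- resp[resp$band == b, , drop = FALSE]
      n_sig <- sum(el$significant)
      if (n_sig < 3L) {
        log_stage(subject, "kernel",
                  sprintf("band %s skipped: %d significant electrodes (< 3)", b, n_sig),
                  log_con)
        curves[[b]] <- NULL
        summary_rows[[b]] <- data.frame(
          subject = subject, band = b, skipped = TRUE, n_electrodes = n_sig,
          peak_sigma = NA_real_, peak_r2 = NA_real_, peak_slope = NA_real_,
          peak_on_boundary = NA, concavity_sigma = NA_real_,
          concavity_r2 = NA_real_, concavity_flag = "skipped",
          stringsAsFactors = FALSE)
        next
      }
      kc <- fit_kernel_curve(zmap, el, sigma_grid = grid,
                             trunc_k = config$trunc_k,
                             method = config$correlation,
                             concavity_stencil_mm = config$concavity_stencil_mm)
      curves[[b]] <- kc
      curve_path <- file.path(p$deriv,
                              sprintf("%s_band-%s_kernel_curve.tsv", subject, b))
      sum_path <- file.path(p$deriv,
                            sprintf("%s_band-%s_kernel_summary.json", subject, b))
      write_tsv(as.data.frame(kc), curve_path)
      jsonlite::write_json(
        list(band = b, n_electrodes = kc$n_electrodes,
             peak_sigma = kc$peak_sigma, peak_r2 = kc$peak_r2,
             peak_slope = kc$peak_slope,
             peak_on_boundary = kc$peak_on_boundary,
             concavity_sigma = kc$concavity_sigma,
             concavity_r2 = kc$concavity_r2,
             concavity_flag = kc$concavity_flag),
        sum_path, auto_unbox = TRUE, digits = NA, na = "null")
      written <- c(written, curve_path, sum_path)
      summary_rows[[b]] <- data.frame(
        subject = subject, band = b, skipped = FALSE,
        n_electrodes = kc$n_electrodes,
        peak_sigma = kc$peak_sigma, peak_r2 = kc$peak_r2,
        peak_slope = kc$peak_slope, peak_on_boundary = kc$peak_on_boundary,
        concavity_sigma = kc$concavity_sigma, concavity_r2 = kc$concavity_r2,
        concavity_flag = kc$concavity_flag, stringsAsFactors = FALSE)
      log_stage(subject, "kernel",
                sprintf("band %s: peak %.2f mm (r2 %.2f), concavity %s", b,
                        kc$peak_sigma, kc$peak_r2,
                        if (kc$concavity_flag == "ok")
                          sprintf("%.2f mm", kc$concavity_sigma) else "none"),
                log_con)
    }
    log_stage(subject, "kernel",
              sprintf("done (%.1f s)", as.numeric(Sys.time() - t0, units = "secs")),
              log_con)
  }

  cfg_path <- file.path(p$deriv, paste0(subject, "_config.json"))
  jsonlite::write_json(config, cfg_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  written <- c(written, cfg_path)
  invisible(list(curves = curves,
                 summary = if (length(summary_rows))
                   do.call(rbind, summary_rows) else NULL,
                 files = written, log = log_path))
}

#' Run one synthetic subject fully in memory
#'
#' Generates a synthetic subject and runs the complete analysis without
#' touching the filesystem — the path used for simulation studies
#' (parameter sweeps over many seeds).
#'
#' @param config Run configuration, see [default_config()].
#' @param seed Integer seed for this subject.
#' @return List with the per-band `kernel_curve` objects (`curves`,
#'   `NULL` where skipped), the per-band `summary` data frame, the
#'   electrode response table (`responses`), the `zmap`, and the ground
#'   truth (`truth`).
#' @export
run_synthetic_subject <- function(config = default_config(), seed = config$seed) {
  config <- validate_config(config)
  syn <- config$synthetic
  scene <- make_scene(grid_shape = syn$grid_shape, pitch_mm = syn$pitch_mm,
                      voxel_mm = syn$voxel_mm,
                      sheet_thickness_mm = syn$sheet_thickness_mm,
                      margin_mm = syn$margin_mm, seed = seed)
  truth <- make_truth(scene, n_foci = syn$n_foci,
                      focus_width_mm = syn$focus_width_mm,
                      sigma_true = syn$sigma_true, seed = seed,
                      band_effects = syn$band_effects, noise = syn$noise,
                      background = syn$background)
  design_ecog <- do.call(make_design, as.list(syn$design_ecog))
  design_bold <- do.call(make_design, as.list(syn$design_bold))
  ecog <- simulate_ecog(scene, truth, design_ecog, fs = syn$fs,
                        bands = config$bands, seed = seed + 1L)
  bold <- simulate_bold(scene, truth, design_bold, tr = syn$tr,
                        baseline = syn$bold_baseline,
                        amplitude = syn$bold_amplitude, seed = seed + 2L)

  scr <- reject_channels(ecog)
  rec <- common_average_reference(ecog, scr$retained)
  resp <- ecog_band_responses(rec, design_ecog, measured_electrodes(scene, truth),
                              bands = config$bands, win_s = config$window_s,
                              alpha_electrode = config$alpha_electrode,
                              welch = config$welch)
  reg <- build_regressor(design_bold, tr = bold$tr, n_vols = dim(bold$data)[4])
  zmap <- glm_zmap(bold, reg, scene$gm_mask, sigma_s = config$highpass_sigma_s)

  grid <- config_sigma_grid(config)
  curves <- list()
  rows <- list()
  for (b in config$bands$name) {
    el <- resp[resp$band == b, , drop = FALSE]
    if (sum(el$significant) < 3L) {
      curves[[b]] <- NULL
      rows[[b]] <- data.frame(
        subject = NA_character_, band = b, skipped = TRUE,
        n_electrodes = sum(el$significant), peak_sigma = NA_real_,
        peak_r2 = NA_real_, peak_slope = NA_real_, peak_on_boundary = NA,
        concavity_sigma = NA_real_, concavity_r2 = NA_real_,
        concavity_flag = "skipped", stringsAsFactors = FALSE)
      next
    }
    kc <- fit_kernel_curve(zmap, el, sigma_grid = grid,
                           trunc_k = config$trunc_k,
                           method = config$correlation,
                           concavity_stencil_mm = config$concavity_stencil_mm)
    curves[[b]] <- kc
    rows[[b]] <- data.frame(
      subject = NA_character_, band = b, skipped = FALSE,
      n_electrodes = kc$n_electrodes, peak_sigma = kc$peak_sigma,
      peak_r2 = kc$peak_r2, peak_slope = kc$peak_slope,
      peak_on_boundary = kc$peak_on_boundary,
      concavity_sigma = kc$concavity_sigma, concavity_r2 = kc$concavity_r2,
      concavity_flag = kc$concavity_flag, stringsAsFactors = FALSE)
  }
  list(curves = curves, summary = do.call(rbind, rows), responses = resp,
       zmap = zmap, truth = truth, scene = scene)
}

#' Aggregate per-subject kernel summaries into group statistics
#'
#' Computes, per band, the group mean, sample (n-1) standard deviation and
#' range of the peak kernel width, peak explained variance, slope at the
#' peak, and concavity width. Subjects whose peak sits on the grid
#' boundary are excluded from the peak statistics (a boundary argmax is
#' censored, not estimated) but counted; subjects with no downwards
#' concavity, or skipped bands, are likewise excluded from the concavity
#' statistics and counted.
#'
#' @param summaries A data frame row-binding the `summary` components of
#'   [run_subject()] / [run_synthetic_subject()] results.
#' @return A `group_summary`: data frame with one row per band.
#' @export
aggregate_group <- function(summaries) {
  stopifnot(is.data.frame(summaries), nrow(summaries) > 0)
  need <- c("band", "skipped", "peak_sigma", "peak_r2", "peak_slope",
            "peak_on_boundary", "concavity_sigma", "concavity_flag")
  stopifnot(all(need %in% names(summaries)))
  sd_or_na <- function(x) if (length(x) >= 2L) stats::sd(x) else NA_real_
  rows <- lapply(split(summaries, summaries$band), function(d) {
    ok <- !d$skipped
    if (!any(ok)) stop("no unskipped subjects for band ", d$band[1], call. = FALSE)
    peak_ok <- ok & !d$peak_on_boundary
    conc_ok <- ok & d$concavity_flag == "ok"
    data.frame(
      band = d$band[1],
      n_subjects = sum(ok),
      n_boundary_excluded = sum(ok) - sum(peak_ok),
      n_no_concavity = sum(ok) - sum(conc_ok),
      peak_sigma_mean = if (any(peak_ok)) mean(d$peak_sigma[peak_ok]) else NA_real_,
      peak_sigma_sd = sd_or_na(d$peak_sigma[peak_ok]),
      peak_sigma_min = if (any(peak_ok)) min(d$peak_sigma[peak_ok]) else NA_real_,
      peak_sigma_max = if (any(peak_ok)) max(d$peak_sigma[peak_ok]) else NA_real_,
      peak_r2_mean = mean(d$peak_r2[ok]),
      peak_r2_sd = sd_or_na(d$peak_r2[ok]),
      slope_mean = mean(d$peak_slope[ok]),
      slope_sd = sd_or_na(d$peak_slope[ok]),
      concavity_sigma_mean = if (any(conc_ok)) mean(d$concavity_sigma[conc_ok]) else NA_real_,
      concavity_sigma_sd = sd_or_na(d$concavity_sigma[conc_ok]),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("group_summary", "data.frame")
  out
}

#' @export
print.group_summary <- function(x, ...) {
  cat("Group kernel-width summary\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-6s n=%d  peak sigma %.2f mm (sd %.2f, excl. %d boundary)  r2 %.2f  slope %+.3f  concavity %.2f mm (sd %.2f, %d without)\n",
                x$band[i], x$n_subjects[i], x$peak_sigma_mean[i],
                x$peak_sigma_sd[i], x$n_boundary_excluded[i],
                x$peak_r2_mean[i], x$slope_mean[i],
                x$concavity_sigma_mean[i], x$concavity_sigma_sd[i],
                x$n_no_concavity[i]))
  }
  invisible(x)
}
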