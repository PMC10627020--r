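# Reading and writing the BIDS-like subject layout.
#
# <root>/<sub>/ieeg/  <sub>_task-motor_ieeg.tsv (+ .json sidecar),
#                     <sub>_task-motor_channels.tsv, _events.tsv,
#                     <sub>_electrodes.tsv
# <root>/<sub>/func/  <sub>_task-motor_bold.nii.gz, _events.tsv
# <root>/<sub>/anat/  <sub>_label-GM_mask.nii.gz
# <root>/<sub>/<sub>_truth.json          (synthetic subjects only)
# <root>/derivatives/<sub>/  analysis outputs

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path) {
  if (!file.exists(path)) stop("missing required file: ", path, call. = FALSE)
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

subject_paths <- function(root, subject) {
  base <- file.path(root, subject)
  list(
    ieeg_dir = file.path(base, "ieeg"),
    func_dir = file.path(base, "func"),
    anat_dir = file.path(base, "anat"),
    ecog_tsv = file.path(base, "ieeg", paste0(subject, "_task-motor_ieeg.tsv")),
    ecog_json = file.path(base, "ieeg", paste0(subject, "_task-motor_ieeg.json")),
    channels = file.path(base, "ieeg", paste0(subject, "_task-motor_channels.tsv")),
    ecog_events = file.path(base, "ieeg", paste0(subject, "_task-motor_events.tsv")),
    electrodes = file.path(base, "ieeg", paste0(subject, "_electrodes.tsv")),
    bold = file.path(base, "func", paste0(subject, "_task-motor_bold.nii.gz")),
    bold_events = file.path(base, "func", paste0(subject, "_task-motor_events.tsv")),
    gm_mask = file.path(base, "anat", paste0(subject, "_label-GM_mask.nii.gz")),
    truth = file.path(base, paste0(subject, "_truth.json")),
    deriv = file.path(root, "derivatives", subject)
  )
}

#' Write a synthetic subject to a BIDS-like directory tree
#'
#' Generates (or takes) a scene, truth, designs and the paired recordings,
#' and writes the raw-data side of the subject layout: electrodes, channels
#' and events TSVs, the ECoG sample matrix as a plain TSV with a JSON
#' sidecar stating the sampling rate, the BOLD series and gray-matter mask
#' as NIfTI volumes sharing one affine, and a truth sidecar with the
#' ground-truth point-spread width, band effects and seed.
#'
#' @param root Dataset root directory (created if needed).
#' @param subject Subject label, e.g. `"sub-01"`.
#' @param config Run configuration, see [default_config()].
#' @param seed Integer seed for this subject's scene, truth and recordings.
#' @return Invisibly, the list of generated objects
#'   (`scene`, `truth`, `design_ecog`, `design_bold`, `ecog`, `bold`).
#' @export
write_synthetic_subject <- function(root, subject, config = default_config(),
                                    seed = config$seed) {
  config <- validate_config(config)
  p <- subject_paths(root, subject)
  for (d in c(p$ieeg_dir, p$func_dir, p$anat_dir))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)

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
  ecog <- simulate_ecog(scene, truth, design_ecog, fs = syn$fs, seed = seed + 1L)
  bold <- simulate_bold(scene, truth, design_bold, tr = syn$tr,
                        baseline = syn$bold_baseline,
                        amplitude = syn$bold_amplitude, seed = seed + 2L)

  el <- measured_electrodes(scene, truth)
  write_tsv(data.frame(name = el$name, x = round(el$x, 4),
                       y = round(el$y, 4), z = round(el$z, 4)), p$electrodes)
  write_tsv(data.frame(name = ecog$channel_names, status = "good"), p$channels)
  write_tsv(as.data.frame(design_ecog), p$ecog_events)
  write_tsv(as.data.frame(design_bold), p$bold_events)

  # ECoG samples: time x channel numeric matrix, channel names as header
  m <- t(ecog$samples)
  colnames(m) <- ecog$channel_names
  utils::write.table(round(m, 5), p$ecog_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(list(SamplingFrequency = ecog$fs,
                            RecordingDuration = ncol(ecog$samples) / ecog$fs,
                            Reference = ecog$reference),
                       p$ecog_json, auto_unbox = TRUE, digits = NA)

  write_nifti_vol(bold$data, bold$affine, p$bold, pixdim = scene$voxel_mm,
                  tr = bold$tr)
  write_nifti_vol(array(as.numeric(scene$gm_mask), dim = dim(scene$gm_mask)),
                  scene$affine, p$gm_mask, pixdim = scene$voxel_mm)
  jsonlite::write_json(list(sigma_true = truth$sigma_true,
                            band_effects = truth$band_effects,
                            noise = truth$noise,
                            focus_width_mm = truth$focus_width_mm,
                            n_foci = nrow(truth$foci),
                            seed = seed),
                       p$truth, auto_unbox = TRUE, digits = NA)
  invisible(list(scene = scene, truth = truth, design_ecog = design_ecog,
                 design_bold = design_bold, ecog = ecog, bold = bold))
}

write_nifti_vol <- function(data, affine, path, pixdim, tr = NULL) {
  img <- RNifti::asNifti(data)
  RNifti::qform(img) <- structure(affine, code = 2L)
  RNifti::sform(img) <- structure(affine, code = 2L)
  nd <- length(dim(data))
  RNifti::pixdim(img) <- c(rep(pixdim, 3), rep(tr, nd - 3))
  RNifti::writeNifti(img, path)
  invisible(path)
}

read_nifti_vol <- function(path) {
  if (!file.exists(path)) stop("missing required file: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  list(data = array(as.vector(img), dim = dim(img)),
       affine = unname(unclass(RNifti::xform(img))),
       tr = RNifti::pixdim(img)[4])
}

#' Read the ECoG side of a subject directory
#'
#' Reads the plain-matrix ECoG file with its JSON sidecar, honoring the
#' `status` column of the channels table (only `"good"` channels are kept).
#'
#' @param root Dataset root.
#' @param subject Subject label.
#' @return List with `rec` (an `ecog_recording`), `design` (a
#'   `task_design`), `electrodes` (coordinates table).
#' @export
read_subject_ecog <- function(root, subject) {
  p <- subject_paths(root, subject)
  side <- jsonlite::read_json(p$ecog_json, simplifyVector = TRUE)
  m <- as.matrix(read_tsv(p$ecog_tsv))
  channels <- read_tsv(p$channels)
  good <- channels$name[channels$status == "good"]
  keep <- colnames(m) %in% good
  samples <- t(m[, keep, drop = FALSE])
  dimnames(samples) <- NULL
  rec <- structure(list(samples = samples,
                        fs = side$SamplingFrequency,
                        channel_names = colnames(m)[keep],
                        reference = if (!is.null(side$Reference)) side$Reference else "raw"),
                   class = "ecog_recording")
  if (anyNA(rec$samples)) stop("ECoG samples contain NA", call. = FALSE)
  list(rec = rec,
       design = as_task_design(read_tsv(p$ecog_events)),
       electrodes = read_tsv(p$electrodes))
}

#' Read the fMRI side of a subject directory
#'
#' Reads the 4D BOLD series, the gray-matter mask (shared affine enforced)
#' and the scanner-session events table.
#'
#' @param root Dataset root.
#' @param subject Subject label.
#' @return List with `bold` (a `bold_series`), `gm_mask` (3D logical),
#'   `design` (a `task_design`).
#' @export
read_subject_fmri <- function(root, subject) {
  p <- subject_paths(root, subject)
  b <- read_nifti_vol(p$bold)
  g <- read_nifti_vol(p$gm_mask)
  if (max(abs(b$affine - g$affine)) > 1e-4)
    stop("BOLD and gray-matter mask affines do not match", call. = FALSE)
  bold <- structure(list(data = b$data, affine = b$affine, tr = b$tr),
                    class = "bold_series")
  list(bold = bold, gm_mask = g$data > 0.5,
       design = as_task_design(read_tsv(p$bold_events)))
}
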