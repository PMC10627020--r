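# Shared fixtures, built in code. Test problem sizes are scaled down from
# the full protocol (fewer electrodes, 256 Hz, shorter blocks) so the whole
# suite stays fast; full-size behavior is exercised in the acceptance tests.

tiny_scene <- function(seed = 1, grid = c(4, 4)) {
  make_scene(grid_shape = grid, pitch_mm = 10, voxel_mm = 4,
             sheet_thickness_mm = 8, margin_mm = 8, seed = seed)
}

tiny_config <- function(...) {
  default_config(synthetic = list(grid_shape = c(5, 5), margin_mm = 10,
                                  fs = 256, design_ecog = c(3, 3, 20),
                                  design_bold = c(3, 4, 20)),
                 ...)
}

# ecog_recording wrapper around a plain channels x samples matrix
make_rec <- function(m, fs = 256) {
  structure(list(samples = m, fs = fs,
                 channel_names = sprintf("C%02d", seq_len(nrow(m))),
                 reference = "raw"),
            class = "ecog_recording")
}

# zmap with an arbitrary z vector over the GM voxels of a scene
zmap_from_scene <- function(scene, z_gm) {
  zvol <- array(NA_real_, dim = dim(scene$gm_mask))
  zvol[scene$gm_mask] <- z_gm
  structure(list(z = zvol, gm_mask = scene$gm_mask, affine = scene$affine),
            class = "zmap")
}

# zmap whose GM voxels are so far apart that, for any sigma on the default
# grid, each electrode only ever sees its own voxel (weighted z constant
# in sigma).
isolated_zmap <- function(n = 5, z = seq_len(n), spacing_mm = 500) {
  mask <- array(FALSE, dim = c(n, 1, 1))
  mask[, 1, 1] <- TRUE
  affine <- rbind(cbind(diag(c(spacing_mm, 1, 1)), c(0, 0, 0)), c(0, 0, 0, 1))
  zvol <- array(NA_real_, dim = dim(mask))
  zvol[mask] <- z
  structure(list(z = zvol, gm_mask = mask, affine = affine), class = "zmap")
}
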