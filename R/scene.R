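#' Build a synthetic recording geometry: gray-matter slab plus electrode grid
#'
#' Creates an idealized scene standing in for an implanted subdural grid: a
#' flat gray-matter (GM) sheet of given thickness sampled on an isotropic
#' voxel lattice, with a planar electrode grid at fixed pitch sitting
#' directly on top of the sheet. Clinical grids have 10 mm inter-electrode
#' spacing and ~2.3 mm contacts; functional volumes in the emulated protocol
#' use 4 mm isotropic voxels.
#'
#' Electrode positions are jittered by a small seeded amount (uniform within
#' +/- 0.1 voxel) so that electrodes do not sit at lattice-symmetric points.
#'
#' @param grid_shape Integer vector of length 2: electrodes per grid side.
#' @param pitch_mm Inter-electrode spacing in mm.
#' @param voxel_mm Isotropic voxel size in mm.
#' @param sheet_thickness_mm Thickness of the GM slab in mm.
#' @param margin_mm In-plane margin of the volume beyond the grid footprint.
#' @param seed Integer seed controlling the electrode jitter.
#'
#' @return A `synthetic_scene`: list with `gm_mask` (3D logical array),
#'   `affine` (4x4 voxel-index-to-mm transform, voxel centers at integer
#'   0-based indices), `voxel_mm`, and `electrodes` (data frame with
#'   `name`, `x`, `y`, `z` in world mm).
#' @export
make_scene <- function(grid_shape = c(8, 8), pitch_mm = 10, voxel_mm = 4,
                       sheet_thickness_mm = 8, margin_mm = 12, seed = 1) {
  if (length(grid_shape) == 1L) grid_shape <- rep(grid_shape, 2L)
  n1 <- check_count(grid_shape[1], "grid_shape[1]")
  n2 <- check_count(grid_shape[2], "grid_shape[2]")
  check_scalar(pitch_mm, "pitch_mm")
  check_scalar(voxel_mm, "voxel_mm")
  check_scalar(sheet_thickness_mm, "sheet_thickness_mm")
  check_scalar(margin_mm, "margin_mm", positive = FALSE)

  extent_x <- (n1 - 1) * pitch_mm
  extent_y <- (n2 - 1) * pitch_mm
  nx <- max(1L, ceiling((extent_x + 2 * margin_mm) / voxel_mm) + 1L)
  ny <- max(1L, ceiling((extent_y + 2 * margin_mm) / voxel_mm) + 1L)
  n_slab <- ceiling(sheet_thickness_mm / voxel_mm)
  if (n_slab < 1L)
    stop("gray-matter slab is empty at the requested voxel size", call. = FALSE)
  nz_pad <- 2L                       # empty voxels above/below the slab
  nz <- n_slab + 2L * nz_pad

  # Volume origin: voxel (0,0,0) center; grid centered in-plane at x=y=0.
  x0 <- -(nx - 1) * voxel_mm / 2
  y0 <- -(ny - 1) * voxel_mm / 2
  z0 <- 0
  affine <- rbind(cbind(diag(voxel_mm, 3), c(x0, y0, z0)), c(0, 0, 0, 1))

  # GM slab: z in [pad, pad + thickness)
  zc <- z0 + (seq_len(nz) - 1) * voxel_mm
  slab_lo <- z0 + nz_pad * voxel_mm
  in_slab <- zc >= slab_lo - 1e-9 & zc < slab_lo + sheet_thickness_mm - 1e-9
  gm_mask <- array(FALSE, dim = c(nx, ny, nz))
  gm_mask[, , which(in_slab)] <- TRUE
  if (!any(gm_mask))
    stop("gray-matter slab is empty at the requested voxel size", call. = FALSE)

  ex <- rep(seq_len(n1), times = n2)
  ey <- rep(seq_len(n2), each = n1)
  xe <- (ex - 1) * pitch_mm - extent_x / 2
  ye <- (ey - 1) * pitch_mm - extent_y / 2
  # electrodes rest on the cortical surface: half a voxel above the top
  # slab voxel center (the slab's upper edge on the sampled lattice)
  z_surface <- max(zc[in_slab]) + voxel_mm / 2
  ze <- rep(z_surface, n1 * n2)
  jitter <- with_seed(seed, matrix(stats::runif(3L * n1 * n2, -0.1, 0.1) * voxel_mm,
                                   ncol = 3L))
  electrodes <- data.frame(
    name = sprintf("E%02d", seq_len(n1 * n2)),
    x = xe + jitter[, 1], y = ye + jitter[, 2], z = ze + jitter[, 3],
    stringsAsFactors = FALSE
  )

  structure(
    list(gm_mask = gm_mask, affine = affine, voxel_mm = voxel_mm,
         sheet_thickness_mm = sheet_thickness_mm, pitch_mm = pitch_mm,
         electrodes = electrodes, seed = as.integer(seed)),
    class = "synthetic_scene"
  )
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("Synthetic scene: %s volume (%g mm voxels), %d GM voxels, %d electrodes at %g mm pitch\n",
              paste(dim(x$gm_mask), collapse = " x "), x$voxel_mm,
              sum(x$gm_mask), nrow(x$electrodes), x$pitch_mm))
  invisible(x)
}
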