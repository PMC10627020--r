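# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without clobbering the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

check_scalar <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < min)
    stop(sprintf("`%s` must be an integer >= %d", name, min), call. = FALSE)
  invisible(as.integer(x))
}

# Default z-score cap shared by the ECoG and fMRI modules: the largest |z|
# representable with a two-sided p that does not underflow double precision.
Z_CAP <- 38

# Convert a t statistic into a signed z-score through the two-sided
# p-value: z = sign(t) * qnorm(1 - p/2). Evaluated on the upper tail in
# log space so extreme |t| do not underflow before the cap.
t_to_z <- function(t_stat, df, z_cap = Z_CAP) {
  if (!is.finite(t_stat)) return(sign(t_stat) * z_cap)
  log_half_p <- stats::pt(-abs(t_stat), df = df, log.p = TRUE)
  z <- sign(t_stat) * stats::qnorm(log_half_p, lower.tail = FALSE, log.p = TRUE)
  max(-z_cap, min(z_cap, z))
}

# World-mm coordinates of voxel centers for 1-based array indices `ijk`
# (n x 3). The affine maps 0-based voxel indices to the mm position of the
# voxel center (NIfTI convention), hence the `- 1`.
voxel_to_world <- function(ijk, affine) {
  ijk <- matrix(as.numeric(ijk), ncol = 3L)
  xyz1 <- cbind(ijk - 1, 1) %*% t(affine)
  xyz1[, 1:3, drop = FALSE]
}

# 1-based index triplets of TRUE voxels in a 3D mask, n x 3.
mask_indices <- function(mask) {
  which(mask, arr.ind = TRUE)
}
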