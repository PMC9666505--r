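#' Sample pseudo-random rod layouts for every scattering layer
#'
#' Layers are stacked every `layer_pitch` um starting at
#' `z = rod_height / 2` (so no rod protrudes from the cube) and alternate
#' orientation between x-aligned and y-aligned. Within a layer, rods are
#' laid out along the transverse axis with edge-to-edge gaps drawn i.i.d.
#' from `Uniform(rod_gap_range)`; the first rod gets a random phase offset
#' so layouts are statistically stationary across the cube.
#'
#' @param spec a [phantom_spec()]
#' @param rng_seed integer seed; defaults to `spec$seed`
#' @return list of layouts, each a list with `z_center` (um), `orientation`
#'   (`"x"` or `"y"`, the rod axis) and `rod_positions` (transverse centre
#'   coordinates, um)
#' @export
sample_rod_layouts <- function(spec, rng_seed = spec$seed) {
  validate_phantom_spec(spec)
  h <- spec$cube_size[3]
  z0 <- spec$rod_height / 2
  if (h < spec$rod_height || h < spec$layer_pitch)
    stop("degenerate cube: height smaller than one layer")
  # layers whose rods fit entirely inside the cube
  n_layers <- 1L + floor((h - spec$rod_height) / spec$layer_pitch)
  z_centers <- z0 + (seq_len(n_layers) - 1L) * spec$layer_pitch

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(rng_seed)

  w <- spec$rod_width
  glo <- spec$rod_gap_range[1]; ghi <- spec$rod_gap_range[2]
  lapply(seq_len(n_layers), function(k) {
    orient <- if (k %% 2L == 1L) "x" else "y"
    extent <- spec$cube_size[if (orient == "x") 2L else 1L]
    # left edge of the first rod, randomly phased into the tiling
    edge <- -stats::runif(1, 0, w + ghi)
    pos <- numeric(0)
    while (edge < extent) {
      if (edge + w > 0) pos <- c(pos, edge + w / 2)
      edge <- edge + w + stats::runif(1, glo, ghi)
    }
    list(z_center = z_centers[k], orientation = orient, rod_positions = pos)
  })
}

#' Rasterize rod layouts into a refractive-index volume
#'
#' A voxel is polymer iff its centre lies inside the rectangular
#' cross-section of some rod (half-open intervals `[lo, hi)` on each axis,
#' so adjacent rods never share a voxel). Polymer voxels take
#' `n_background + delta_ri_max`; all others `n_background`. Rods are
#' clipped at the cube faces.
#'
#' @param layouts output of [sample_rod_layouts()]
#' @param spec a [phantom_spec()]
#' @param voxel_pitch voxel pitch (um), scalar or length-3; must not exceed
#'   `rod_width / 2`
#' @return an [ri_volume()]
#' @export
rasterize_scattering_cube <- function(layouts, spec, voxel_pitch = 0.1) {
  voxel_pitch <- rep_len(as.numeric(voxel_pitch), 3L)
  if (any(voxel_pitch > spec$rod_width / 2 + 1e-12))
    stop("undersampled geometry: voxel_pitch must be <= rod_width / 2")
  dims <- pmax(1L, as.integer(round(spec$cube_size / voxel_pitch)))
  vol <- array(spec$n_background, dims)
  centers <- lapply(1:3, function(a) (seq_len(dims[a]) - 0.5) * voxel_pitch[a])
  n_poly <- spec$n_background + spec$delta_ri_max
  w2 <- spec$rod_width / 2
  h2 <- spec$rod_height / 2
  for (lay in layouts) {
    zi <- which(centers[[3]] >= lay$z_center - h2 &
                centers[[3]] <  lay$z_center + h2)
    if (!length(zi) || !length(lay$rod_positions)) next
    trans_axis <- if (lay$orientation == "x") 2L else 1L
    cc <- centers[[trans_axis]]
    hit <- rep(FALSE, length(cc))
    for (p in lay$rod_positions)
      hit <- hit | (cc >= p - w2 & cc < p + w2)
    ti <- which(hit)
    if (!length(ti)) next
    if (lay$orientation == "x") vol[, ti, zi] <- n_poly else vol[ti, , zi] <- n_poly
  }
  ri_volume(vol, voxel_pitch, origin = c(0, 0, 0),
            n_background = spec$n_background)
}
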