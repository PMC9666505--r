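# Composition of the scattering cube and the embedded cell target, plus
# the fill-factor estimator used to characterise the design.

#' Compose scattering cube and cell target into the final phantom
#'
#' Rod (polymer) voxels are suppressed wherever their Euclidean distance to
#' any cell-target voxel is below `clearance`; inside the target the cell
#' RI always takes priority over rods. The clearance zone is computed by
#' dilating the cell mask with a digital ball of radius `clearance`
#' (FFT-based binary convolution), which reproduces a voxel-centre distance
#' test exactly up to the voxel discretisation of the ball.
#'
#' @param cube scattering-cube [ri_volume()]
#' @param cell cell-target [ri_volume()] on the identical grid
#' @param clearance minimum rod-to-target distance, um
#' @return composed [ri_volume()]; the `line_groups` attribute of `cell`
#'   is carried over
#' @export
compose_phantom <- function(cube, cell, clearance = 0.5) {
  stopifnot_same_grid(cube, cell)
  nb <- cube$n_background
  if (is.na(nb)) nb <- min(cube$values)
  cell_mask <- cell$values > nb + 1e-12
  out <- cube$values
  if (any(cell_mask)) {
    clear_mask <- if (clearance > 0)
      dilate_mask_ball(cell_mask, clearance, cube$voxel_pitch)
    else cell_mask
    out[clear_mask] <- nb
    out[cell_mask] <- cell$values[cell_mask]
  }
  res <- ri_volume(out, cube$voxel_pitch, cube$origin, n_background = nb)
  attr(res, "line_groups") <- attr(cell, "line_groups")
  res
}

# Dilate a logical 3D mask by a Euclidean ball of physical radius r (um).
# Uses FFT convolution with the ball indicator; exact for voxel centres.
#' @noRd
dilate_mask_ball <- function(mask, r, pitch) {
  d <- dim(mask)
  rv <- pmax(1L, as.integer(floor(r / pitch)))     # ball half-extent in voxels
  kd <- 2L * rv + 1L
  off <- lapply(1:3, function(a) ((seq_len(kd[a]) - 1L) - rv[a]) * pitch[a])
  K <- array(0, kd)
  K[] <- as.numeric(outer(outer(off[[1]]^2, off[[2]]^2, "+"), off[[3]]^2, "+") <= r^2 + 1e-12)
  # embed kernel centred at the origin of a padded grid (cyclic convolution)
  pd <- d + kd - 1L
  A <- array(0, pd); A[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- mask
  B <- array(0, pd); B[seq_len(kd[1]), seq_len(kd[2]), seq_len(kd[3])] <- K
  conv <- Re(stats::fft(stats::fft(A) * stats::fft(B), inverse = TRUE)) / prod(pd)
  sel <- lapply(1:3, function(a) rv[a] + seq_len(d[a]))
  conv[sel[[1]], sel[[2]], sel[[3]]] > 0.5
}

#' Polymer volume fraction of a region
#'
#' Fraction of voxels whose RI exceeds the background level, evaluated over
#' an index box, optionally excluding a mask (e.g. the cell-target region
#' when measuring the scattering cube's nominal fill).
#'
#' @param volume an [ri_volume()]
#' @param region list with integer vectors `x`, `y`, `z` of index ranges;
#'   `NULL` (default) means the whole volume
#' @param exclude optional logical array (same dims as the volume): voxels
#'   to drop from the count
#' @return fraction in `[0, 1]`
#' @export
compute_fill_factor <- function(volume, region = NULL, exclude = NULL) {
  d <- dim(volume$values)
  if (is.null(region))
    region <- list(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3]))
  if (!length(region$x) || !length(region$y) || !length(region$z))
    stop("empty region")
  if (max(region$x) > d[1] || max(region$y) > d[2] || max(region$z) > d[3])
    stop("region outside volume")
  nb <- volume$n_background
  if (is.na(nb)) nb <- min(volume$values)
  v <- volume$values[region$x, region$y, region$z, drop = FALSE]
  keep <- rep(TRUE, length(v))
  if (!is.null(exclude))
    keep <- !(exclude[region$x, region$y, region$z])
  if (!any(keep)) stop("empty region")
  mean(v[keep] > nb + 1e-12)
}

#' Generate the complete microphantom
#'
#' Convenience wrapper: samples rod layouts, rasterizes the scattering
#' cube, builds the cell target (unless `cspec` is `NULL`) and composes
#' them with the spec's clearance.
#'
#' @param spec a [phantom_spec()]
#' @param cspec a [cell_target_spec()] or `NULL` for rods only
#' @param voxel_pitch voxel pitch, um
#' @param seed overrides `spec$seed` when given
#' @return an [ri_volume()]
#' @export
generate_phantom <- function(spec = phantom_spec(), cspec = cell_target_spec(),
                             voxel_pitch = 0.1, seed = NULL) {
  if (!is.null(seed)) spec$seed <- as.integer(seed)
  layouts <- sample_rod_layouts(spec)
  cube <- rasterize_scattering_cube(layouts, spec, voxel_pitch)
  if (is.null(cspec)) return(cube)
  cell <- build_cell_target(cspec, spec, voxel_pitch)
  compose_phantom(cube, cell, spec$clearance)
}
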