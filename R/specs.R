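#' Scattering microphantom specification
#'
#' Collects every geometric and refractive-index parameter of the
#' scattering microphantom design: a cube of pseudo-randomly spaced polymer
#' rods, stacked in layers of alternating orientation, that encloses a
#' cell-like imaging target. Defaults are the printed design values of the
#' fabricated structure.
#'
#' @param cube_size cube dimensions (x, y, z) in um
#' @param rod_width lateral rod width in um
#' @param rod_height vertical rod height in um
#' @param rod_gap_range interval (um) from which edge-to-edge gaps between
#'   adjacent rods in a layer are drawn uniformly at random
#' @param layer_pitch vertical spacing between consecutive rod layers, um
#' @param clearance minimum Euclidean distance (um) kept between any rod
#'   voxel and the cell target
#' @param fill_factor_nominal nominal polymer volume fraction of the
#'   scattering cube (design metadata)
#' @param n_background background / immersion refractive index
#' @param delta_ri_max maximal refractive-index offset above
#'   `n_background` anywhere in the phantom
#' @param ri_accuracy fabrication RI accuracy (metadata only)
#' @param seed integer seed making generation deterministic
#' @return an object of class `phantom_spec`
#' @export
phantom_spec <- function(cube_size = c(60, 60, 40),
                         rod_width = 0.5,
                         rod_height = 1.8,
                         rod_gap_range = c(0.7, 3.0),
                         layer_pitch = 1.4,
                         clearance = 0.5,
                         fill_factor_nominal = 0.25,
                         n_background = 1.5123,
                         delta_ri_max = 0.03,
                         ri_accuracy = 5e-4,
                         seed = 1L) {
  spec <- structure(
    list(cube_size = rep_len(as.numeric(cube_size), 3L),
         rod_width = rod_width, rod_height = rod_height,
         rod_gap_range = as.numeric(rod_gap_range),
         layer_pitch = layer_pitch, clearance = clearance,
         fill_factor_nominal = fill_factor_nominal,
         n_background = n_background, delta_ri_max = delta_ri_max,
         ri_accuracy = ri_accuracy, seed = as.integer(seed)),
    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

#' @noRd
validate_phantom_spec <- function(spec) {
  with(spec, {
    if (rod_gap_range[1] <= 0) stop("rod_gap_range lower bound must be > 0")
    if (diff(rod_gap_range) < 0) stop("rod_gap_range must be non-decreasing")
    if (layer_pitch <= 0) stop("layer_pitch must be > 0")
    if (rod_width <= 0 || rod_height <= 0) stop("rod dimensions must be > 0")
    if (delta_ri_max <= 0) stop("delta_ri_max must be > 0")
    if (any(cube_size <= 0)) stop("cube_size must be positive")
    if (clearance < 0) stop("clearance must be >= 0")
  })
  invisible(spec)
}

#' Cell-target specification
#'
#' Describes the biomimetic imaging target embedded at the centre of the
#' scattering cube: a truncated ellipsoid ("cytoplasm") that contains bar
#' resolution line groups, a nucleus with suspended nucleoli and a region
#' of slow refractive-index variation. `ellipsoid_size` gives the external
#' dimensions of the *truncated* solid; the underlying full ellipsoid is
#' taller by `1 / (1 - truncation)` so that removing the bottom
#' `truncation` fraction of its height leaves exactly the stated extent.
#'
#' All `*_delta_ri` values are offsets above the background RI and must lie
#' in `(0, delta_ri_max]` of the enclosing [phantom_spec()]; the line-group
#' bars carry the maximal offset so that the overall phantom contrast
#' equals `delta_ri_max` exactly.
#'
#' @param ellipsoid_size external (x, y, z) dimensions of the truncated
#'   ellipsoid, um
#' @param truncation fraction of the full ellipsoid height cut away flat at
#'   the substrate (low-z) side
#' @param line_group_frequencies increasing spatial frequencies of the bar
#'   groups, lp/mm; finest group defaults to 1667 lp/mm (0.6 um period)
#' @param line_group_delta_ri RI offset of the resolution bars
#' @param lines_per_group bars per group
#' @param line_length bar length, um
#' @param line_height bar thickness along z, um
#' @param cytoplasm_delta_ri RI offset of the ellipsoid body
#' @param nucleus_size,nucleus_center_offset nucleus ellipsoid dimensions
#'   and centre offset from the target centre, um
#' @param nucleus_delta_ri RI offset of the nucleus
#' @param nucleoli_radii radii of the nucleolus spheres, um
#' @param nucleoli_delta_ri RI offset of the nucleoli
#' @param gradient_center,gradient_radius location/size of the slow-varying
#'   RI region, um
#' @param gradient_delta_ri_max peak RI offset at the gradient centre,
#'   decaying linearly to 0 at `gradient_radius`
#' @return an object of class `cell_target_spec`
#' @export
cell_target_spec <- function(ellipsoid_size = c(30, 25, 12),
                             truncation = 0.1,
                             line_group_frequencies = c(417, 595, 833, 1190, 1667),
                             line_group_delta_ri = 0.03,
                             lines_per_group = 3L,
                             line_length = 3,
                             line_height = 1.5,
                             cytoplasm_delta_ri = 0.008,
                             nucleus_size = c(12, 10, 6),
                             nucleus_center_offset = c(-6, 4, 1),
                             nucleus_delta_ri = 0.014,
                             nucleoli_radii = c(1.2, 1.0, 0.8),
                             nucleoli_delta_ri = 0.022,
                             gradient_center = c(8, 6, 0),
                             gradient_radius = 4,
                             gradient_delta_ri_max = 0.015) {
  f <- as.numeric(line_group_frequencies)
  if (length(f) && any(diff(f) <= 0))
    stop("line_group_frequencies must be strictly increasing")
  structure(
    list(ellipsoid_size = rep_len(as.numeric(ellipsoid_size), 3L),
         truncation = truncation,
         line_group_frequencies = f,
         line_group_delta_ri = line_group_delta_ri,
         lines_per_group = as.integer(lines_per_group),
         line_length = line_length, line_height = line_height,
         cytoplasm_delta_ri = cytoplasm_delta_ri,
         nucleus_size = rep_len(as.numeric(nucleus_size), 3L),
         nucleus_center_offset = rep_len(as.numeric(nucleus_center_offset), 3L),
         nucleus_delta_ri = nucleus_delta_ri,
         nucleoli_radii = as.numeric(nucleoli_radii),
         nucleoli_delta_ri = nucleoli_delta_ri,
         gradient_center = rep_len(as.numeric(gradient_center), 3L),
         gradient_radius = gradient_radius,
         gradient_delta_ri_max = gradient_delta_ri_max),
    class = "cell_target_spec")
}

#' Rescale a phantom design to a smaller working volume
#'
#' All lengths (cube, rods, gaps, pitches, cell-target geometry) are
#' multiplied by `factor`; RI offsets are unchanged, so the scaled phantom
#' keeps the design contrast while fitting a small simulation grid.
#'
#' @param spec a [phantom_spec()]
#' @param cspec a [cell_target_spec()] or `NULL`
#' @param factor scale factor in (0, 1]
#' @param scale_rods scale the rod cross-section and layer pitch too
#'   (default). With `FALSE`, only the cube and the cell target shrink
#'   while individual rods keep their printed dimensions, so a scaled
#'   working volume remains resolvable on a coarse voxel grid and keeps
#'   the design's scattering strength per unit length.
#' @return list with elements `spec` and `cspec`
#' @export
scale_phantom_design <- function(spec, cspec = NULL, factor,
                                 scale_rods = TRUE) {
  stopifnot(factor > 0)
  s <- spec
  fields <- c("cube_size", "clearance",
              if (scale_rods) c("rod_width", "rod_height", "rod_gap_range",
                                "layer_pitch"))
  for (f in fields) s[[f]] <- s[[f]] * factor
  c2 <- cspec
  if (!is.null(cspec)) {
    for (f in c("ellipsoid_size", "line_length", "line_height",
                "nucleus_size", "nucleus_center_offset", "nucleoli_radii",
                "gradient_center", "gradient_radius"))
      c2[[f]] <- c2[[f]] * factor
    # spatial frequencies scale inversely with length
    c2$line_group_frequencies <- c2$line_group_frequencies / factor
  }
  list(spec = s, cspec = c2)
}
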