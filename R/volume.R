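#' Refractive-index volume
#'
#' Container for a 3D scalar refractive-index field on a regular voxel grid.
#' Axis order is (x, y, z) with z the optical axis; voxel indices are
#' 1-based in R but physical positions follow the half-voxel convention
#' `position = origin + (index - 0.5) * pitch`, i.e. `origin` is the corner
#' of the first voxel.
#'
#' @param values 3D numeric array of refractive index, dims (nx, ny, nz)
#' @param voxel_pitch voxel pitch in um; scalar or length-3 vector
#' @param origin physical position (um) of the corner of voxel (1,1,1);
#'   length-3 vector, default `c(0, 0, 0)`
#' @param n_background background (immersion) refractive index recorded as
#'   metadata; default `NA`
#' @return an object of class `ri_volume` with fields `values`,
#'   `voxel_pitch`, `origin`, `n_background`
#' @export
ri_volume <- function(values, voxel_pitch, origin = c(0, 0, 0),
                      n_background = NA_real_) {
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  voxel_pitch <- rep_len(as.numeric(voxel_pitch), 3L)
  if (any(voxel_pitch <= 0)) stop("voxel_pitch must be strictly positive")
  structure(
    list(values = values, voxel_pitch = voxel_pitch,
         origin = rep_len(as.numeric(origin), 3L),
         n_background = as.numeric(n_background)),
    class = "ri_volume")
}

#' @export
print.ri_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<ri_volume> %d x %d x %d voxels, pitch (%.4g, %.4g, %.4g) um\n",
              d[1], d[2], d[3],
              x$voxel_pitch[1], x$voxel_pitch[2], x$voxel_pitch[3]))
  cat(sprintf("  extent %.3g x %.3g x %.3g um; RI range [%.6g, %.6g]\n",
              d[1] * x$voxel_pitch[1], d[2] * x$voxel_pitch[2],
              d[3] * x$voxel_pitch[3],
              min(x$values), max(x$values)))
  if (!is.na(x$n_background))
    cat(sprintf("  n_background = %.6g\n", x$n_background))
  invisible(x)
}

#' Voxel-centre coordinates along one axis of a volume
#'
#' @param vol an `ri_volume`
#' @param axis 1 (x), 2 (y) or 3 (z)
#' @return numeric vector of physical centre positions (um)
#' @export
voxel_centers <- function(vol, axis) {
  n <- dim(vol$values)[axis]
  vol$origin[axis] + (seq_len(n) - 0.5) * vol$voxel_pitch[axis]
}

#' @noRd
stopifnot_same_grid <- function(a, b) {
  if (!identical(dim(a$values), dim(b$values)) ||
      max(abs(a$voxel_pitch - b$voxel_pitch)) > 1e-9 ||
      max(abs(a$origin - b$origin)) > 1e-9)
    stop("grid mismatch: volumes must share shape, pitch and origin")
  invisible(TRUE)
}
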