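# On-disk interchange. Volumes and projection sets are written as
# multi-page 32-bit TIFF stacks (one page per z-slice, or per projection
# real/imaginary pair) next to a JSON sidecar holding grid metadata and
# the affine value scaling (TIFF float pages are stored normalized to
# [0, 1]). Round-trips are lossless to 32-bit float precision.

#' @noRd
sidecar_path <- function(path) paste0(sub("\\.tiff?$", "", path), ".json")

#' @noRd
norm_pages <- function(vals, lo, hi) {
  sc <- hi - lo
  if (sc <= 0) sc <- 1
  (vals - lo) / sc
}

#' Write / read a refractive-index volume
#'
#' `write_volume()` stores an [ri_volume()] as a multi-page 32-bit float
#' TIFF (one page per z-slice) with a `.json` sidecar carrying
#' `voxel_pitch_um`, `origin_um`, `n_background` and the value scaling;
#' `read_volume()` restores it.
#'
#' @param vol an [ri_volume()]
#' @param path output `.tif` path (sidecar written next to it)
#' @return `write_volume()`: the path, invisibly. `read_volume()`: an
#'   [ri_volume()].
#' @export
write_volume <- function(vol, path) {
  lo <- min(vol$values); hi <- max(vol$values)
  pages <- lapply(seq_len(dim(vol$values)[3]), function(k)
    norm_pages(vol$values[, , k], lo, hi))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(format = "tpmphantom_ri_volume", dims = dim(vol$values),
               voxel_pitch_um = vol$voxel_pitch, origin_um = vol$origin,
               n_background = vol$n_background,
               value_min = lo, value_max = hi)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = FALSE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) stop("missing sidecar metadata file: ", sp)
  meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  for (k in c("dims", "voxel_pitch_um", "value_min", "value_max"))
    if (is.null(meta[[k]])) stop("sidecar lacks required field '", k, "'")
  pages <- tiff::readTIFF(path, all = TRUE)
  vals <- array(0, meta$dims)
  sc <- meta$value_max - meta$value_min
  if (sc <= 0) sc <- 1
  for (k in seq_along(pages))
    vals[, , k] <- pages[[k]] * sc + meta$value_min
  ri_volume(vals, meta$voxel_pitch_um,
            origin = if (is.null(meta$origin_um)) c(0, 0, 0) else meta$origin_um,
            n_background = if (is.null(meta$n_background)) NA_real_
                           else meta$n_background)
}

#' Write / read an angle-resolved projection set
#'
#' Fields are stored as interleaved real/imaginary 32-bit float TIFF
#' pages (2 per projection); the JSON sidecar records the optical
#' configuration, per-projection directions and snapped transverse
#' wavevectors, the simulation geometry and the value scaling.
#'
#' @param pset a [projection_set()]
#' @param path output `.tif` path
#' @return `write_projection_set()`: the path, invisibly.
#'   `read_projection_set()`: a [projection_set()].
#' @export
write_projection_set <- function(pset, path) {
  re <- unlist(lapply(pset$fields, function(f) range(Re(f$values), Im(f$values))))
  lo <- min(re); hi <- max(re)
  pages <- list()
  for (f in pset$fields) {
    pages[[length(pages) + 1L]] <- norm_pages(Re(f$values), lo, hi)
    pages[[length(pages) + 1L]] <- norm_pages(Im(f$values), lo, hi)
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  cfg <- pset$config
  dirs <- t(vapply(pset$fields, function(f) f$direction, numeric(3)))
  kt <- t(vapply(pset$fields, function(f)
    if (is.null(f$k_trans)) c(NA_real_, NA_real_) else f$k_trans, numeric(2)))
  az <- atan2(dirs[, 2], dirs[, 1]) * 180 / pi
  meta <- list(format = "tpmphantom_projection_set",
               n_projections = length(pset$fields),
               field_dims = dim(pset$fields[[1]]$values),
               pixel_pitch_um = pset$fields[[1]]$pixel_pitch,
               wavelength_nm = cfg$wavelength_nm, na = cfg$na,
               n_immersion = cfg$n_immersion, zenith_deg = cfg$zenith_deg,
               azimuth_step_deg = cfg$azimuth_step_deg,
               azimuth_deg = az, directions = dirs, k_trans = kt,
               noise_sigma = pset$noise_sigma,
               geometry = attr(pset, "geometry"),
               value_min = lo, value_max = hi)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = FALSE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_projection_set
#' @export
read_projection_set <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) stop("missing sidecar metadata file: ", sp)
  meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  for (k in c("azimuth_deg", "wavelength_nm", "pixel_pitch_um", "field_dims",
              "value_min", "value_max", "n_immersion"))
    if (is.null(meta[[k]])) stop("sidecar lacks required field '", k, "'")
  pages <- tiff::readTIFF(path, all = TRUE)
  np <- length(pages) / 2L
  sc <- meta$value_max - meta$value_min
  if (sc <= 0) sc <- 1
  fields <- vector("list", np)
  for (i in seq_len(np)) {
    re <- pages[[2L * i - 1L]] * sc + meta$value_min
    im <- pages[[2L * i]] * sc + meta$value_min
    dirv <- if (!is.null(meta$directions)) meta$directions[i, ] else c(0, 0, 1)
    ktv <- if (!is.null(meta$k_trans) && all(is.finite(meta$k_trans[i, ])))
      meta$k_trans[i, ] else NULL
    fields[[i]] <- complex_field(matrix(complex(real = re, imaginary = im),
                                        nrow(re), ncol(re)),
                                 meta$pixel_pitch_um, dirv, ktv)
  }
  cfg <- optical_config(wavelength_nm = meta$wavelength_nm,
                        na = if (is.null(meta$na)) 1.3 else meta$na,
                        n_immersion = meta$n_immersion,
                        zenith_deg = if (is.null(meta$zenith_deg)) 47 else meta$zenith_deg,
                        n_projections = np,
                        azimuth_step_deg = if (is.null(meta$azimuth_step_deg)) 2
                                           else meta$azimuth_step_deg)
  ps <- projection_set(fields, cfg,
                       noise_sigma = if (is.null(meta$noise_sigma)) 0
                                     else meta$noise_sigma)
  if (!is.null(meta$geometry)) attr(ps, "geometry") <- meta$geometry
  ps
}

#' Write a JSON run report for a reconstruction
#'
#' @param history a [recon_history()]
#' @param eps the stopping level used
#' @param path output `.json` path
#' @param settings optional named list of run settings to embed
#' @return the path, invisibly
#' @export
write_run_report <- function(history, eps, path, settings = NULL) {
  rep <- list(dynamics = history$dynamics, misfit = history$misfit,
              eps = eps, stopped_at = history$n_iter)
  if (!is.null(settings)) rep$settings <- settings
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
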