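# Evaluation protocol: cross-section profiles with +/- pixel statistics,
# resolution readout on the generated line groups, RI error metrics and
# the phase-noise estimator used to characterise measurement datasets.

#' Cross-section profile with windowed statistics
#'
#' Mean and standard deviation of the pixel values across the
#' `2 * halfwidth + 1` rows (or columns) centred on `line_index`,
#' reported per position along the line -- the statistic shown as shaded
#' bands around the published cross-sectional plots (halfwidth 4, i.e.
#' +/-4 pixels, in the reference protocol). The standard deviation is the
#' population form (divisor `n`).
#'
#' @param slice2d 2D numeric matrix (a z-slice of a volume)
#' @param line_index row (axis `"horizontal"`) or column
#'   (`"vertical"`) index the window is centred on
#' @param axis `"horizontal"` (profile along x, window over columns y) or
#'   `"vertical"` (profile along y, window over rows x)
#' @param halfwidth window half-width in pixels
#' @param pixel_pitch pitch used for the returned positions, um
#' @return object of class `cross_section_profile`: list with
#'   `positions`, `mean`, `std`, `axis`
#' @export
cross_section_profile <- function(slice2d, line_index, axis = c("horizontal", "vertical"),
                                  halfwidth = 4L, pixel_pitch = 1) {
  axis <- match.arg(axis)
  d <- dim(slice2d)
  w <- as.integer(halfwidth)
  ortho_n <- if (axis == "horizontal") d[2] else d[1]
  if (line_index - w < 1L || line_index + w > ortho_n)
    stop("window exceeds slice bounds")
  win <- (line_index - w):(line_index + w)
  block <- if (axis == "horizontal") slice2d[, win, drop = FALSE]
           else t(slice2d[win, , drop = FALSE])
  mu <- rowMeans(block)
  sd_pop <- sqrt(rowMeans((block - mu)^2))
  structure(list(positions = (seq_along(mu) - 0.5) * pixel_pitch,
                 mean = mu, std = sd_pop, axis = axis),
            class = "cross_section_profile")
}

#' Highest resolved line-group frequency of a profile
#'
#' For each bar group the modulation contrast over the group's extent is
#' evaluated: the single-bin Fourier modulation amplitude of the profile's
#' delta-n at the group's design frequency, normalized by the group's mean
#' delta-n above `background` (for an ideal square-wave bar pattern this
#' contrast is larger than 1; blur suppresses it towards 0, and unlike a
#' raw peak-to-trough Michelson ratio it is insensitive to smooth
#' pedestals bleeding in from neighbouring structures). The highest
#' frequency whose contrast reaches `contrast_threshold` is reported
#' (0 if none resolve).
#'
#' @param profile a [cross_section_profile()] (positions in um)
#' @param groups data frame with columns `frequency` (lp/mm), `lo`, `hi`
#'   (group extent along the profile, um), as produced by
#'   [build_cell_target()]'s `line_groups` attribute (pre-filtered to one
#'   axis)
#' @param contrast_threshold minimal Michelson contrast (default 0.1)
#' @param background RI level the contrast is measured above (default:
#'   minimum of the profile mean)
#' @return highest resolved frequency, lp/mm
#' @export
resolved_frequency <- function(profile, groups, contrast_threshold = 0.1,
                               background = NULL) {
  if (is.unsorted(groups$frequency)) stop("groups must be increasing in frequency")
  if (is.null(background)) background <- min(profile$mean)
  best <- 0
  for (i in seq_len(nrow(groups))) {
    sel <- profile$positions >= groups$lo[i] & profile$positions < groups$hi[i]
    if (sum(sel) < 3L) {
      warning(sprintf("group %g lp/mm not covered by profile; skipped",
                      groups$frequency[i]))
      next
    }
    seg <- profile$mean[sel] - background
    ctr <- mean(seg)
    if (ctr <= 0) next
    x <- profile$positions[sel]
    f_um <- groups$frequency[i] / 1000            # lp/mm -> cycles/um
    mod_amp <- 2 * Mod(sum((seg - ctr) * exp(-2i * pi * f_um * x))) / length(seg)
    if (mod_amp / ctr >= contrast_threshold)
      best <- max(best, groups$frequency[i])
  }
  best
}

#' RI error metrics over a mask
#'
#' @param recon,truth volumes on the same grid
#' @param mask logical array of voxels to evaluate (e.g. the object mask)
#' @return list with `rmse` and `bias` (mean signed error), RI units
#' @export
ri_error_metrics <- function(recon, truth, mask) {
  stopifnot_same_grid(recon, truth)
  if (!any(mask)) stop("empty mask")
  e <- recon$values[mask] - truth$values[mask]
  list(rmse = sqrt(mean(e^2)), bias = mean(e))
}

#' Phase-noise standard deviation in an object-free region
#'
#' For each projection the field phase over the background box is
#' extracted (relative to the ideal incident carrier when the set carries
#' its illumination metadata), the best-fit phase plane is removed
#' (tilt removal -- residual carrier would otherwise dominate), and the
#' per-projection variances are pooled into one standard deviation.
#'
#' @param pset a [projection_set()]
#' @param background_region list with integer index vectors `x`, `y`
#'   delimiting an object-free box
#' @return pooled phase standard deviation, radians
#' @export
phase_noise_std <- function(pset, background_region) {
  km <- k_medium(pset$config)
  g <- pset_geometry(pset)
  xi <- background_region$x; yi <- background_region$y
  vars <- vapply(pset$fields, function(f) {
    sub <- f$values[xi, yi, drop = FALSE]
    if (any(Mod(sub) < 1e-12)) stop("background region contains ~zero amplitude")
    ref <- incident_reference(f, km, g$thickness_um)
    ph <- Arg(sub / ref$u[xi, yi])
    X <- cbind(1, rep(xi, length(yi)), rep(yi, each = length(xi)))
    res <- stats::lsfit(X[, 2:3], as.vector(ph))$residuals
    mean(res^2)
  }, numeric(1))
  sqrt(mean(vars))
}

#' Beer-Lambert transmittance through a path
#'
#' @param extinction_per_mm extinction coefficient, 1/mm
#' @param path_um geometric path length, um
#' @return transmitted fraction in (0, 1]
#' @export
beer_lambert_transmittance <- function(extinction_per_mm, path_um) {
  exp(-extinction_per_mm * path_um / 1000)
}

#' Summarise a reconstruction against the ground truth
#'
#' Compact evaluation report: RMSE and bias over the object mask, the
#' measured fill factor, and (when the phantom carries line-group
#' metadata plus a sufficiently fine grid) the highest resolved frequency
#' along each axis.
#'
#' @param recon reconstructed [ri_volume()]
#' @param truth ground-truth [ri_volume()] (with optional `line_groups`
#'   attribute)
#' @param contrast_threshold passed to [resolved_frequency()]
#' @return list of class `evaluation_report`
#' @export
evaluate_reconstruction <- function(recon, truth, contrast_threshold = 0.1) {
  nb <- truth$n_background
  if (is.na(nb)) nb <- min(truth$values)
  mask <- truth$values > nb + 1e-12
  err <- ri_error_metrics(recon, truth, mask)
  rep <- list(rmse_object = err$rmse, bias_object = err$bias,
              fill_factor_measured = compute_fill_factor(recon))
  lg <- attr(truth, "line_groups")
  if (!is.null(lg)) {
    # groups below the grid Nyquist are not representable; drop them
    lg <- lg[lg$period >= 2 * recon$voxel_pitch[1], , drop = FALSE]
  }
  if (!is.null(lg) && nrow(lg)) {
    res <- list()
    for (ax in unique(lg$axis)) {
      gr <- lg[lg$axis == ax, ]
      zc <- max(1L, round(mean(c(gr$z_lo[1], gr$z_hi[1])) / recon$voxel_pitch[3]))
      lc <- max(1L, round(mean(c(gr$line_lo[1], gr$line_hi[1])) / recon$voxel_pitch[1]))
      pr <- cross_section_profile(recon$values[, , zc], lc,
                                  axis = if (ax == "x") "horizontal" else "vertical",
                                  halfwidth = 4L,
                                  pixel_pitch = recon$voxel_pitch[1])
      res[[ax]] <- resolved_frequency(pr, gr, contrast_threshold)
    }
    rep$resolved_max_frequency <- res
  }
  class(rep) <- "evaluation_report"
  rep
}
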