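# Cell-like imaging target: truncated ellipsoid body containing bar
# resolution groups, nucleus + nucleoli and a slow RI gradient. The target
# is centred in the cube so that its bounding box matches the stated
# external dimensions on the output grid. Feature painting is restricted
# to each feature's bounding box to keep full-size rasterization fast.

#' Rasterize the cell-like imaging target
#'
#' Builds the truncated-ellipsoid cell target with all internal features as
#' an RI volume on the same grid convention as the scattering cube. Voxels
#' outside the ellipsoid stay at `spec$n_background`; inside, features are
#' painted in priority order cytoplasm < gradient < nucleus < nucleoli <
#' resolution bars, each with its configured RI offset.
#'
#' The returned volume carries an attribute `"line_groups"`: a data frame
#' with one row per generated bar group (`frequency` in lp/mm, `period` and
#' `bar_width` in um, the group's extent `lo`/`hi` along its frequency
#' `axis`, the bar extent `line_lo`/`line_hi` on the transverse axis and
#' `z_lo`/`z_hi`), used by the evaluation module to anchor resolution
#' readout to the generated geometry.
#'
#' @param cspec a [cell_target_spec()]
#' @param spec the enclosing [phantom_spec()] (cube size, background RI,
#'   RI contrast cap)
#' @param voxel_pitch voxel pitch (um), scalar or length-3
#' @return an [ri_volume()]
#' @export
build_cell_target <- function(cspec, spec, voxel_pitch = 0.1) {
  voxel_pitch <- rep_len(as.numeric(voxel_pitch), 3L)
  offs <- c(cspec$cytoplasm_delta_ri, cspec$nucleus_delta_ri,
            cspec$nucleoli_delta_ri, cspec$gradient_delta_ri_max,
            if (length(cspec$line_group_frequencies)) cspec$line_group_delta_ri)
  if (any(offs > spec$delta_ri_max + 1e-12))
    stop("feature RI offset exceeds delta_ri_max")
  if (any(cspec$ellipsoid_size > spec$cube_size))
    stop("ellipsoid does not fit inside the cube")

  dims <- pmax(1L, as.integer(round(spec$cube_size / voxel_pitch)))
  ctr <- spec$cube_size / 2
  cx <- (seq_len(dims[1]) - 0.5) * voxel_pitch[1] - ctr[1]
  cy <- (seq_len(dims[2]) - 0.5) * voxel_pitch[2] - ctr[2]
  cz <- (seq_len(dims[3]) - 0.5) * voxel_pitch[3] - ctr[3]

  # Full ellipsoid is taller so that cutting the bottom `truncation`
  # fraction of its height leaves exactly ellipsoid_size[3].
  a <- cspec$ellipsoid_size[1] / 2
  b <- cspec$ellipsoid_size[2] / 2
  hfull <- cspec$ellipsoid_size[3] / (1 - cspec$truncation)
  cfull <- hfull / 2
  z_top <- cfull                      # relative to full-ellipsoid centre
  z_cut <- -cfull + cspec$truncation * hfull
  z_mid <- (z_top + z_cut) / 2        # shift: truncated solid centred in z

  # ellipsoid + truncation over the full grid, via 1D outer sums
  qx <- (cx / a)^2
  qy <- (cy / b)^2
  qz <- ((cz + z_mid) / cfull)^2
  inside <- outer(outer(qx, qy, "+"), qz, "+") <= 1
  zi_keep <- (cz + z_mid) >= z_cut
  inside[, , !zi_keep] <- FALSE

  off <- array(0, dims)
  off[inside] <- cspec$cytoplasm_delta_ri

  # index ranges covering a physical box [lo, hi] (centre coordinates)
  rng <- function(coords, lo, hi) which(coords >= lo & coords <= hi)

  # gradient region: offset decays linearly from the centre to the rim
  g <- cspec$gradient_center; gr <- cspec$gradient_radius
  gi <- list(rng(cx, g[1] - gr, g[1] + gr), rng(cy, g[2] - gr, g[2] + gr),
             rng(cz, g[3] - gr, g[3] + gr))
  if (all(lengths(gi) > 0)) {
    r <- sqrt(outer(outer((cx[gi[[1]]] - g[1])^2, (cy[gi[[2]]] - g[2])^2, "+"),
                    (cz[gi[[3]]] - g[3])^2, "+"))
    sub <- off[gi[[1]], gi[[2]], gi[[3]], drop = FALSE]
    m <- r < gr & inside[gi[[1]], gi[[2]], gi[[3]], drop = FALSE]
    sub[m] <- cspec$cytoplasm_delta_ri +
      (cspec$gradient_delta_ri_max - cspec$cytoplasm_delta_ri) * (1 - r[m] / gr)
    off[gi[[1]], gi[[2]], gi[[3]]] <- sub
  }

  # nucleus ellipsoid
  nc <- cspec$nucleus_center_offset
  ns <- cspec$nucleus_size / 2
  ni <- list(rng(cx, nc[1] - ns[1], nc[1] + ns[1]),
             rng(cy, nc[2] - ns[2], nc[2] + ns[2]),
             rng(cz, nc[3] - ns[3], nc[3] + ns[3]))
  nmask_sub <- NULL
  if (all(lengths(ni) > 0)) {
    nmask_sub <- outer(outer(((cx[ni[[1]]] - nc[1]) / ns[1])^2,
                             ((cy[ni[[2]]] - nc[2]) / ns[2])^2, "+"),
                       ((cz[ni[[3]]] - nc[3]) / ns[3])^2, "+") <= 1
    nmask_sub <- nmask_sub & inside[ni[[1]], ni[[2]], ni[[3]], drop = FALSE]
    sub <- off[ni[[1]], ni[[2]], ni[[3]], drop = FALSE]
    sub[nmask_sub] <- cspec$nucleus_delta_ri
    off[ni[[1]], ni[[2]], ni[[3]]] <- sub
  }

  # nucleoli: spheres spread along x inside the nucleus
  nr <- cspec$nucleoli_radii
  if (length(nr) && !is.null(nmask_sub)) {
    xs <- seq(-ns[1] / 2, ns[1] / 2,
              length.out = max(length(nr), 2L))[seq_along(nr)]
    sub <- off[ni[[1]], ni[[2]], ni[[3]], drop = FALSE]
    for (i in seq_along(nr)) {
      r2 <- outer(outer((cx[ni[[1]]] - nc[1] - xs[i])^2,
                        (cy[ni[[2]]] - nc[2])^2, "+"),
                  (cz[ni[[3]]] - nc[3])^2, "+")
      sub[nmask_sub & r2 <= nr[i]^2] <- cspec$nucleoli_delta_ri
    }
    off[ni[[1]], ni[[2]], ni[[3]]] <- sub
  }

  # resolution bar groups, one row per frequency and axis (x then y)
  groups <- NULL
  freqs <- cspec$line_group_frequencies
  if (length(freqs)) {
    periods <- 1000 / freqs                      # lp/mm -> um period
    gap_between <- 0.8                           # um between groups
    z_lo <- -cspec$line_height / 2
    z_hi <- cspec$line_height / 2
    ziL <- rng(cz, z_lo, z_hi)
    rows <- list()
    for (axis in c("x", "y")) {
      total <- sum(cspec$lines_per_group * periods) +
        gap_between * (length(freqs) - 1)
      start <- -total / 2
      # x-frequency row sits below the centre, y-frequency row to the right
      if (axis == "x") { ylo <- -cspec$ellipsoid_size[2] * 0.22 - cspec$line_length / 2
                         yhi <- ylo + cspec$line_length }
      else             { ylo <- cspec$ellipsoid_size[1] * 0.04
                         yhi <- ylo + cspec$line_length }
      for (i in seq_along(freqs)) {
        p <- periods[i]; bw <- p / 2
        g_lo <- start
        for (k in seq_len(cspec$lines_per_group)) {
          b_lo <- start + (k - 1) * p
          if (axis == "x") {
            xi <- which(cx >= b_lo & cx < b_lo + bw)
            yi <- which(cy >= ylo & cy < yhi)
          } else {
            xi <- which(cx >= ylo & cx < yhi)
            yi <- which(cy >= b_lo & cy < b_lo + bw)
          }
          if (length(xi) && length(yi) && length(ziL)) {
            sub <- off[xi, yi, ziL, drop = FALSE]
            m <- inside[xi, yi, ziL, drop = FALSE]
            sub[m] <- cspec$line_group_delta_ri
            off[xi, yi, ziL] <- sub
          }
        }
        g_hi <- start + cspec$lines_per_group * p
        rows[[length(rows) + 1L]] <- data.frame(
          frequency = freqs[i], period = p, bar_width = bw,
          lo = g_lo + ctr[if (axis == "x") 1L else 2L],
          hi = g_hi + ctr[if (axis == "x") 1L else 2L],
          line_lo = ylo + ctr[if (axis == "x") 2L else 1L],
          line_hi = yhi + ctr[if (axis == "x") 2L else 1L],
          z_lo = z_lo + ctr[3], z_hi = z_hi + ctr[3], axis = axis)
        start <- g_hi + gap_between
      }
    }
    groups <- do.call(rbind, rows)
  }

  out <- ri_volume(spec$n_background + off, voxel_pitch,
                   origin = c(0, 0, 0), n_background = spec$n_background)
  attr(out, "line_groups") <- groups
  out
}
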