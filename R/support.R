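# Object-support generation for the Gerchberg-Papoulis loop: threshold
# the initial delta-n map, keep the largest connected component, dilate.

# 6-connected component labelling by iterative minimum-label propagation.
#' @noRd
label_components_3d <- function(mask) {
  d <- dim(mask)
  lab <- array(0, d)
  lab[mask] <- seq_len(sum(mask))
  shift_min <- function(l) {
    m <- l
    m[-1, , ]    <- pmin(m[-1, , ],    l[-d[1], , ])
    m[-d[1], , ] <- pmin(m[-d[1], , ], l[-1, , ])
    m[, -1, ]    <- pmin(m[, -1, ],    l[, -d[2], ])
    m[, -d[2], ] <- pmin(m[, -d[2], ], l[, -1, ])
    m[, , -1]    <- pmin(m[, , -1],    l[, , -d[3]])
    m[, , -d[3]] <- pmin(m[, , -d[3]], l[, , -1])
    m
  }
  big <- .Machine$integer.max
  l <- lab; l[!mask] <- big
  repeat {
    l2 <- shift_min(l)
    l2[!mask] <- big
    if (identical(l2, l)) break
    l <- l2
  }
  l[!mask] <- 0
  l
}

# binary dilation by k steps of the 26-neighbourhood (Chebyshev ball)
#' @noRd
dilate_mask_steps <- function(mask, k) {
  d <- dim(mask)
  for (s in seq_len(k)) {
    m <- mask
    m[-1, , ]    <- m[-1, , ]    | mask[-d[1], , ]
    m[-d[1], , ] <- m[-d[1], , ] | mask[-1, , ]
    mask2 <- m
    m <- mask2
    m[, -1, ]    <- m[, -1, ]    | mask2[, -d[2], ]
    m[, -d[2], ] <- m[, -d[2], ] | mask2[, -1, ]
    mask2 <- m
    m <- mask2
    m[, , -1]    <- m[, , -1]    | mask2[, , -d[3]]
    m[, , -d[3]] <- m[, , -d[3]] | mask2[, , -1]
    mask <- m
  }
  mask
}

#' Binarize an initial reconstruction into an object support
#'
#' Thresholds the delta-n histogram (Otsu by default), keeps the largest
#' 6-connected component and dilates it by `dilation` voxels
#' (26-neighbourhood steps).
#'
#' @param init an [ri_volume()] (typically the TV-regularized initial
#'   reconstruction)
#' @param method `"otsu"` or a numeric delta-n threshold
#' @param dilation dilation steps in voxels
#' @return logical 3D array (class `support_mask` attribute set)
#' @export
make_support <- function(init, method = "otsu", dilation = 2L) {
  dn <- init$values - if (!is.na(init$n_background)) init$n_background else min(init$values)
  if (identical(method, "otsu")) {
    rng <- range(dn)
    if (diff(rng) < 1e-12) stop("no object detected: constant volume")
    thr <- EBImage::otsu(matrix(dn, nrow = length(dn), ncol = 1), range = rng)
  } else thr <- as.numeric(method)
  mask <- dn > thr
  if (!any(mask)) stop("no object detected: empty mask after threshold")
  lab <- label_components_3d(mask)
  tab <- tabulate(lab[lab > 0])
  mask <- lab == which.max(tab)
  if (dilation > 0) mask <- dilate_mask_steps(mask, as.integer(dilation))
  structure(mask, class = c("support_mask", class(mask)))
}
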