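# Isotropic total variation on 3D grids: forward differences with
# Neumann (replicate) boundaries, the matching negative-adjoint
# divergence, the TV seminorm, and an approximate proximal map computed
# with Chambolle's dual projection algorithm.

# forward differences along each axis; last plane is 0 (Neumann)
#' @noRd
grad3 <- function(x) {
  d <- dim(x)
  gx <- array(0, d); gy <- array(0, d); gz <- array(0, d)
  if (d[1] > 1) gx[-d[1], , ] <- x[-1, , ] - x[-d[1], , ]
  if (d[2] > 1) gy[, -d[2], ] <- x[, -1, ] - x[, -d[2], ]
  if (d[3] > 1) gz[, , -d[3]] <- x[, , -1] - x[, , -d[3]]
  list(x = gx, y = gy, z = gz)
}

# divergence = -adjoint of grad3
#' @noRd
div3 <- function(p) {
  d <- dim(p$x)
  out <- array(0, d)
  if (d[1] > 1) {
    out[1, , ] <- p$x[1, , ]
    if (d[1] > 2) out[2:(d[1] - 1), , ] <- p$x[2:(d[1] - 1), , ] - p$x[1:(d[1] - 2), , ]
    out[d[1], , ] <- -p$x[d[1] - 1, , ]
  }
  if (d[2] > 1) {
    out[, 1, ] <- out[, 1, ] + p$y[, 1, ]
    if (d[2] > 2) out[, 2:(d[2] - 1), ] <- out[, 2:(d[2] - 1), ] + p$y[, 2:(d[2] - 1), ] - p$y[, 1:(d[2] - 2), ]
    out[, d[2], ] <- out[, d[2], ] - p$y[, d[2] - 1, ]
  }
  if (d[3] > 1) {
    out[, , 1] <- out[, , 1] + p$z[, , 1]
    if (d[3] > 2) out[, , 2:(d[3] - 1)] <- out[, , 2:(d[3] - 1)] + p$z[, , 2:(d[3] - 1)] - p$z[, , 1:(d[3] - 2)]
    out[, , d[3]] <- out[, , d[3]] - p$z[, , d[3] - 1]
  }
  out
}

#' Isotropic total variation of a 3D scalar field
#'
#' @param x 3D numeric array or [ri_volume()]
#' @return scalar TV seminorm (sum of gradient magnitudes, forward
#'   differences, Neumann boundaries)
#' @export
tv_norm <- function(x) {
  if (inherits(x, "ri_volume")) x <- x$values
  g <- grad3(x)
  sum(sqrt(g$x^2 + g$y^2 + g$z^2))
}

#' Approximate proximal map of isotropic TV
#'
#' Solves `argmin_u 0.5 ||u - x||^2 + weight * TV(u)` with `n_inner`
#' iterations of Chambolle's projection algorithm on the dual problem
#' (step 1/12, the 3D stability bound). `weight = 0` is the identity.
#'
#' @param x 3D numeric array or [ri_volume()]
#' @param weight TV weight (>= 0), in the units of `x`
#' @param n_inner dual iterations (default 20)
#' @return same type as `x`
#' @export
tv_prox <- function(x, weight, n_inner = 20L) {
  if (weight < 0) stop("weight must be >= 0")
  isvol <- inherits(x, "ri_volume")
  v <- if (isvol) x$values else x
  if (weight == 0 || n_inner < 1L) return(x)
  d <- dim(v)
  p <- list(x = array(0, d), y = array(0, d), z = array(0, d))
  tau <- 1 / 12
  for (it in seq_len(n_inner)) {
    g <- grad3(div3(p) - v / weight)
    denom <- 1 + tau * sqrt(g$x^2 + g$y^2 + g$z^2)
    p$x <- (p$x + tau * g$x) / denom
    p$y <- (p$y + tau * g$y) / denom
    p$z <- (p$z + tau * g$z) / denom
  }
  out <- v - weight * div3(p)
  if (isvol) { x$values <- out; x } else out
}
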