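# Gerchberg-Papoulis with object support (GPSC): iterative refinement of
# the Direct Inversion estimate. Signal-domain constraints (nonnegative
# delta-n, finite support) alternate with replenishment of the measured
# frequencies; both constraint sets are convex in the scattering-potential
# domain, so the measured-frequency misfit is non-increasing.

#' TV-regularized initial reconstruction
#'
#' Solves the linearized tomographic problem
#' `min_x 0.5 || M F x - y ||^2 + lambda TV(x)` with Chambolle-Pock
#' primal-dual iterations, where `M F` samples the unitary 3D spectrum on
#' the frequencies covered by the Ewald caps and `y` is the gridded
#' measured spectrum. With `tv_weight = 0` the solution matches the
#' Direct Inversion (minimum-norm least squares) output. The absolute TV
#' weight is `tv_weight * max |x_DI|`, i.e. relative to the data term's
#' natural scale; `1e-2` acts as the "strong" setting used for support
#' generation, `1e-3` as a weak one.
#'
#' @param pset a [projection_set()]
#' @param tv_weight relative TV weight (>= 0)
#' @param n_iter Chambolle-Pock iterations
#' @param di optional precomputed [direct_inversion()] result (saves one
#'   pass)
#' @return an [ri_volume()]
#' @export
tv_initial_reconstruction <- function(pset, tv_weight = 1e-2, n_iter = 50L,
                                      di = NULL) {
  if (is.null(di)) di <- direct_inversion(pset)
  cfg <- pset$config
  k0 <- 2 * pi / wavelength_um(cfg)
  n0 <- cfg$n_immersion
  vol0 <- di$volume
  dims <- dim(vol0$values)
  pitch3 <- vol0$voxel_pitch
  mask <- di$coverage$filled_mask
  sn <- sqrt(prod(dims))

  # data in unitary-DFT units: Y = DFT(V_DI) / sqrt(N) on the mask
  V_di <- k0^2 * (vol0$values^2 - n0^2)
  Y <- (stats::fft(V_di) / sn)[mask]
  lambda <- tv_weight * max(abs(V_di))

  A <- function(x) (stats::fft(x) / sn)[mask]
  At <- function(q) {
    Q <- array(0 + 0i, dims)
    Q[mask] <- q
    Re(stats::fft(Q, inverse = TRUE)) / sn
  }

  tau <- sigma <- 1 / sqrt(13)        # ||[A; grad]||^2 <= 1 + 12
  x <- array(0, dims)
  xbar <- x
  q <- complex(length.out = sum(mask))
  p <- list(x = array(0, dims), y = array(0, dims), z = array(0, dims))
  mis_prev <- Inf; n_up <- 0L
  for (it in seq_len(n_iter)) {
    q <- (q + sigma * (A(xbar) - Y)) / (1 + sigma)
    if (lambda > 0) {
      g <- grad3(xbar)
      px <- p$x + sigma * g$x; py <- p$y + sigma * g$y; pz <- p$z + sigma * g$z
      nrm <- pmax(1, sqrt(px^2 + py^2 + pz^2) / lambda)
      p <- list(x = px / nrm, y = py / nrm, z = pz / nrm)
    }
    x_new <- x - tau * (At(q) - if (lambda > 0) div3(p) else 0)
    xbar <- 2 * x_new - x
    x <- x_new
    mis <- sum(Mod(A(x) - Y)^2)
    n_up <- if (mis > mis_prev) n_up + 1L else 0L
    if (n_up >= 50L) {
      warning("TV initializer not converging; returning current iterate")
      break
    }
    mis_prev <- mis
  }
  n <- sqrt(pmax(n0^2 + x / k0^2, 0))
  ri_volume(n, pitch3, vol0$origin, n_background = n0)
}

#' Gerchberg-Papoulis reconstruction with object support
#'
#' Starting from the Direct Inversion estimate, iterates between the
#' signal domain -- delta-n clamped nonnegative and to zero outside the
#' support -- and the frequency domain, where the measured (gridded)
#' spectrum is re-imposed on its covered frequencies. Terminates via the
#' median-dynamics rule with saturation level `eps` (0.02 for this
#' algorithm in the reference configuration).
#'
#' @param pset a [projection_set()]
#' @param support logical 3D array from [make_support()]
#' @param eps stopping saturation level
#' @param max_iter iteration cap
#' @param di optional precomputed [direct_inversion()] result
#' @return list with `volume` (an [ri_volume()]) and `history`
#'   (a [recon_history()])
#' @export
gpsc_reconstruct <- function(pset, support, eps = 0.02, max_iter = 100L,
                             di = NULL) {
  if (!any(support)) stop("support mask is empty")
  if (is.null(di)) di <- direct_inversion(pset)
  cfg <- pset$config
  k0 <- 2 * pi / wavelength_um(cfg)
  n0 <- cfg$n_immersion
  vol0 <- di$volume
  dims <- dim(vol0$values)
  mask <- di$coverage$filled_mask
  Yg <- dft_spectrum_grid(di$coverage$accumulated_spectrum, vol0$voxel_pitch)
  Ym <- Yg[mask]

  V <- k0^2 * (vol0$values^2 - n0^2)       # state: scattering potential
  history <- recon_history()
  first_norm <- NA_real_
  for (it in seq_len(max_iter)) {
    V_old <- V
    # (a) signal domain: nonnegativity + finite support
    V[V < 0] <- 0
    V[!support] <- 0
    # (b) frequency domain: misfit on measured bins, then replenish
    S <- stats::fft(V)
    mis <- sum(Mod(S[mask] - Ym)^2) / max(sum(Mod(Ym)^2), .Machine$double.eps)
    S[mask] <- Ym
    V <- Re(stats::fft(S, inverse = TRUE)) / prod(dims)
    dn_step <- sqrt(sum((V - V_old)^2))
    # a first step at rounding level means the input was already a fixed
    # point of both constraint sets
    v_scale <- max(sqrt(sum(V_old^2)), 1e-300)
    if (it == 1L) first_norm <- if (dn_step <= 1e-9 * v_scale) 0 else dn_step
    dk <- if (is.na(first_norm) || first_norm == 0) 0 else dn_step / first_norm
    history <- history_append(history, dk, mis)
    if (first_norm == 0 || should_stop(history, eps)) break
  }
  # return an iterate that satisfies the signal-domain constraints exactly
  V[V < 0] <- 0
  V[!support] <- 0
  n <- sqrt(pmax(n0^2 + V / k0^2, 0))
  out <- ri_volume(n, vol0$voxel_pitch, vol0$origin, n_background = n0)
  list(volume = out, history = history)
}

# continuous-FT-scaled spectrum (as stored in frequency_coverage) ->
# plain DFT-grid spectrum of the potential volume
#' @noRd
dft_spectrum_grid <- function(spec, pitch3) {
  dims <- dim(spec)
  phs <- lapply(1:3, function(a)
    exp(1i * fft_freq(dims[a], pitch3[a]) * (0.5 - dims[a] / 2) * pitch3[a]))
  spec * outer(outer(phs[[1]], phs[[2]]), phs[[3]]) / prod(pitch3)
}
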