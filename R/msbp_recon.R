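# Multiple-scattering reconstruction: Learning-Tomography style loop on
# the multi-slice beam propagation model. MSBP-E fits the measured
# complex fields; MSBP-I fits amplitudes only. The misfit gradient is the
# exact adjoint of the discrete forward chain (phase screens +
# angular-spectrum steps + mid-plane registration + pupil), so
# finite-difference checks agree to first order.

#' Settings for the MSBP reconstruction loop
#'
#' @param mode `"field"` (MSBP-E, complex-field data) or `"intensity"`
#'   (MSBP-I, amplitude-only data)
#' @param step_size maximal delta-n increment applied by the first
#'   per-projection update; the internal gradient scale is fixed from it
#'   and halved whenever the epoch misfit increases. Default `NULL`:
#'   `3e-4` in field mode, `2e-4` in intensity mode (the amplitude-only
#'   objective starting from zeros needs the gentler step)
#' @param tv_weight TV proximal weight in RI units (applied once per full
#'   cycle over the projections)
#' @param eps stopping saturation level for the median-dynamics rule
#'   (0.01 for both MSBP variants in the reference configuration)
#' @param max_iter cap on full cycles
#' @param init `"direct_inversion"`, `"zeros"`, an [ri_volume()] or
#'   `NULL` for the mode default (field -> direct inversion,
#'   intensity -> zeros)
#' @param nonneg clamp delta-n to >= 0 after each TV step
#' @param pad_factor padding for the forward model
#' @return an object of class `msbp_settings`
#' @export
msbp_settings <- function(mode = c("field", "intensity"),
                          step_size = NULL, tv_weight = 2e-5,
                          eps = 0.01, max_iter = 40L, init = NULL,
                          nonneg = TRUE, pad_factor = 2) {
  mode <- match.arg(mode)
  if (is.null(step_size)) step_size <- if (mode == "field") 3e-4 else 2e-4
  if (step_size <= 0) stop("step_size must be > 0")
  if (is.null(init)) init <- if (mode == "field") "direct_inversion" else "zeros"
  structure(list(mode = mode, step_size = step_size, tv_weight = tv_weight,
                 eps = eps, max_iter = as.integer(max_iter), init = init,
                 nonneg = nonneg, pad_factor = pad_factor),
            class = "msbp_settings")
}

#' @noRd
mode_residual <- function(sim, meas, mode) {
  if (mode == "field") return(sim - meas)
  amp <- Mod(sim)
  (amp - Mod(meas)) * sim / pmax(amp, 1e-12)
}

#' Data misfit of a volume estimate against a projection set
#'
#' `sum ||simulated - measured||^2` over projections in field mode;
#' `sum (|simulated| - |measured|)^2` in intensity mode (amplitude
#' misfit, phase of the data ignored).
#'
#' @param volume an [ri_volume()]
#' @param pset a [projection_set()]
#' @param mode `"field"` or `"intensity"`
#' @param pad_factor forward-model padding
#' @return list with `misfit` (scalar) and `residuals` (list of complex
#'   matrices, the Wirtinger residual fields used by [msbp_gradient()])
#' @export
msbp_residual <- function(volume, pset, mode = c("field", "intensity"),
                          pad_factor = 2) {
  mode <- match.arg(mode)
  cfg <- pset$config
  res <- vector("list", length(pset$fields))
  mis <- 0
  for (i in seq_along(pset$fields)) {
    f <- pset$fields[[i]]
    sim <- msbp_forward(volume, f$direction, cfg, apply_pupil = TRUE,
                        pad_factor = pad_factor)
    r <- mode_residual(sim$values, f$values, mode)
    mis <- mis + if (mode == "field") sum(Mod(sim$values - f$values)^2)
      else sum((Mod(sim$values) - Mod(f$values))^2)
    res[[i]] <- r
  }
  list(misfit = mis, residuals = res)
}

# adjoint backpropagation of one residual through the cached forward chain
#' @noRd
msbp_backprop <- function(core, r_crop) {
  np <- core$np
  R <- matrix(0 + 0i, np[1], np[2])
  R[core$xi, core$yi] <- r_crop
  U <- fft2(R)
  if (!is.null(core$pupil)) U[!core$pupil] <- 0
  v <- ifft2(U * Conj(core$Hback))
  nz <- length(core$states)
  d1 <- length(core$xi); d2 <- length(core$yi)
  g <- array(0, c(d1, d2, nz))
  for (j in nz:1) {
    v <- ifft2(fft2(v) * Conj(core$Hdz))         # adjoint of the slice step
    a <- core$states[[j]] * core$screens[[j]]
    gj <- Re(1i * core$dn_scale * a * Conj(v))
    g[, , j] <- gj[core$xi, core$yi]
    v <- v * Conj(core$screens[[j]])
  }
  g
}

#' Misfit gradient with respect to the refractive-index volume
#'
#' Applies the adjoint of the multi-slice forward model to the residual
#' fields of every projection and sums the contributions. The result is
#' the exact gradient of [msbp_residual()]'s misfit with respect to
#' delta-n, on the volume grid.
#'
#' @param volume an [ri_volume()]
#' @param residuals `residuals` element from [msbp_residual()] (computed
#'   on the same volume)
#' @param pset the matching [projection_set()]
#' @param mode `"field"` or `"intensity"`
#' @param pad_factor forward-model padding
#' @return real 3D array, same dims as the volume
#' @export
msbp_gradient <- function(volume, residuals, pset,
                          mode = c("field", "intensity"), pad_factor = 2) {
  mode <- match.arg(mode)
  g <- array(0, dim(volume$values))
  for (i in seq_along(pset$fields)) {
    core <- msbp_core(volume, pset$fields[[i]]$direction, pset$config,
                      apply_pupil = TRUE, pad_factor = pad_factor,
                      keep_states = TRUE)
    g <- g + 2 * msbp_backprop(core, residuals[[i]])
  }
  g
}

#' MSBP iterative reconstruction (MSBP-E / MSBP-I)
#'
#' Learning-Tomography loop: sequential per-projection gradient updates
#' (fixed cyclic order), followed once per cycle by a TV proximal step, a
#' nonnegativity projection of delta-n, and the median-dynamics stopping
#' test with level `settings$eps`. In intensity mode only the data
#' amplitudes are consumed.
#'
#' @param pset a [projection_set()]
#' @param settings an [msbp_settings()]
#' @return list with `volume` (an [ri_volume()]) and `history`
#'   (a [recon_history()])
#' @export
msbp_reconstruct <- function(pset, settings = msbp_settings()) {
  cfg <- pset$config
  n0 <- cfg$n_immersion
  g <- pset_geometry(pset)
  mode <- settings$mode

  vol <- settings$init
  if (identical(vol, "direct_inversion")) vol <- direct_inversion(pset)$volume
  else if (identical(vol, "zeros")) {
    dims <- c(dim(pset$fields[[1]]$values), g$nz)
    vol <- ri_volume(array(n0, dims),
                     c(g$pitch_um, g$pitch_um, g$thickness_um / g$nz),
                     n_background = n0)
  }
  if (!inherits(vol, "ri_volume")) stop("invalid init")

  history <- recon_history()
  first_norm <- NA_real_
  grad_scale <- NA_real_
  mis_prev <- Inf
  n_div <- 0L
  for (it in seq_len(settings$max_iter)) {
    v_old <- vol$values
    mis_epoch <- 0
    for (i in seq_along(pset$fields)) {
      f <- pset$fields[[i]]
      core <- msbp_core(vol, f$direction, cfg, apply_pupil = TRUE,
                        pad_factor = settings$pad_factor, keep_states = TRUE)
      r <- mode_residual(core$field$values, f$values, mode)
      mis_epoch <- mis_epoch + if (mode == "field")
        sum(Mod(core$field$values - f$values)^2)
      else sum((Mod(core$field$values) - Mod(f$values))^2)
      gi <- 2 * msbp_backprop(core, r)
      if (is.na(grad_scale)) {
        gm <- max(abs(gi))
        grad_scale <- if (gm > 0) settings$step_size / gm else 0
      }
      vol$values <- vol$values - grad_scale * gi
    }
    # converged before regularization: the data gradient no longer moves
    # the estimate (e.g. initialized at the global minimum)
    grad_step <- sqrt(sum((vol$values - v_old)^2))
    vol_scale <- max(sqrt(sum((v_old - n0)^2)), 1e-12)
    if (grad_step <= 1e-8 * vol_scale) {
      history <- history_append(history, 0, mis_epoch)
      break
    }
    if (settings$tv_weight > 0) {
      dn <- tv_prox(vol$values - n0, settings$tv_weight)
      vol$values <- n0 + dn
    }
    if (settings$nonneg) vol$values <- pmax(vol$values, n0)

    if (mis_epoch > mis_prev) {
      grad_scale <- grad_scale / 2
      n_div <- n_div + 1L
      if (n_div >= 20L) stop("step size too large: misfit diverging")
    } else n_div <- 0L
    mis_prev <- mis_epoch

    step_norm <- sqrt(sum((vol$values - v_old)^2))
    if (it == 1L) first_norm <- step_norm
    dk <- if (is.na(first_norm) || first_norm == 0) 0 else step_norm / first_norm
    history <- history_append(history, dk, mis_epoch)
    if (first_norm == 0 || should_stop(history, settings$eps)) break
  }
  list(volume = vol, history = history)
}
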