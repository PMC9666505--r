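# Shared convergence machinery: per-iteration "dynamics" (relative change
# between consecutive volume estimates) and the median-dynamics stopping
# rule used by all three reconstruction loops.

#' Reconstruction history
#'
#' Ordered per-iteration record of the dynamics values and data-misfit
#' scalars driving the stopping criterion.
#'
#' @param dynamics numeric vector of per-iteration dynamics (>= 0)
#' @param misfit numeric vector of per-iteration data misfits, same length
#' @return an object of class `recon_history`
#' @export
recon_history <- function(dynamics = numeric(0), misfit = numeric(0)) {
  if (length(dynamics) != length(misfit))
    stop("dynamics and misfit must have equal length")
  if (any(dynamics < 0)) stop("dynamics must be >= 0")
  structure(list(dynamics = dynamics, misfit = misfit,
                 n_iter = length(dynamics)),
            class = "recon_history")
}

#' @noRd
history_append <- function(history, dynamics, misfit) {
  recon_history(c(history$dynamics, dynamics), c(history$misfit, misfit))
}

#' Relative change between consecutive volume estimates
#'
#' `d_k = ||current - previous||_2 / first_step_norm`, where
#' `first_step_norm = ||x_1 - x_0||_2` is the norm of the first update.
#' Normalizing by the first step makes the saturation threshold epsilon
#' scale-free; by construction `d_1 = 1`. A zero first step means the
#' iteration converged immediately and the dynamics is defined as 0.
#'
#' @param current,previous volumes (`ri_volume` or plain arrays) on the
#'   same grid
#' @param first_step_norm norm of the first update (`||x_1 - x_0||`)
#' @return scalar dynamics value
#' @export
dynamics <- function(current, previous, first_step_norm) {
  a <- if (inherits(current, "ri_volume")) current$values else current
  b <- if (inherits(previous, "ri_volume")) previous$values else previous
  if (!identical(dim(a), dim(b))) stop("grid mismatch")
  if (first_step_norm == 0) return(0)
  sqrt(sum((a - b)^2)) / first_step_norm
}

#' Median-dynamics stopping rule
#'
#' Stops when the median of the dynamics over the last 10 iterations
#' falls below the saturation level `eps`. The median (standard midpoint
#' of the 5th/6th order statistics for the even window) needs a full
#' window, so the rule never fires before 10 recorded iterations.
#' Empirically chosen levels: `eps = 0.02` for GPSC, `0.01` for the MSBP
#' variants.
#'
#' @param history a [recon_history()]
#' @param eps saturation level, > 0
#' @param window window length (default 10)
#' @return logical
#' @export
should_stop <- function(history, eps, window = 10L) {
  if (eps <= 0) stop("eps must be > 0")
  n <- length(history$dynamics)
  if (n < window) return(FALSE)
  stats::median(history$dynamics[(n - window + 1L):n]) < eps
}
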