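# MSBP residual, adjoint gradient and the Learning-Tomography loops.

n0 <- 1.5123

small_pair <- function() fixture("msbp_small", function() {
  set.seed(7)
  n <- 12L; nz <- 6L; p <- 0.3
  cfg <- optical_config(n_projections = 2, azimuth_step_deg = 180,
                        zenith_deg = 30)
  vol <- ri_volume(array(n0 + 0.003 * runif(n * n * nz), c(n, n, nz)),
                   p, n_background = n0)
  target <- ri_volume(array(n0 + 0.003 * runif(n * n * nz), c(n, n, nz)),
                      p, n_background = n0)
  list(vol = vol, ps = simulate_projection_set(target, cfg), cfg = cfg)
})

test_that("residual vanishes on the generating volume and validates mode", {
  w <- weak_fixture()
  rr <- msbp_residual(w$truth, w$ps, "field")
  data_norm <- sum(vapply(w$ps$fields, function(f) sum(Mod(f$values)^2),
                          numeric(1)))
  expect_lt(rr$misfit / data_norm, 1e-10)
  expect_error(msbp_residual(w$truth, w$ps, "phase"), "arg")
})

test_that("intensity misfit ignores the data phase", {
  sm <- small_pair()
  ps2 <- sm$ps
  for (i in seq_along(ps2$fields))
    ps2$fields[[i]]$values <- ps2$fields[[i]]$values * exp(1i * 0.7)
  m1 <- msbp_residual(sm$vol, sm$ps, "intensity")$misfit
  m2 <- msbp_residual(sm$vol, ps2, "intensity")$misfit
  expect_equal(m1, m2, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(
    msbp_residual(sm$vol, sm$ps, "field")$misfit,
    msbp_residual(sm$vol, ps2, "field")$misfit)))
})

test_that("the adjoint gradient matches finite differences in both modes", {
  sm <- small_pair()
  d <- dim(sm$vol$values)
  for (mode in c("field", "intensity")) {
    rr <- msbp_residual(sm$vol, sm$ps, mode)
    g <- msbp_gradient(sm$vol, rr$residuals, sm$ps, mode)
    set.seed(9)
    dirn <- array(rnorm(prod(d)), d); dirn <- dirn / sqrt(sum(dirn^2))
    h <- 1e-7
    vp <- sm$vol; vp$values <- vp$values + h * dirn
    vm <- sm$vol; vm$values <- vm$values - h * dirn
    fd <- (msbp_residual(vp, sm$ps, mode)$misfit -
           msbp_residual(vm, sm$ps, mode)$misfit) / (2 * h)
    expect_lt(abs(sum(g * dirn) - fd) / abs(fd), 1e-4)
  }
})

test_that("zero residuals give a zero gradient", {
  sm <- small_pair()
  zero_res <- lapply(sm$ps$fields, function(f) f$values * 0)
  g <- msbp_gradient(sm$vol, zero_res, sm$ps, "field")
  expect_equal(max(abs(g)), 0)
})

test_that("the ground truth is a fixed point of the iteration", {
  w <- weak_fixture()
  res <- msbp_reconstruct(w$ps, msbp_settings("field", init = w$truth,
                                              max_iter = 5))
  expect_lt(max(abs(res$volume$values - w$truth$values)), 1e-6)
  expect_equal(res$history$n_iter, 1L)
})

test_that("MSBP-E converges on noise-free data and beats its initialization", {
  w <- weak_fixture()
  res <- fixture("weak_msbpe", function()
    msbp_reconstruct(w$ps, msbp_settings("field", max_iter = 25)))
  expect_lt(tail(res$history$misfit, 1) / res$history$misfit[1], 0.01)
  expect_lt(rmse_in(res$volume, w$truth, w$obj),
            rmse_in(w$di$volume, w$truth, w$obj))
})

test_that("misfit is non-increasing without TV at a small step", {
  sm <- small_pair()
  res <- msbp_reconstruct(sm$ps, msbp_settings(
    "field", step_size = 5e-5, tv_weight = 0, nonneg = FALSE,
    init = sm$vol, max_iter = 12))
  expect_true(all(diff(res$history$misfit) <= 1e-12))
})

test_that("intensity-only reconstruction shows stronger low-frequency error", {
  s <- strong_fixture()
  w <- weak_fixture()
  ps <- fixture("weak_noisy", function()
    add_phase_noise(w$ps, 0.10, seed = 11L))
  me <- fixture("noisy_msbpe", function()
    msbp_reconstruct(ps, msbp_settings("field", step_size = 2e-4,
                                       max_iter = 15)))
  mi <- fixture("noisy_msbpi", function()
    msbp_reconstruct(ps, msbp_settings("intensity", step_size = 2e-4,
                                       max_iter = 15)))
  shell_rms <- function(vol) {
    e <- vol$values - w$truth$values
    E <- stats::fft(e)
    d <- dim(e)
    kv <- lapply(d, function(n)
      c(seq(0, floor((n - 1) / 2)), seq(-floor(n / 2), -1)) / n)
    KR <- sqrt(outer(outer(kv[[1]]^2, kv[[2]]^2, "+"), kv[[3]]^2, "+"))
    sqrt(mean(Mod(E[KR < 0.06])^2))
  }
  expect_gt(shell_rms(mi$volume) / shell_rms(me$volume), 1)
})
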