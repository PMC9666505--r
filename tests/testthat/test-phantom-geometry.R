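# Rod-layer sampling, rasterization, cell target and composition.

test_that("rod layouts cover the cube with alternating layers", {
  sp <- phantom_spec()
  lay <- sample_rod_layouts(sp, 1L)
  expect_length(lay, 28L)                       # floor-fit of 1.8 um rods on 1.4 um pitch in 40 um
  zc <- vapply(lay, `[[`, numeric(1), "z_center")
  expect_equal(diff(zc), rep(sp$layer_pitch, 27L))
  expect_true(min(zc) - sp$rod_height / 2 >= 0)
  expect_true(max(zc) + sp$rod_height / 2 <= sp$cube_size[3])
  ori <- vapply(lay, `[[`, character(1), "orientation")
  expect_equal(unique(ori[c(TRUE, FALSE)]), "x")
  expect_equal(unique(ori[c(FALSE, TRUE)]), "y")
  # gaps fall inside the configured interval
  gaps <- unlist(lapply(lay, function(l) diff(l$rod_positions) - sp$rod_width))
  expect_true(all(gaps >= sp$rod_gap_range[1] - 1e-9))
  expect_true(all(gaps <= sp$rod_gap_range[2] + 1e-9))
})

test_that("degenerate gap interval gives a periodic layout", {
  sp <- phantom_spec(rod_gap_range = c(1, 1))
  lay <- sample_rod_layouts(sp, 5L)
  pitches <- unlist(lapply(lay, function(l) diff(l$rod_positions)))
  expect_equal(pitches, rep(1.5, length(pitches)))  # width + gap
})

test_that("layout sampling is deterministic per seed and errors on degenerate cubes", {
  sp <- phantom_spec()
  expect_identical(sample_rod_layouts(sp, 42L), sample_rod_layouts(sp, 42L))
  expect_false(identical(sample_rod_layouts(sp, 1L), sample_rod_layouts(sp, 2L)))
  expect_error(sample_rod_layouts(phantom_spec(cube_size = c(60, 60, 1))),
               "degenerate cube")
})

test_that("sampled gaps are uniform on the configured interval", {
  sp <- phantom_spec(cube_size = c(60, 60, 40))
  gaps <- numeric(0)
  s <- 0L
  while (length(gaps) < 1e4) {
    s <- s + 1L
    lay <- sample_rod_layouts(sp, s)
    gaps <- c(gaps, unlist(lapply(lay, function(l)
      diff(l$rod_positions) - sp$rod_width)))
  }
  ks <- stats::ks.test(gaps, "punif", 0.7, 3.0)
  expect_gt(ks$p.value, 0.01)
})

test_that("rasterization renders exact rod cross-sections", {
  sp <- phantom_spec(cube_size = c(4, 4, 4))
  lay <- list(list(z_center = 2, orientation = "x", rod_positions = 2))
  vol <- rasterize_scattering_cube(lay, sp, 0.1)
  occ <- vol$values > sp$n_background
  # cross-section perpendicular to the rod axis: width x height
  cs <- occ[20, , ]
  expect_equal(sum(rowSums(cs) > 0), 5L)        # 0.5 um wide at 0.1 um pitch
  expect_equal(sum(colSums(cs) > 0), 18L)       # 1.8 um tall
  expect_equal(sum(cs), 5L * 18L)
  # rod extends through the whole cube along its axis
  expect_true(all(apply(occ, 1, sum) == sum(cs)))
})

test_that("rasterization handles empty layouts and enforces sampling", {
  sp <- phantom_spec(cube_size = c(4, 4, 4))
  vol <- rasterize_scattering_cube(list(), sp, 0.1)
  expect_true(all(vol$values == sp$n_background))
  expect_error(rasterize_scattering_cube(list(), sp, 0.3),
               "undersampled")
})

test_that("generated volumes keep the exact design RI range", {
  sp <- phantom_spec(cube_size = c(10, 10, 8))
  vol <- rasterize_scattering_cube(sample_rod_layouts(sp, 3L), sp, 0.2)
  expect_identical(min(vol$values), sp$n_background)
  expect_lte(max(vol$values) - sp$n_background, sp$delta_ri_max + 1e-15)
  expect_equal(max(vol$values) - sp$n_background, sp$delta_ri_max)
})

test_that("fill factor is around a quarter across seeds", {
  sp <- phantom_spec(cube_size = c(30, 30, 20))
  ff <- vapply(1:20, function(s) {
    v <- rasterize_scattering_cube(sample_rod_layouts(sp, s), sp, 0.25)
    compute_fill_factor(v)
  }, numeric(1))
  expect_gte(mean(ff), 0.20)
  expect_lte(mean(ff), 0.30)
})

test_that("compute_fill_factor handles trivial regions and errors", {
  sp <- phantom_spec(cube_size = c(2, 2, 2))
  v0 <- ri_volume(array(sp$n_background, c(8, 8, 8)), 0.25,
                  n_background = sp$n_background)
  expect_equal(compute_fill_factor(v0), 0)
  v1 <- ri_volume(array(sp$n_background + 0.03, c(8, 8, 8)), 0.25,
                  n_background = sp$n_background)
  expect_equal(compute_fill_factor(v1), 1)
  expect_error(compute_fill_factor(v0, list(x = integer(0), y = 1:8, z = 1:8)),
               "empty region")
  expect_error(compute_fill_factor(v0, list(x = 1:20, y = 1:8, z = 1:8)),
               "outside")
})

test_that("cell target external dimensions match the design", {
  sp <- phantom_spec(cube_size = c(32, 28, 14))
  cell <- fixture("cell_02", function()
    build_cell_target(cell_target_spec(), sp, 0.2))
  m <- cell$values > sp$n_background + 1e-12
  ext <- vapply(1:3, function(a) {
    idx <- range(which(apply(m, a, any)))
    (diff(idx) + 1) * cell$voxel_pitch[a]
  }, numeric(1))
  expect_true(all(abs(ext - c(30, 25, 12)) <= cell$voxel_pitch + 1e-9))  # one voxel per axis
})

test_that("line groups follow the printed frequency series", {
  sp <- phantom_spec(cube_size = c(32, 28, 14))
  cell <- fixture("cell_02", function()
    build_cell_target(cell_target_spec(), sp, 0.2))
  lg <- attr(cell, "line_groups")
  expect_equal(max(lg$frequency), 1667)
  expect_equal(lg$period[lg$frequency == 1667][1], 1000 / 1667)  # 0.6 um
  expect_equal(lg$bar_width, lg$period / 2)
  for (ax in c("x", "y"))
    expect_true(all(diff(lg$frequency[lg$axis == ax]) > 0))
})

test_that("featureless cell spec yields a single-level truncated ellipsoid", {
  sp <- phantom_spec(cube_size = c(12, 12, 8))
  cs <- cell_target_spec(ellipsoid_size = c(7, 6, 4),
                         line_group_frequencies = numeric(0),
                         nucleoli_radii = numeric(0),
                         nucleus_size = c(0, 0, 0) + 1e-9,
                         gradient_radius = 1e-9,
                         cytoplasm_delta_ri = 0.005)
  cell <- build_cell_target(cs, sp, 0.25)
  lev <- sort(unique(as.vector(cell$values)))
  expect_equal(lev, c(sp$n_background, sp$n_background + 0.005))
})

test_that("cell features beyond the RI cap are rejected", {
  sp <- phantom_spec(cube_size = c(32, 28, 14), delta_ri_max = 0.02)
  expect_error(build_cell_target(cell_target_spec(), sp, 0.25),
               "delta_ri_max")
})

test_that("composition respects clearance and cell priority", {
  sp <- phantom_spec(cube_size = c(8, 8, 6), delta_ri_max = 0.03)
  cs <- cell_target_spec(ellipsoid_size = c(4, 3.5, 2.5),
                         line_group_frequencies = numeric(0),
                         nucleoli_radii = numeric(0),
                         nucleus_size = c(1.5, 1.2, 1),
                         nucleus_center_offset = c(0, 0, 0),
                         gradient_radius = 1e-9)
  lay <- sample_rod_layouts(sp, 2L)
  cube <- rasterize_scattering_cube(lay, sp, 0.25)
  cell <- build_cell_target(cs, sp, 0.25)
  nb <- sp$n_background

  # empty cell -> unchanged cube
  empty <- ri_volume(array(nb, dim(cube$values)), 0.25, n_background = nb)
  expect_equal(compose_phantom(cube, empty, 0.5)$values, cube$values)

  comp <- compose_phantom(cube, cell, 0.5)
  cell_mask <- cell$values > nb + 1e-12
  rod_mask <- comp$values > nb + 1e-12 & !cell_mask
  # cell voxels keep the cell RI
  expect_equal(comp$values[cell_mask], cell$values[cell_mask])
  # brute-force clearance check: every rod voxel >= 0.5 um from the cell
  ci <- which(cell_mask, arr.ind = TRUE)
  ri <- which(rod_mask, arr.ind = TRUE)
  px <- comp$voxel_pitch
  mind <- vapply(seq_len(nrow(ri)), function(i) {
    dd <- (ci[, 1] - ri[i, 1])^2 * px[1]^2 + (ci[, 2] - ri[i, 2])^2 * px[2]^2 +
      (ci[, 3] - ri[i, 3])^2 * px[3]^2
    sqrt(min(dd))
  }, numeric(1))
  expect_true(all(mind >= 0.5 - 1e-9))

  # clearance 0: voxelwise cell-priority overwrite only
  comp0 <- compose_phantom(cube, cell, 0)
  exp0 <- cube$values
  exp0[cell_mask] <- cell$values[cell_mask]
  expect_equal(comp0$values, exp0)

  other <- ri_volume(array(nb, c(4, 4, 4)), 0.25, n_background = nb)
  expect_error(compose_phantom(cube, other, 0.5), "grid mismatch")
})

test_that("phantom generation is bit-reproducible per (spec, seed)", {
  d <- strong_design(seed = 9L)
  v1 <- generate_phantom(d$spec, d$cspec, voxel_pitch = 0.25)
  v2 <- generate_phantom(d$spec, d$cspec, voxel_pitch = 0.25)
  expect_identical(v1$values, v2$values)
})
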