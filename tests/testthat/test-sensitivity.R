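test_that("sweep plans enumerate the half-open angular grid", {
  expect_equal(nrow(sweep_events(sweep_plan(step = 0.5))), 129600)
  ev <- sweep_events(sweep_plan(step = 90))
  expect_equal(nrow(ev), 4)
  expect_equal(ev$azimuth, c(0, 90, 0, 90))
  expect_equal(ev$elevation, c(0, 0, 90, 90))
  for (st in c(0.5, 2, 5, 30)) {
    expect_equal(length(unique(sweep_events(sweep_plan(step = st))$azimuth)),
                 180 / st)
  }
  expect_error(sweep_plan(step = 0), "positive")
  expect_error(sweep_plan(step = 7), "divide")
})

test_that("a single-element focused field is the directivity-weighted 1/r pattern", {
  spec <- single_element_spec()
  arr <- build_array(spec)
  med <- oil_medium()
  vol <- volume_grid(extent = c(0.01, 0.01, 0.2),
                     spacing = c(0.01, 0.01, 0.05))
  f <- focused_field(arr, spec, c(90, 90), med, vol)
  z <- grid_axes(vol)$z
  # on-axis amplitude halves from z to 2z (pure spherical spreading)
  expect_equal(f[1, 1, 1] / f[1, 1, 3], z[3] / z[1], tolerance = 1e-9)
})

test_that("broadside focus on a symmetric array yields a symmetric field", {
  spec <- transducer_spec(n_elements = c(8L, 8L))
  arr <- build_array(spec)
  vol <- small_volume()
  f <- focused_field(arr, spec, c(90, 90), oil_medium(), vol)
  expect_equal(f, f[rev(seq_len(dim(f)[1])), , ], tolerance = 1e-9)
  expect_equal(f, f[, rev(seq_len(dim(f)[2])), ], tolerance = 1e-9)
  expect_error(focused_field(arr, spec, c(0, 0), oil_medium(), vol),
               "hemisphere")
})

test_that("the focal-time field value matches a brute-force delayed-pulse sum", {
  spec <- transducer_spec(n_elements = c(2L, 2L))
  arr <- build_array(spec)
  med <- oil_medium()
  # voxel on the steered ray: focal-time evaluation equals the temporal peak
  for (dir in list(c(90, 90), c(75, 90), c(80, 70))) {
    u <- irai:::steering_direction(dir[1], dir[2])
    p <- 0.1 * u
    vol <- volume_grid(extent = rep(2e-3, 3), spacing = 2e-3,
                       origin = p - 1e-3)
    f <- focused_field(arr, spec, dir, med, vol)
    expect_equal(as.numeric(f),
                 focused_field_oracle(arr, spec, dir, med, p),
                 tolerance = 1e-3)
  }
  # off the ray the temporal-peak search still matches the oracle
  p <- c(0.012, -0.008, 0.11)
  vol <- volume_grid(extent = rep(2e-3, 3), spacing = 2e-3, origin = p - 1e-3)
  f <- focused_field(arr, spec, c(85, 92), med, vol, time_search = TRUE)
  expect_equal(as.numeric(f),
               focused_field_oracle(arr, spec, c(85, 92), med, p),
               tolerance = 2e-2)
})

test_that("the sweep kernel reproduces the per-event reference field", {
  spec <- mat_spec()
  arr <- build_array(spec)
  med <- oil_medium()
  vol <- small_volume()
  plan <- sweep_plan(step = 10)
  m <- simulate_sensitivity_map(arr, spec, plan, med, vol, window_deg = Inf)
  ev <- sweep_events(plan)
  ref <- array(0, dim(vol))
  for (k in seq_len(nrow(ev))) {
    u <- irai:::steering_direction(ev$azimuth[k], ev$elevation[k])
    if (is.null(u)) next
    ref <- pmax(ref, focused_field(arr, spec,
                                   c(ev$azimuth[k], ev$elevation[k]),
                                   med, vol))
  }
  expect_equal(m$values, ref / max(ref), tolerance = 1e-10)
  # angular pruning does not alter the maximum once the window spans a step
  m2 <- simulate_sensitivity_map(arr, spec, plan, med, vol, window_deg = 12)
  expect_equal(m2$values, m$values, tolerance = 5e-3)
})

test_that("sensitivity maps are normalized, monotone under event refinement, and symmetric", {
  spec <- mat_spec()
  arr <- build_array(spec)
  med <- oil_medium()
  vol <- small_volume()
  fine <- simulate_sensitivity_map(arr, spec, sweep_plan(step = 45), med,
                                   vol, window_deg = Inf)
  expect_true(all(fine$values >= 0 & fine$values <= 1))
  expect_equal(max(fine$values), 1)
  # max-projection monotonicity on the raw (un-normalized) fields: the
  # step-45 events are a superset of the step-90 events
  raw_max <- function(step) {
    ev <- sweep_events(sweep_plan(step = step))
    out <- array(0, dim(vol))
    for (k in seq_len(nrow(ev))) {
      if (is.null(irai:::steering_direction(ev$azimuth[k],
                                            ev$elevation[k]))) next
      out <- pmax(out, focused_field(arr, spec,
                                     c(ev$azimuth[k], ev$elevation[k]),
                                     med, vol))
    }
    out
  }
  expect_true(all(raw_max(45) >= raw_max(90) - 1e-12))
  # azimuth/elevation swap for a square array mirrors the volume axes
  expect_equal(fine$values, aperm(fine$values, c(2, 1, 3)), tolerance = 1e-9)
})

test_that("one-event sweeps equal that event's normalized field", {
  spec <- mat_spec()
  arr <- build_array(spec)
  med <- oil_medium()
  vol <- small_volume()
  m <- simulate_sensitivity_map(arr, spec,
                                sweep_plan(c(80, 90), c(85, 95), 10),
                                med, vol, window_deg = Inf)
  f <- focused_field(arr, spec, c(80, 85), med, vol)
  expect_equal(m$values, f / max(f), tolerance = 1e-10)
})

test_that("the simulated on-axis sensitivity peaks near the 15 cm focal zone", {
  spec <- mat_spec()
  arr <- build_array(spec)
  vol <- volume_grid(extent = c(0.01, 0.01, 0.25),
                     spacing = c(0.01, 0.01, 0.005))
  m <- simulate_sensitivity_map(arr, spec, sweep_plan(step = 1), oil_medium(),
                                vol, window_deg = 2)
  zpk <- grid_axes(vol)$z[which.max(m$values)]
  expect_gt(zpk, 0.13)
  expect_lt(zpk, 0.17)
})

test_that("the virtual point-source protocol agrees with the sweep simulation", {
  spec <- mat_spec()
  arr <- build_array(spec)
  med <- oil_medium()
  pos <- as.matrix(expand.grid(x = c(-0.02, 0, 0.02), y = 0,
                               z = c(0.08, 0.11, 0.14)))
  vmap <- virtual_point_source_map(arr, spec, med, pos,
                                   window_halfwidth = 5e-3,
                                   window_spacing = 2.5e-3)
  svals <- vapply(seq_len(nrow(pos)), function(i) {
    vol <- volume_grid(extent = rep(1e-3, 3), spacing = 1e-3,
                       origin = pos[i, ] - 5e-4)
    az <- acos(pos[i, 1] / sqrt(sum(pos[i, ]^2))) * 180 / pi
    el <- acos(pos[i, 2] / sqrt(sum(pos[i, ]^2))) * 180 / pi
    as.numeric(focused_field(arr, spec, c(az, el), med, vol))
  }, 0)
  expect_equal(as.numeric(vmap$values), svals / max(svals), tolerance = 0.05)
})

test_that("noise averaging shrinks the virtual protocol's spread as 1/sqrt(n)", {
  spec <- transducer_spec(n_elements = c(4L, 4L))
  arr <- build_array(spec)
  med <- oil_medium()
  pos <- c(0, 0, 0.1)
  ch0 <- irai:::point_source_channels(pos, arr, spec, med, 20e6)
  raw <- function(n_avg, seeds) {
    vapply(seeds, function(s) {
      ch <- acquire(ch0, noise_std = 0.02, n_averages = n_avg, seed = s)
      w <- volume_grid(extent = rep(1e-2, 3), spacing = 5e-3,
                       origin = pos - 5e-3)
      max(suppressMessages(das_reconstruct(ch, arr, w, med))$amplitude)
    }, 0)
  }
  s1 <- sd(raw(1, 1:30))
  s16 <- sd(raw(16, 31:60))
  expect_gt(s1 / s16, 2.4)
  expect_lt(s1 / s16, 6.7)
  expect_error(virtual_point_source_map(arr, spec, med, matrix(pos, 1),
                                        n_averages = 0), "n_averages")
})

test_that("sparse maps densify by trilinear interpolation with edge clamping", {
  lat <- volume_grid(extent = c(0.1, 0.1, 0.1), spacing = 0.05,
                     origin = c(-0.05, -0.05, 0.02))
  vals <- array(0.5, dim(lat))
  sparse <- irai:::new_sensitivity_map(vals, lat, normalized = TRUE)
  target <- volume_grid(extent = c(0.1, 0.1, 0.1), spacing = 0.0125,
                        origin = lat$origin)
  dense <- densify_map(sparse, target)
  expect_true(all(abs(dense$values - 0.5) < 1e-12))
  # lattice-point values preserved, midpoints interpolate linearly
  v2 <- array(rep(c(0.4, 0.8), 4), c(2, 2, 2))  # varies along x only
  lat2 <- volume_grid(extent = c(0.2, 0.2, 0.2), spacing = 0.1,
                      origin = c(-0.1, -0.1, 0))
  sp2 <- irai:::new_sensitivity_map(v2, lat2, normalized = TRUE)
  # identical target grid: lattice values preserved exactly
  same <- densify_map(sp2, lat2)
  expect_equal(same$values, v2, tolerance = 1e-12)
  # midpoint between lattice values 0.4 and 0.8 interpolates to 0.6, and
  # points beyond the hull clamp to the nearest lattice value
  tg2 <- volume_grid(extent = c(0.2, 0.2, 0.2), spacing = c(0.04, 0.1, 0.1),
                     origin = lat2$origin)
  d2 <- densify_map(sp2, tg2)
  expect_equal(as.numeric(d2$values[, 1, 1]), c(0.4, 0.44, 0.6, 0.76, 0.8),
               tolerance = 1e-12)
  expect_error(densify_map(irai:::new_sensitivity_map(array(1, c(1, 1, 1)),
                                                      lat, TRUE), target),
               "lattice")
})

test_that("correction factors are floored reciprocals of normalized sensitivity", {
  lat <- volume_grid(extent = rep(0.02, 3), spacing = 0.01, origin = c(0, 0, 0))
  m <- irai:::new_sensitivity_map(array(c(1, 0.5, 0, 0.25, 1, 0.8, 0.04, 0.6),
                                        c(2, 2, 2)), lat, normalized = TRUE)
  cf <- suppressMessages(correction_factors(m, floor_epsilon = 0.05))
  expect_equal(cf$factors[1, 1, 1], 1)
  expect_equal(cf$factors[2, 1, 1], 2)
  expect_equal(cf$factors[1, 2, 1], 20)  # capped at 1/epsilon
  expect_equal(cf$n_capped, 2L)
  expect_true(all(cf$factors >= 1 & cf$factors <= 20))
  raw <- irai:::new_sensitivity_map(m$values * 3, lat, normalized = FALSE)
  expect_error(correction_factors(raw, 0.05), "normalize")
  expect_error(correction_factors(m, 1.5), "floor_epsilon")
})
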