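test_that("envelope detection recovers amplitude envelopes", {
  fs <- 20e6
  t <- (0:999) / fs
  cosine <- cos(2 * pi * 0.5e6 * t)
  env <- envelope(cosine)
  interior <- 100:900
  expect_equal(env[interior], rep(1, length(interior)), tolerance = 1e-2)
  # Gaussian-windowed cosine: envelope matches the window within 2% away
  # from the edges
  g <- exp(-(t - 25e-6)^2 / (2 * (3e-6)^2))
  env2 <- envelope(g * cos(2 * pi * 0.5e6 * t))
  sel <- which(g > 0.05)
  expect_lt(max(abs(env2[sel] - g[sel]) / max(g)), 0.02)
  expect_equal(envelope(numeric(10)), numeric(10))
  expect_error(envelope(numeric(0)), "empty")
  expect_error(envelope(c(1, NA)), "finite")
})

test_that("delay-and-sum of a single element matches a hand-computed sample", {
  spec <- single_element_spec()
  arr <- build_array(spec)
  med <- oil_medium()
  fs <- 20e6
  # Gaussian burst whose envelope peaks at t1
  t <- (0:2999) / fs
  t1 <- 80e-6
  sig <- 2.5e-6
  tr <- exp(-(t - t1)^2 / (2 * sig^2)) * cos(2 * pi * 0.35e6 * (t - t1))
  ch <- irai:::new_channel_data(matrix(tr, 1), fs, 0, arr$positions)
  value_at <- function(z) {
    vol <- volume_grid(extent = rep(1e-3, 3), spacing = 1e-3,
                       origin = c(-5e-4, -5e-4, z - 5e-4))
    as.numeric(das_reconstruct(ch, arr, vol, med)$amplitude)
  }
  # voxel whose delay hits the envelope peak reads the peak amplitude (1)
  expect_equal(value_at(med$sound_speed * t1), 1, tolerance = 1e-2)
  # a voxel one envelope-sigma earlier reads exp(-1/2)
  expect_equal(value_at(med$sound_speed * (t1 - sig)), exp(-0.5),
               tolerance = 2e-2)
})

test_that("all-zero channels reconstruct to zero and scaling is preserved", {
  spec <- transducer_spec(n_elements = c(2L, 2L))
  arr <- build_array(spec)
  med <- oil_medium()
  vol <- volume_grid(extent = rep(0.02, 3), spacing = 0.01,
                     origin = c(-0.01, -0.01, 0.05))
  ch0 <- irai:::new_channel_data(matrix(0, 4, 2000), 20e6, 0, arr$positions)
  expect_true(all(das_reconstruct(ch0, arr, vol, med)$amplitude == 0))
  tr <- matrix(rnorm(4 * 2000), 4)
  ch <- irai:::new_channel_data(tr, 20e6, 0, arr$positions)
  ch2 <- irai:::new_channel_data(2 * tr, 20e6, 0, arr$positions)
  expect_equal(das_reconstruct(ch2, arr, vol, med)$amplitude,
               2 * das_reconstruct(ch, arr, vol, med)$amplitude,
               tolerance = 1e-12)
  expect_error(das_reconstruct(irai:::new_channel_data(tr[1:2, ], 20e6, 0,
                                                       arr$positions),
                               arr, vol, med), "channel count")
})

test_that("a forward-modeled point source reconstructs at its own voxel", {
  spec <- mat_spec()
  arr <- build_array(spec)
  med <- oil_medium()
  vol <- volume_grid(extent = c(0.04, 0.04, 0.04), spacing = 5e-3,
                     origin = c(-0.02, -0.02, 0.09))
  p0 <- array(0, dim(vol)); p0[4, 4, 4] <- 1
  ch <- suppressWarnings(propagate(p0, arr, spec, med, pulse = NULL,
                                   volume = vol))
  rec <- suppressMessages(das_reconstruct(ch, arr, vol, med))
  peak <- which(rec$amplitude == max(rec$amplitude), arr.ind = TRUE)
  expect_true(all(abs(peak - c(4, 4, 4)) <= 1))
})

test_that("delays beyond the trace support zero the voxel with a report", {
  spec <- single_element_spec()
  arr <- build_array(spec)
  med <- oil_medium()
  ch <- irai:::new_channel_data(matrix(1, 1, 64), 20e6, 0, arr$positions)
  vol <- volume_grid(extent = rep(2e-3, 3), spacing = 2e-3,
                     origin = c(0, 0, 0.2))  # delay ~138 us >> 3.2 us support
  expect_message(rec <- das_reconstruct(ch, arr, vol, med), "zeroed")
  expect_true(all(rec$amplitude == 0))
  expect_equal(rec$n_zeroed, 1L)
})

test_that("compensation multiplies voxel-wise and refuses double application", {
  g <- volume_grid(extent = rep(0.03, 3), spacing = 0.01, origin = c(0, 0, 0.01))
  set.seed(42)
  amp <- array(runif(27), dim(g))
  fac <- array(runif(27, 1, 5), dim(g))
  rec <- irai:::new_recon_volume(amp, g)
  corr <- structure(list(factors = fac, grid = g, floor_epsilon = 0.05,
                         n_capped = 0L), class = "correction_volume")
  out <- compensate(rec, corr)
  for (i in sample(27, 5)) {
    expect_equal(as.numeric(out$amplitude)[i],
                 as.numeric(amp)[i] * as.numeric(fac)[i])
  }
  expect_true(out$compensated)
  expect_error(compensate(out, corr), "already")
  ones <- structure(list(factors = array(1, dim(g)), grid = g,
                         floor_epsilon = 0.05, n_capped = 0L),
                    class = "correction_volume")
  expect_equal(compensate(rec, ones)$amplitude, rec$amplitude)
  g2 <- volume_grid(extent = rep(0.03, 3), spacing = 0.01, origin = c(0, 0, 0.02))
  corr2 <- structure(list(factors = fac, grid = g2, floor_epsilon = 0.05,
                          n_capped = 0L), class = "correction_volume")
  expect_error(compensate(rec, corr2), "different grids")
})
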