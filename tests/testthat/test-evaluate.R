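test_that("DVH curves are complementary-cumulative and match closed forms", {
  # uniform volume: 100% up to the dose, 0% above
  u <- array(2, c(4, 4, 4))
  curve <- dvh(u, n_bins = 11, max_value = 4)
  expect_equal(curve$volume_fraction, c(rep(100, 6), rep(0, 5)))
  # linear ramp over equal-count voxels: fraction(d) = (1 - d/Dmax) * 100
  n <- 2000
  ramp <- seq(0, 10, length.out = n)
  cr <- dvh(array(ramp, c(10, 10, 20)), n_bins = 51)
  expect_equal(cr$volume_fraction, (1 - cr$dose / 10) * 100, tolerance = 0.2)
  expect_equal(cr$volume_fraction[1], 100)
  # non-increasing for arbitrary volumes
  set.seed(1)
  for (i in 1:5) {
    r <- dvh(array(rexp(64), c(4, 4, 4)))
    expect_true(all(diff(r$volume_fraction) <= 0))
  }
  expect_error(dvh(numeric(0)), "empty")
  expect_error(dvh(array(1, c(2, 2, 2)), n_bins = 1), "bins")
})

test_that("DVH-RMSE matches direct formula evaluation", {
  mk <- function(f) structure(data.frame(dose = seq(0, 1, length.out = 101),
                                         volume_fraction = f),
                              class = c("dvh_curve", "data.frame"))
  a <- mk(seq(100, 0, length.out = 101))
  expect_equal(dvh_rmse(a, a), 0)
  b <- mk(a$volume_fraction + 5)
  expect_equal(dvh_rmse(a, b), 5)
  set.seed(2)
  fa <- runif(101, 0, 100); fb <- runif(101, 0, 100)
  expect_equal(dvh_rmse(mk(fa), mk(fb)), sqrt(mean((fa - fb)^2)))
  # differing level axes are resampled with a warning
  c2 <- structure(data.frame(dose = seq(0, 2, length.out = 101),
                             volume_fraction = fa),
                  class = c("dvh_curve", "data.frame"))
  expect_warning(dvh_rmse(mk(fa), c2), "resampling")
})

test_that("gamma analysis passes identity, hits the uniform-offset boundary, and matches brute force", {
  set.seed(3)
  g <- volume_grid(rep(0.02, 3), 5e-3, c(0, 0, 0.01))
  ref <- array(runif(64, 0.2, 1), c(4, 4, 4))
  res <- gamma_index(ref, ref, spacing = g$spacing)
  expect_true(all(res$gamma_map == 0))
  expect_equal(res$pass_rate, 100)
  # uniform reference, evaluated scaled by 1 + dd%: gamma exactly 1
  u <- array(1, c(4, 4, 4))
  ru <- gamma_index(u, 1.05 * u, dd_percent = 5, spacing = g$spacing)
  expect_equal(as.numeric(ru$gamma_map), rep(1, 64), tolerance = 1e-9)
  # global scale invariance: scaling both volumes leaves gamma unchanged
  ev <- ref + array(rnorm(64, sd = 0.05), c(4, 4, 4))
  r1 <- gamma_index(ref, ev, spacing = g$spacing)
  r2 <- gamma_index(10 * ref, 10 * ev, spacing = g$spacing)
  expect_equal(r1$gamma_map, r2$gamma_map, tolerance = 1e-12)
  # exhaustive brute-force oracle on small grids
  oracle <- gamma_oracle(ref, ev, g$spacing, 0.05 * max(ref), 5e-3)
  expect_equal(r1$gamma_map, oracle, tolerance = 1e-10)
  expect_error(gamma_index(ref, ev, dta_mm = 2, spacing = g$spacing),
               "spacing exceeds")
})

test_that("SSIM matches its closed forms and a direct windowed evaluation", {
  a <- matrix(0.5, 9, 9)
  expect_equal(ssim_index(a, a), 1)
  # constant offset: variance terms vanish, SSIM reduces to the luminance
  # term (2 mu_a mu_b + C1) / (mu_a^2 + mu_b^2 + C1)
  b <- a + 0.2
  C1 <- 1e-4
  expect_equal(ssim_index(a, b, dynamic_range = 1),
               (2 * 0.5 * 0.7 + C1) / (0.25 + 0.49 + C1), tolerance = 1e-9)
  expect_lt(ssim_index(a, b, dynamic_range = 1), 1)
  # random toy image against an independent loop implementation
  set.seed(4)
  x <- matrix(runif(49), 7, 7); y <- matrix(runif(49), 7, 7)
  w1 <- exp(-(-2:2)^2 / (2 * 1.5^2)); w1 <- w1 / sum(w1)
  w2 <- outer(w1, w1)
  refl <- function(i, n) ifelse(i < 1, 1 - i, ifelse(i > n, 2 * n + 1 - i, i))
  direct <- 0
  for (i in 1:7) for (j in 1:7) {
    pa <- pb <- matrix(0, 5, 5)
    for (di in -2:2) for (dj in -2:2) {
      pa[di + 3, dj + 3] <- x[refl(i + di, 7), refl(j + dj, 7)]
      pb[di + 3, dj + 3] <- y[refl(i + di, 7), refl(j + dj, 7)]
    }
    mua <- sum(w2 * pa); mub <- sum(w2 * pb)
    va <- sum(w2 * pa^2) - mua^2; vb <- sum(w2 * pb^2) - mub^2
    cab <- sum(w2 * pa * pb) - mua * mub
    L <- max(x, y) - min(x, y)
    C1 <- (0.01 * L)^2; C2 <- (0.03 * L)^2
    direct <- direct + ((2 * mua * mub + C1) * (2 * cab + C2)) /
      ((mua^2 + mub^2 + C1) * (va + vb + C2)) / 49
  }
  expect_equal(ssim_index(x, y, window_size = 5), direct, tolerance = 1e-10)
  expect_error(ssim_index(x, y[1:5, 1:5]), "shapes")
})

test_that("isodose contours trace level sets", {
  # binary disc: the 0.8 contour follows the disc boundary within one pixel
  n <- 41
  xy <- seq(-2, 2, length.out = n)
  disc <- outer(xy, xy, function(x, y) as.numeric(x^2 + y^2 <= 1))
  ct <- isodose_contour(disc, 0.8, x = xy, y = xy)
  r <- sqrt(ct$contours[[1]]$x^2 + ct$contours[[1]]$y^2)
  expect_true(all(abs(r - 1) < diff(xy)[1] * 1.01))
  # isotropic Gaussian: 0.8-level radius = sigma * sqrt(2 log(1/0.8))
  sig <- 0.6
  gsp <- outer(xy, xy, function(x, y) exp(-(x^2 + y^2) / (2 * sig^2)))
  cg <- isodose_contour(gsp, 0.8, x = xy, y = xy)
  rg <- sqrt(cg$contours[[1]]$x^2 + cg$contours[[1]]$y^2)
  expect_equal(mean(rg), sig * sqrt(2 * log(1 / 0.8)), tolerance = 0.02)
  # nesting: the 0.9 region lies inside the 0.8 region
  c9 <- isodose_contour(gsp, 0.9, x = xy, y = xy)
  expect_lt(max(sqrt(c9$contours[[1]]$x^2 + c9$contours[[1]]$y^2)), min(rg))
  expect_warning(isodose_contour(matrix(1, 3, 3), 0.8), "empty")
})

test_that("region means and line profiles behave on analytic inputs", {
  g <- volume_grid(rep(0.04, 3), 0.01, c(-0.02, -0.02, 0.05))
  ones <- irai:::new_recon_volume(array(1, dim(g)), g)
  mask <- array(FALSE, dim(g)); mask[2:3, 2:3, 2:3] <- TRUE
  expect_equal(region_mean_amplitude(ones, mask), 1)
  zeros <- irai:::new_recon_volume(array(0, dim(g)), g)
  expect_equal(region_mean_amplitude(zeros, mask), 0)
  expect_error(region_mean_amplitude(ones, array(FALSE, dim(g))), "empty")
  prof <- line_profile(ones, "z", c(0, 0))
  expect_equal(prof$amplitude, rep(1, 4))
  expect_equal(prof$coord_cm, (grid_axes(g)$z) * 100)
  expect_error(line_profile(ones, "z", c(0.5, 0)), "outside")
})
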