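# Shared fixtures and independent oracles for the test suite. Everything is
# generated in code; expensive volumes are cached per session.

mat_spec <- function() transducer_spec()
oil_medium <- function() acoustic_medium()

# small volume a little in front of the array, coarse enough for R-level
# reference computations
small_volume <- function(spacing = 2e-2) {
  volume_grid(extent = c(0.06, 0.06, 0.08), spacing = spacing,
              origin = c(-0.03, -0.03, 0.06))
}

# single-element "array": directivity 1 on its axis, pure 1/r physics
single_element_spec <- function() {
  transducer_spec(n_elements = c(1L, 1L))
}

.cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# Correction volume shared by the beam studies (depth/lateral/size share one
# working grid and one transducer, so one sweep map serves all three).
beam_study_correction <- function(config = default_run_config()) {
  cached("beam_corr", {
    spec <- transducer_spec()
    vol <- beam_phantom_grid(config$grid_spacing)
    smap <- simulate_sensitivity_map(build_array(spec), spec,
                                     sweep_plan(step = config$sweep$step),
                                     oil_medium(), vol,
                                     window_deg = config$sweep$window_deg)
    suppressMessages(correction_factors(smap, 0.05))
  })
}

# ---- independent oracles -------------------------------------------------

# Exhaustive gamma search: no pruning, its own candidate lattice and
# trilinear interpolation, plain R loops.
gamma_oracle <- function(ref, ev, spacing, dd_abs, dta,
                         search_radius_factor = 3, subsample_factor = 3) {
  d <- dim(ref)
  step <- spacing / subsample_factor
  radius <- search_radius_factor * dta
  k <- floor(radius / step)
  cand <- expand.grid(i = -k[1]:k[1], j = -k[2]:k[2], l = -k[3]:k[3])
  cand <- cand[sqrt((cand$i * step[1])^2 + (cand$j * step[2])^2 +
                    (cand$l * step[3])^2) <= radius, ]
  tri <- function(a, x, y, z) {
    if (x < 1 || y < 1 || z < 1 || x > d[1] || y > d[2] || z > d[3]) {
      return(NA_real_)
    }
    i0 <- min(max(floor(x), 1), d[1] - 1); fx <- x - i0
    j0 <- min(max(floor(y), 1), d[2] - 1); fy <- y - j0
    k0 <- min(max(floor(z), 1), d[3] - 1); fz <- z - k0
    if (d[1] == 1) { i0 <- 1; fx <- 0 }
    if (d[2] == 1) { j0 <- 1; fy <- 0 }
    if (d[3] == 1) { k0 <- 1; fz <- 0 }
    v <- 0
    for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
      w <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) *
           (if (dz) fz else 1 - fz)
      v <- v + w * a[min(i0 + dx, d[1]), min(j0 + dy, d[2]),
                     min(k0 + dz, d[3])]
    }
    v
  }
  g <- array(NA_real_, d)
  for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
    best <- Inf
    for (c_ in seq_len(nrow(cand))) {
      e <- tri(ev, x + cand$i[c_] * step[1] / spacing[1],
                   y + cand$j[c_] * step[2] / spacing[2],
                   z + cand$l[c_] * step[3] / spacing[3])
      if (is.na(e)) next
      dist2 <- (cand$i[c_] * step[1])^2 + (cand$j[c_] * step[2])^2 +
               (cand$l[c_] * step[3])^2
      g2 <- ((ref[x, y, z] - e) / dd_abs)^2 + dist2 / dta^2
      if (g2 < best) best <- g2
    }
    g[x, y, z] <- sqrt(best)
  }
  g
}

# Brute-force delayed-pulse superposition for a focused event: builds actual
# time traces for every element and takes the temporal peak of the envelope
# of their sum.
focused_field_oracle <- function(grid, spec, direction_deg, medium, point) {
  u <- irai:::steering_direction(direction_deg[1], direction_deg[2])
  c0 <- medium$sound_speed
  f0 <- spec$center_frequency
  sig <- sqrt(2 * log(2)) / (pi * spec$fractional_bandwidth * f0)
  lam <- c0 / f0
  ex <- grid$positions[, 1]; ey <- grid$positions[, 2]
  dx <- point[1] - ex; dy <- point[2] - ey; dz <- point[3]
  ri <- sqrt(dx^2 + dy^2 + dz^2)
  sx <- pi * (spec$directivity_size / lam) * dx / ri
  sy <- pi * (spec$directivity_size / lam) * dy / ri
  D <- ifelse(abs(sx) < 1e-12, 1, sin(sx) / sx) *
       ifelse(abs(sy) < 1e-12, 1, sin(sy) / sy)
  r <- sqrt(sum(point^2))
  f <- r * u
  rf <- sqrt((f[1] - ex)^2 + (f[2] - ey)^2 + f[3]^2)
  del <- (ri - rf) / c0
  t <- seq(min(del) - 6 * sig, max(del) + 6 * sig, by = 1 / (50 * f0))
  tr <- rowSums(vapply(seq_along(ri), function(i) {
    (D[i] / ri[i]) * exp(-(t - del[i])^2 / (2 * sig^2)) *
      cos(2 * pi * f0 * (t - del[i]))
  }, numeric(length(t))))
  max(envelope(tr))
}
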