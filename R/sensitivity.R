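#' Angular sweep plan for the dynamic-focusing sensitivity simulation
#'
#' Half-open angular grids in azimuth and elevation. The half-open convention
#' `[0, 180)` makes a 0.5 degree step produce 360 angles per axis and 129600
#' focusing events, the event count of the full-resolution characterization.
#'
#' @param azimuth,elevation half-open angular ranges in degrees, as
#'   `c(from, to)`.
#' @param step angular step in degrees; must divide both ranges.
#' @export
sweep_plan <- function(azimuth = c(0, 180), elevation = c(0, 180), step = 0.5) {
  if (step <= 0) stop("step must be positive")
  for (rng in list(azimuth, elevation)) {
    stopifnot(length(rng) == 2, rng[2] > rng[1])
    k <- (rng[2] - rng[1]) / step
    if (abs(k - round(k)) > 1e-9) stop("step must divide the angular range")
  }
  structure(list(azimuth = azimuth, elevation = elevation, step = step),
            class = "sweep_plan")
}

#' Enumerate the focusing events of a sweep plan
#'
#' Row-major enumeration of the half-open angular grid: elevation is the
#' outer (slow) index and azimuth the inner (fast) one.
#'
#' @param plan a [sweep_plan()].
#' @return data.frame with columns `azimuth` and `elevation` (degrees).
#' @examples
#' nrow(sweep_events(sweep_plan(step = 0.5)))  # 129600
#' @export
sweep_events <- function(plan) {
  stopifnot(inherits(plan, "sweep_plan"))
  az <- seq(plan$azimuth[1], plan$azimuth[2] - plan$step, by = plan$step)
  el <- seq(plan$elevation[1], plan$elevation[2] - plan$step, by = plan$step)
  data.frame(azimuth = rep(az, times = length(el)),
             elevation = rep(el, each = length(az)))
}

# Unit steering direction for a pair of steering angles (degrees). The two
# angles are direction angles measured from the +x (azimuth) and +y
# (elevation) axes, the parameterization of a two-angle dynamic-focusing
# sweep: u = (cos az, cos el, sqrt(1 - cos^2 az - cos^2 el)). Directions with
# cos^2 az + cos^2 el >= 1 fall outside the forward hemisphere.
steering_direction <- function(azimuth_deg, elevation_deg) {
  ux <- cos(azimuth_deg * pi / 180)
  uy <- cos(elevation_deg * pi / 180)
  s2 <- ux^2 + uy^2
  if (s2 >= 1) return(NULL)
  c(ux, uy, sqrt(1 - s2))
}

#' Dynamically focused acoustic field for one sweep event
#'
#' Reference (pure R) implementation of the per-event field. The array is
#' steered along the direction given by the two steering angles with focal
#' delays tracking range along that direction (dynamic focusing), so for a
#' voxel at range r the focal point is `r * u`. The field value is the peak
#' of the envelope of the coherent element sum: each element contributes its
#' Gaussian-enveloped burst delayed by its time of flight, weighted by
#' 1/r and its directivity. By default the envelope is evaluated at the
#' focal-zone passage time (exact on the steered ray, where the delays
#' align); `time_search = TRUE` searches the temporal peak explicitly and is
#' used to validate that shortcut.
#'
#' Intended for coarse grids and for testing; [simulate_sensitivity_map()]
#' runs the compiled sweep for production volumes.
#'
#' @param grid an [build_array()] element grid.
#' @param spec the [transducer_spec()].
#' @param focus_direction `c(azimuth, elevation)` steering angles in degrees.
#' @param medium an [acoustic_medium()].
#' @param volume a [volume_grid()].
#' @param time_search search the temporal envelope peak instead of evaluating
#'   at focal-zone passage.
#' @param baffle element baffle model, `"rigid"` or `"soft"`.
#' @return 3D array of peak envelope amplitude per voxel.
#' @export
focused_field <- function(grid, spec, focus_direction, medium, volume,
                          time_search = FALSE, baffle = "rigid") {
  stopifnot(inherits(grid, "element_grid"), inherits(volume, "volume_grid"))
  u <- steering_direction(focus_direction[1], focus_direction[2])
  if (is.null(u)) stop("focus direction lies outside the sweep hemisphere")
  c0 <- medium$sound_speed
  lambda <- c0 / spec$center_frequency
  alam <- spec$directivity_size / lambda
  sig <- pulse_sigma(spec)
  omega <- 2 * pi * spec$center_frequency
  ex <- grid$positions[, 1]; ey <- grid$positions[, 2]
  vox <- voxel_centers(volume)
  obliq <- identical(baffle, "soft")

  vals <- vapply(seq_len(nrow(vox)), function(v) {
    px <- vox[v, 1]; py <- vox[v, 2]; pz <- vox[v, 3]
    dx <- px - ex; dy <- py - ey
    ri <- sqrt(dx^2 + dy^2 + pz^2)
    if (any(ri < 1e-12)) return(NA_real_)  # voxel at an element position
    sx <- pi * alam * dx / ri; sy <- pi * alam * dy / ri
    D <- ifelse(abs(sx) < 1e-12, 1, sin(sx) / sx) *
         ifelse(abs(sy) < 1e-12, 1, sin(sy) / sy)
    if (obliq) D <- D * pz / ri
    a <- D / ri
    r <- sqrt(px^2 + py^2 + pz^2)
    f <- r * u
    rf <- sqrt((f[1] - ex)^2 + (f[2] - ey)^2 + f[3]^2)
    d <- (ri - rf) / c0
    value_at <- function(t) {
      Mod(sum(a * exp(-(t - d)^2 / (2 * sig^2)) * exp(1i * omega * d)))
    }
    if (!time_search) return(value_at(0))
    tg <- seq(min(d) - sig, max(d) + sig, length.out = 41)
    max(vapply(tg, value_at, 0))
  }, 0)

  if (anyNA(vals)) {
    warning(sum(is.na(vals)), " voxel(s) coincide with an element; ",
            "filled from nearest valid neighbor")
    vals <- fill_nearest(vals, vox)
  }
  array(vals, dim(volume))
}

fill_nearest <- function(vals, vox) {
  bad <- which(is.na(vals)); good <- which(!is.na(vals))
  for (b in bad) {
    d2 <- (vox[good, 1] - vox[b, 1])^2 + (vox[good, 2] - vox[b, 2])^2 +
          (vox[good, 3] - vox[b, 3])^2
    vals[b] <- vals[good[which.min(d2)]]
  }
  vals
}

new_sensitivity_map <- function(values, grid, normalized = FALSE) {
  structure(list(values = values, grid = grid, normalized = normalized),
            class = "sensitivity_map")
}

#' Normalize a sensitivity map to unit maximum
#' @param map a `sensitivity_map`.
#' @export
normalize_map <- function(map) {
  stopifnot(inherits(map, "sensitivity_map"))
  m <- max(map$values)
  if (m <= 0) stop("cannot normalize an all-zero map")
  new_sensitivity_map(map$values / m, map$grid, normalized = TRUE)
}

#' @export
print.sensitivity_map <- function(x, ...) {
  cat(sprintf("<sensitivity_map> %s, %s, max %.3g\n",
              paste(dim(x$values), collapse = " x "),
              if (x$normalized) "normalized" else "raw", max(x$values)))
  invisible(x)
}

#' Simulated volumetric detection-sensitivity map
#'
#' Runs the dynamic-focusing sweep: for every focusing event of the plan an
#' acoustic field is evaluated (see [focused_field()]) and each voxel keeps
#' the maximum value across all events; the result is normalized to unit
#' maximum. The compiled kernel prunes events whose steering angles differ
#' from the voxel's direction angles by more than `window_deg` (the field of
#' an event steered further away than a few beamwidths cannot exceed the
#' in-window maximum); the nearest event per axis is always evaluated.
#' `window_deg = Inf` disables pruning and reproduces the exhaustive sweep.
#'
#' @inheritParams focused_field
#' @param plan a [sweep_plan()].
#' @param window_deg pruning half-window in degrees; the default
#'   `max(1.5, plan$step)` covers about 1.5 beamwidths of the 1024-element
#'   array at 0.35 MHz, widened to one sweep step for coarse plans. Use `Inf`
#'   for the exhaustive sweep.
#' @return A normalized `sensitivity_map` on `volume`.
#' @export
simulate_sensitivity_map <- function(grid, spec, plan, medium, volume,
                                     baffle = "rigid", window_deg = NULL) {
  stopifnot(inherits(grid, "element_grid"), inherits(plan, "sweep_plan"),
            inherits(volume, "volume_grid"))
  if (is.null(window_deg)) window_deg <- max(1.5, plan$step)
  ev <- sweep_events(plan)
  if (nrow(ev) < 1) stop("sweep plan contains no events")
  if (prod(dim(volume)) < 1) stop("empty volume")
  az <- sort(unique(ev$azimuth)) * pi / 180
  el <- sort(unique(ev$elevation)) * pi / 180
  c0 <- medium$sound_speed
  vals <- cpp_sweep_max(voxel_centers(volume), grid$positions[, 1:2], az, el,
                        c0, 2 * pi * spec$center_frequency, pulse_sigma(spec),
                        spec$directivity_size / (c0 / spec$center_frequency),
                        as.integer(identical(baffle, "soft")),
                        window_deg * pi / 180)
  normalize_map(new_sensitivity_map(array(vals, dim(volume)), volume))
}

#' Virtual point-source sensitivity measurement
#'
#' Digital twin of the experimental protocol: a point acoustic source is
#' placed at each lattice position, its channel data are simulated (with
#' optional noise and averaging), the volume is reconstructed by
#' delay-and-sum, and the image maximum represents the detection sensitivity
#' at that position. The map is normalized over all positions.
#'
#' The source is excited impulsively (the nanosecond laser pulse satisfies
#' stress confinement), so each trace is the element impulse response scaled
#' by spreading and directivity. Reconstruction uses a local window centered
#' on the source; the delay-and-sum maximum of a point target lies at the
#' target, so a window a few voxels wide captures the image maximum.
#'
#' @inheritParams simulate_sensitivity_map
#' @param source_positions n x 3 matrix of source positions (m).
#' @param sampling_rate channel-data sampling rate (Hz).
#' @param noise_std white-noise standard deviation added per acquisition
#'   (same arbitrary units as the traces).
#' @param n_averages number of averaged acquisitions.
#' @param seed integer seed for the noise.
#' @param window_halfwidth half-width (m) of the local reconstruction window.
#' @param window_spacing voxel size (m) of the local reconstruction window.
#' @return A normalized sparse `sensitivity_map` whose `values` is the vector
#'   of per-position sensitivities, with `positions` attached; if the
#'   positions form a full regular lattice the map is also shaped as a 3D
#'   array on the lattice grid so it can be densified.
#' @export
virtual_point_source_map <- function(grid, spec, medium, source_positions,
                                     sampling_rate = 20e6, noise_std = 0,
                                     n_averages = 1, seed = NULL,
                                     window_halfwidth = 0.02,
                                     window_spacing = 5e-3,
                                     baffle = "rigid") {
  stopifnot(inherits(grid, "element_grid"), is.matrix(source_positions),
            ncol(source_positions) == 3)
  if (n_averages < 1) stop("n_averages must be at least 1")
  vals <- vapply(seq_len(nrow(source_positions)), function(i) {
    p <- source_positions[i, ]
    ch <- point_source_channels(p, grid, spec, medium, sampling_rate,
                                baffle = baffle)
    if (noise_std > 0) {
      ch <- acquire(ch, noise_std = noise_std, n_averages = n_averages,
                    seed = if (is.null(seed)) NULL else seed + i)
    }
    w <- volume_grid(extent = rep(2 * window_halfwidth, 3),
                     spacing = window_spacing,
                     origin = p - window_halfwidth)
    rec <- das_reconstruct(ch, grid, w, medium)
    max(rec$amplitude)
  }, 0)
  out <- new_sensitivity_map(vals / max(vals), lattice_grid(source_positions),
                             normalized = TRUE)
  attr(out$values, "positions") <- source_positions
  if (!is.null(out$grid)) {
    dim(out$values) <- dim(out$grid)
  }
  out
}

# Channel data of an impulsively excited point source at p: element impulse
# response delayed by time of flight, scaled by 1/(4 pi r) and directivity.
point_source_channels <- function(p, grid, spec, medium, sampling_rate,
                                  baffle = "rigid") {
  ir <- receive_impulse(spec, sampling_rate)
  kern <- ir$samples
  peak <- which.max(envelope(kern))
  c0 <- medium$sound_speed
  rmax <- max(sqrt(colSums((t(grid$positions) - p)^2)))
  t0 <- -(peak - 1) / sampling_rate
  nt <- ceiling((rmax / c0) * sampling_rate) + length(kern) + 4L
  sp <- cpp_splat(matrix(p, 1, 3), 1 / (4 * pi), grid$positions, c0,
                  sampling_rate, t0, nt,
                  spec$directivity_size / (c0 / spec$center_frequency),
                  as.integer(identical(baffle, "soft")), 1e-6)
  tr <- t(apply(sp$traces, 1, function(x) {
    stats::convolve(x, rev(kern), type = "open")[peak:(peak + nt - 1)]
  }))
  new_channel_data(tr, sampling_rate, t0, grid$positions)
}

# Reconstruct a volume_grid from lattice positions if they form a full
# regular grid (voxel centers); otherwise NULL.
lattice_grid <- function(positions) {
  ux <- sort(unique(positions[, 1])); uy <- sort(unique(positions[, 2]))
  uz <- sort(unique(positions[, 3]))
  if (length(ux) * length(uy) * length(uz) != nrow(positions)) return(NULL)
  step <- function(u) if (length(u) > 1) min(diff(u)) else 1e-2
  sp <- c(step(ux), step(uy), step(uz))
  volume_grid(extent = sp * c(length(ux), length(uy), length(uz)),
              spacing = sp,
              origin = c(ux[1], uy[1], max(0, uz[1])) - sp / 2)
}

#' Densify a sparse sensitivity map onto a target grid
#'
#' Trilinear interpolation of the lattice values; target voxels outside the
#' lattice hull are clamped to the nearest lattice value (constant
#' extrapolation).
#'
#' @param sparse a `sensitivity_map` on a coarse lattice grid.
#' @param target the target [volume_grid()].
#' @export
densify_map <- function(sparse, target) {
  stopifnot(inherits(sparse, "sensitivity_map"),
            inherits(target, "volume_grid"))
  if (is.null(sparse$grid) || is.null(dim(sparse$values))) {
    stop("sparse map does not lie on a regular lattice")
  }
  if (any(dim(sparse$values) < 2)) {
    stop("need at least 2 lattice points per axis to interpolate")
  }
  sa <- grid_axes(sparse$grid)
  vox <- voxel_centers(target)
  idx <- function(u, centers) {
    # fractional index with clamping to the lattice hull
    pmin(pmax(approx(centers, seq_along(centers), xout = u, rule = 2)$y,
              1), length(centers))
  }
  fx <- idx(vox[, 1], sa$x); fy <- idx(vox[, 2], sa$y); fz <- idx(vox[, 3], sa$z)
  vals <- trilinear_sample(sparse$values, fx, fy, fz)
  out <- new_sensitivity_map(array(vals, dim(target)), target,
                             normalized = sparse$normalized)
  out
}

trilinear_sample <- function(a, fx, fy, fz) {
  d <- dim(a)
  i0 <- pmin(pmax(floor(fx), 1), d[1] - 1); wx <- fx - i0
  j0 <- pmin(pmax(floor(fy), 1), d[2] - 1); wy <- fy - j0
  k0 <- pmin(pmax(floor(fz), 1), d[3] - 1); wz <- fz - k0
  if (d[1] == 1) { i0[] <- 1; wx[] <- 0 }
  if (d[2] == 1) { j0[] <- 1; wy[] <- 0 }
  if (d[3] == 1) { k0[] <- 1; wz[] <- 0 }
  at <- function(di, dj, dk) a[cbind(i0 + di, j0 + dj, k0 + dk)]
  v <- 0
  for (dk in 0:1) for (dj in 0:1) for (di in 0:1) {
    w <- (if (di) wx else 1 - wx) * (if (dj) wy else 1 - wy) *
         (if (dk) wz else 1 - wz)
    v <- v + w * at(min(di, dim(a)[1] - 1), min(dj, d[2] - 1),
                    min(dk, d[3] - 1))
  }
  v
}

#' Correction-factor volume from a normalized sensitivity map
#'
#' Voxel-wise reciprocal of the sensitivity, floored at `floor_epsilon` so
#' that near-zero sensitivity cannot amplify noise without bound: factors lie
#' in `[1, 1/floor_epsilon]`. The number of floored voxels is reported as a
#' message.
#'
#' @param map a normalized `sensitivity_map`.
#' @param floor_epsilon reciprocal floor in (0, 1).
#' @return An object of class `correction_volume`.
#' @export
correction_factors <- function(map, floor_epsilon = 0.05) {
  stopifnot(inherits(map, "sensitivity_map"))
  if (!isTRUE(map$normalized)) {
    stop("sensitivity map must be normalized first (see normalize_map())")
  }
  if (!(floor_epsilon > 0 && floor_epsilon < 1)) {
    stop("floor_epsilon must lie in (0, 1)")
  }
  capped <- sum(map$values < floor_epsilon)
  if (capped > 0) {
    message(capped, " voxel(s) below the sensitivity floor; factors capped at ",
            signif(1 / floor_epsilon, 4))
  }
  structure(list(factors = 1 / pmax(map$values, floor_epsilon),
                 grid = map$grid, floor_epsilon = floor_epsilon,
                 n_capped = capped),
            class = "correction_volume")
}
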