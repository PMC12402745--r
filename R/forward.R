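#' Voxelized dose volume
#'
#' @param dose 3D array of absorbed dose (Gy), non-negative, with dimensions
#'   matching `grid`.
#' @param grid the [volume_grid()] the dose lives on.
#' @export
dose_volume <- function(dose, grid) {
  stopifnot(inherits(grid, "volume_grid"))
  if (!all(dim(dose) == dim(grid))) stop("dose dimensions do not match grid")
  if (any(dose < 0)) stop("dose must be non-negative")
  structure(list(dose = dose, grid = grid), class = "dose_volume")
}

#' Initial acoustic pressure from a dose distribution
#'
#' Thermoacoustic conversion under stress confinement:
#' `p0 = Grueneisen * density * dose` (Gy is J/kg, so `density * dose` is the
#' volumetric absorbed energy density and p0 is in Pa).
#'
#' @param dose a [dose_volume()].
#' @param medium an [acoustic_medium()].
#' @return 3D array of initial pressure (Pa) on the dose grid.
#' @export
initial_pressure <- function(dose, medium) {
  stopifnot(inherits(dose, "dose_volume"), inherits(medium, "acoustic_medium"))
  medium$grueneisen * medium$density * dose$dose
}

new_channel_data <- function(traces, sampling_rate, t0, element_positions,
                             seed = NULL) {
  structure(list(traces = traces, sampling_rate = sampling_rate, t0 = t0,
                 element_positions = element_positions, seed = seed),
            class = "channel_data")
}

#' @export
print.channel_data <- function(x, ...) {
  cat(sprintf("<channel_data> %d elements x %d samples @ %.3g MHz\n",
              nrow(x$traces), ncol(x$traces), x$sampling_rate / 1e6))
  invisible(x)
}

# Row-wise FFT convolution of an ne x nt trace matrix with a kernel whose
# envelope peaks at sample `peak`; the output is cropped so the kernel peak
# stays at each impulse's original sample (zero-phase alignment).
convolve_rows <- function(traces, kern, peak) {
  ne <- nrow(traces); nt <- ncol(traces); m <- length(kern)
  n <- stats::nextn(nt + m - 1, 2)
  K <- fft(c(kern, rep(0, n - m)))
  X <- stats::mvfft(t(cbind(traces, matrix(0, ne, n - nt))))
  Y <- Re(stats::mvfft(X * K, inverse = TRUE)) / n
  t(Y)[, peak:(peak + nt - 1), drop = FALSE]
}

#' Propagate a source distribution to per-element channel data
#'
#' Retarded-potential superposition in a homogeneous lossless medium: every
#' source voxel contributes `p0 * voxel_volume / (4 pi r)` to each element,
#' delayed by `r / c` and weighted by the element directivity toward the
#' voxel. The impulse train is then convolved with the time derivative of the
#' excitation-pulse envelope (the finite x-ray pulse violates stress
#' confinement, so the delta-excitation response is filtered by the envelope
#' derivative) and, by default, with the element receive impulse response.
#' The combined kernel is applied zero-phase (its envelope peak carries no
#' delay), so a point source at range r peaks at exactly t = r / c.
#'
#' A warning is emitted when the source grid spacing exceeds a quarter
#' wavelength at the transducer center frequency, the point-source sampling
#' limit of the superposition.
#'
#' @param p0 3D array of initial pressure (Pa), or a [dose_volume()] (then
#'   converted via [initial_pressure()]).
#' @param grid the [build_array()] element grid.
#' @param spec the [transducer_spec()].
#' @param medium an [acoustic_medium()].
#' @param pulse an [excitation_pulse()], or `NULL` for impulsive (delta)
#'   excitation.
#' @param volume the [volume_grid()] of `p0` (not needed when `p0` is a
#'   `dose_volume`).
#' @param sampling_rate channel sampling rate (Hz).
#' @param apply_receive_ir convolve with the element receive impulse response.
#' @param baffle element baffle model, `"rigid"` or `"soft"`.
#' @return A `channel_data` object.
#' @export
propagate <- function(p0, grid, spec, medium, pulse = excitation_pulse(),
                      volume = NULL, sampling_rate = 20e6,
                      apply_receive_ir = TRUE, baffle = "rigid") {
  if (inherits(p0, "dose_volume")) {
    volume <- p0$grid
    p0 <- initial_pressure(p0, medium)
  }
  stopifnot(inherits(volume, "volume_grid"), all(dim(p0) == dim(volume)))
  c0 <- medium$sound_speed
  lambda <- c0 / spec$center_frequency
  if (max(volume$spacing) > lambda / 4) {
    warning("source grid spacing exceeds lambda/4 at the center frequency (",
            signif(lambda / 4 * 1e3, 3), " mm); the point-source ",
            "superposition under-samples the wavefield")
  }
  ax <- grid_axes(volume)
  if (min(ax$z) <= 0) stop("all source voxels must lie in front of the array")

  src <- which(p0 != 0)
  vox <- voxel_centers(volume)
  amp <- p0[src] * voxel_volume(volume) / (4 * pi)
  srcpos <- vox[src, , drop = FALSE]

  # combined band-limiting kernel, zero-phase aligned at its envelope peak
  kern <- 1
  if (!is.null(pulse)) {
    env <- pulse_envelope(pulse, sampling_rate)
    kern <- diff(c(0, env, 0)) * sampling_rate
  }
  if (apply_receive_ir) {
    ir <- receive_impulse(spec, sampling_rate)$samples
    kern <- if (length(kern) > 1) {
      stats::convolve(kern, rev(ir), type = "open")
    } else ir
  }
  if (length(kern) == 1) kern <- c(kern)  # pure delta: no filtering

  # trace length covers the farthest corner of the whole volume, so that a
  # reconstruction anywhere on the same grid finds its delays recorded
  rmax <- 0
  for (i in 1:3) {
    rng <- volume$origin[i] + c(0, volume$extent[i])
    erng <- if (i == 3) c(0, 0) else range(grid$positions[, i])
    rmax <- rmax + max(abs(rng[1] - erng[2]), abs(rng[2] - erng[1]))^2
  }
  rmax <- sqrt(rmax)
  nt <- ceiling(rmax / c0 * sampling_rate) + length(kern) + 8L

  sp <- cpp_splat(srcpos, amp, grid$positions, c0, sampling_rate, 0, nt,
                  spec$directivity_size / lambda,
                  as.integer(identical(baffle, "soft")),
                  min(volume$spacing) / 2)
  if (sp$skipped > 0) {
    warning(sp$skipped, " source-element pair(s) closer than half a voxel ",
            "excluded")
  }
  tr <- sp$traces
  if (length(kern) > 1) {
    peak <- which.max(envelope(kern))
    tr <- convolve_rows(tr, kern, peak)
  }
  new_channel_data(tr, sampling_rate, 0, grid$positions)
}

#' Number of full acquisitions from multiplexed pulse trains
#'
#' The 1024-element array is read out through 256 channels with a 4-to-1
#' multiplexer, so `pulses / multiplexer_ratio` pulses yield one full
#' acquisition each: 1000 pulses give 250 full acquisitions.
#'
#' @param pulses number of excitation pulses delivered.
#' @param multiplexer_ratio elements per acquisition channel.
#' @export
effective_averages <- function(pulses, multiplexer_ratio = 4) {
  stopifnot(pulses >= 1, multiplexer_ratio >= 1)
  pulses / multiplexer_ratio
}

#' Simulate noisy averaged acquisition
#'
#' Adds independent white Gaussian noise per acquisition and returns the mean
#' over `n_averages` repetitions. The averaged noise is drawn directly with
#' standard deviation `noise_std / sqrt(n_averages)`, which is exactly the
#' distribution of the mean of `n_averages` independent draws. When `pulses`
#' is given, the number of averages is derived as
#' [effective_averages()]`(pulses, multiplexer_ratio)`.
#'
#' @param channels a `channel_data` object.
#' @param noise_std per-acquisition noise standard deviation (trace units).
#' @param n_averages number of averaged acquisitions.
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @param pulses optional pulse count from which `n_averages` is derived.
#' @param multiplexer_ratio see [effective_averages()].
#' @export
acquire <- function(channels, noise_std, n_averages = 1, seed = NULL,
                    pulses = NULL, multiplexer_ratio = 4) {
  stopifnot(inherits(channels, "channel_data"))
  if (noise_std < 0) stop("noise_std must be non-negative")
  if (!is.null(pulses)) {
    n_averages <- effective_averages(pulses, multiplexer_ratio)
  }
  if (n_averages < 1) stop("n_averages must be at least 1")
  if (noise_std == 0) return(channels)
  if (!is.null(seed)) set.seed(seed)
  tr <- channels$traces +
    matrix(rnorm(length(channels$traces), sd = noise_std / sqrt(n_averages)),
           nrow(channels$traces))
  new_channel_data(tr, channels$sampling_rate, channels$t0,
                   channels$element_positions, seed = seed)
}
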