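#' Analytic signal and envelope of an RF trace
#'
#' `analytic_signal()` returns the complex analytic signal (negative
#' frequencies suppressed via the FFT); `envelope()` returns its magnitude,
#' the amplitude envelope of the trace.
#'
#' @param trace real numeric vector.
#' @return complex (analytic_signal) or non-negative numeric (envelope)
#'   vector of the same length.
#' @export
analytic_signal <- function(trace) {
  n <- length(trace)
  if (n == 0) stop("empty trace")
  if (!all(is.finite(trace))) stop("trace must be finite")
  X <- fft(trace)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; if (n > 1) h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' @rdname analytic_signal
#' @export
envelope <- function(trace) {
  Mod(analytic_signal(trace))
}

# Analytic signal of every row of a trace matrix at once, zero-padded to a
# power of two for the FFT (the padding carries no signal).
analytic_rows <- function(tr) {
  ne <- nrow(tr); nt <- ncol(tr)
  n <- stats::nextn(nt, 2)
  X <- stats::mvfft(t(cbind(tr, matrix(0, ne, n - nt))))
  h <- numeric(n)
  h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  t(stats::mvfft(X * h, inverse = TRUE) / n)[, seq_len(nt), drop = FALSE]
}

new_recon_volume <- function(amplitude, grid, compensated = FALSE,
                             normalization = "none", n_zeroed = 0L) {
  structure(list(amplitude = amplitude, grid = grid, compensated = compensated,
                 normalization = normalization, n_zeroed = n_zeroed),
            class = "recon_volume")
}

#' @export
print.recon_volume <- function(x, ...) {
  cat(sprintf("<recon_volume> %s, %s, normalization %s, max %.3g\n",
              paste(dim(x$amplitude), collapse = " x "),
              if (x$compensated) "compensated" else "uncompensated",
              x$normalization, max(x$amplitude)))
  invisible(x)
}

#' 3D delay-and-sum reconstruction with envelope detection
#'
#' For each voxel, the analytic (complex) trace of every element is sampled
#' at the geometric time of flight `t = r / c` with linear inter-sample
#' interpolation and summed coherently across elements; the voxel amplitude
#' is the magnitude of the complex sum (complex/analytic delay-and-sum, which
#' performs envelope detection on the beamformed signal). An alternative
#' `mode = "rf"` sums the raw RF traces and is provided for comparison; its
#' output is the rectified RF sum without envelope detection and is not used
#' by the quantification pipeline.
#'
#' Voxels whose delay falls outside the recorded trace support are zeroed,
#' flagged in the returned `n_zeroed` count, and reported as a message.
#'
#' @param channels a `channel_data` object.
#' @param grid the [build_array()] element grid (must match the channel
#'   count).
#' @param volume the [volume_grid()] to reconstruct on.
#' @param medium an [acoustic_medium()].
#' @param apodization `"none"` (uniform weights); no other scheme is applied.
#' @param mode `"complex"` (analytic DAS, default) or `"rf"`.
#' @return A `recon_volume`.
#' @export
das_reconstruct <- function(channels, grid, volume, medium,
                            apodization = c("none", "uniform"),
                            mode = c("complex", "rf")) {
  apodization <- match.arg(apodization)
  mode <- match.arg(mode)
  stopifnot(inherits(channels, "channel_data"),
            inherits(grid, "element_grid"),
            inherits(volume, "volume_grid"))
  if (nrow(channels$traces) != nrow(grid$positions)) {
    stop("channel count does not match element count")
  }
  if (mode == "complex") {
    an <- analytic_rows(channels$traces)
    re <- Re(an); im <- Im(an)
  } else {
    re <- channels$traces; im <- matrix(0, nrow(re), ncol(re))
  }
  res <- cpp_das(re, im, grid$positions, voxel_centers(volume),
                 medium$sound_speed, channels$sampling_rate, channels$t0)
  if (res$zeroed > 0) {
    message(res$zeroed, " voxel(s) required delays beyond the trace length; ",
            "zeroed")
  }
  new_recon_volume(array(res$amplitude, dim(volume)), volume,
                   n_zeroed = res$zeroed)
}

#' Normalize a reconstruction to unit maximum
#' @param volume a `recon_volume`.
#' @export
normalize_recon <- function(volume) {
  stopifnot(inherits(volume, "recon_volume"))
  m <- max(volume$amplitude)
  if (m <= 0) stop("cannot normalize an all-zero reconstruction")
  out <- volume
  out$amplitude <- volume$amplitude / m
  out$normalization <- "max"
  out
}

#' Voxel-wise sensitivity compensation
#'
#' Element-wise multiplication of the reconstructed amplitudes with the
#' correction-factor volume (the regularized reciprocal of the normalized
#' detection-sensitivity map). Refuses to compensate twice.
#'
#' @param volume a `recon_volume`.
#' @param correction a [correction_factors()] volume on the same grid.
#' @export
compensate <- function(volume, correction) {
  stopifnot(inherits(volume, "recon_volume"),
            inherits(correction, "correction_volume"))
  if (isTRUE(volume$compensated)) {
    stop("volume is already sensitivity-compensated")
  }
  if (!is.null(correction$grid) && !grids_match(volume$grid, correction$grid)) {
    stop("reconstruction and correction volumes lie on different grids")
  }
  if (!all(dim(volume$amplitude) == dim(correction$factors))) {
    stop("reconstruction and correction volumes have different dimensions")
  }
  new_recon_volume(volume$amplitude * correction$factors, volume$grid,
                   compensated = TRUE, normalization = volume$normalization,
                   n_zeroed = volume$n_zeroed)
}
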