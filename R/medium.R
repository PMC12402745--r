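#' Homogeneous acoustic medium
#'
#' Defaults describe the solidified-vegetable-oil phantom used for the beam
#' studies: c = 1445 m/s, rho = 920 kg/m^3. The Grueneisen parameter converts
#' absorbed energy density to initial pressure; 0.9 is a representative value
#' for lipid-like media and is configurable.
#'
#' @param sound_speed speed of sound (m/s).
#' @param density mass density (kg/m^3).
#' @param grueneisen dimensionless thermoacoustic efficiency.
#' @export
acoustic_medium <- function(sound_speed = 1445, density = 920,
                            grueneisen = 0.9) {
  stopifnot(sound_speed > 0, density > 0, grueneisen > 0)
  structure(list(sound_speed = sound_speed, density = density,
                 grueneisen = grueneisen),
            class = "acoustic_medium")
}

#' X-ray excitation pulse
#'
#' Temporal envelope of one accelerator pulse. The default is a 4 us raised
#' cosine (Hann) envelope at a 330 Hz repetition rate; the repetition rate is
#' bookkeeping only (a single pulse period is simulated).
#'
#' @param duration pulse width in seconds.
#' @param repetition_rate pulse repetition rate in Hz; the period must exceed
#'   the pulse duration.
#' @param shape `"hann"` or `"rect"` envelope on `[0, duration]`.
#' @export
excitation_pulse <- function(duration = 4e-6, repetition_rate = 330,
                             shape = c("hann", "rect")) {
  shape <- match.arg(shape)
  stopifnot(duration > 0, repetition_rate > 0)
  if (1 / repetition_rate <= duration) {
    stop("pulse period must exceed the pulse duration")
  }
  structure(list(duration = duration, repetition_rate = repetition_rate,
                 shape = shape),
            class = "excitation_pulse")
}

# Sampled envelope of the excitation pulse on [0, duration].
pulse_envelope <- function(pulse, sampling_rate) {
  n <- max(2L, ceiling(pulse$duration * sampling_rate))
  t <- (seq_len(n) - 0.5) / sampling_rate
  switch(pulse$shape,
         hann = 0.5 * (1 - cos(2 * pi * t / pulse$duration)),
         rect = rep(1, n))
}
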