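#' Default run configuration
#'
#' Named list of every tunable of the end-to-end studies, serializable to
#' YAML. Defaults are the study conditions: the 0.35 MHz 32 x 32 array, the
#' solidified-oil medium, 4 us Hann excitation at 330 Hz, a 0.5 degree
#' dynamic-focusing sweep, noiseless single-shot acquisition, simulated-map
#' compensation with a 0.05 reciprocal floor, and 5%/5 mm global gamma with a
#' 10% low-dose threshold. `grid_spacing` (default 5 mm) sets the working
#' voxel size of reconstruction and sensitivity volumes;
#' `forward$source_spacing` (default 1 mm, the quarter-wavelength limit) sets
#' the forward model's source discretization.
#'
#' @param ... overrides merged over the defaults (named, possibly nested).
#' @export
default_run_config <- function(...) {
  cfg <- list(
    transducer = list(center_frequency = 0.35e6, fractional_bandwidth = 0.5,
                      n_elements = c(32L, 32L), element_size = 3.45e-3,
                      kerf = 0.2e-3, directivity_size = 8e-3),
    medium = list(sound_speed = 1445, density = 920, grueneisen = 0.9),
    pulse = list(duration = 4e-6, repetition_rate = 330, shape = "hann"),
    grid_spacing = 5e-3,
    sweep = list(step = 0.5, window_deg = 1.5),
    forward = list(sampling_rate = 20e6, source_spacing = 1e-3,
                   apply_receive_ir = FALSE, noise_std = 0, n_averages = 1,
                   seed = 1L),
    compensation = list(source = "simulated", floor_epsilon = 0.05,
                        virtual_lattice_step = 0.025),
    evaluation = list(dd_percent = 5, dta_mm = 5, low_dose_threshold = 10,
                      n_bins = 101)
  )
  overrides <- list(...)
  if (length(overrides)) cfg <- modifyList(cfg, overrides)
  cfg
}

#' Save / load a run configuration as YAML
#' @param config a configuration list (see [default_run_config()]).
#' @param path a YAML file path.
#' @export
save_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname save_run_config
#' @export
load_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$transducer$n_elements <- as.integer(cfg$transducer$n_elements)
  cfg$forward$seed <- as.integer(cfg$forward$seed)
  cfg
}

config_spec <- function(cfg) {
  do.call(transducer_spec, cfg$transducer)
}

config_medium <- function(cfg) {
  do.call(acoustic_medium, cfg$medium)
}

config_pulse <- function(cfg) {
  do.call(excitation_pulse, cfg$pulse)
}
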