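#' Run an end-to-end study
#'
#' Generates the phantom dose volume(s) of the chosen study, simulates
#' channel data with the linear forward model, reconstructs by delay-and-sum,
#' compensates with correction factors from the configured sensitivity
#' source, and evaluates. Deterministic given the seed in the configuration.
#'
#' The forward model discretizes the dose on its own fine source grid
#' (`config$forward$source_spacing`, default 1 mm, the quarter-wavelength
#' sampling limit) while sensitivity, reconstruction and evaluation share the
#' working grid (`config$grid_spacing`, default 5 mm). In study mode the
#' channel data carry the excitation-envelope derivative only (the receive
#' impulse response is not applied, `config$forward$apply_receive_ir`), the
#' wideband recording of the reference full-wave treatment; see the package
#' vignette.
#'
#' Studies:
#' * `depth`: seven 1 x 1 cm beams at 5-17 cm depth on the array axis;
#'   reports pre/post-compensation region-mean amplitudes over each beam's
#'   central cross-section (normalized to the family maximum) and their
#'   coefficients of variation.
#' * `lateral`: seven 1 x 1 cm beams at 11 cm depth, offsets -6 to +6 cm;
#'   same summaries.
#' * `size`: beams of 1-5 cm at 11 cm depth; additionally reports midline
#'   depth profiles and their pre/post plateau slopes.
#' * `cshape`: the C-shaped plan in a 15 x 15 x 15 cm volume; reports
#'   pre/post DVH-RMSE against the plan DVH, gamma pass rates, and SSIM,
#'   all on max-normalized (relative) volumes.
#'
#' @param config configuration list, see [default_run_config()].
#' @param study one of `"depth"`, `"lateral"`, `"size"`, `"cshape"`.
#' @param out_dir optional output directory for volumes, a JSON report and a
#'   log file.
#' @param correction optional precomputed [correction_factors()] volume on
#'   the study's working grid, reused instead of simulating the sensitivity
#'   map (the map only depends on the transducer and grid, so it can be
#'   shared across studies).
#' @return The report, a named list.
#' @export
run_experiment <- function(config = default_run_config(),
                           study = c("depth", "lateral", "size", "cshape"),
                           out_dir = NULL, correction = NULL) {
  study <- match.arg(study)
  spec <- config_spec(config)
  medium <- config_medium(config)
  pulse <- config_pulse(config)
  arr <- build_array(spec)
  seed <- config$forward$seed
  set.seed(seed)

  if (study == "cshape") {
    volume <- volume_grid(extent = c(0.15, 0.15, 0.15),
                          spacing = config$grid_spacing,
                          origin = c(-0.075, -0.075, 0.025))
    source_grid <- volume_grid(extent = volume$extent,
                               spacing = config$forward$source_spacing,
                               origin = volume$origin)
  } else {
    volume <- beam_phantom_grid(config$grid_spacing)
    source_grid <- beam_phantom_grid(config$forward$source_spacing)
  }

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  corr <- if (!is.null(correction)) {
    stopifnot(inherits(correction, "correction_volume"))
    if (!grids_match(correction$grid, volume)) {
      stop("[sensitivity] supplied correction volume is on a different grid")
    }
    correction
  } else stage("sensitivity", {
    smap <- if (identical(config$compensation$source, "virtual")) {
      ax <- grid_axes(volume)
      st <- config$compensation$virtual_lattice_step
      lat <- as.matrix(expand.grid(
        x = seq(min(ax$x), max(ax$x), by = st),
        y = seq(min(ax$y), max(ax$y), by = st),
        z = seq(min(ax$z), max(ax$z), by = st)))
      densify_map(virtual_point_source_map(
        arr, spec, medium, lat,
        sampling_rate = config$forward$sampling_rate,
        noise_std = config$forward$noise_std,
        n_averages = config$forward$n_averages, seed = seed), volume)
    } else {
      simulate_sensitivity_map(arr, spec, sweep_plan(step = config$sweep$step),
                               medium, volume,
                               window_deg = config$sweep$window_deg)
    }
    correction_factors(smap, config$compensation$floor_epsilon)
  })

  image_dose <- function(dose_fine) {
    ch <- stage("forward", propagate(
      dose_fine, arr, spec, medium, pulse = pulse,
      sampling_rate = config$forward$sampling_rate,
      apply_receive_ir = isTRUE(config$forward$apply_receive_ir)))
    if (config$forward$noise_std > 0) {
      ch <- stage("acquire", acquire(ch, config$forward$noise_std,
                                     config$forward$n_averages, seed = seed))
    }
    rec <- stage("recon", suppressMessages(
      das_reconstruct(ch, arr, volume, medium)))
    list(pre = rec, post = stage("compensate", compensate(rec, corr)))
  }

  ev <- config$evaluation
  report <- list(study = study, seed = seed,
                 grid_spacing_mm = config$grid_spacing * 1e3,
                 source_spacing_mm = config$forward$source_spacing * 1e3,
                 correction_capped_voxels = corr$n_capped)

  if (study %in% c("depth", "lateral", "size")) {
    beams <- beam_study_layouts()[[study]]
    recs <- lapply(beams, function(b) {
      image_dose(square_beam_dose(b, source_grid))
    })
    masks <- lapply(beams, beam_region_mask, volume = volume)
    pre <- vapply(seq_along(recs), function(i) {
      region_mean_amplitude(recs[[i]]$pre, masks[[i]])
    }, 0)
    post <- vapply(seq_along(recs), function(i) {
      region_mean_amplitude(recs[[i]]$post, masks[[i]])
    }, 0)
    report$positions <- t(vapply(beams, function(b) b$target_position,
                                 numeric(2)))
    report$field_size_cm <- vapply(beams, function(b) b$field_size * 100, 0)
    report$region_mean_pre <- pre / max(pre)
    report$region_mean_post <- post / max(post)
    report$cv_pre <- sd(pre) / mean(pre)
    report$cv_post <- sd(post) / mean(post)
    if (study == "size") {
      report$profiles <- lapply(seq_along(recs), function(i) {
        list(pre = line_profile(recs[[i]]$pre, "z"),
             post = line_profile(recs[[i]]$post, "z"))
      })
      slopes <- vapply(seq_along(recs), function(i) {
        c(pre = profile_slope(report$profiles[[i]]$pre, beams[[i]]),
          post = profile_slope(report$profiles[[i]]$post, beams[[i]]))
      }, numeric(2))
      report$slope_pre <- slopes["pre", ]
      report$slope_post <- slopes["post", ]
    }
    vols <- recs
  } else {
    plan_fine <- stage("phantom", c_shape_dose(c_shape_spec(), source_grid))
    plan <- stage("phantom", c_shape_dose(c_shape_spec(), volume))
    rec <- image_dose(plan_fine)
    pre_n <- normalize_recon(rec$pre); post_n <- normalize_recon(rec$post)
    plan_rel <- plan$dose / max(plan$dose)
    d_plan <- dvh(plan_rel, ev$n_bins, max_value = 1)
    d_pre <- dvh(pre_n$amplitude, ev$n_bins, max_value = 1)
    d_post <- dvh(post_n$amplitude, ev$n_bins, max_value = 1)
    g_pre <- gamma_index(plan_rel, pre_n$amplitude, ev$dd_percent, ev$dta_mm,
                         ev$low_dose_threshold, spacing = volume$spacing)
    g_post <- gamma_index(plan_rel, post_n$amplitude, ev$dd_percent,
                          ev$dta_mm, ev$low_dose_threshold,
                          spacing = volume$spacing)
    report$dvh_rmse_pre <- dvh_rmse(d_plan, d_pre)
    report$dvh_rmse_post <- dvh_rmse(d_plan, d_post)
    report$gamma_pass_pre <- g_pre$pass_rate
    report$gamma_pass_post <- g_post$pass_rate
    report$gamma_pass_all_pre <- g_pre$pass_rate_all
    report$gamma_pass_all_post <- g_post$pass_rate_all
    report$ssim_pre <- ssim_index(plan_rel, pre_n$amplitude)
    report$ssim_post <- ssim_index(plan_rel, post_n$amplitude)
    vols <- list(list(pre = rec$pre, post = rec$post))
    report$plan_max_dose <- max(plan$dose)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(vols)) {
      write_volume(vols[[i]]$pre,
                   file.path(out_dir, sprintf("%s_%02d_pre.nii.gz", study, i)))
      write_volume(vols[[i]]$post,
                   file.path(out_dir, sprintf("%s_%02d_post.nii.gz", study, i)))
    }
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = 10, dataframe = "columns")
    writeLines(c(sprintf("study: %s", study),
                 sprintf("seed: %d", seed),
                 sprintf("voxels: %s", paste(dim(volume), collapse = "x")),
                 sprintf("capped correction voxels: %d", corr$n_capped),
                 sprintf("package: irai %s",
                         as.character(utils::packageVersion("irai")))),
               file.path(out_dir, "run.log"))
  }
  report
}

#' Region mask of a beam's central cross-section
#'
#' Voxels at or above half the beam's maximum dose, restricted to the beam's
#' central cross-section along the beam axis (`|y| <= field_size / 2`) — the
#' region the per-position quantification averages, mirroring quantification
#' on cross-sectional beam images.
#'
#' @param beam a [beam_spec()].
#' @param volume the working [volume_grid()].
#' @return logical array on `volume`.
#' @export
beam_region_mask <- function(beam, volume) {
  d <- square_beam_dose(beam, volume)
  ay <- grid_axes(volume)$y
  ymask <- abs(ay) <= beam$field_size / 2 + 1e-9
  (d$dose >= max(d$dose) / 2) &
    array(rep(ymask, each = dim(volume)[1]), dim(volume))
}

# Linear-fit slope (relative units per cm) of a midline profile over the beam
# plateau, keeping one voxel of margin inside the nominal beam edges; the
# slope is normalized by the plateau mean so beams of different brightness
# are comparable.
profile_slope <- function(profile, beam) {
  z0 <- beam$target_position[2] * 100
  h <- beam$field_size / 2 * 100
  dz <- min(diff(profile$coord_cm))
  sel <- abs(profile$coord_cm - z0) <= max(h - dz, dz / 2 + 1e-9)
  if (sum(sel) < 2) sel <- abs(profile$coord_cm - z0) <= h
  fit <- lm(amplitude ~ coord_cm, data = profile[sel, ])
  unname(coef(fit)[2]) / mean(profile$amplitude[sel])
}
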