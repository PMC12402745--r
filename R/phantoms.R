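#' Square x-ray beam specification
#'
#' A vertically directed square beam (entry along +y, perpendicular to the
#' array axis) whose column crosses the phantom at a target position stated
#' as (x, z): x is the lateral offset from the array axis and z the depth
#' from the array face.
#'
#' @param field_size beam side length (m).
#' @param target_position `c(x, z)` (m): lateral offset and depth of the beam
#'   column axis.
#' @param depth_dose_model `"uniform"` (constant dose along the beam path,
#'   the default: the beam column itself is the imaging target) or
#'   `"exponential"` (attenuated as `exp(-mu_eff * path)` from the entry
#'   face).
#' @param mu_eff effective linear attenuation (1/m) for the exponential
#'   model.
#' @param edge_softness Gaussian edge width (m); 0 gives hard edges.
#' @export
beam_spec <- function(field_size, target_position = c(0, 0.11),
                      depth_dose_model = c("uniform", "exponential"),
                      mu_eff = 5, edge_softness = 0) {
  depth_dose_model <- match.arg(depth_dose_model)
  stopifnot(field_size > 0, length(target_position) == 2, edge_softness >= 0)
  structure(list(field_size = field_size, target_position = target_position,
                 depth_dose_model = depth_dose_model, mu_eff = mu_eff,
                 edge_softness = edge_softness),
            class = "beam_spec")
}

# soft-edged indicator of |u| <= h via Gaussian-convolved edges
soft_edge <- function(u, h, s) {
  if (s <= 0) return(as.numeric(abs(u) <= h))
  stats::pnorm((h - u) / s) - stats::pnorm((-h - u) / s)
}

#' Dose volume of a square vertical beam
#'
#' The dose is non-zero only inside the rectangular beam column (cross
#' section `field_size` x `field_size` in x and z, spanning the phantom in
#' y); along the beam axis (y) it follows the depth-dose model.
#'
#' @param spec a [beam_spec()].
#' @param volume a [volume_grid()].
#' @param peak_dose dose at the beam entry (Gy); the default is the 2.26 Gy
#'   delivered per measurement in the beam studies.
#' @return A [dose_volume()].
#' @export
square_beam_dose <- function(spec, volume, peak_dose = 2.26) {
  stopifnot(inherits(spec, "beam_spec"), inherits(volume, "volume_grid"))
  ax <- grid_axes(volume)
  h <- spec$field_size / 2
  x0 <- spec$target_position[1]; z0 <- spec$target_position[2]
  if (x0 - h < min(ax$x) - volume$spacing[1] / 2 ||
      x0 + h > max(ax$x) + volume$spacing[1] / 2 ||
      z0 - h < min(ax$z) - volume$spacing[3] / 2 ||
      z0 + h > max(ax$z) + volume$spacing[3] / 2) {
    stop("beam column does not fit inside the volume")
  }
  wx <- soft_edge(ax$x - x0, h, spec$edge_softness)
  wz <- soft_edge(ax$z - z0, h, spec$edge_softness)
  wy <- switch(spec$depth_dose_model,
               uniform = rep(1, length(ax$y)),
               exponential = exp(-spec$mu_eff * (max(ax$y) - ax$y)))
  dose <- peak_dose * outer(outer(wx, wy), wz)
  dose_volume(dose, volume)
}

#' Beam layouts of the square-beam study
#'
#' Three layout families of 1 cm beams (except the size family) in the
#' 17 x 17 x 20 cm phantom:
#' * `depth`: 1 x 1 cm beams on the array axis at depths 5, 7, ..., 17 cm;
#' * `lateral`: 1 x 1 cm beams at 11 cm depth at lateral offsets
#'   -6, -4, ..., +6 cm (seven positions spaced 2 cm);
#' * `size`: beams of 1-5 cm side at 11 cm depth on the axis.
#'
#' @return named list of lists of [beam_spec()]s.
#' @export
beam_study_layouts <- function() {
  depth <- lapply(seq(0.05, 0.17, by = 0.02), function(z) {
    beam_spec(field_size = 0.01, target_position = c(0, z))
  })
  lateral <- lapply(seq(-0.06, 0.06, by = 0.02), function(x) {
    beam_spec(field_size = 0.01, target_position = c(x, 0.11))
  })
  size <- lapply(seq(0.01, 0.05, by = 0.01), function(fs) {
    beam_spec(field_size = fs, target_position = c(0, 0.11))
  })
  list(depth = depth, lateral = lateral, size = size)
}

#' Default phantom grid for the beam studies
#'
#' The 17 x 17 x 20 cm phantom box with the array face at z = 0.
#' @param spacing voxel size (m).
#' @export
beam_phantom_grid <- function(spacing = 5e-3) {
  volume_grid(extent = c(0.17, 0.17, 0.20), spacing = spacing)
}

#' C-shaped treatment-plan specification
#'
#' Synthetic stand-in for a clinically relevant C-shaped plan (a target
#' wrapping around a spared central structure such as the spine): an annular
#' sector prism with a gap, 21.6 Gy maximum dose. The reference plan fixes
#' only the topology and maximum dose; the default dimensions (outer radius
#' 5 cm, inner 2.5 cm, 90 degree gap, 5 cm height, 3 mm Gaussian edge) are
#' this package's stand-in geometry.
#'
#' @param outer_radius,inner_radius annulus radii (m).
#' @param gap_half_angle half-angle of the spared gap sector (radians).
#' @param height prism height along z (m).
#' @param max_dose maximum dose (Gy).
#' @param edge_softness Gaussian edge width (m).
#' @export
c_shape_spec <- function(outer_radius = 0.05, inner_radius = 0.025,
                         gap_half_angle = pi / 4, height = 0.05,
                         max_dose = 21.6, edge_softness = 3e-3) {
  stopifnot(inner_radius > 0, outer_radius > inner_radius,
            gap_half_angle > 0, gap_half_angle < pi,
            height > 0, max_dose > 0, edge_softness >= 0)
  structure(list(outer_radius = outer_radius, inner_radius = inner_radius,
                 gap_half_angle = gap_half_angle, height = height,
                 max_dose = max_dose, edge_softness = edge_softness),
            class = "c_shape_spec")
}

#' Dose volume of the C-shaped plan
#'
#' The C lies in the axial (x-y) plane, centered laterally on the volume and
#' at the mid-depth of the volume along z, with the gap sector centered on
#' the +y direction (so the volume is mirror-symmetric about the x = 0
#' plane). Voxels in the gap sector and inner core receive zero dose; after
#' Gaussian edge smoothing the volume is rescaled so its maximum equals
#' `max_dose`.
#'
#' @param spec a [c_shape_spec()].
#' @param volume a [volume_grid()].
#' @export
c_shape_dose <- function(spec, volume) {
  stopifnot(inherits(spec, "c_shape_spec"), inherits(volume, "volume_grid"))
  ax <- grid_axes(volume)
  cx <- mean(range(ax$x)); cy <- mean(range(ax$y)); cz <- mean(range(ax$z))
  if (spec$outer_radius > min(diff(range(ax$x)), diff(range(ax$y))) / 2 +
        1e-12 || spec$height > diff(range(ax$z)) + min(volume$spacing)) {
    stop("C shape does not fit inside the volume")
  }
  # exactly antisymmetric centered coordinates, so the mask (and the gap
  # boundary in particular) is mirror-symmetric to the last bit
  sym <- function(u, c0) { v <- u - c0; (v - rev(v)) / 2 }
  xx <- array(rep(sym(ax$x, cx), times = volume$n[2] * volume$n[3]), volume$n)
  yy <- array(rep(rep(sym(ax$y, cy), each = volume$n[1]),
                  times = volume$n[3]), volume$n)
  zz <- array(rep(sym(ax$z, cz), each = volume$n[1] * volume$n[2]), volume$n)
  rr <- sqrt(xx^2 + yy^2)
  theta <- atan2(xx, yy)  # 0 along +y, the gap center
  mask <- (rr >= spec$inner_radius) & (rr <= spec$outer_radius) &
    (abs(theta) >= spec$gap_half_angle) & (abs(zz) <= spec$height / 2)
  dose <- array(as.numeric(mask), volume$n)
  if (spec$edge_softness > 0) {
    dose <- gaussian_blur3(dose, spec$edge_softness / volume$spacing)
  }
  dose <- dose / max(dose) * spec$max_dose
  dose_volume(dose, volume)
}

# separable 3D Gaussian blur; sigma in voxels per axis
gaussian_blur3 <- function(a, sigma) {
  blur1 <- function(v, s) {
    if (s <= 0) return(v)
    n <- max(1L, ceiling(3 * s))
    k <- exp(-(-n:n)^2 / (2 * s^2)); k <- k / sum(k)
    pad <- c(rep(v[1], n), v, rep(v[length(v)], n))
    stats::filter(pad, k, sides = 2)[(n + 1):(n + length(v))]
  }
  for (axis in 1:3) {
    a <- apply(a, setdiff(1:3, axis), blur1, s = sigma[axis])
    a <- aperm(a, order(c(axis, setdiff(1:3, axis))))
  }
  a
}
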