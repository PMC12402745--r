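#' Write a volumetric object to NIfTI
#'
#' Stores the voxel array with its physical grid (spacing and first-voxel
#' center, in mm, via the NIfTI transform) plus a JSON sidecar
#' (`<file>.json`) carrying the object class and flags (`normalized`,
#' `compensated`, `floor_epsilon`), so the object reloads without any run
#' configuration.
#'
#' @param x a `dose_volume`, `sensitivity_map`, `correction_volume` or
#'   `recon_volume`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  vals <- switch(class(x)[1],
                 dose_volume = x$dose,
                 sensitivity_map = x$values,
                 correction_volume = x$factors,
                 recon_volume = x$amplitude,
                 stop("unsupported volume class: ", class(x)[1]))
  grid <- x$grid
  img <- RNifti::asNifti(array(as.numeric(vals), dim(grid)))
  mm <- grid$spacing * 1e3
  img <- RNifti::`pixdim<-`(img, mm)
  m <- diag(c(mm, 1))
  m[1:3, 4] <- (grid$origin + grid$spacing / 2) * 1e3
  img <- RNifti::`qform<-`(img, structure(m, code = 2L))
  RNifti::writeNifti(img, path)
  meta <- list(class = class(x)[1],
               normalized = isTRUE(x$normalized),
               compensated = isTRUE(x$compensated),
               normalization = x$normalization,
               floor_epsilon = x$floor_epsilon)
  jsonlite::write_json(meta[!vapply(meta, is.null, TRUE)],
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a volumetric object written by [write_volume()]
#' @param path a NIfTI file with its JSON sidecar.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  vals <- as.array(img)
  attributes(vals) <- list(dim = dim(vals))
  sp <- RNifti::pixdim(img) * 1e-3
  off <- RNifti::xform(img)[1:3, 4] * 1e-3
  grid <- volume_grid(extent = sp * dim(vals), spacing = sp,
                      origin = off - sp / 2)
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  cls <- if (is.null(meta$class)) "recon_volume" else meta$class
  switch(cls,
         dose_volume = dose_volume(vals, grid),
         sensitivity_map = new_sensitivity_map(vals, grid,
                                               isTRUE(meta$normalized)),
         correction_volume = structure(
           list(factors = vals, grid = grid,
                floor_epsilon = meta$floor_epsilon %||% NA_real_,
                n_capped = NA_integer_),
           class = "correction_volume"),
         recon_volume = new_recon_volume(
           vals, grid, compensated = isTRUE(meta$compensated),
           normalization = meta$normalization %||% "none"),
         stop("unknown volume class in sidecar: ", cls))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Channel-data container I/O
#'
#' Serializes the channel container (datasets `traces`, `sampling_rate`,
#' `t0`, `element_positions`, `seed`) as an RDS file.
#'
#' @param channels a `channel_data` object.
#' @param path output path (`.rds`).
#' @export
write_channel_data <- function(channels, path) {
  stopifnot(inherits(channels, "channel_data"))
  saveRDS(unclass(channels), path)
  invisible(path)
}

#' @rdname write_channel_data
#' @export
read_channel_data <- function(path) {
  x <- readRDS(path)
  new_channel_data(x$traces, x$sampling_rate, x$t0, x$element_positions,
                   x$seed)
}
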