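#' Imaging configuration for synthetic field rendering
#'
#' Geometry and camera model of the simulated two-channel acquisition.
#' The real instrument captures nine fields per well; field size and
#' magnification are not part of the published protocol, so the defaults
#' here are declared configuration (512 x 512 px, 16-bit), not inferred
#' values — every downstream endpoint is a per-image count or sum and is
#' invariant to field size.
#'
#' @param field_shape integer (rows, cols) in pixels.
#' @param bit_depth pixel bit depth (images are clipped to
#'   `2^bit_depth - 1`).
#' @param background_level constant background (a.u.) in both channels.
#' @param blur_sigma Gaussian optical blur (px) applied to the rendered
#'   scene.
#' @param noise_model `"none"`, `"gaussian"` (additive, sd =
#'   `noise_params$sd`), or `"poisson_gaussian"` (Poisson shot noise on
#'   each pixel's expected value plus Gaussian read noise).
#' @param noise_params list; `sd` for the Gaussian component.
#' @param fields_per_well fields imaged per well (default 9).
#' @param nucleus_amplitude peak nuclear-channel intensity above
#'   background (a.u.).
#' @return an `imaging_config` object.
#' @export
imaging_config <- function(field_shape = c(512L, 512L), bit_depth = 16L,
                           background_level = 500, blur_sigma = 1,
                           noise_model = c("none", "gaussian", "poisson_gaussian"),
                           noise_params = list(sd = 50),
                           fields_per_well = 9L,
                           nucleus_amplitude = 8000) {
  noise_model <- match.arg(noise_model)
  if (any(field_shape < 1)) stop("field_shape must be positive", call. = FALSE)
  structure(list(field_shape = as.integer(field_shape),
                 bit_depth = as.integer(bit_depth),
                 background_level = background_level,
                 blur_sigma = blur_sigma, noise_model = noise_model,
                 noise_params = noise_params,
                 fields_per_well = as.integer(fields_per_well),
                 nucleus_amplitude = nucleus_amplitude),
            class = "imaging_config")
}
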