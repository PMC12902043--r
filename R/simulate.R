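#' Sensor noise model
#'
#' Shot/read noise and quantisation of the monochrome sensor. Intensity 1.0
#' (the unit background of the plane-wave model) corresponds to
#' `photons_at_unit_intensity` expected photons; detected photons are
#' Poisson, Gaussian read noise (in counts) is added, and the result is
#' quantised to `bit_depth` bits. Digital gain maps intensity 1.0 to a
#' quarter of full scale so that constructive interference (up to 4x the
#' background) never saturates. `photons_at_unit_intensity = 0` selects the
#' noiseless mode: the exact intensity scaled and quantised to 12-bit.
#'
#' @param photons_at_unit_intensity Expected photon count at intensity 1.0
#'   (default 5000; 0 for noiseless).
#' @param read_noise_sd Gaussian read noise in counts (default 3).
#' @param bit_depth Quantisation depth (default 12).
#' @param seed Optional integer seed for the noise draw.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(photons_at_unit_intensity = 5000,
                        read_noise_sd = 3, bit_depth = 12L, seed = NULL) {
  if (!is.numeric(photons_at_unit_intensity) ||
      photons_at_unit_intensity < 0)
    stop("photons_at_unit_intensity must be >= 0", call. = FALSE)
  if (!is.numeric(read_noise_sd) || read_noise_sd < 0)
    stop("read_noise_sd must be >= 0", call. = FALSE)
  structure(
    list(photons_at_unit_intensity = photons_at_unit_intensity,
         read_noise_sd = read_noise_sd, bit_depth = as.integer(bit_depth),
         seed = seed),
    class = "noise_model"
  )
}

#' Forward-simulate the in-line hologram of a phantom scene
#'
#' Illuminates the scene's transmission function with a unit-amplitude
#' plane wave, propagates it forward to the sensor plane by the angular
#' spectrum method, records the intensity (the interference of the
#' unscattered and object-scattered light), and applies the sensor's
#' shot/read noise and quantisation per the [noise_model()].
#'
#' @param scene A [scene_phantom()].
#' @param h Positive object-to-sensor distance in um.
#' @param noise A [noise_model()] (default: 5000 photons at unit intensity).
#' @param pad_factor Grid enlargement for the propagation (default 2).
#' @return A raw [hologram_frame()] in sensor counts.
#' @examples
#' sc <- render_phantom(field_geometry(128, 128), 1, seed = 1)
#' holo <- simulate_hologram(sc, 2546, noise_model(0))
#' @export
simulate_hologram <- function(scene, h, noise = noise_model(),
                              pad_factor = 2L) {
  if (!inherits(scene, "scene_phantom"))
    stop("scene must be a scene_phantom", call. = FALSE)
  if (!inherits(noise, "noise_model"))
    stop("noise must be a noise_model", call. = FALSE)
  if (!is.numeric(h) || length(h) != 1L || !is.finite(h) || h <= 0)
    stop("h must be a single positive distance (um)", call. = FALSE)
  sensor <- propagate(scene$transmission, h, pad_factor)
  intensity <- Mod(sensor$values)^2
  full_scale <- 2^noise$bit_depth - 1
  counts_per_unit <- full_scale / 4
  if (noise$photons_at_unit_intensity == 0) {
    counts <- round(intensity * counts_per_unit)
  } else {
    counts <- with_seed_if(noise$seed, {
      photons <- stats::rpois(length(intensity),
                              intensity * noise$photons_at_unit_intensity)
      est <- photons / noise$photons_at_unit_intensity * counts_per_unit
      round(est + stats::rnorm(length(est), 0, noise$read_noise_sd))
    })
  }
  counts <- matrix(pmin(pmax(counts, 0), full_scale),
                   scene$geometry$n_y, scene$geometry$n_x)
  hologram_frame(counts, bit_depth = noise$bit_depth,
                 geometry = scene$geometry)
}
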