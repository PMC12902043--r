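#' Measured or simulated in-line hologram frame
#'
#' Holds a single-channel intensity image together with its geometry, the
#' sensor bit depth and an optional background reference. Raw frames carry
#' integer sensor counts bounded by `2^bit_depth - 1`; normalised frames hold
#' dimensionless intensities whose background level is approximately 1.
#'
#' @param intensity Non-negative numeric matrix, shape `(n_y, n_x)`.
#' @param pitch Pixel pitch in um (default 2.0).
#' @param wavelength Illumination wavelength in um (default 0.658).
#' @param bit_depth Sensor bit depth (default 12; values in a raw frame must
#'   not exceed `2^bit_depth - 1`).
#' @param normalized Logical; `TRUE` when the frame has already been divided
#'   by a background estimate.
#' @param background Optional scalar or matrix background estimate attached
#'   by [normalize_hologram()].
#' @param source_path Optional provenance string (e.g. the TIFF file read).
#' @param geometry Optional [field_geometry()]; derived from `intensity`,
#'   `pitch` and `wavelength` when omitted.
#' @return An object of class `hologram_frame`.
#' @export
hologram_frame <- function(intensity, pitch = 2.0, wavelength = 0.658,
                           bit_depth = 12L, normalized = FALSE,
                           background = NULL, source_path = NULL,
                           geometry = NULL) {
  if (!is.matrix(intensity) || !is.numeric(intensity))
    stop("intensity must be a numeric matrix", call. = FALSE)
  if (!all(is.finite(intensity)))
    stop("intensity must be finite everywhere", call. = FALSE)
  if (any(intensity < 0))
    stop("intensity must be non-negative everywhere", call. = FALSE)
  bit_depth <- as.integer(bit_depth)
  if (is.na(bit_depth) || bit_depth < 1L)
    stop("bit_depth must be a positive integer", call. = FALSE)
  if (is.null(geometry))
    geometry <- field_geometry(ncol(intensity), nrow(intensity),
                               pitch, wavelength)
  if (nrow(intensity) != geometry$n_y || ncol(intensity) != geometry$n_x)
    stop("intensity shape does not match geometry", call. = FALSE)
  if (!isTRUE(normalized) && max(intensity) > 2^bit_depth - 1)
    stop(sprintf("raw frame exceeds %d-bit range (max %.1f > %d)",
                 bit_depth, max(intensity), 2^bit_depth - 1), call. = FALSE)
  structure(
    list(geometry = geometry, intensity = intensity, bit_depth = bit_depth,
         normalized = isTRUE(normalized), background = background,
         source_path = source_path),
    class = "hologram_frame"
  )
}

#' @export
print.hologram_frame <- function(x, ...) {
  cat(sprintf(
    "<hologram_frame> %d x %d px, %d-bit, %s; intensity in [%.3g, %.3g]\n",
    x$geometry$n_y, x$geometry$n_x, x$bit_depth,
    if (x$normalized) "normalised" else "raw",
    min(x$intensity), max(x$intensity)))
  invisible(x)
}

is_hologram_frame <- function(x) inherits(x, "hologram_frame")

#' Normalise a hologram to its background
#'
#' Divides the raw intensity by a background estimate so that object-free
#' regions sit at intensity ~ 1, the level assumed by the unit-amplitude
#' plane-wave model of the reconstruction. Three estimators are offered:
#'
#' * `frame_mean` (default): the mean of the whole frame. Appropriate when
#'   objects are sparse on the slide, so the frame mean is dominated by
#'   background.
#' * `border_mean`: the mean of the outer 8-pixel frame; robust when objects
#'   crowd the centre of the field of view.
#' * `reference_frame`: pixelwise division by a supplied object-free frame,
#'   which also flattens illumination non-uniformity. Reference pixels below
#'   1% of the reference mean are clamped to that floor to guard the
#'   division.
#'
#' @param raw A [hologram_frame()] with non-negative, not-all-zero intensity.
#' @param method One of `"frame_mean"`, `"border_mean"`, `"reference_frame"`.
#' @param reference A [hologram_frame()] or numeric matrix; required for
#'   `method = "reference_frame"`.
#' @return A normalised [hologram_frame()] carrying the background estimate.
#' @export
normalize_hologram <- function(raw,
                               method = c("frame_mean", "border_mean",
                                          "reference_frame"),
                               reference = NULL) {
  if (!is_hologram_frame(raw)) stop("raw must be a hologram_frame",
                                    call. = FALSE)
  method <- match.arg(method)
  if (all(raw$intensity == 0))
    stop("degenerate input: all-zero hologram frame", call. = FALSE)
  if (method == "reference_frame") {
    if (is.null(reference))
      stop("method 'reference_frame' requires a reference frame",
           call. = FALSE)
    ref <- if (is_hologram_frame(reference)) reference$intensity else reference
    if (!is.matrix(ref) || !identical(dim(ref), dim(raw$intensity)))
      stop("reference frame shape does not match the raw frame",
           call. = FALSE)
    floor_val <- 0.01 * mean(ref)
    if (floor_val <= 0)
      stop("degenerate input: all-zero reference frame", call. = FALSE)
    bg <- pmax(ref, floor_val)
  } else {
    bg <- switch(method,
                 frame_mean = mean(raw$intensity),
                 border_mean = border_mean(raw$intensity))
    if (bg <= 0) stop("degenerate input: zero background estimate",
                      call. = FALSE)
  }
  hologram_frame(raw$intensity / bg,
                 bit_depth = raw$bit_depth, normalized = TRUE,
                 background = bg, source_path = raw$source_path,
                 geometry = raw$geometry)
}

#' Initial sensor-plane wavefield of a hologram
#'
#' Forms the starting guess of the complex wavefield at the imaging plane as
#' the square root of the normalised hologram intensity, with zero phase:
#' the measured intensity fixes the amplitude and the unknown phase starts
#' flat.
#'
#' @param holo A normalised [hologram_frame()].
#' @return A [complex_field()] at `plane_offset = 0` (the sensor plane).
#' @export
initial_wavefield <- function(holo) {
  if (!is_hologram_frame(holo)) stop("holo must be a hologram_frame",
                                     call. = FALSE)
  if (!holo$normalized)
    stop("hologram must be normalised first (see normalize_hologram)",
         call. = FALSE)
  if (any(holo$intensity < 0))
    stop("intensity must be non-negative", call. = FALSE)
  complex_field(holo$geometry, sqrt(holo$intensity) + 0i, plane_offset = 0)
}
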