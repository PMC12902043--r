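#' Sensor grid and illumination geometry
#'
#' A `field_geometry` bundles the pixel grid and wavelength shared by every
#' optics operation: the sensor (or simulation) grid size, the pixel pitch and
#' the illumination wavelength. The defaults are the geometry of a board-level
#' 3840 x 2160 monochrome sensor with 2.0 um pixels illuminated by a 658 nm
#' laser diode, treated as a quasi-plane wave.
#'
#' Coordinates are pixel-centred, row-major, with the origin at the top-left
#' corner. Spatial frequencies are expressed in cycles/um on the standard
#' discrete-transform grid with spacing `1/(n * pitch)` per axis. A geometry
#' never resamples: sub-Nyquist fringes are allowed and left to the caller.
#'
#' @param n_x Number of pixel columns (>= 2).
#' @param n_y Number of pixel rows (>= 2).
#' @param pitch Pixel spacing in um (> 0). Default 2.0.
#' @param wavelength Illumination wavelength in um (> 0). Default 0.658.
#' @return An object of class `field_geometry`.
#' @examples
#' g <- field_geometry(256, 256)
#' g$wavelength
#' @export
field_geometry <- function(n_x, n_y, pitch = 2.0, wavelength = 0.658) {
  n_x <- as.integer(n_x)
  n_y <- as.integer(n_y)
  if (length(n_x) != 1L || length(n_y) != 1L || is.na(n_x) || is.na(n_y) ||
      n_x < 2L || n_y < 2L)
    stop("n_x and n_y must be single integers >= 2", call. = FALSE)
  if (!is.numeric(pitch) || length(pitch) != 1L || !is.finite(pitch) ||
      pitch <= 0)
    stop("pitch must be a single positive number (um)", call. = FALSE)
  if (!is.numeric(wavelength) || length(wavelength) != 1L ||
      !is.finite(wavelength) || wavelength <= 0)
    stop("wavelength must be a single positive number (um)", call. = FALSE)
  structure(
    list(n_x = n_x, n_y = n_y, pitch = as.numeric(pitch),
         wavelength = as.numeric(wavelength)),
    class = "field_geometry"
  )
}

#' @export
print.field_geometry <- function(x, ...) {
  cat(sprintf(
    "<field_geometry> %d x %d px, pitch %.3g um, wavelength %.4g um\n",
    x$n_x, x$n_y, x$pitch, x$wavelength))
  invisible(x)
}

is_field_geometry <- function(x) inherits(x, "field_geometry")

#' Complex wavefield on a sensor grid
#'
#' Wraps a complex-valued matrix of amplitudes together with its
#' [field_geometry()] and the axial coordinate of the plane it lives in
#' (`plane_offset`, in um relative to the sensor plane; negative values are on
#' the object side).
#'
#' @param geometry A [field_geometry()].
#' @param values Complex (or numeric, promoted) matrix of shape
#'   `(n_y, n_x)`; all entries must be finite.
#' @param plane_offset Axial plane coordinate in um relative to the sensor.
#' @return An object of class `complex_field`.
#' @examples
#' g <- field_geometry(8, 8)
#' f <- complex_field(g, matrix(1 + 0i, 8, 8))
#' @export
complex_field <- function(geometry, values, plane_offset = 0) {
  if (!is_field_geometry(geometry)) stop("geometry must be a field_geometry",
                                         call. = FALSE)
  if (!is.matrix(values))
    stop("values must be a matrix", call. = FALSE)
  if (is.numeric(values)) values <- values + 0i
  if (!is.complex(values))
    stop("values must be numeric or complex", call. = FALSE)
  if (nrow(values) != geometry$n_y || ncol(values) != geometry$n_x)
    stop(sprintf("values shape (%d, %d) does not match geometry (%d, %d)",
                 nrow(values), ncol(values), geometry$n_y, geometry$n_x),
         call. = FALSE)
  if (!all(is.finite(Re(values))) || !all(is.finite(Im(values))))
    stop("field values must all be finite", call. = FALSE)
  if (!is.numeric(plane_offset) || length(plane_offset) != 1L ||
      !is.finite(plane_offset))
    stop("plane_offset must be a single finite number (um)", call. = FALSE)
  structure(
    list(geometry = geometry, values = values,
         plane_offset = as.numeric(plane_offset)),
    class = "complex_field"
  )
}

#' @export
print.complex_field <- function(x, ...) {
  cat(sprintf(
    "<complex_field> %d x %d px at plane %+.1f um; max |U| = %.4g\n",
    x$geometry$n_y, x$geometry$n_x, x$plane_offset, max(Mod(x$values))))
  invisible(x)
}

is_complex_field <- function(x) inherits(x, "complex_field")

# Discrete-transform frequency axis in cycles/um: 0, 1, ..., -1 over n*d.
fft_freq <- function(n, d) {
  k <- c(seq.int(0L, floor((n - 1) / 2)), seq.int(-ceiling((n - 1) / 2), -1L))
  k / (n * d)
}

# Mean of the outer `width`-pixel frame of a matrix. The width shrinks on
# small matrices so an interior always remains; whole-matrix mean when none
# can.
border_mean <- function(m, width = 8L) {
  nr <- nrow(m); nc <- ncol(m)
  w <- min(width, (min(nr, nc) - 1L) %/% 2L)
  if (w < 1L) return(mean(m))
  inner <- m[(w + 1L):(nr - w), (w + 1L):(nc - w), drop = FALSE]
  (sum(m) - sum(inner)) / (length(m) - length(inner))
}
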