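#' Angular spectrum transfer function
#'
#' Builds the free-space transfer function of the angular spectrum method for
#' a signed propagation distance. The kernel at spatial frequency
#' `(f_x, f_y)` (cycles/um) is
#' \deqn{H(f_x, f_y) = \exp\left(i 2\pi d \sqrt{1/\lambda^2 - f_x^2 - f_y^2}\right)}
#' on the propagating band `f_x^2 + f_y^2 <= 1/lambda^2` and exactly 0 on the
#' evanescent band, which would otherwise blow up exponentially under
#' backpropagation. The exact square-root kernel is used rather than the
#' paraxial (Fresnel) approximation: at millimetre working distances over a
#' near-centimetre sensor the paraxial condition is not comfortably met.
#'
#' Sign convention: forward propagation (object to sensor, positive distance)
#' carries the `+i` exponent. `transfer(-d)` is the complex conjugate of
#' `transfer(d)`.
#'
#' @param geometry A [field_geometry()].
#' @param distance Signed propagation distance in um.
#' @return An object of class `transfer_function` with elements `geometry`,
#'   `distance` and `values` (complex matrix in standard discrete-transform
#'   frequency ordering, shape `(n_y, n_x)`).
#' @examples
#' tf <- make_transfer_function(field_geometry(64, 64), 500)
#' Mod(tf$values[1, 1])  # unit modulus on the propagating band
#' @export
make_transfer_function <- function(geometry, distance) {
  if (!is_field_geometry(geometry)) stop("geometry must be a field_geometry",
                                         call. = FALSE)
  if (!is.numeric(distance) || length(distance) != 1L || !is.finite(distance))
    stop("distance must be a single finite number (um)", call. = FALSE)
  fx <- fft_freq(geometry$n_x, geometry$pitch)
  fy <- fft_freq(geometry$n_y, geometry$pitch)
  f2 <- outer(fy^2, fx^2, `+`)
  kz2 <- 1 / geometry$wavelength^2 - f2
  values <- matrix(0 + 0i, geometry$n_y, geometry$n_x)
  band <- kz2 >= 0
  values[band] <- exp(2i * pi * distance * sqrt(kz2[band]))
  structure(
    list(geometry = geometry, distance = as.numeric(distance),
         values = values),
    class = "transfer_function"
  )
}

#' @export
print.transfer_function <- function(x, ...) {
  cat(sprintf(
    "<transfer_function> %d x %d px, distance %+.1f um, %.1f%% propagating\n",
    x$geometry$n_y, x$geometry$n_x, x$distance,
    100 * mean(Mod(x$values) > 0)))
  invisible(x)
}

#' Propagate a complex field by the angular spectrum method
#'
#' Transforms the field to frequency space, multiplies by
#' [make_transfer_function()] for the requested distance, and transforms
#' back. Before the transform the field is embedded centrally in a grid
#' enlarged `pad_factor`-fold per axis; the border is filled with the mean of
#' the field's outer 8-pixel frame, which for a normalised hologram is the
#' unit background (zero-padding a unit-background hologram would create a
#' spurious aperture edge). The result is cropped back to the input grid and
#' `plane_offset` advances by `distance`.
#'
#' @param field A [complex_field()].
#' @param distance Signed propagation distance in um.
#' @param pad_factor Integer >= 1 grid enlargement per axis (default 2).
#' @return A [complex_field()] at the new plane.
#' @seealso [backpropagate()]
#' @examples
#' g <- field_geometry(64, 64)
#' f <- complex_field(g, matrix(1 + 0i, 64, 64))
#' p <- propagate(f, 500)
#' p$plane_offset
#' @export
propagate <- function(field, distance, pad_factor = 2L) {
  if (!is_complex_field(field)) stop("field must be a complex_field",
                                     call. = FALSE)
  if (!is.numeric(distance) || length(distance) != 1L || !is.finite(distance))
    stop("distance must be a single finite number (um)", call. = FALSE)
  pad_factor <- as.integer(pad_factor)
  if (is.na(pad_factor) || pad_factor < 1L)
    stop("pad_factor must be an integer >= 1", call. = FALSE)

  g <- field$geometry
  v <- field$values
  if (pad_factor > 1L) {
    ny <- g$n_y * pad_factor
    nx <- g$n_x * pad_factor
    big <- matrix(border_mean(v), ny, nx)
    r0 <- (ny - g$n_y) %/% 2L
    c0 <- (nx - g$n_x) %/% 2L
    big[r0 + seq_len(g$n_y), c0 + seq_len(g$n_x)] <- v
    gg <- field_geometry(nx, ny, g$pitch, g$wavelength)
  } else {
    big <- v
    gg <- g
  }

  tf <- make_transfer_function(gg, distance)
  out <- stats::fft(stats::fft(big) * tf$values, inverse = TRUE) / length(big)
  if (pad_factor > 1L)
    out <- out[r0 + seq_len(g$n_y), c0 + seq_len(g$n_x)]
  complex_field(g, out, field$plane_offset + distance)
}

#' Backpropagate a field from the sensor towards the object plane
#'
#' Alias for [propagate()] with the sign of `distance` flipped, so that
#' reconstruction code reads in the direction of the physical workflow:
#' sensor plane back to object plane.
#'
#' @param field A [complex_field()].
#' @param distance Positive propagation distance in um.
#' @param pad_factor Integer >= 1 grid enlargement per axis (default 2).
#' @return A [complex_field()] at `plane_offset - distance`.
#' @export
backpropagate <- function(field, distance, pad_factor = 2L) {
  if (!is.numeric(distance) || length(distance) != 1L || !is.finite(distance))
    stop("distance must be a single finite number (um)", call. = FALSE)
  if (distance < 0)
    stop("backpropagate expects a positive distance; use propagate for signed",
         call. = FALSE)
  propagate(field, -distance, pad_factor)
}
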