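#' Settings for the iterative Gerchberg-Saxton reconstruction
#'
#' @param n_iterations Number of full back-and-forth iterations (default 200,
#'   which reaches convergence on pollen holograms; there is no tolerance
#'   based early exit — the iteration count is fixed).
#' @param clip_level Object-plane amplitude ceiling (default 1: a passive,
#'   non-amplifying object).
#' @param pad_factor Grid enlargement per axis for every transform
#'   (default 2).
#' @param background_method Background estimator passed to
#'   [normalize_hologram()] by pipeline drivers.
#' @param record_misfit Logical; record the per-iteration sensor-plane RMS
#'   amplitude residual (a diagnostic, not a stopping rule).
#' @return An object of class `gs_config`.
#' @export
gs_config <- function(n_iterations = 200L, clip_level = 1.0, pad_factor = 2L,
                      background_method = c("frame_mean", "border_mean",
                                            "reference_frame"),
                      record_misfit = TRUE) {
  n_iterations <- as.integer(n_iterations)
  if (is.na(n_iterations) || n_iterations < 0L)
    stop("n_iterations must be a non-negative integer", call. = FALSE)
  if (!is.numeric(clip_level) || length(clip_level) != 1L ||
      !is.finite(clip_level) || clip_level <= 0)
    stop("clip_level must be a single positive number", call. = FALSE)
  structure(
    list(n_iterations = n_iterations, clip_level = clip_level,
         pad_factor = as.integer(pad_factor),
         background_method = match.arg(background_method),
         record_misfit = isTRUE(record_misfit)),
    class = "gs_config"
  )
}

#' Reconstructed object transmission function
#'
#' Container for the recovered transmission amplitude (a brightfield-like
#' image), its phase, the refocus distance and the iteration diagnostics.
#'
#' @param amplitude Non-negative numeric matrix, the transmission amplitude.
#' @param phase Numeric matrix of phases in radians.
#' @param h Refocus distance in um.
#' @param iterations_run Number of iterations performed (0 for a single
#'   backpropagation).
#' @param misfit_trace Optional numeric vector of per-iteration sensor-plane
#'   RMS amplitude residuals.
#' @return An object of class `reconstruction_result`.
#' @export
reconstruction_result <- function(amplitude, phase, h, iterations_run,
                                  misfit_trace = NULL) {
  if (!is.matrix(amplitude) || !is.matrix(phase) ||
      !identical(dim(amplitude), dim(phase)))
    stop("amplitude and phase must be matrices of identical shape",
         call. = FALSE)
  if (!all(is.finite(amplitude)) || !all(is.finite(phase)))
    stop("amplitude and phase must be finite everywhere", call. = FALSE)
  structure(
    list(amplitude = amplitude, phase = phase, h = as.numeric(h),
         iterations_run = as.integer(iterations_run),
         misfit_trace = misfit_trace),
    class = "reconstruction_result"
  )
}

#' @export
print.reconstruction_result <- function(x, ...) {
  cat(sprintf(
    "<reconstruction_result> %d x %d px, h = %.1f um, %d iteration(s)\n",
    nrow(x$amplitude), ncol(x$amplitude), x$h, x$iterations_run))
  if (!is.null(x$misfit_trace) && length(x$misfit_trace))
    cat(sprintf("  sensor misfit: first %.4g, last %.4g\n",
                x$misfit_trace[1], x$misfit_trace[length(x$misfit_trace)]))
  invisible(x)
}

#' Object-plane constraint: passive transmission
#'
#' Enforces that the object cannot amplify light: at pixels where the
#' amplitude exceeds `clip_level` the value is replaced by
#' `clip_level + 0i`, i.e. the amplitude is clipped and the phase at those
#' pixels (and only those pixels) is reset to zero. All other pixels pass
#' through unchanged.
#'
#' @param field A [complex_field()] at the object plane.
#' @param clip_level Amplitude ceiling (default 1).
#' @return The constrained [complex_field()].
#' @export
apply_object_constraint <- function(field, clip_level = 1.0) {
  if (!is_complex_field(field)) stop("field must be a complex_field",
                                     call. = FALSE)
  v <- field$values
  over <- Mod(v) > clip_level
  if (any(over)) {
    v[over] <- clip_level + 0i
    field$values <- v
  }
  field
}

#' Sensor-plane constraint: measured amplitude replacement
#'
#' Replaces the amplitude of the propagated field with the measured one
#' (the square root of the normalised hologram) while keeping the retrieved
#' phase: `value <- measured * exp(i * arg(value))`. Pixels with exactly
#' zero amplitude have no defined phase and adopt phase 0, so the output
#' there is `measured + 0i`.
#'
#' @param field A [complex_field()] at the sensor plane.
#' @param measured_amplitude Non-negative numeric matrix matching the field
#'   shape.
#' @return The constrained [complex_field()]; `Mod(values)` equals
#'   `measured_amplitude` exactly.
#' @export
apply_sensor_constraint <- function(field, measured_amplitude) {
  if (!is_complex_field(field)) stop("field must be a complex_field",
                                     call. = FALSE)
  if (!is.matrix(measured_amplitude) ||
      !identical(dim(measured_amplitude), dim(field$values)))
    stop("measured_amplitude shape does not match the field", call. = FALSE)
  if (any(measured_amplitude < 0))
    stop("measured_amplitude must be non-negative", call. = FALSE)
  v <- field$values
  m <- Mod(v)
  zero <- m == 0
  phase_factor <- v / m
  phase_factor[zero] <- 1 + 0i
  field$values <- measured_amplitude * phase_factor
  field
}

# Propagation with the plane-wave carrier phase divided out, so retrieved
# phases are referenced to the illuminating wave: without this, an empty
# scene would reconstruct with the arbitrary global phase exp(-2 pi i h /
# lambda) and the zero-phase reset of the object constraint would lose its
# meaning.
propagate_relative <- function(field, distance, pad_factor) {
  out <- propagate(field, distance, pad_factor)
  out$values <- out$values *
    exp(-2i * pi * distance / field$geometry$wavelength)
  out
}

#' Single backpropagation of a hologram
#'
#' Backpropagates the initial sensor-plane wavefield (square root of the
#' normalised hologram, zero phase) to the object plane in one step. The
#' focused real image is recovered but remains superimposed with the
#' defocused twin image, visible as concentric rings around each grain; no
#' clipping is applied.
#'
#' @param holo A normalised [hologram_frame()].
#' @param h Positive refocus distance in um.
#' @param pad_factor Grid enlargement per axis (default 2).
#' @return A [reconstruction_result()] with `iterations_run = 0`.
#' @export
single_backpropagation <- function(holo, h, pad_factor = 2L) {
  if (!is.numeric(h) || length(h) != 1L || !is.finite(h) || h <= 0)
    stop("h must be a single positive distance (um)", call. = FALSE)
  f <- propagate_relative(initial_wavefield(holo), -h, pad_factor)
  reconstruction_result(Mod(f$values), Arg(f$values), h,
                        iterations_run = 0L)
}

#' Iterative Gerchberg-Saxton phase retrieval
#'
#' Runs the twin-image-suppressing phase-retrieval loop. Starting from the
#' initial wavefield `sqrt(H)` at the sensor, each iteration:
#' backpropagates by `h`, applies the object constraint
#' ([apply_object_constraint()]), propagates forward by `h`, and applies the
#' sensor constraint ([apply_sensor_constraint()]). When
#' `config$record_misfit` is set, the RMS of `|U| - sqrt(H)` at the sensor
#' is logged each iteration just before the sensor constraint. After the
#' fixed iteration count one final backpropagation plus object constraint
#' yields the transmission amplitude and phase; taking the output after the
#' constraint guarantees the amplitude never exceeds `clip_level`. All
#' retrieved phases (here and in [single_backpropagation()]) are referenced
#' to the illuminating plane wave, so a clear background sits at phase 0.
#'
#' With `n_iterations = 0` the result is exactly a single backpropagation
#' followed by one object constraint.
#'
#' @param holo A normalised [hologram_frame()].
#' @param h Positive refocus distance in um.
#' @param config A [gs_config()].
#' @return A [reconstruction_result()].
#' @examples
#' g <- field_geometry(64, 64)
#' holo <- hologram_frame(matrix(1, 64, 64), normalized = TRUE)
#' rec <- gs_reconstruct(holo, 2546, gs_config(n_iterations = 2))
#' range(rec$amplitude)
#' @export
gs_reconstruct <- function(holo, h, config = gs_config()) {
  if (!inherits(config, "gs_config")) stop("config must be a gs_config",
                                           call. = FALSE)
  if (!is.numeric(h) || length(h) != 1L || !is.finite(h) || h <= 0)
    stop("h must be a single positive distance (um)", call. = FALSE)
  u <- initial_wavefield(holo)
  measured <- Mod(u$values)
  misfit <- if (config$record_misfit && config$n_iterations > 0L)
    numeric(config$n_iterations) else NULL
  for (it in seq_len(config$n_iterations)) {
    obj <- apply_object_constraint(
      propagate_relative(u, -h, config$pad_factor), config$clip_level)
    u <- propagate_relative(obj, h, config$pad_factor)
    if (!is.null(misfit))
      misfit[it] <- sqrt(mean((Mod(u$values) - measured)^2))
    u <- apply_sensor_constraint(u, measured)
  }
  final <- apply_object_constraint(
    propagate_relative(u, -h, config$pad_factor), config$clip_level)
  reconstruction_result(Mod(final$values), Arg(final$values), h,
                        iterations_run = config$n_iterations,
                        misfit_trace = misfit)
}
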