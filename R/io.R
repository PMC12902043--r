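#' Read a raw hologram from a single-channel TIFF
#'
#' Reads a 16-bit-container TIFF holding 12-bit sensor counts (the storage
#' convention of the acquisition pipeline: counts stored directly in the
#' 16-bit words). Values above `2^bit_depth - 1` are rejected for raw
#' frames.
#'
#' @param path TIFF file path.
#' @param pitch Pixel pitch in um (default 2.0).
#' @param wavelength Illumination wavelength in um (default 0.658).
#' @param bit_depth Expected bit depth (default 12).
#' @return A raw [hologram_frame()] in sensor counts.
#' @export
read_hologram_tiff <- function(path, pitch = 2.0, wavelength = 0.658,
                               bit_depth = 12L) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  img <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] != 1L)
      stop("expected a single-channel TIFF: ", path, call. = FALSE)
    img <- img[, , 1]
  }
  counts <- round(img * 65535)
  if (max(counts) > 2^bit_depth - 1)
    stop(sprintf("frame exceeds %d-bit range (max count %d): %s",
                 bit_depth, max(counts), path), call. = FALSE)
  hologram_frame(counts, pitch = pitch, wavelength = wavelength,
                 bit_depth = bit_depth, source_path = path)
}

#' Write a raw hologram to a single-channel 16-bit TIFF
#'
#' Counts are stored directly in the 16-bit words (uncompressed,
#' little-endian), so a 12-bit frame occupies the range 0..4095.
#'
#' @param holo A raw [hologram_frame()].
#' @param path Output TIFF path.
#' @return The path, invisibly.
#' @export
write_hologram_tiff <- function(holo, path) {
  if (!is_hologram_frame(holo)) stop("holo must be a hologram_frame",
                                     call. = FALSE)
  if (holo$normalized)
    stop("write_hologram_tiff expects raw counts, not a normalised frame",
         call. = FALSE)
  tiff::writeTIFF(holo$intensity / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' Write a reconstruction amplitude as a 16-bit TIFF
#'
#' Linearly maps amplitudes so that `clip_level` lands on 65535; values
#' above `clip_level` (possible for an unclipped single backpropagation)
#' saturate.
#'
#' @param amplitude Non-negative numeric matrix.
#' @param path Output TIFF path.
#' @param clip_level Amplitude mapped to full scale (default 1).
#' @return The path, invisibly.
#' @export
write_amplitude_tiff <- function(amplitude, path, clip_level = 1.0) {
  scaled <- pmin(pmax(amplitude / clip_level, 0), 1)
  tiff::writeTIFF(scaled, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' Write an 8-bit PNG preview of an image matrix
#'
#' Rescales the matrix to its own [min, max] range (constant images map to
#' mid-grey) and writes an 8-bit greyscale PNG.
#'
#' @param image Numeric matrix.
#' @param path Output PNG path.
#' @return The path, invisibly.
#' @export
write_png_preview <- function(image, path) {
  rng <- range(image)
  scaled <- if (diff(rng) == 0) matrix(0.5, nrow(image), ncol(image))
            else (image - rng[1]) / diff(rng)
  png::writePNG(scaled, path)
  invisible(path)
}

#' Read evaluation records from CSV
#'
#' Validates the fixed schema (`image_id`, `modality`, `evaluator`,
#' `true_species`, `assigned_species`; header mandatory) and that all
#' species labels belong to the six-class vocabulary. Malformed rows are
#' listed in the error message.
#'
#' @param path CSV file path.
#' @return A data.frame of records.
#' @export
read_records_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_id", "modality", "evaluator", "true_species",
            "assigned_species")
  missing_cols <- setdiff(need, names(rec))
  if (length(missing_cols))
    stop("records CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  bad <- which(!(rec$true_species %in% pollen_classes()) |
               !(rec$assigned_species %in% pollen_classes()) |
               is.na(rec$image_id) | rec$image_id == "")
  if (length(bad))
    stop("malformed record row(s): ",
         paste(utils::head(bad, 20L), collapse = ", "), call. = FALSE)
  rec
}

#' Write evaluation records to CSV
#'
#' @param records A record data.frame in the standard schema.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_records_csv <- function(records, path) {
  check_records(records)
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}
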