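#' Default pipeline configuration
#'
#' The run configuration is a nested list with four blocks mirroring the
#' pipeline stages; the defaults echo the study conditions: 658 nm
#' illumination, 2.0 um pixel pitch, 200 Gerchberg-Saxton iterations, and
#' an autofocus scan over 2300-2800 um in 10 um steps. The default
#' simulation grid is 512 x 512 pixels (the full 3840 x 2160 sensor format
#' is supported but slow to iterate on).
#'
#' @return A nested configuration list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    geometry = list(n_x = 512L, n_y = 512L, pitch = 2.0,
                    wavelength = 0.658),
    reconstruction = list(n_iterations = 200L, clip_level = 1.0,
                          pad_factor = 2L,
                          background_method = "frame_mean",
                          record_misfit = TRUE,
                          h = NULL,
                          autofocus = list(h_min = 2300, h_max = 2800,
                                           step = 10, refine = FALSE)),
    simulation = list(n_grains = 3L, species = pollen_classes(),
                      h = 2546,
                      noise = list(photons_at_unit_intensity = 5000,
                                   read_noise_sd = 3, bit_depth = 12L),
                      seed = 1L),
    stats = list(accuracy_digits = 1L, f1_digits = 3L)
  ), class = "run_config")
}

merge_block <- function(defaults, user, path) {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config key(s) under '", path, "': ",
         paste(unknown, collapse = ", "), call. = FALSE)
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])))
      defaults[[k]] <- merge_block(defaults[[k]], user[[k]],
                                   paste0(path, "$", k))
    else defaults[[k]] <- user[[k]]
  }
  defaults
}

#' Load a pipeline configuration from YAML
#'
#' Reads a single YAML document, validates it against the known
#' configuration schema (unknown keys are rejected with their path), and
#' merges it over [default_run_config()].
#'
#' @param path YAML file path, or `NULL` for the pure defaults.
#' @return A `run_config` list.
#' @export
load_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  if (is.null(user)) return(cfg)
  structure(merge_block(unclass(cfg), user, "config"), class = "run_config")
}

config_geometry <- function(cfg) {
  g <- cfg$geometry
  field_geometry(g$n_x, g$n_y, g$pitch, g$wavelength)
}

config_gs <- function(cfg) {
  r <- cfg$reconstruction
  gs_config(n_iterations = r$n_iterations, clip_level = r$clip_level,
            pad_factor = r$pad_factor,
            background_method = r$background_method,
            record_misfit = r$record_misfit)
}
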