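#' The six pollen classes
#'
#' Ordered label vector of the six allergenic pollen taxa covered by the
#' package: timothy grass (*Phleum pratense*), common ragweed (*Ambrosia
#' artemisiifolia*), silver birch (*Betula pendula*), common alder (*Alnus
#' glutinosa*), olive tree (*Olea europaea*) and hazel (*Corylus avellana*).
#'
#' @return Character vector of length 6.
#' @export
pollen_classes <- function() {
  c("timothy_grass", "common_ragweed", "silver_birch",
    "common_alder", "olive_tree", "hazel")
}

#' Stylised morphology parameters per pollen species
#'
#' One row per species: the shape family of its silhouette, the grain
#' diameter distribution, the minimum transmission amplitude inside the
#' grain (`amplitude_contrast`), the maximum phase shift, and spike
#' parameters for the echinate (spiked) family. Silhouettes are stylised
#' renderings of the qualitative morphology used by human evaluators —
#' timothy grass as a smooth oval, ragweed as a round grain with prominent
#' spikes, hazel as a rounded triangle, birch as a more variable triangular
#' shape, alder as a rounded pentagon, and olive as a coffee-bean outline
#' with a central furrow. Diameters (20-40 um) are literature-typical
#' pollen scales, not measurements from any particular slide set.
#'
#' @return A data.frame with one row per species.
#' @export
pollen_species <- function() {
  data.frame(
    species = pollen_classes(),
    shape_family = c("oval_single_pore", "round_spiked",
                     "triangular_3pore_variant", "pentagonal_5pore",
                     "bean_furrowed", "triangular_3pore"),
    diameter_mean = c(34, 20, 24, 26, 22, 25),
    diameter_sd = c(2.5, 1.5, 2.0, 2.0, 1.5, 2.0),
    amplitude_contrast = c(0.30, 0.25, 0.30, 0.30, 0.25, 0.30),
    phase_shift_max = c(1.2, 1.0, 1.1, 1.1, 1.0, 1.1),
    spike_count = c(0, 12, 0, 0, 0, 0),
    spike_length = c(0, 3.0, 0, 0, 0, 0),
    stringsAsFactors = FALSE
  )
}

# Run code with a fixed seed without disturbing the caller's RNG state;
# seed = NULL runs the code on the ambient RNG stream.
with_seed_if <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}

# Silhouette boundary radius r_b(theta) in um for one grain.
boundary_radius <- function(theta, family, diameter, shape_jitter = 0) {
  R <- diameter / 2
  switch(family,
    oval_single_pore = {
      a <- R; b <- 0.75 * R
      a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
    },
    round_spiked = R,  # spikes are added separately
    triangular_3pore = R * (1 + 0.14 * cos(3 * theta)) / 1.14,
    triangular_3pore_variant = {
      e <- 0.06 + shape_jitter  # birch: variable triangularity
      R * (1 + e * cos(3 * theta)) / (1 + e)
    },
    pentagonal_5pore = R * (1 + 0.09 * cos(5 * theta)) / 1.09,
    bean_furrowed = {
      a <- R; b <- 0.62 * R
      a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
    },
    stop("unknown shape family: ", family, call. = FALSE)
  )
}

# Rasterise one grain into the running transmission/mask matrices.
# Returns list(transmission, mask) updated in the grain's bounding box.
rasterise_grain <- function(trans, mask, geometry, species_row, cx, cy,
                            diameter, rotation, shape_jitter, edge_width = 2) {
  pitch <- geometry$pitch
  reach <- diameter / 2 + species_row$spike_length + edge_width + 2 * pitch
  cmin <- max(1L, floor((cx - reach) / pitch))
  cmax <- min(geometry$n_x, ceiling((cx + reach) / pitch))
  rmin <- max(1L, floor((cy - reach) / pitch))
  rmax <- min(geometry$n_y, ceiling((cy + reach) / pitch))
  cols <- cmin:cmax; rows <- rmin:rmax
  xs <- (cols - 0.5) * pitch - cx
  ys <- (rows - 0.5) * pitch - cy
  dx <- matrix(xs, length(rows), length(cols), byrow = TRUE)
  dy <- matrix(ys, length(rows), length(cols))
  u <- dx * cos(rotation) + dy * sin(rotation)
  v <- -dx * sin(rotation) + dy * cos(rotation)
  r <- sqrt(u^2 + v^2)
  theta <- atan2(v, u)
  rb <- boundary_radius(theta, species_row$shape_family, diameter,
                        shape_jitter)
  if (species_row$spike_count > 0) {
    # echinate surface: short radial spikes protruding beyond the round body
    bump <- pmax(cos(species_row$spike_count * theta), 0)^12
    rb <- rb + species_row$spike_length * bump
  }
  profile <- pmin(1, pmax(0, (rb - r) / edge_width))
  # optical path follows the chord thickness of the roughly dome-shaped
  # grain, so absorption and phase peak at the centre and fall to zero at
  # the rim (a flat-top profile would act as an annular axicon)
  thickness <- sqrt(pmax(0, 1 - (r / pmax(rb, 1e-9))^2)) * (profile > 0)
  amp <- 1 - (1 - species_row$amplitude_contrast) * thickness
  if (species_row$shape_family == "bean_furrowed") {
    furrow <- 0.3 * exp(-(v / (0.08 * diameter))^2) * (profile > 0.5)
    amp <- pmax(amp - furrow, 0.1)
  }
  phase <- species_row$phase_shift_max * thickness
  sub <- amp * exp(1i * phase)
  inside <- profile > 0
  t_block <- trans[rows, cols]
  t_block[inside] <- sub[inside]
  trans[rows, cols] <- t_block
  m_block <- mask[rows, cols]
  m_block[inside] <- TRUE
  mask[rows, cols] <- m_block
  list(trans = trans, mask = mask)
}

#' Render a pollen phantom scene
#'
#' Places `n_grains` non-overlapping stylised pollen grains at random
#' positions and orientations in the field of view and rasterises their
#' complex transmission function at the object plane. The transmission
#' amplitude ramps from 1 (clear background) down to the species'
#' `amplitude_contrast` inside the grain over a ~2 um edge, and the phase
#' rises to `phase_shift_max` on the same profile. Every scene satisfies
#' `max |T| <= 1` (a passive object, the working assumption of the
#' object-plane constraint). Generation is deterministic for a fixed seed.
#'
#' @param geometry A [field_geometry()] for the object plane grid.
#' @param n_grains Number of grains to place (>= 0).
#' @param species Character vector of species to draw from (default all
#'   six); recycled sampling with replacement.
#' @param seed Optional integer seed; the caller's RNG state is preserved.
#' @param max_retries Placement attempts per grain before a placement error
#'   is raised (default 100).
#' @return An object of class `scene_phantom`: `geometry`, `grains`
#'   (data.frame of species, centre, diameter, rotation), `transmission`
#'   (a [complex_field()]) and `truth_mask` (logical matrix).
#' @examples
#' sc <- render_phantom(field_geometry(128, 128), 2, seed = 7)
#' sum(sc$truth_mask)
#' @export
render_phantom <- function(geometry, n_grains, species = pollen_classes(),
                           seed = NULL, max_retries = 100L) {
  if (!is_field_geometry(geometry)) stop("geometry must be a field_geometry",
                                         call. = FALSE)
  n_grains <- as.integer(n_grains)
  if (is.na(n_grains) || n_grains < 0L)
    stop("n_grains must be a non-negative integer", call. = FALSE)
  tab <- pollen_species()
  unknown <- setdiff(species, tab$species)
  if (length(unknown))
    stop("unknown species: ", paste(unknown, collapse = ", "), call. = FALSE)

  with_seed_if(seed, {
    width <- geometry$n_x * geometry$pitch
    height <- geometry$n_y * geometry$pitch
    trans <- matrix(1 + 0i, geometry$n_y, geometry$n_x)
    mask <- matrix(FALSE, geometry$n_y, geometry$n_x)
    grains <- data.frame(species = character(0), x = numeric(0),
                         y = numeric(0), diameter = numeric(0),
                         rotation = numeric(0))
    for (k in seq_len(n_grains)) {
      sp <- sample(species, 1L)
      row <- tab[tab$species == sp, ]
      d <- max(row$diameter_mean / 2,
               stats::rnorm(1, row$diameter_mean, row$diameter_sd))
      reach <- d / 2 + row$spike_length
      margin <- reach + 4
      if (2 * margin >= width || 2 * margin >= height)
        stop("placement error: field of view too small for grain size",
             call. = FALSE)
      placed <- FALSE
      for (try in seq_len(max_retries)) {
        cx <- stats::runif(1, margin, width - margin)
        cy <- stats::runif(1, margin, height - margin)
        if (nrow(grains) == 0L ||
            all(sqrt((grains$x - cx)^2 + (grains$y - cy)^2) >
                (grains$diameter + d) / 2 + row$spike_length + 6)) {
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop(sprintf(
          "placement error: could not place grain %d without overlap after %d retries",
          k, max_retries), call. = FALSE)
      rot <- stats::runif(1, 0, 2 * pi)
      jitter <- stats::runif(1, 0, 0.10)  # birch shape variability
      out <- rasterise_grain(trans, mask, geometry, row, cx, cy, d, rot,
                             jitter)
      trans <- out$trans
      mask <- out$mask
      grains <- rbind(grains,
                      data.frame(species = sp, x = cx, y = cy, diameter = d,
                                 rotation = rot))
    }
    structure(
      list(geometry = geometry, grains = grains,
           transmission = complex_field(geometry, trans, plane_offset = 0),
           truth_mask = mask),
      class = "scene_phantom"
    )
  })
}

#' @export
print.scene_phantom <- function(x, ...) {
  cat(sprintf("<scene_phantom> %d x %d px, %d grain(s): %s\n",
              x$geometry$n_y, x$geometry$n_x, nrow(x$grains),
              paste(x$grains$species, collapse = ", ")))
  invisible(x)
}
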