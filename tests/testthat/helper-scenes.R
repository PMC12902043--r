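# Shared fixtures, all generated in code.

# Centred Gaussian amplitude spot (1/e radius w0 um) on a zero background.
gaussian_field <- function(n, w0, pitch = 2.0, wavelength = 0.658) {
  g <- field_geometry(n, n, pitch, wavelength)
  xs <- (seq_len(n) - n / 2 - 0.5) * pitch
  v <- matrix(exp(-outer(xs^2, xs^2, `+`) / w0^2), n, n) + 0i
  complex_field(g, v)
}

# Uniform normalised hologram (empty scene).
uniform_hologram <- function(n = 64) {
  hologram_frame(matrix(1, n, n), normalized = TRUE)
}

# Render a seeded phantom, simulate its noiseless hologram and normalise.
scene_and_hologram <- function(seed, n = 128, n_grains = 2, h = 2546,
                               amplitude_only = FALSE) {
  sc <- render_phantom(field_geometry(n, n), n_grains, seed = seed)
  if (amplitude_only)
    sc$transmission$values <- Mod(sc$transmission$values) + 0i
  holo <- simulate_hologram(sc, h, noise_model(0))
  list(scene = sc, holo = normalize_hologram(holo),
       truth = Mod(sc$transmission$values))
}

rmse <- function(a, b) sqrt(mean((a - b)^2))

# Identity-confusion study spec (every assignment correct).
identity_study_spec <- function(...) {
  cls <- pollen_classes()
  id <- diag(6)
  dimnames(id) <- list(cls, cls)
  evaluation_study_spec(confusion_probs = list(DIHM = id, optical = id), ...)
}
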