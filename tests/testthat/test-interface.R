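test_that("configuration defaults echo the acquisition conditions", {
  cfg <- load_run_config(NULL)
  expect_equal(cfg$geometry$wavelength, 0.658)
  expect_equal(cfg$geometry$pitch, 2.0)
  expect_equal(cfg$reconstruction$n_iterations, 200L)
  expect_equal(cfg$reconstruction$autofocus$h_min, 2300)
  expect_equal(cfg$reconstruction$autofocus$h_max, 2800)
  expect_equal(cfg$reconstruction$autofocus$step, 10)
})

test_that("YAML configs merge over defaults and unknown keys are rejected", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("geometry:", "  n_x: 64", "  n_y: 48",
               "reconstruction:", "  n_iterations: 5"), path)
  cfg <- load_run_config(path)
  expect_equal(cfg$geometry$n_x, 64L)
  expect_equal(cfg$geometry$n_y, 48L)
  expect_equal(cfg$reconstruction$n_iterations, 5L)
  expect_equal(cfg$geometry$wavelength, 0.658)  # untouched default

  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("geometry:", "  n_z: 3"), bad)
  expect_error(load_run_config(bad), "n_z")
  expect_error(load_run_config("no/such/file.yaml"), "no such")
})

test_that("holograms round-trip through 16-bit TIFF exactly", {
  dir <- withr::local_tempdir()
  sc <- render_phantom(field_geometry(64, 64), 1, seed = 2)
  holo <- simulate_hologram(sc, 2546, noise_model(0))
  path <- file.path(dir, "h.tiff")
  write_hologram_tiff(holo, path)
  back <- read_hologram_tiff(path)
  expect_identical(back$intensity, holo$intensity)
  expect_equal(back$bit_depth, 12L)

  # a frame exceeding the 12-bit range is rejected on read
  big <- file.path(dir, "big.tiff")
  tiff::writeTIFF(matrix(5000 / 65535, 8, 8), big, bits.per.sample = 16L)
  expect_error(read_hologram_tiff(big), "12-bit")
  expect_error(read_hologram_tiff(file.path(dir, "none.tiff")), "no such")
})

test_that("record CSVs validate their schema on read", {
  dir <- withr::local_tempdir()
  rec <- pollen_study_records()
  path <- file.path(dir, "records.csv")
  write_records_csv(rec, path)
  back <- read_records_csv(path)
  expect_equal(back, rec)

  broken <- rec[, setdiff(names(rec), "true_species")]
  p2 <- file.path(dir, "broken.csv")
  utils::write.csv(broken, p2, row.names = FALSE)
  expect_error(read_records_csv(p2), "true_species")

  rec2 <- rec
  rec2$assigned_species[3] <- "dandelion"
  p3 <- file.path(dir, "badlabel.csv")
  utils::write.csv(rec2, p3, row.names = FALSE)
  expect_error(read_records_csv(p3), "malformed")
})

small_config <- function(n = 64, n_grains = 1, iters = 2, h = 1200) {
  cfg <- default_run_config()
  cfg$geometry$n_x <- n
  cfg$geometry$n_y <- n
  cfg$simulation$n_grains <- n_grains
  cfg$simulation$h <- h
  cfg$simulation$noise$photons_at_unit_intensity <- 0
  cfg$reconstruction$n_iterations <- iters
  cfg$reconstruction$h <- h
  cfg
}

test_that("cli_simulate writes reproducible holograms and a manifest", {
  cfg <- small_config()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  cli_simulate(cfg, d1)
  cli_simulate(cfg, d2)
  expect_identical(unname(tools::md5sum(file.path(d1, "hologram.tiff"))),
                   unname(tools::md5sum(file.path(d2, "hologram.tiff"))))
  manifest <- jsonlite::read_json(file.path(d1, "manifest.json"))
  expect_equal(manifest$n_grains, cfg$simulation$n_grains)
  expect_equal(length(manifest$grains), cfg$simulation$n_grains)
  expect_true(file.exists(file.path(d1, "config_echo.yaml")))

  # an object-free run normalises to a flat unit field
  cfg0 <- small_config(n_grains = 0)
  d3 <- withr::local_tempdir()
  cli_simulate(cfg0, d3)
  holo <- read_hologram_tiff(file.path(d3, "hologram.tiff"))
  nh <- normalize_hologram(holo)
  expect_lt(max(abs(nh$intensity - 1)), 0.01)
})

test_that("cli_reconstruct ties the pipeline together", {
  cfg <- small_config(iters = 0)
  sim_dir <- withr::local_tempdir()
  out_dir <- withr::local_tempdir()
  cli_simulate(cfg, sim_dir)
  res <- cli_reconstruct(file.path(sim_dir, "hologram.tiff"), cfg, out_dir)

  # zero iterations: iterative output equals the clipped backpropagation
  expect_identical(res$gs$amplitude, pmin(res$backprop$amplitude, 1))
  expect_true(all(file.exists(unlist(res$paths))))
  # written amplitude never exceeds the mapped clip level
  written <- tiff::readTIFF(res$paths$amplitude) * 65535
  expect_lte(max(written), 65535)

  # the CLI autofocus path picks the same distance as the library call
  cfg_af <- small_config(n = 96, iters = 1, h = 1200)
  cfg_af$reconstruction$h <- NULL
  cfg_af$reconstruction$autofocus <- list(h_min = 1100, h_max = 1300,
                                          step = 20, refine = FALSE)
  sim2 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  cli_simulate(cfg_af, sim2)
  res2 <- cli_reconstruct(file.path(sim2, "hologram.tiff"), cfg_af, out2)
  holo <- normalize_hologram(read_hologram_tiff(file.path(sim2,
                                                          "hologram.tiff")))
  direct <- autofocus(holo, 1100, 1300, 20)
  expect_equal(res2$h, direct$best_h)
})

test_that("cli_stats summarises a records CSV", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "records.csv")
  write_records_csv(pollen_study_records(), path)
  out <- withr::local_tempdir()
  res <- cli_stats(path, out)
  s <- res$summary
  expect_equal(s$value[s$metric == "pooled_accuracy" &
                       s$modality == "DIHM"], 95.8)
  expect_true(file.exists(file.path(out, "study_summary.csv")))
  expect_true(file.exists(file.path(out, "confusion_DIHM.png")))
  expect_true(file.exists(file.path(out, "per_class_f1.csv")))

  # identity records: an all-100 summary
  p2 <- file.path(dir, "ident.csv")
  write_records_csv(generate_study_records(identity_study_spec()), p2)
  res2 <- cli_stats(p2, withr::local_tempdir())
  acc <- res2$summary$value[grepl("accuracy", res2$summary$metric)]
  expect_true(all(acc == 100.0))

  # a schema violation names the missing column
  broken <- pollen_study_records()
  broken$modality <- NULL
  p3 <- file.path(dir, "broken.csv")
  utils::write.csv(broken, p3, row.names = FALSE)
  expect_error(cli_stats(p3, withr::local_tempdir()), "modality")
})
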