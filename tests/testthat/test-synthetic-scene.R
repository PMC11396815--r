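test_that("scene_config validates fields and names the offender", {
  expect_s3_class(scene_config(), "scene_config")
  expect_error(scene_config(n_plots = 2), "n_plots")
  expect_error(scene_config(raster_size = 4), "raster_size")
  expect_error(scene_config(soil_fraction = 1), "soil_fraction")
  expect_error(scene_config(layer_correlation = 0), "layer_correlation")
  expect_error(scene_config(noise_sd_thermal = -1), "noise_sd_thermal")
  expect_error(scene_config(smc_range_by_layer =
                              list(c(0.2, 0.1), c(0.1, 0.2), c(0.1, 0.2))),
               "smc_range_by_layer")
})

test_that("generate_experiment is bit-reproducible and leaves RNG state alone", {
  cfg <- small_config(seed = 42)
  set.seed(7); before <- runif(3)
  set.seed(7)
  e1 <- generate_experiment(cfg)
  after <- runif(3)
  e2 <- generate_experiment(cfg)
  expect_identical(e1$truth, e2$truth)
  expect_identical(e1$scenes[[3]]$reflectance, e2$scenes[[3]]$reflectance)
  expect_identical(e1$scenes[[3]]$thermal, e2$scenes[[3]]$thermal)
  expect_identical(before, after)  # generator restores the caller's RNG
  e3 <- generate_experiment(small_config(seed = 43))
  expect_false(identical(e1$truth$smc_0_20, e3$truth$smc_0_20))
})

test_that("experiment structure matches the config", {
  cfg <- small_config(seed = 1)
  e <- generate_experiment(cfg)
  expect_length(e$scenes, cfg$n_plots)
  expect_equal(nrow(e$truth), cfg$n_plots)
  expect_equal(e$truth$plot_id, sprintf("P%03d", 1:cfg$n_plots))
  sc <- e$scenes[[1]]
  expect_equal(dim(sc$reflectance), c(16, 16, 6))
  expect_true(all(sc$reflectance >= 0 & sc$reflectance <= 1))
  expect_true(all(sc$canopy_mask + sc$soil_mask == 1))  # disjoint, covering
  for (col in c("smc_0_20", "smc_20_40", "smc_40_60"))
    expect_true(all(e$truth[[col]] > 0 & e$truth[[col]] < 1))
  expect_equal(nrow(e$calibration), cfg$n_calibration_points)
  expect_setequal(unique(e$calibration$kind), c("leaf", "water"))
})

test_that("noiseless couplings are exact: r(SMC, NIR) = 1, r(SMC, T) = -1", {
  # soil_fraction = 0: with no mask restriction the exactly mean-centred
  # structure/texture fields drop out of the canopy means entirely
  cfg <- scene_config(n_plots = 24, raster_size = 16,
                      noise_sd_reflectance = 0, noise_sd_thermal = 0,
                      texture_amplitude_sd = 0, calibration_noise_sd = 0,
                      soil_fraction = 0, seed = 5)
  e <- generate_experiment(cfg)
  nir <- vapply(e$scenes, function(s) mean(s$reflectance[, , 5][s$canopy_mask]),
                numeric(1))
  tc <- vapply(e$scenes, function(s) {
    mean((cfg$thermal_gain * s$thermal + cfg$thermal_offset)[s$canopy_mask])
  }, numeric(1))
  expect_equal(cor(e$truth$smc_0_20, nir), 1, tolerance = 1e-9)
  expect_equal(cor(e$truth$smc_0_20, tc), -1, tolerance = 1e-9)
})

test_that("planted signal weakens with depth (50-seed property)", {
  worse <- vapply(1:50, function(s) {
    cfg <- scene_config(n_plots = 48, raster_size = 8, seed = s)
    e <- generate_experiment(cfg)
    r12 <- abs(cor(e$truth$smc_0_20, e$truth$smc_20_40))
    r13 <- abs(cor(e$truth$smc_0_20, e$truth$smc_40_60))
    r12 > r13
  }, logical(1))
  expect_gte(mean(worse), 0.9)
})

test_that("write/read round-trip preserves the experiment at float32 precision", {
  dir <- tempfile("exp")
  on.exit(unlink(dir, recursive = TRUE))
  e <- generate_experiment(small_config(seed = 9))
  man <- write_experiment(e, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  expect_equal(man$n_plots, 12)
  # 2 TIFFs per plot + ground truth + calibration
  expect_length(man$files, 2 * 12 + 2)
  expect_true(all(file.exists(file.path(dir, man$files))))
  e2 <- read_experiment(dir)
  expect_equal(e2$truth$smc_0_20, e$truth$smc_0_20, tolerance = 1e-12)
  expect_equal(e2$scenes[[4]]$reflectance, e$scenes[[4]]$reflectance,
               tolerance = 1e-6)
  expect_equal(e2$scenes[[4]]$thermal, e$scenes[[4]]$thermal,
               tolerance = 1e-4)  # float32 over a 150 degC span
  expect_equal(e2$calibration$reference_temperature,
               e$calibration$reference_temperature, tolerance = 1e-12)
})
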