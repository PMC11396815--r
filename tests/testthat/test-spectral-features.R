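refl_example <- c(blue = 0.05, green = 0.12, red = 0.1, rededge = 0.25,
                  nir800 = 0.5, nir900 = 0.48)

test_that("hand-checked vegetation index values", {
  expect_equal(compute_vi("NDVI", refl_example), (0.5 - 0.1) / (0.5 + 0.1))
  expect_equal(compute_vi("SAVI", refl_example), 1.5 * 0.4 / 1.1)
  expect_equal(compute_vi("DVI", refl_example), 0.4)
  expect_equal(compute_vi("RVI", refl_example), 5)
  expect_equal(compute_vi("GCVI", refl_example), 0.5 / 0.12 - 1)
  expect_equal(compute_vi("GNDVI", refl_example), (0.5 - 0.12) / (0.5 + 0.12))
  expect_equal(compute_vi("NDRE", refl_example), 0.25 / 0.75)
  expect_equal(compute_vi("OSAVI", refl_example),
               1.16 * (0.5 - 0.12) / (0.5 + 0.12 + 0.16))
  expect_equal(compute_vi("RDVI", refl_example), 0.4 / sqrt(0.6))
  expect_equal(compute_vi("MSR", refl_example), 4 / (sqrt(5) + 1))
  expect_equal(compute_vi("NLI", refl_example), (0.25 - 0.25) / (0.25 + 0.25))
  expect_equal(compute_vi("TVI", refl_example), 60 * 0.38 - 100 * (-0.02))
  expect_equal(compute_vi("MTVI", refl_example),
               1.2 * (1.2 * 0.38 - 2.5 * 0.13))
  expect_equal(compute_vi("MSAVI", refl_example),
               (2 * 0.5 + 1 - sqrt((2 * 0.5 + 1)^2 - 8 * 0.4)) / 2)
  expect_equal(compute_vi("EVI", refl_example),
               2.5 * 0.4 / (0.5 + 0.6 - 7.5 * 0.05 + 1))
})

test_that("index identities: equal bands give zero where expected", {
  r <- refl_example
  r[["nir800"]] <- r[["red"]]
  expect_equal(compute_vi("NDVI", r), 0)
  expect_equal(compute_vi("DVI", r), 0)
  expect_equal(compute_vi("MSR", r), 0)
  r2 <- refl_example
  r2[["nir800"]] <- r2[["green"]]
  expect_equal(compute_vi("GNDVI", r2), 0)
  expect_equal(compute_vi("GCVI", r2), 0)
})

test_that("the 900 nm band substitutes for RNIR on request", {
  v8 <- compute_vi("NDVI", refl_example, nir_band = 800)
  v9 <- compute_vi("NDVI", refl_example, nir_band = 900)
  expect_equal(v9, (0.48 - 0.1) / (0.48 + 0.1))
  expect_false(isTRUE(all.equal(v8, v9)))
})

test_that("zero denominators raise undefined-value errors", {
  r <- refl_example
  r[["red"]] <- 0; r[["nir800"]] <- 0
  expect_error(compute_vi("NDVI", r), "undefined-value")
  expect_error(compute_vi("RVI", r), "undefined-value")
  r2 <- refl_example; r2[["green"]] <- 0
  expect_error(compute_vi("GCVI", r2), "undefined-value")
})

test_that("compute_vi_table returns plots x 15 with NA where undefined", {
  tab <- rbind(refl_example, refl_example)
  tab[2, c("red", "nir800")] <- 0
  out <- compute_vi_table(as.data.frame(tab))
  expect_equal(dim(out), c(2, 15))
  expect_equal(colnames(out), VI_CATALOG)
  expect_true(is.na(out[2, "NDVI"]))
  expect_false(anyNA(out[1, ]))
})

test_that("canopy mask thresholds per-pixel NDVI and counts pixels", {
  e <- generate_experiment(small_config(seed = 3))
  sc <- e$scenes[[1]]
  m <- canopy_mask(sc, vi_threshold = 0.3)
  red <- sc$reflectance[, , 3]; nir <- sc$reflectance[, , 5]
  ndvi <- (nir - red) / (nir + red)
  expect_identical(unclass(m)[1:16, 1:16], ndvi > 0.3)
  expect_equal(attr(m, "count"), sum(m))
  # generator soil strips have low NDVI, canopy high: the NDVI mask agrees
  # with the generator layout except where pixel noise crosses the threshold
  expect_gt(mean(m == sc$canopy_mask), 0.95)
  soil_cols <- which(!sc$canopy_mask[1, ])
  expect_lt(mean(m[, soil_cols]), 0.05)
  expect_error(canopy_mask(sc, vi_threshold = 0.999), "masking error")
})

test_that("plot_reflectance averages masked pixels per band", {
  e <- generate_experiment(small_config(seed = 3))
  sc <- e$scenes[[2]]
  m <- canopy_mask(sc)
  v <- plot_reflectance(sc, m)
  expect_named(v, c("blue", "green", "red", "rededge", "nir800", "nir900"))
  expect_equal(v[["nir800"]], mean(sc$reflectance[, , 5][m]))
})

test_that("select_nir_band picks the stronger band, ties to 800", {
  set.seed(11)
  smc <- runif(30, 0.1, 0.25)
  base <- matrix(rnorm(30 * 15), 30, 15, dimnames = list(NULL, VI_CATALOG))
  vi800 <- base; vi900 <- base
  vi800[, "NDVI"] <- smc + rnorm(30, 0, 0.01)    # strong at 800
  vi900[, "NDVI"] <- rnorm(30)
  vi900[, "SAVI"] <- -smc + rnorm(30, 0, 0.01)   # strong at 900
  vi800[, "SAVI"] <- rnorm(30)
  vi900[, "DVI"] <- vi800[, "DVI"]               # exact tie
  sel <- select_nir_band(vi800, vi900, smc)
  expect_equal(sel[["NDVI"]], 800L)
  expect_equal(sel[["SAVI"]], 900L)
  expect_equal(sel[["DVI"]], 800L)
  vi800[, "EVI"] <- 1                            # degenerate at 800
  expect_warning(sel2 <- select_nir_band(vi800, vi900, smc), "degenerate")
  expect_equal(sel2[["EVI"]], 900L)
  vi900[, "EVI"] <- 2                            # degenerate at both
  expect_warning(sel3 <- select_nir_band(vi800, vi900, smc), "excluded")
  expect_true(is.na(sel3[["EVI"]]))
})
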