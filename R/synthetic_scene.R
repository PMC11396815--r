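# Canopy and soil spectral profiles used by the generator. Bases are typical
# flowering-canopy reflectances at the six MS600 wavelengths; the coupling
# weight scales how strongly each band responds to 0-20 cm SMC relative to
# the 800 nm band (red reflectance falls as moisture/vigor rise, NIR rises).
BAND_WAVELENGTHS <- c(490, 555, 680, 720, 800, 900)
CANOPY_BASE  <- c(`490` = 0.05, `555` = 0.12, `680` = 0.08,
                  `720` = 0.25, `800` = 0.35, `900` = 0.33)
BAND_COUPLING_WEIGHT <- c(`490` = 0.0, `555` = 0.2, `680` = -0.3,
                          `720` = 0.5, `800` = 1.0, `900` = 0.9)
SOIL_BASE <- c(`490` = 0.08, `555` = 0.15, `680` = 0.25,
               `720` = 0.28, `800` = 0.30, `900` = 0.31)

#' Configuration for a synthetic plot experiment
#'
#' Defines the study conditions emulated by [generate_experiment()]: a field
#' of `n_plots` plots under 16 mulching/nitrogen treatment labels, each plot
#' observed as a six-band reflectance raster and a thermal raster, with
#' ground-truth SMC in three depth layers (0-20, 20-40, 40-60 cm).
#'
#' The planted statistical structure is linear-in-SMC with additive Gaussian
#' noise: NIR reflectance rises with surface SMC, canopy temperature falls
#' with it, and within-canopy high-frequency heterogeneity (the carrier of
#' GLCM texture signal) falls with it. Deeper layers are noisier copies of
#' the surface layer, so planted signal weakens with depth.
#'
#' @param n_plots number of plots (>= 6); the field campaign emulated has 96
#' @param raster_size pixels per raster side (>= 8)
#' @param bands the six band centre wavelengths in nm
#' @param smc_range_by_layer list of length-2 min/max SMC fractions for the
#'   three depth layers; defaults span wilting point to field capacity of a
#'   loess soil (about 0.09-0.25 by mass)
#' @param layer_correlation correlation in (0,1] linking each layer's SMC to
#'   the layer above it
#' @param noise_sd_reflectance reflectance-unit noise, applied both as a
#'   per-plot offset and as per-pixel sensor noise (scaled per band)
#' @param noise_sd_thermal thermal noise in degrees C, applied as a per-plot
#'   offset and as per-pixel sensor noise
#' @param texture_amplitude_sd per-plot noise on the high-frequency texture
#'   amplitude (reflectance units)
#' @param structure_amplitude amplitude of the smooth (low-frequency) canopy
#'   structure field, constant across plots
#' @param soil_fraction fraction of pixels that are soil background, laid out
#'   as inter-row strips; in [0, 1)
#' @param air_temperature ambient air temperature in degrees C
#' @param coupling_strengths list with elements `reflectance` (d reflectance /
#'   d SMC at 800 nm), `temperature` (d degC / d SMC, negative), and `texture`
#'   (d heterogeneity amplitude / d SMC, negative)
#' @param thermal_gain,thermal_offset the linear map from raw sensor values to
#'   true temperature (`true = gain * raw + offset`); the generator emits raw
#'   rasters plus calibration points so the calibration stage is exercised
#' @param n_calibration_points number of leaf/water reference points
#' @param calibration_noise_sd degC noise on calibration image temperatures
#' @param treatment_effect additive SMC offset per treatment (recycled over
#'   the 16 treatment labels); 0 disables treatment effects
#' @param seed integer seed; the generator is bit-reproducible given the seed
#' @return validated object of class `scene_config`
#' @export
scene_config <- function(n_plots = 96,
                         raster_size = 64,
                         bands = BAND_WAVELENGTHS,
                         smc_range_by_layer = list(c(0.09, 0.25),
                                                   c(0.09, 0.25),
                                                   c(0.09, 0.25)),
                         layer_correlation = 0.8,
                         noise_sd_reflectance = 0.045,
                         noise_sd_thermal = 2.0,
                         texture_amplitude_sd = 0.008,
                         structure_amplitude = 0.05,
                         soil_fraction = 0.2,
                         air_temperature = 30,
                         coupling_strengths = list(reflectance = 0.5,
                                                   temperature = -40,
                                                   texture = -0.15),
                         thermal_gain = 1.05,
                         thermal_offset = -1.5,
                         n_calibration_points = 12,
                         calibration_noise_sd = 0.15,
                         treatment_effect = 0,
                         seed = 1L) {
  cfg <- list(n_plots = as.integer(n_plots), raster_size = as.integer(raster_size),
              bands = bands, smc_range_by_layer = smc_range_by_layer,
              layer_correlation = layer_correlation,
              noise_sd_reflectance = noise_sd_reflectance,
              noise_sd_thermal = noise_sd_thermal,
              texture_amplitude_sd = texture_amplitude_sd,
              structure_amplitude = structure_amplitude,
              soil_fraction = soil_fraction,
              air_temperature = air_temperature,
              coupling_strengths = coupling_strengths,
              thermal_gain = thermal_gain, thermal_offset = thermal_offset,
              n_calibration_points = as.integer(n_calibration_points),
              calibration_noise_sd = calibration_noise_sd,
              treatment_effect = treatment_effect,
              seed = as.integer(seed))
  class(cfg) <- "scene_config"
  validate_scene_config(cfg)
  cfg
}

validate_scene_config <- function(cfg) {
  if (!is.numeric(cfg$n_plots) || cfg$n_plots < 6)
    stop_config("n_plots", "must be at least 6")
  if (!is.numeric(cfg$raster_size) || cfg$raster_size < 8)
    stop_config("raster_size", "must be at least 8")
  if (length(cfg$bands) != 6 || any(!is.finite(cfg$bands)))
    stop_config("bands", "must list six finite wavelengths")
  if (!is.list(cfg$smc_range_by_layer) || length(cfg$smc_range_by_layer) != 3)
    stop_config("smc_range_by_layer", "must give min/max for three layers")
  for (rg in cfg$smc_range_by_layer) {
    if (length(rg) != 2 || !(0 < rg[1] && rg[1] < rg[2] && rg[2] < 1))
      stop_config("smc_range_by_layer", "needs 0 < min < max < 1 per layer")
  }
  if (!(cfg$layer_correlation > 0 && cfg$layer_correlation <= 1))
    stop_config("layer_correlation", "must lie in (0, 1]")
  if (cfg$soil_fraction < 0 || cfg$soil_fraction >= 1)
    stop_config("soil_fraction", "must lie in [0, 1)")
  for (f in c("noise_sd_reflectance", "noise_sd_thermal",
              "texture_amplitude_sd", "structure_amplitude",
              "calibration_noise_sd")) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0)
      stop_config(f, "must be a non-negative number")
  }
  if (cfg$n_calibration_points < 2)
    stop_config("n_calibration_points", "must be at least 2")
  if (!is.finite(cfg$thermal_gain) || cfg$thermal_gain == 0)
    stop_config("thermal_gain", "must be finite and non-zero")
  invisible(cfg)
}

# 3x3 box blur with edge replication; used to build smooth structure fields.
box_blur3 <- function(m) {
  n <- nrow(m); p <- ncol(m)
  mp <- m[c(1, 1:n, n), c(1, 1:p, p)]
  acc <- matrix(0, n, p)
  for (dr in 0:2) for (dc in 0:2)
    acc <- acc + mp[dr + 1:n, dc + 1:p]
  acc / 9
}

# Smooth, exactly mean-centred, unit-sd spatial field.
structure_field <- function(size) {
  s <- box_blur3(box_blur3(matrix(rnorm(size * size), size, size)))
  s <- s - mean(s)
  sdv <- sd(as.numeric(s))
  if (sdv > 0) s / sdv else s
}

# Inter-row soil strips: deterministic layout given size and soil fraction.
soil_strip_mask <- function(size, soil_fraction, period = 16L) {
  width <- round(soil_fraction * period)
  cols <- (seq_len(size) - 1) %% period < width
  matrix(rep(cols, each = size), size, size)
}

#' Generate a synthetic plot experiment
#'
#' Draws ground-truth SMC for every plot and depth layer, then renders a
#' six-band reflectance raster and a raw (uncalibrated) thermal raster per
#' plot with the planted couplings described in [scene_config()]. Also emits
#' leaf/water calibration points tying raw thermal values to true
#' temperatures. Bit-identical output for identical config (including seed).
#'
#' @param config a [scene_config()] object
#' @return object of class `smc_experiment`: list with `scenes` (list of
#'   `plot_scene` objects: `plot_id`, `reflectance` array (rows x cols x 6),
#'   `thermal` matrix of raw sensor values, `canopy_mask`, `soil_mask`,
#'   `air_temperature`, `bands`), `truth` (data.frame `plot_id`, `treatment`,
#'   `smc_0_20`, `smc_20_40`, `smc_40_60`), `calibration` (data.frame
#'   `image_temperature`, `reference_temperature`, `kind`), and `config`
#' @export
generate_experiment <- function(config = scene_config()) {
  validate_scene_config(config)
  cfg <- config
  n <- cfg$n_plots
  size <- cfg$raster_size
  with_seed(cfg$seed, {
    rngs <- cfg$smc_range_by_layer
    mid1 <- mean(rngs[[1]])
    sd1 <- diff(rngs[[1]]) / sqrt(12)
    rho <- cfg$layer_correlation

    treatments <- rep(sprintf("T%02d", 1:16), length.out = n)
    smc1 <- runif(n, rngs[[1]][1], rngs[[1]][2])
    if (any(cfg$treatment_effect != 0)) {
      eff <- rep(cfg$treatment_effect, length.out = 16)
      smc1 <- smc1 + eff[as.integer(factor(treatments, sprintf("T%02d", 1:16)))]
    }
    smc1 <- pmin(pmax(smc1, rngs[[1]][1]), rngs[[1]][2])
    noisy_copy <- function(parent, rg) {
      mid <- mean(rg)
      x <- mid + rho * (parent - mid1) + sqrt(1 - rho^2) * sd1 * rnorm(n)
      pmin(pmax(x, rg[1]), rg[2])
    }
    smc2 <- noisy_copy(smc1, rngs[[2]])
    smc3 <- noisy_copy(smc2, rngs[[3]])

    k_r <- cfg$coupling_strengths$reflectance
    k_t <- cfg$coupling_strengths$temperature
    k_x <- cfg$coupling_strengths$texture
    scale_b <- as.numeric(CANOPY_BASE / CANOPY_BASE["800"])

    # per-plot modality offsets (the dominant noise at plot level)
    d_refl <- matrix(rnorm(n * 6), n, 6) %*% diag(cfg$noise_sd_reflectance * scale_b)
    d_temp <- rnorm(n, 0, cfg$noise_sd_thermal)
    eta <- 0.04 + k_x * (smc1 - mid1) + rnorm(n, 0, cfg$texture_amplitude_sd)
    eta <- pmax(eta, 0.004)

    soil <- soil_strip_mask(size, cfg$soil_fraction)
    canopy <- !soil
    t_lo <- cfg$air_temperature - 25
    t_hi <- cfg$air_temperature + 25

    scenes <- vector("list", n)
    for (p in seq_len(n)) {
      S <- structure_field(size)                   # smooth canopy structure
      W <- matrix(rnorm(size * size), size, size)  # high-frequency texture
      W <- W - mean(W)
      refl <- array(0, dim = c(size, size, 6))
      for (b in 1:6) {
        canopy_val <- CANOPY_BASE[b] +
          BAND_COUPLING_WEIGHT[b] * k_r * (smc1[p] - mid1) + d_refl[p, b] +
          scale_b[b] * (cfg$structure_amplitude * S + eta[p] * W)
        layer <- matrix(canopy_val, size, size)
        if (any(soil)) layer[soil] <- SOIL_BASE[b]
        if (cfg$noise_sd_reflectance > 0)
          layer <- layer + matrix(
            rnorm(size * size, 0, cfg$noise_sd_reflectance * scale_b[b]),
            size, size)
        refl[, , b] <- pmin(pmax(layer, 0), 1)
      }
      t_canopy <- (cfg$air_temperature - 2) + k_t * (smc1[p] - mid1) + d_temp[p]
      thermal <- matrix(t_canopy, size, size)
      if (any(soil)) thermal[soil] <- cfg$air_temperature + 6 + 0.5 * d_temp[p]
      if (cfg$noise_sd_thermal > 0)
        thermal <- thermal + matrix(rnorm(size * size, 0, cfg$noise_sd_thermal),
                                    size, size)
      thermal <- pmin(pmax(thermal, t_lo), t_hi)
      raw <- (thermal - cfg$thermal_offset) / cfg$thermal_gain
      scenes[[p]] <- structure(
        list(plot_id = sprintf("P%03d", p), reflectance = refl, thermal = raw,
             canopy_mask = canopy, soil_mask = soil,
             air_temperature = cfg$air_temperature, bands = cfg$bands),
        class = "plot_scene")
    }

    ncal <- cfg$n_calibration_points
    n_leaf <- ceiling(ncal / 2)
    true_t <- c(rnorm(n_leaf, cfg$air_temperature - 2, 1.5),
                rnorm(ncal - n_leaf, 22, 0.5))
    calibration <- data.frame(
      image_temperature = (true_t - cfg$thermal_offset) / cfg$thermal_gain +
        rnorm(ncal, 0, cfg$calibration_noise_sd),
      reference_temperature = true_t,
      kind = c(rep("leaf", n_leaf), rep("water", ncal - n_leaf)),
      stringsAsFactors = FALSE)

    truth <- data.frame(plot_id = sprintf("P%03d", seq_len(n)),
                        treatment = treatments,
                        smc_0_20 = smc1, smc_20_40 = smc2, smc_40_60 = smc3,
                        stringsAsFactors = FALSE)
    structure(list(scenes = scenes, truth = truth, calibration = calibration,
                   config = cfg),
              class = "smc_experiment")
  })
}

THERMAL_STORE_OFFSET <- -50  # degC mapped to 0 in stored [0,1] thermal TIFFs
THERMAL_STORE_RANGE <- 150   # degC span of the stored [0,1] interval

#' Write an experiment to disk
#'
#' Writes one multi-page 32-bit float TIFF per plot for reflectance (pages in
#' ascending wavelength order), one single-page TIFF for the raw thermal
#' raster (temperatures affinely mapped into \[0,1\]; the mapping is recorded
#' in the manifest), the ground-truth CSV, the calibration-point CSV, and a
#' JSON manifest listing every file written.
#'
#' @param experiment an `smc_experiment` from [generate_experiment()]
#' @param out_dir output directory (created if missing)
#' @return invisibly, the manifest as a list; `manifest$files` names every
#'   file written (relative to `out_dir`)
#' @export
write_experiment <- function(experiment, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  scenes <- experiment$scenes
  plots <- list()
  files <- character(0)
  for (sc in scenes) {
    rf <- sprintf("refl_%s.tif", sc$plot_id)
    tf <- sprintf("thermal_%s.tif", sc$plot_id)
    pages <- lapply(seq_len(dim(sc$reflectance)[3]),
                    function(b) sc$reflectance[, , b])
    tiff::writeTIFF(pages, file.path(out_dir, rf), bits.per.sample = 32)
    tscaled <- (sc$thermal - THERMAL_STORE_OFFSET) / THERMAL_STORE_RANGE
    if (any(tscaled < 0 | tscaled > 1))
      stop("thermal values outside the storable range [-50, 100] degC")
    tiff::writeTIFF(tscaled, file.path(out_dir, tf), bits.per.sample = 32)
    plots[[length(plots) + 1]] <- list(plot_id = sc$plot_id,
                                       reflectance = rf, thermal = tf)
    files <- c(files, rf, tf)
  }
  utils::write.csv(experiment$truth, file.path(out_dir, "ground_truth.csv"),
                   row.names = FALSE)
  utils::write.csv(experiment$calibration,
                   file.path(out_dir, "calibration_points.csv"),
                   row.names = FALSE)
  files <- c(files, "ground_truth.csv", "calibration_points.csv")
  manifest <- list(
    format = "smcfusion-experiment/1",
    n_plots = length(scenes),
    raster_size = nrow(scenes[[1]]$thermal),
    bands = scenes[[1]]$bands,
    air_temperature = scenes[[1]]$air_temperature,
    thermal_store = list(offset = THERMAL_STORE_OFFSET,
                         range = THERMAL_STORE_RANGE),
    ground_truth = "ground_truth.csv",
    calibration = "calibration_points.csv",
    plots = plots,
    files = files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read an experiment written by [write_experiment()]
#'
#' @param dir directory containing `manifest.json` and the files it names
#' @return an `smc_experiment` (masks are left `NULL`; downstream masking
#'   recomputes them from NDVI)
#' @export
read_experiment <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) stop("no manifest.json in ", dir)
  man <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  truth <- utils::read.csv(file.path(dir, man$ground_truth),
                           stringsAsFactors = FALSE)
  calibration <- utils::read.csv(file.path(dir, man$calibration),
                                 stringsAsFactors = FALSE)
  off <- man$thermal_store$offset
  rng <- man$thermal_store$range
  plots <- man$plots
  scenes <- lapply(seq_len(nrow(plots)), function(i) {
    pages <- tiff::readTIFF(file.path(dir, plots$reflectance[i]), all = TRUE)
    size <- nrow(pages[[1]])
    refl <- array(0, dim = c(size, ncol(pages[[1]]), length(pages)))
    for (b in seq_along(pages)) refl[, , b] <- pages[[b]]
    thermal <- tiff::readTIFF(file.path(dir, plots$thermal[i])) * rng + off
    structure(list(plot_id = plots$plot_id[i], reflectance = refl,
                   thermal = thermal, canopy_mask = NULL, soil_mask = NULL,
                   air_temperature = man$air_temperature, bands = man$bands),
              class = "plot_scene")
  })
  structure(list(scenes = scenes, truth = truth, calibration = calibration,
                 config = NULL),
            class = "smc_experiment")
}

#' @export
print.plot_scene <- function(x, ...) {
  cat(sprintf("<plot_scene %s: %dx%d px, %d bands, air %.1f degC>\n",
              x$plot_id, nrow(x$thermal), ncol(x$thermal),
              dim(x$reflectance)[3], x$air_temperature))
  invisible(x)
}

#' @export
print.smc_experiment <- function(x, ...) {
  cat(sprintf("<smc_experiment: %d plots, raster %dx%d>\n",
              length(x$scenes), nrow(x$scenes[[1]]$thermal),
              ncol(x$scenes[[1]]$thermal)))
  invisible(x)
}
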