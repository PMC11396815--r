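#' Calibrate a thermal raster against reference temperatures
#'
#' Fits the ordinary least-squares line
#' `reference = a * image + b` to leaf/water calibration points and applies
#' it pixelwise to the raster.
#'
#' @param raster matrix of raw image temperatures (degC)
#' @param points data.frame with columns `image_temperature`,
#'   `reference_temperature` (and optionally `kind`); at least two points
#'   with distinct image temperatures
#' @return list with `raster` (calibrated), `a`, `b`, and `r_squared` of the
#'   fit
#' @export
calibrate_thermal <- function(raster, points) {
  need <- c("image_temperature", "reference_temperature")
  if (!all(need %in% names(points)))
    stop("calibration points need columns: ", paste(need, collapse = ", "))
  if (nrow(points) < 2)
    stop("calibration error: need at least two reference points")
  if (length(unique(points$image_temperature)) < 2)
    stop("calibration error: image temperatures are all identical")
  fit <- stats::lm(reference_temperature ~ image_temperature, data = points)
  a <- unname(coef(fit)[2]); b <- unname(coef(fit)[1])
  ssr <- sum(residuals(fit)^2)
  sst <- sum((points$reference_temperature -
              mean(points$reference_temperature))^2)
  r2 <- if (sst > 0) 1 - ssr / sst else NA_real_
  list(raster = a * raster + b, a = a, b = b, r_squared = r2)
}

#' Field-wide canopy temperature extremes
#'
#' Maximum and minimum calibrated canopy temperature over the canopy pixels
#' of all plots; these anchor NRCT and CRTD.
#'
#' @param thermals list of calibrated thermal matrices, one per plot
#' @param masks list of canopy masks matching `thermals`
#' @return list with `t_c_max`, `t_c_min`
#' @export
field_canopy_extremes <- function(thermals, masks) {
  vals <- unlist(mapply(function(t, m) t[m], thermals, masks,
                        SIMPLIFY = FALSE))
  if (length(vals) == 0) stop("no canopy pixels in any plot")
  list(t_c_max = max(vals), t_c_min = min(vals))
}

#' Per-plot thermal summary
#'
#' Plot-mean canopy temperature, field-wide canopy extremes, and within-plot
#' soil extremes, the ingredients of the four thermal indices.
#'
#' @param scene a `plot_scene` (for its plot id and air temperature)
#' @param thermal calibrated thermal matrix for the plot
#' @param canopy_mask,soil_mask logical pixel masks
#' @param field_extremes list from [field_canopy_extremes()]
#' @return list of class `thermal_summary`: `plot_id`, `t_canopy_mean`,
#'   `t_c_max`, `t_c_min`, `t_s_max`, `t_s_min` (NA when the plot has no soil
#'   pixels), `air_temperature`
#' @export
thermal_summary <- function(scene, thermal, canopy_mask, soil_mask,
                            field_extremes) {
  if (!any(canopy_mask)) stop("masking error: empty canopy mask")
  soil_vals <- thermal[soil_mask]
  structure(list(
    plot_id = scene$plot_id,
    t_canopy_mean = mean(thermal[canopy_mask]),
    t_c_max = field_extremes$t_c_max,
    t_c_min = field_extremes$t_c_min,
    t_s_max = if (length(soil_vals)) max(soil_vals) else NA_real_,
    t_s_min = if (length(soil_vals)) min(soil_vals) else NA_real_,
    air_temperature = scene$air_temperature), class = "thermal_summary")
}

#' Thermal-infrared vegetation indices
#'
#' From a plot's thermal summary computes, in degrees Celsius:
#' canopy-air temperature difference `TcD = Tci - Tair`; normalized canopy
#' temperature `NRCT = (Tci - Tcmin)/(Tcmax - Tcmin)`; canopy relative
#' temperature difference `CRTD = (Tcmax - Tcmin)/(Tcmax + Tcmin)`; soil
#' relative temperature difference `SRTD = (Tsmax - Tsmin)/(Tsmax + Tsmin)`.
#' `Tci` is the plot-mean canopy temperature; the canopy extremes are
#' field-wide. SRTD is NA when the plot has no soil pixels; a zero
#' denominator yields NA with a warning rather than an abort.
#'
#' @param s a `thermal_summary`
#' @return named numeric vector `TcD`, `NRCT`, `CRTD`, `SRTD`
#' @export
thermal_indices <- function(s) {
  tcd <- s$t_canopy_mean - s$air_temperature
  drange <- s$t_c_max - s$t_c_min
  nrct <- if (drange == 0) {
    warning("undefined NRCT: field canopy extremes coincide"); NA_real_
  } else (s$t_canopy_mean - s$t_c_min) / drange
  dsum <- s$t_c_max + s$t_c_min
  crtd <- if (dsum == 0) {
    warning("undefined CRTD: zero denominator"); NA_real_
  } else drange / dsum
  srtd <- if (is.na(s$t_s_max) || is.na(s$t_s_min)) {
    NA_real_
  } else if (s$t_s_max + s$t_s_min == 0) {
    warning("undefined SRTD: zero denominator"); NA_real_
  } else (s$t_s_max - s$t_s_min) / (s$t_s_max + s$t_s_min)
  c(TcD = tcd, NRCT = nrct, CRTD = crtd, SRTD = srtd)
}

#' Thermal feature table for an experiment
#'
#' Calibrates every plot's thermal raster, derives field-wide canopy
#' extremes, and returns the four thermal indices per plot.
#'
#' @param scenes list of `plot_scene` objects
#' @param canopy_masks,soil_masks lists of masks matching `scenes`
#' @param calibration calibration-point data.frame (see
#'   [calibrate_thermal()]); NULL skips calibration (rasters used as-is)
#' @return list with `table` (plots x 4 matrix of TcD, NRCT, CRTD, SRTD,
#'   plot IDs as row names) and `calibration_fit` (a, b, r_squared or NULL)
#' @export
thermal_feature_table <- function(scenes, canopy_masks, soil_masks,
                                  calibration = NULL) {
  fit <- NULL
  thermals <- lapply(scenes, `[[`, "thermal")
  if (!is.null(calibration)) {
    cal <- calibrate_thermal(thermals[[1]], calibration)
    fit <- cal[c("a", "b", "r_squared")]
    thermals <- lapply(thermals, function(t) fit$a * t + fit$b)
  }
  ext <- field_canopy_extremes(thermals, canopy_masks)
  rows <- mapply(function(sc, t, cm, sm) {
    thermal_indices(thermal_summary(sc, t, cm, sm, ext))
  }, scenes, thermals, canopy_masks, soil_masks)
  tab <- t(rows)
  rownames(tab) <- vapply(scenes, `[[`, character(1), "plot_id")
  list(table = tab, calibration_fit = fit)
}
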