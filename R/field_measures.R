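#' Gravimetric soil moisture content
#'
#' Computes soil moisture content (SMC) from the wet mass `M1` of a soil
#' sample and its oven-dry mass `M2`. The default is the wet-basis form
#' `W = (M1 - M2) / M1`; `basis = "dry"` selects the conventional
#' gravimetric water content `(M1 - M2) / M2`.
#'
#' @param wet_mass_g wet sample mass in grams (`M1`), positive
#' @param dry_mass_g oven-dry sample mass in grams (`M2`), with
#'   `0 < dry_mass_g <= wet_mass_g`
#' @param basis `"wet"` (default) or `"dry"`
#' @return SMC as a fraction (vectorized over the mass arguments)
#' @examples
#' gravimetric_smc(100, 80)          # 0.20
#' gravimetric_smc(100, 80, "dry")   # 0.25
#' @export
gravimetric_smc <- function(wet_mass_g, dry_mass_g, basis = c("wet", "dry")) {
  basis <- match.arg(basis)
  if (length(wet_mass_g) != length(dry_mass_g))
    stop("wet_mass_g and dry_mass_g must have the same length")
  if (any(!is.finite(wet_mass_g)) || any(!is.finite(dry_mass_g)))
    stop("masses must be finite")
  if (any(wet_mass_g <= 0))
    stop("wet mass M1 must be positive")
  if (any(dry_mass_g <= 0) || any(dry_mass_g > wet_mass_g))
    stop("dry mass M2 must satisfy 0 < M2 <= M1")
  num <- wet_mass_g - dry_mass_g
  if (basis == "wet") num / wet_mass_g else num / dry_mass_g
}

#' Plot-level aggregation of point measurements
#'
#' Arithmetic mean of repeated point measurements within a plot (the field
#' protocol samples five points per plot and keeps their average).
#'
#' @param values numeric vector of measurements, non-empty and finite
#' @return the arithmetic mean
#' @examples
#' plot_mean(c(0.1, 0.2, 0.3, 0.4, 0.5))  # 0.3
#' @export
plot_mean <- function(values) {
  if (length(values) == 0)
    stop("cannot aggregate an empty set of measurements")
  if (!is.numeric(values) || any(!is.finite(values)))
    stop("measurements must be finite numbers")
  mean(values)
}

#' Read per-point soil sample masses and aggregate to plot SMC
#'
#' Reads a CSV with columns `plot_id`, `wet_mass_g`, `dry_mass_g` (one row per
#' sampling point) and returns one SMC value per plot, the mean over points.
#'
#' @param path CSV file path
#' @param basis passed to [gravimetric_smc()]
#' @return data.frame with columns `plot_id`, `smc`, `n_points`
#' @export
read_soil_samples <- function(path, basis = "wet") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("plot_id", "wet_mass_g", "dry_mass_g")
  if (!all(need %in% names(df)))
    stop("soil sample CSV must have columns: ", paste(need, collapse = ", "))
  w <- gravimetric_smc(df$wet_mass_g, df$dry_mass_g, basis)
  agg <- tapply(w, df$plot_id, plot_mean)
  cnt <- tapply(w, df$plot_id, length)
  data.frame(plot_id = names(agg), smc = as.numeric(agg),
             n_points = as.integer(cnt), row.names = NULL,
             stringsAsFactors = FALSE)
}
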