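#' Vegetation index catalog
#'
#' The 15 vegetation indices computed by [compute_vi()], in catalog order.
#' @export
VI_CATALOG <- c("MTVI", "SAVI", "OSAVI", "MSAVI", "DVI", "GNDVI", "GCVI",
                "NLI", "RVI", "RDVI", "MSR", "NDRE", "TVI", "NDVI", "EVI")

band_index <- function(scene, wavelength) {
  i <- match(wavelength, scene$bands)
  if (is.na(i)) stop("scene has no ", wavelength, " nm band")
  i
}

#' NDVI-threshold canopy mask
#'
#' Classifies pixels as canopy when per-pixel NDVI exceeds `vi_threshold`,
#' separating vegetation from soil background and shadow.
#'
#' @param scene a `plot_scene`
#' @param vi_threshold NDVI cut; 0.3 suits a dense flowering canopy
#' @param nir_band NIR wavelength used for the masking NDVI (800 or 900)
#' @return logical matrix (TRUE = canopy) with attribute `count`, the number
#'   of canopy pixels
#' @export
canopy_mask <- function(scene, vi_threshold = 0.3, nir_band = 800) {
  red <- scene$reflectance[, , band_index(scene, 680)]
  nir <- scene$reflectance[, , band_index(scene, nir_band)]
  den <- nir + red
  ndvi <- ifelse(den == 0, 0, (nir - red) / den)
  mask <- ndvi > vi_threshold
  if (!any(mask))
    stop("masking error: no canopy pixel exceeds NDVI threshold ",
         vi_threshold, " for plot ", scene$plot_id)
  attr(mask, "count") <- sum(mask)
  mask
}

#' Plot-level band reflectance
#'
#' Arithmetic mean of each band over the masked (canopy) pixels.
#'
#' @param scene a `plot_scene`
#' @param mask logical matrix of pixels to include
#' @return named numeric vector `blue`, `green`, `red`, `rededge`, `nir800`,
#'   `nir900`
#' @export
plot_reflectance <- function(scene, mask) {
  if (!any(mask)) stop("masking error: empty mask")
  v <- vapply(seq_len(dim(scene$reflectance)[3]),
              function(b) mean(scene$reflectance[, , b][mask]), numeric(1))
  names(v) <- band_name_for(scene$bands)
  v
}

band_name_for <- function(bands) {
  lab <- c(`490` = "blue", `555` = "green", `680` = "red", `720` = "rededge",
           `800` = "nir800", `900` = "nir900")
  out <- lab[as.character(bands)]
  if (any(is.na(out))) out[is.na(out)] <- paste0("band", bands[is.na(out)])
  unname(out)
}

#' Compute one vegetation index
#'
#' Evaluates a Table-style band-arithmetic vegetation index from plot-level
#' band reflectances. `OSAVI` and `MTVI` follow the green/red-edge band
#' choices of the source catalog (OSAVI here uses the green band and NLI the
#' red edge), and `X` is the soil-adjustment constant of OSAVI.
#'
#' @param name one of [VI_CATALOG]
#' @param refl named reflectance vector as returned by [plot_reflectance()]
#' @param nir_band which NIR band (800 or 900) stands in for RNIR
#' @param X soil-adjustment constant for OSAVI (default 0.16)
#' @return the index value; an exactly zero denominator raises an
#'   undefined-value error
#' @examples
#' r <- c(blue = 0.05, green = 0.12, red = 0.1, rededge = 0.25,
#'        nir800 = 0.5, nir900 = 0.48)
#' compute_vi("NDVI", r)   # 0.6667
#' compute_vi("SAVI", r)   # 0.5455
#' @export
compute_vi <- function(name, refl, nir_band = 800, X = 0.16) {
  name <- match.arg(name, VI_CATALOG)
  RB <- refl[["blue"]]; RG <- refl[["green"]]; RR <- refl[["red"]]
  RRE <- refl[["rededge"]]
  RNIR <- refl[[paste0("nir", nir_band)]]
  div <- function(num, den) {
    if (any(den == 0)) stop("undefined-value error: zero denominator in ", name)
    num / den
  }
  val <- switch(name,
    MTVI  = 1.2 * (1.2 * (RNIR - RG) - 2.5 * (RRE - RG)),
    SAVI  = 1.5 * div(RNIR - RR, RNIR + RR + 0.5),
    OSAVI = (1 + X) * div(RNIR - RG, RNIR + RG + X),
    MSAVI = (2 * RNIR + 1 - sqrt((2 * RNIR + 1)^2 - 8 * (RNIR - RR))) / 2,
    DVI   = RNIR - RR,
    GNDVI = div(RNIR - RG, RNIR + RG),
    GCVI  = div(RNIR, RG) - 1,
    NLI   = div(RNIR^2 - RRE, RNIR^2 + RRE),
    RVI   = div(RNIR, RR),
    RDVI  = div(RNIR - RR, sqrt(RNIR + RR)),
    MSR   = div(div(RNIR, RR) - 1, sqrt(div(RNIR, RR)) + 1),
    NDRE  = div(RNIR - RRE, RNIR + RRE),
    TVI   = 60 * (RNIR - RG) - 100 * (RR - RG),
    NDVI  = div(RNIR - RR, RNIR + RR),
    EVI   = 2.5 * div(RNIR - RR, RNIR + 6 * RR - 7.5 * RB + 1))
  if (!is.finite(val)) stop("undefined-value error: ", name, " is not finite")
  val
}

#' All 15 vegetation indices for a table of plot reflectances
#'
#' @param refl_table data.frame/matrix with the columns of
#'   [plot_reflectance()] (one row per plot)
#' @param nir_band 800 or 900
#' @param X soil-adjustment constant
#' @return matrix plots x 15; indices undefined for a plot are NA
#' @export
compute_vi_table <- function(refl_table, nir_band = 800, X = 0.16) {
  refl_table <- as.data.frame(refl_table)
  out <- matrix(NA_real_, nrow(refl_table), length(VI_CATALOG),
                dimnames = list(NULL, VI_CATALOG))
  for (i in seq_len(nrow(refl_table))) {
    r <- as.list(refl_table[i, ])
    for (nm in VI_CATALOG) {
      v <- tryCatch(compute_vi(nm, r, nir_band = nir_band, X = X),
                    error = function(e) NA_real_)
      out[i, nm] <- v
    }
  }
  out
}

#' Choose the NIR band per vegetation index
#'
#' For each index, picks the NIR band (800 or 900 nm) whose index values have
#' the larger absolute Pearson correlation with SMC; ties go to 800 nm. A
#' band whose index is constant (correlation undefined) is skipped with a
#' warning; if both are constant the index is excluded (NA).
#'
#' @param vi800,vi900 matrices from [compute_vi_table()] at each band
#' @param smc SMC vector (typically restricted to the training split, as are
#'   the rows of the two matrices)
#' @return named integer vector over [VI_CATALOG]: 800, 900, or NA
#' @export
select_nir_band <- function(vi800, vi900, smc) {
  sel <- setNames(rep(NA_integer_, length(VI_CATALOG)), VI_CATALOG)
  for (nm in VI_CATALOG) {
    r8 <- safe_abs_cor(vi800[, nm], smc)
    r9 <- safe_abs_cor(vi900[, nm], smc)
    if (is.na(r8) && is.na(r9)) {
      warning("index ", nm, " is degenerate at both NIR bands; excluded")
    } else if (is.na(r8)) {
      warning("index ", nm, " is degenerate at 800 nm; selecting 900 nm")
      sel[nm] <- 900L
    } else if (is.na(r9)) {
      warning("index ", nm, " is degenerate at 900 nm; selecting 800 nm")
      sel[nm] <- 800L
    } else {
      sel[nm] <- if (r9 > r8) 900L else 800L  # tie -> 800
    }
  }
  sel
}

safe_abs_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3) return(NA_real_)
  if (sd(x[ok]) == 0 || sd(y[ok]) == 0) return(NA_real_)
  abs(cor(x[ok], y[ok]))
}
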