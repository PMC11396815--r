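#' GLCM texture statistic catalog
#'
#' The eight statistics computed from a gray-level co-occurrence matrix, in
#' catalog order: mean, variance, homogeneity, contrast, dissimilarity,
#' entropy, second moment, correlation.
#' @export
TEXTURE_FEATURES <- c("Mea", "Var", "Hom", "Con", "Dis", "Ent", "Sec", "Cor")

#' Texture index forms
#'
#' The six two-feature texture-index families: normalized difference (NDTI),
#' difference (DTI), ratio (RTI), nonlinear (NTI), reciprocal difference
#' (RDTI), reciprocal additive (RATI).
#' @export
TI_FORMS <- c("NDTI", "DTI", "RTI", "NTI", "RDTI", "RATI")

GLCM_DIRECTIONS <- c(0, 45, 90, 135)

glcm_offset <- function(direction) {
  switch(as.character(direction),
         `0`   = c(0L, 1L),
         `45`  = c(-1L, 1L),
         `90`  = c(-1L, 0L),
         `135` = c(-1L, -1L),
         stop("direction must be one of 0, 45, 90, 135"))
}

#' Quantize a band to G gray levels
#'
#' Linear min-max scaling of the raster to integer bins `0 .. levels-1`.
#' A constant raster maps to bin 0.
#'
#' @param raster numeric matrix of finite values
#' @param levels number of gray levels G (>= 2)
#' @return integer matrix in `[0, levels-1]`
#' @export
quantize_band <- function(raster, levels = 32) {
  if (levels < 2) stop_config("levels", "must be at least 2")
  if (any(!is.finite(raster))) stop("raster must be finite")
  rng <- range(raster)
  q <- if (rng[1] == rng[2]) {
    matrix(0L, nrow(raster), ncol(raster))
  } else {
    b <- floor((raster - rng[1]) / (rng[2] - rng[1]) * levels)
    matrix(as.integer(pmin(b, levels - 1)), nrow(raster), ncol(raster))
  }
  q
}

#' GLCM for a single window
#'
#' Symmetric co-occurrence counting at the given direction and distance,
#' normalized to probabilities.
#'
#' @param q integer matrix of gray levels in `[0, levels-1]`
#' @param direction degrees, one of 0, 45, 90, 135
#' @param distance offset in pixels (default 1)
#' @param levels gray-level count G; defaults to `max(q) + 1`
#' @return object of class `glcm_matrix`: G x G probability matrix `P`
#'   (rows/cols labelled with 1-based gray levels) with attributes
#'   `direction` and `distance`
#' @export
glcm_window <- function(q, direction, distance = 1, levels = max(q) + 1L) {
  if (!is.matrix(q)) q <- as.matrix(q)
  storage.mode(q) <- "integer"
  off <- glcm_offset(direction) * as.integer(distance)
  cnt <- glcm_counts_cpp(q, as.integer(levels), off[1], off[2])
  tot <- sum(cnt)
  if (tot == 0)
    stop("degenerate window: no pixel pairs at direction ", direction,
         ", distance ", distance)
  P <- cnt / tot
  dimnames(P) <- list(seq_len(levels), seq_len(levels))
  structure(P, direction = direction, distance = distance,
            class = c("glcm_matrix", "matrix"))
}

#' The eight GLCM texture statistics
#'
#' Computes Mea, Var, Hom, Con, Dis, Ent, Sec, Cor from a co-occurrence
#' probability matrix. Gray levels are labelled 1..G. Entropy is the Shannon
#' entropy `-sum(P log P)` (natural log, with `0 log 0 = 0`). Correlation
#' uses the marginal means/variances; when a marginal variance is zero it
#' returns the sentinel 0 and sets the attribute `degenerate_cor`.
#'
#' @param m a `glcm_matrix` (or any probability matrix summing to 1)
#' @return named numeric vector of the eight statistics
#' @export
texture_stats <- function(m) {
  P <- unclass(m)
  G <- nrow(P)
  if (abs(sum(P) - 1) > 1e-8) stop("GLCM entries must sum to 1")
  i <- matrix(seq_len(G), G, G)
  j <- t(i)
  pi_ <- rowSums(P)   # marginal over i
  pj_ <- colSums(P)
  mea_i <- sum(seq_len(G) * pi_)
  mea_j <- sum(seq_len(G) * pj_)
  var_i <- sum((seq_len(G) - mea_i)^2 * pi_)
  var_j <- sum((seq_len(G) - mea_j)^2 * pj_)
  pos <- P > 0
  ent <- -sum(P[pos] * log(P[pos]))
  degenerate <- (var_i == 0 || var_j == 0)
  corr <- if (degenerate) 0 else
    sum((i - mea_i) * (j - mea_j) * P) / sqrt(var_i * var_j)
  out <- c(Mea = mea_i,
           Var = var_i,
           Hom = sum(P / (1 + (i - j)^2)),
           Con = sum((i - j)^2 * P),
           Dis = sum(abs(i - j) * P),
           Ent = ent,
           Sec = sum(P^2),
           Cor = corr)
  if (degenerate) attr(out, "degenerate_cor") <- TRUE
  out
}

#' Sliding-window texture image for a band
#'
#' For every interior pixel, computes the requested GLCM statistics over the
#' 3x3 window centred on it, in each of the four directions at distance 1,
#' and averages the four directional values. Edge pixels (where the window
#' would fall outside the raster) are NA; no padding is used.
#'
#' @param q integer raster of gray levels (at least 3x3)
#' @param features which statistics to return (default all eight)
#' @return a named list of matrices, one per requested feature
#' @export
band_texture_image <- function(q, features = TEXTURE_FEATURES) {
  if (!is.matrix(q)) q <- as.matrix(q)
  if (nrow(q) < 3 || ncol(q) < 3)
    stop("raster must be at least 3x3 for a 3x3 sliding window")
  storage.mode(q) <- "integer"
  features <- match.arg(features, TEXTURE_FEATURES, several.ok = TRUE)
  imgs <- texture_images_cpp(q)
  imgs[features]
}

#' Plot-level texture features
#'
#' Quantizes each band, computes its eight texture images, and averages every
#' image over the masked pixels with valid (non-edge) texture values. Returns
#' the 48 per-plot texture features (6 bands x 8 statistics).
#'
#' @param scene a `plot_scene`
#' @param mask logical matrix of pixels to include
#' @param levels gray-level count G for quantization (default 32)
#' @return data.frame with columns `band` (1..6), `feature`, `name` (e.g.
#'   `"Mea3"` = mean statistic of band 3), `value`
#' @export
plot_texture <- function(scene, mask, levels = 32) {
  nb <- dim(scene$reflectance)[3]
  out <- vector("list", nb)
  for (b in seq_len(nb)) {
    q <- quantize_band(scene$reflectance[, , b], levels)
    imgs <- texture_images_cpp(q)
    vals <- vapply(TEXTURE_FEATURES, function(f) {
      img <- imgs[[f]]
      keep <- mask & !is.na(img)
      if (!any(keep))
        stop("masking error: no valid interior pixels for band ", b)
      mean(img[keep])
    }, numeric(1))
    out[[b]] <- data.frame(band = b, feature = TEXTURE_FEATURES,
                           name = paste0(TEXTURE_FEATURES, b),
                           value = unname(vals), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Evaluate one texture index
#'
#' Combines two texture feature values `t1`, `t2` with one of the six forms:
#' `NDTI = (T1-T2)/(T1+T2)`, `DTI = T1-T2`, `RTI = T1/T2`,
#' `NTI = (T1^2-T2)/(T1^2+T2)`, `RDTI = 1/T1 - 1/T2`, `RATI = 1/T1 + 1/T2`.
#'
#' @param form one of [TI_FORMS]
#' @param t1,t2 texture feature values (vectorized)
#' @return index value(s); a zero denominator raises an undefined-value error
#' @export
texture_index <- function(form, t1, t2) {
  form <- match.arg(form, TI_FORMS)
  bad <- switch(form,
    NDTI = any(t1 + t2 == 0),
    DTI  = FALSE,
    RTI  = any(t2 == 0),
    NTI  = any(t1^2 + t2 == 0),
    RDTI = any(t1 == 0 | t2 == 0),
    RATI = any(t1 == 0 | t2 == 0))
  if (!all(is.finite(t1)) || !all(is.finite(t2)))
    stop("texture index inputs must be finite")
  if (bad) stop("undefined-value error: zero denominator in ", form)
  switch(form,
    NDTI = (t1 - t2) / (t1 + t2),
    DTI  = t1 - t2,
    RTI  = t1 / t2,
    NTI  = (t1^2 - t2) / (t1^2 + t2),
    RDTI = 1 / t1 - 1 / t2,
    RATI = 1 / t1 + 1 / t2)
}

ti_values <- function(form, A1, A2) {
  # vectorized, NA where undefined (used by the exhaustive search)
  v <- switch(form,
    NDTI = (A1 - A2) / (A1 + A2),
    DTI  = A1 - A2,
    RTI  = A1 / A2,
    NTI  = (A1^2 - A2) / (A1^2 + A2),
    RDTI = 1 / A1 - 1 / A2,
    RATI = 1 / A1 + 1 / A2)
  v[!is.finite(v)] <- NA_real_
  v
}

#' Canonical wide texture table
#'
#' Reshapes `plot_texture()` output for many plots into a plots x 48 matrix
#' whose columns follow the canonical (band-major, catalog feature order)
#' identity ordering: `Mea1, Var1, ..., Cor1, Mea2, ...`.
#'
#' @param texture_long data.frame with columns `plot_id`, `name`, `value`
#' @return numeric matrix with plot IDs as row names
#' @export
texture_wide <- function(texture_long) {
  cols <- as.vector(vapply(1:6, function(b) paste0(TEXTURE_FEATURES, b),
                           character(8)))
  cols <- cols[cols %in% unique(texture_long$name)]
  plots <- unique(texture_long$plot_id)
  m <- matrix(NA_real_, length(plots), length(cols),
              dimnames = list(plots, cols))
  idx <- cbind(match(texture_long$plot_id, plots),
               match(texture_long$name, cols))
  m[idx] <- texture_long$value
  m
}

#' Exhaustive texture-index search
#'
#' For each of the six index forms, evaluates the index over all ordered
#' pairs of texture feature identities (including identical pairs), computes
#' the Pearson correlation of each candidate with SMC, and reports the pair
#' with the largest absolute correlation. Ties resolve to the first pair in
#' canonical (band, feature) order of T1 then T2. Candidates that are
#' undefined for some plot or constant across plots are skipped.
#'
#' @param texture_table plots x identities matrix ([texture_wide()]); its
#'   column order defines the canonical identity order
#' @param smc SMC vector, one value per row
#' @param forms which index forms to search (default all six)
#' @return data.frame with columns `form`, `t1`, `t2`, `r`, `n_candidates`;
#'   attribute `skipped` counts skipped candidates per form
#' @export
search_texture_indices <- function(texture_table, smc, forms = TI_FORMS) {
  texture_table <- as.matrix(texture_table)
  if (nrow(texture_table) < 3) stop("need at least 3 plots for the search")
  if (nrow(texture_table) != length(smc))
    stop("texture table and SMC vector disagree on plot count")
  if (any(!is.finite(texture_table)))
    stop("texture table must be complete (finite)")
  ids <- colnames(texture_table)
  k <- length(ids)
  i1 <- rep(seq_len(k), each = k)   # T1-major: canonical tie-break order
  i2 <- rep(seq_len(k), times = k)
  A1 <- texture_table[, i1, drop = FALSE]
  A2 <- texture_table[, i2, drop = FALSE]
  yc <- smc - mean(smc)
  ysd <- sqrt(sum(yc^2))
  if (ysd == 0) stop("SMC vector is constant; correlation undefined")
  res <- vector("list", length(forms))
  skipped <- setNames(integer(length(forms)), forms)
  for (f in seq_along(forms)) {
    V <- ti_values(forms[f], A1, A2)
    bad <- colSums(!is.finite(V)) > 0
    Vc <- sweep(V, 2, colMeans(V))
    ss <- sqrt(colSums(Vc^2))
    bad <- bad | ss == 0 | !is.finite(ss)
    r <- as.numeric(crossprod(Vc, yc)) / (ss * ysd)
    r[bad] <- NA_real_
    skipped[f] <- sum(bad)
    if (all(is.na(r)))
      stop("search error: every ", forms[f], " candidate was degenerate")
    best <- which.max(abs(r))  # first max in canonical order
    res[[f]] <- data.frame(form = forms[f], t1 = ids[i1[best]],
                           t2 = ids[i2[best]], r = r[best],
                           n_candidates = sum(!is.na(r)),
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  attr(out, "skipped") <- skipped
  out
}
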