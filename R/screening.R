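#' Sample Pearson correlation
#'
#' @param x,y numeric vectors of equal length (>= 3), neither constant
#' @return the sample correlation coefficient
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("inputs must be finite")
  if (sd(x) == 0 || sd(y) == 0)
    stop("undefined correlation: constant input")
  cor(x, y)
}

#' Two-sided p-value for a Pearson correlation
#'
#' Uses the exact null distribution of `t = r sqrt(n-2) / sqrt(1-r^2)`,
#' Student t with `n - 2` degrees of freedom. `|r| = 1` returns 0 by
#' convention.
#'
#' @param r correlation coefficient
#' @param n sample size (>= 3)
#' @return two-sided p-value
#' @export
r_pvalue <- function(r, n) {
  if (n < 3) stop("need n >= 3")
  if (abs(r) > 1) stop("|r| cannot exceed 1")
  if (abs(r) == 1) return(0)
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  2 * stats::pt(-abs(t), df = n - 2)
}

#' Smallest significant |r| at a given alpha
#'
#' The critical absolute correlation above which the two-sided Pearson test
#' rejects at level `alpha` for sample size `n` (about 0.262 at n = 96,
#' alpha = 0.01).
#'
#' @param n sample size
#' @param alpha significance level
#' @return critical |r|
#' @export
critical_r <- function(n, alpha = 0.01) {
  tcrit <- stats::qt(1 - alpha / 2, df = n - 2)
  tcrit / sqrt(n - 2 + tcrit^2)
}

#' Screen features by Pearson significance
#'
#' Correlates every feature column with the response and flags features
#' significant at the two-sided level `alpha` (the selection rule feeding the
#' models). Degenerate (constant or incomplete) features are excluded with a
#' warning, not an error. Output rows are ordered by family, then |r|
#' descending.
#'
#' @param table numeric matrix/data.frame, plots x features, with column names
#' @param smc response vector (one value per row)
#' @param alpha selection level (default 0.01)
#' @param family named character vector mapping feature names to families
#'   (`"VIs"`, `"TF"`, `"TIs"`, `"TVIs"`); unnamed features get `"other"`
#' @param layer optional layer label copied into the output
#' @return data.frame with columns `layer`, `family`, `feature`, `r`, `p`,
#'   `selected`
#' @export
screen_features <- function(table, smc, alpha = 0.01, family = NULL,
                            layer = NA_character_) {
  table <- as.matrix(table)
  if (nrow(table) < 3) stop("need at least 3 plots")
  if (nrow(table) != length(smc)) stop("row count must match response length")
  feats <- colnames(table)
  if (is.null(feats)) stop("feature table must have column names")
  fam <- rep("other", length(feats))
  if (!is.null(family)) {
    hit <- feats %in% names(family)
    fam[hit] <- unname(family[feats[hit]])
  }
  n <- nrow(table)
  rows <- lapply(seq_along(feats), function(k) {
    x <- table[, k]
    if (any(!is.finite(x)) || sd(x) == 0) {
      warning("feature ", feats[k], " is degenerate; excluded from screening")
      return(NULL)
    }
    r <- pearson_r(x, smc)
    p <- r_pvalue(r, n)
    data.frame(layer = layer, family = fam[k], feature = feats[k],
               r = r, p = p, selected = p < alpha, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(layer = character(0), family = character(0),
                      feature = character(0), r = numeric(0), p = numeric(0),
                      selected = logical(0)))
  out <- out[order(out$family, -abs(out$r)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
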