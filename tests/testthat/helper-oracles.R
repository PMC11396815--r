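# Slow, direct reference implementations used to cross-check the fast paths.

# Naive symmetric GLCM pair counting over a full integer raster.
oracle_glcm <- function(q, direction, distance = 1, levels = max(q) + 1L) {
  off <- switch(as.character(direction),
                `0` = c(0, 1), `45` = c(-1, 1), `90` = c(-1, 0),
                `135` = c(-1, -1)) * distance
  P <- matrix(0, levels, levels)
  for (i in seq_len(nrow(q))) {
    for (j in seq_len(ncol(q))) {
      i2 <- i + off[1]; j2 <- j + off[2]
      if (i2 >= 1 && i2 <= nrow(q) && j2 >= 1 && j2 <= ncol(q)) {
        a <- q[i, j] + 1; b <- q[i2, j2] + 1
        P[a, b] <- P[a, b] + 1
        P[b, a] <- P[b, a] + 1   # symmetric counting
      }
    }
  }
  P / sum(P)
}

# Scalar-loop texture statistics from a probability matrix (Table-style
# definitions with 1-based gray labels).
oracle_texture_stats <- function(P) {
  G <- nrow(P)
  mea <- 0; for (i in 1:G) for (j in 1:G) mea <- mea + i * P[i, j]
  va <- 0; for (i in 1:G) for (j in 1:G) va <- va + (i - mea)^2 * P[i, j]
  hom <- 0; con <- 0; dis <- 0; ent <- 0; sec <- 0
  for (i in 1:G) for (j in 1:G) {
    p <- P[i, j]
    hom <- hom + p / (1 + (i - j)^2)
    con <- con + (i - j)^2 * p
    dis <- dis + abs(i - j) * p
    if (p > 0) ent <- ent - p * log(p)
    sec <- sec + p^2
  }
  pi_ <- rowSums(P); pj_ <- colSums(P)
  mi <- sum((1:G) * pi_); mj <- sum((1:G) * pj_)
  vi <- sum(((1:G) - mi)^2 * pi_); vj <- sum(((1:G) - mj)^2 * pj_)
  corr <- if (vi == 0 || vj == 0) 0 else {
    s <- 0
    for (i in 1:G) for (j in 1:G) s <- s + (i - mi) * (j - mj) * P[i, j]
    s / sqrt(vi * vj)
  }
  c(Mea = mea, Var = va, Hom = hom, Con = con, Dis = dis, Ent = ent,
    Sec = sec, Cor = corr)
}

# Per-pixel sliding-window texture image computed directly in R: 3x3 windows,
# four directions at distance 1, direction-averaged, NA at edges.
oracle_texture_image <- function(q, feature) {
  n <- nrow(q); p <- ncol(q)
  out <- matrix(NA_real_, n, p)
  levels <- max(q) + 1L
  for (i in 2:(n - 1)) {
    for (j in 2:(p - 1)) {
      win <- q[(i - 1):(i + 1), (j - 1):(j + 1)]
      vals <- vapply(c(0, 45, 90, 135), function(d) {
        oracle_texture_stats(oracle_glcm(win, d, 1, levels))[[feature]]
      }, numeric(1))
      out[i, j] <- mean(vals)
    }
  }
  out
}

# Brute-force texture-index search over all ordered identity pairs.
oracle_ti_search <- function(tab, smc, forms = TI_FORMS) {
  ids <- colnames(tab)
  best <- list()
  for (f in forms) {
    br <- NA_real_; bt1 <- NA; bt2 <- NA; ncand <- 0
    for (t1 in ids) for (t2 in ids) {
      v <- switch(f,
                  NDTI = (tab[, t1] - tab[, t2]) / (tab[, t1] + tab[, t2]),
                  DTI = tab[, t1] - tab[, t2],
                  RTI = tab[, t1] / tab[, t2],
                  NTI = (tab[, t1]^2 - tab[, t2]) / (tab[, t1]^2 + tab[, t2]),
                  RDTI = 1 / tab[, t1] - 1 / tab[, t2],
                  RATI = 1 / tab[, t1] + 1 / tab[, t2])
      if (any(!is.finite(v)) || sd(v) == 0) next
      r <- cor(v, smc)
      if (!is.finite(r)) next
      ncand <- ncand + 1
      if (is.na(br) || abs(r) > abs(br)) { br <- r; bt1 <- t1; bt2 <- t2 }
    }
    best[[f]] <- data.frame(form = f, t1 = bt1, t2 = bt2, r = br,
                            n_candidates = ncand, stringsAsFactors = FALSE)
  }
  do.call(rbind, best)
}

# Small, quick experiment used by several test files.
small_config <- function(...) {
  scene_config(n_plots = 12, raster_size = 16, ...)
}
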