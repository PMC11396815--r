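test_that("quantize_band maps min-max to 0..G-1 and handles constants", {
  m <- matrix(c(0, 0.25, 0.5, 1), 2, 2)
  q <- quantize_band(m, levels = 4)
  expect_identical(q, matrix(c(0L, 1L, 2L, 3L), 2, 2))
  expect_identical(quantize_band(matrix(0.7, 3, 3), 8), matrix(0L, 3, 3))
  expect_error(quantize_band(matrix(c(1, NA, 1, 1), 2, 2)), "finite")
  expect_error(quantize_band(m, levels = 1), "levels")
})

test_that("glcm_window reproduces the classic 2x2 hand example", {
  # q = [0 0; 0 1], direction 0 deg, distance 1, symmetric counting:
  # horizontal pairs (0,0) and (0,1) -> P = [[0.5, 0.25], [0.25, 0]]
  q <- matrix(c(0L, 0L, 0L, 1L), 2, 2, byrow = TRUE)
  P <- glcm_window(q, direction = 0)
  expect_equal(unname(unclass(P)[1:2, 1:2]),
               matrix(c(0.5, 0.25, 0.25, 0), 2, 2))
  expect_equal(sum(P), 1)
  expect_equal(dimnames(P), list(c("1", "2"), c("1", "2")))
  st <- texture_stats(P)
  expect_equal(st[["Con"]], 0.5)
  expect_equal(st[["Sec"]], 0.5^2 + 2 * 0.25^2)
  expect_equal(st[["Hom"]], 0.5 + 0.25)
  expect_equal(st[["Dis"]], 0.5)
  expect_equal(st[["Ent"]], -(0.5 * log(0.5) + 2 * 0.25 * log(0.25)))
})

test_that("constant window gives Con=0, Hom=1, Sec=1, Ent=0, Cor sentinel 0", {
  q <- matrix(2L, 3, 3)
  st <- texture_stats(glcm_window(q, 90, levels = 4))
  expect_equal(st[["Con"]], 0)
  expect_equal(st[["Hom"]], 1)
  expect_equal(st[["Sec"]], 1)
  expect_equal(st[["Ent"]], 0)
  expect_equal(st[["Cor"]], 0)
  expect_true(isTRUE(attr(st, "degenerate_cor")))
  expect_equal(st[["Mea"]], 3)  # gray level 2 has 1-based label 3
  expect_equal(st[["Var"]], 0)
})

test_that("glcm_window agrees with the naive oracle in all four directions", {
  set.seed(21)
  q <- matrix(sample(0:3, 36, replace = TRUE), 6, 6)
  for (d in c(0, 45, 90, 135)) {
    expect_equal(unname(unclass(glcm_window(q, d, levels = 4))[1:4, 1:4]),
                 oracle_glcm(q, d, levels = 4),
                 tolerance = 1e-12)
  }
  expect_error(glcm_window(matrix(0L, 1, 1), 90), "degenerate window")
  expect_error(glcm_window(q, 30), "direction")
})

test_that("entropy is non-negative and invariant to gray relabeling", {
  set.seed(4)
  q <- matrix(sample(0:7, 64, replace = TRUE), 8, 8)
  st <- texture_stats(glcm_window(q, 0, levels = 8))
  expect_gte(st[["Ent"]], 0)
  qr <- 7L - q   # reverse the gray levels
  str_ <- texture_stats(glcm_window(qr, 0, levels = 8))
  for (f in c("Hom", "Con", "Dis", "Ent", "Sec"))
    expect_equal(st[[f]], str_[[f]], tolerance = 1e-12)
  expect_equal(st[["Cor"]], str_[["Cor"]], tolerance = 1e-12)
})

test_that("band_texture_image matches the per-window oracle and NA borders", {
  set.seed(8)
  q <- matrix(sample(0:5, 25, replace = TRUE), 5, 5)
  imgs <- band_texture_image(q)
  expect_named(imgs, TEXTURE_FEATURES)
  for (f in c("Mea", "Con", "Ent", "Cor")) {
    expect_equal(imgs[[f]], oracle_texture_image(q, f), tolerance = 1e-10)
  }
  border <- imgs$Mea[c(1, 5), ]
  expect_true(all(is.na(border)))
  expect_false(anyNA(imgs$Mea[2:4, 2:4]))
  expect_error(band_texture_image(matrix(0L, 2, 5)), "3x3")
})

test_that("plot_texture yields the 48 named plot-level features", {
  e <- generate_experiment(small_config(seed = 6))
  sc <- e$scenes[[1]]
  d <- plot_texture(sc, canopy_mask(sc), levels = 8)
  expect_equal(nrow(d), 48)
  expect_equal(d$name[1:8], paste0(TEXTURE_FEATURES, 1))
  expect_true(all(d$value[d$feature == "Ent"] >= 0))
  expect_true(all(is.finite(d$value)))
  wide <- texture_wide(transform(d, plot_id = "P001"))
  expect_equal(dim(wide), c(1, 48))
  expect_equal(colnames(wide)[1:9], c(paste0(TEXTURE_FEATURES, 1), "Mea2"))
})

test_that("texture_index identities and error cases", {
  expect_equal(texture_index("NDTI", 3, 1), 0.5)
  expect_equal(texture_index("DTI", 3, 1), 2)
  expect_equal(texture_index("RTI", 3, 1), 3)
  expect_equal(texture_index("RDTI", 2, 4), 0.25)
  expect_equal(texture_index("RATI", 2, 4), 0.75)
  expect_equal(texture_index("NTI", 2, 4), 0)      # T1^2 == T2
  # identical-pair identities
  expect_equal(texture_index("NDTI", 5, 5), 0)
  expect_equal(texture_index("DTI", 5, 5), 0)
  expect_equal(texture_index("RTI", 5, 5), 1)
  expect_equal(texture_index("RDTI", 5, 5), 0)
  expect_error(texture_index("NDTI", 1, -1), "zero denominator")
  expect_error(texture_index("RTI", 1, 0), "zero denominator")
  expect_error(texture_index("RDTI", 0, 1), "zero denominator")
  expect_error(texture_index("DTI", NA, 1), "finite")
})

test_that("search_texture_indices equals brute force, including identical pairs", {
  set.seed(31)
  n <- 20
  smc <- runif(n, 0.1, 0.25)
  tab <- cbind(Mea1 = 5 + smc * 10 + rnorm(n, 0, 0.3),
               Var1 = runif(n, 1, 2),
               Hom2 = runif(n, 0.4, 0.9),
               Con3 = 2 - smc * 4 + rnorm(n, 0, 0.3))
  out <- search_texture_indices(tab, smc)
  ref <- oracle_ti_search(tab, smc)
  expect_equal(out$form, ref$form)
  for (k in seq_len(nrow(out))) {
    expect_equal(abs(out$r[k]), abs(ref$r[k]), tolerance = 1e-10)
    expect_equal(out$n_candidates[k], ref$n_candidates[k])
  }
  # searched values must be reproducible from the named pair
  for (k in seq_len(nrow(out))) {
    v <- texture_index(out$form[k], tab[, out$t1[k]], tab[, out$t2[k]])
    expect_equal(cor(v, smc), out$r[k], tolerance = 1e-12)
  }
})

test_that("search tie-breaking is canonical and degenerate columns are skipped", {
  n <- 12
  smc <- seq(0.1, 0.25, length.out = n)
  x <- smc * 2 + 1
  tab <- cbind(Mea1 = x, Var1 = x, Con1 = rep(1, n))  # duplicate + constant
  out <- search_texture_indices(tab, smc)
  dti <- out[out$form == "DTI", ]
  # all off-diagonal DTI pairs of the duplicates are constant (skipped);
  # winner must come from pairs involving the constant column, with the
  # first-in-canonical-order tie-break
  expect_equal(dti$t1, "Mea1")
  expect_equal(dti$t2, "Con1")
  expect_gt(abs(dti$r), 0.99)
  expect_error(search_texture_indices(tab, rep(0.2, n)), "constant")
  expect_error(search_texture_indices(tab[, 1, drop = FALSE], smc[1:3]),
               "disagree")
})
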