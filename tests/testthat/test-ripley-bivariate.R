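# Cross-K, K_biv, L_biv(r) - r, independence envelopes and LBI.

test_that("cross-K matches hand evaluation on one interior pair", {
  w <- spatial_window(0, 100, 0, 100)
  bp <- bivariate_pattern(point_pattern(50, 50, w, "i"),
                          point_pattern(50, 58, w, "i"))
  k_bs <- k_cross(bp, "bs")
  expect_equal(k_bs$value[k_bs$r < 8], rep(0, 7))
  expect_equal(k_bs$value[k_bs$r >= 8], rep(10000, 233))
  kb <- k_bivariate(bp)
  expect_equal(kb$value[8], 10000)      # (1 * 1e4 + 1 * 1e4) / 2
  expect_equal(round(l_biv_minus_r(kb)$value[10], 2), 46.42)
})

test_that("cross-K equals the literal double-loop estimator", {
  bp <- generate_bivariate(60, 45, "linked", link_distance = 8,
                           linked_fraction = 0.5, seed = 88)
  expect_equal(k_cross(bp, "bs")$value,
               oracle_k_cross(bp$big, bp$small), tolerance = 1e-9)
  expect_equal(k_cross(bp, "sb")$value,
               oracle_k_cross(bp$small, bp$big), tolerance = 1e-9)
})

test_that("toroidal correction makes the directions and label swap exact", {
  bp <- generate_bivariate(50, 70, "independent", seed = 14)
  bs <- k_cross(bp, "bs", correction = "toroidal")$value
  sb <- k_cross(bp, "sb", correction = "toroidal")$value
  expect_equal(bs, sb, tolerance = 1e-12)
  swapped <- bivariate_pattern(bp$small, bp$big)
  expect_equal(k_bivariate(bp, correction = "toroidal")$value,
               k_bivariate(swapped, correction = "toroidal")$value,
               tolerance = 1e-12)
  # isotropic: close but not exact on interior-dominated patterns
  expect_equal(k_bivariate(bp)$value[20:240],
               k_bivariate(swapped)$value[20:240], tolerance = 0.01)
})

test_that("distant species give zero cross-curves; empties error", {
  w <- spatial_window(0, 1000, 0, 1000)
  bp <- bivariate_pattern(point_pattern(c(10, 20), c(10, 10), w, "i"),
                          point_pattern(c(900, 950), c(900, 900), w, "i"))
  expect_equal(k_cross(bp, "bs")$value, rep(0, 240))
  expect_equal(k_cross(bp, "sb")$value, rep(0, 240))
  expect_true(all(diff(k_bivariate(generate_bivariate(
    40, 40, "linked", seed = 2))$value) >= 0))
  empty <- point_pattern(numeric(0), numeric(0), w, "i")
  expect_error(k_cross(bivariate_pattern(point_pattern(1, 1, w, "i"),
                                         empty), "bs"),
               "at least one")
})

test_that("L_biv transform handles the zero and CSR references", {
  r <- default_r_grid()
  expect_equal(l_biv_minus_r(radial_curve(r, rep(0, 240), "K_biv"))$value,
               -r)
  expect_equal(l_biv_minus_r(radial_curve(r, pi * r^2, "K_biv"))$value,
               rep(0, 240))
  expect_error(l_biv_minus_r(radial_curve(r, pi * r^2, "K")), "K_biv")
})

test_that("linked patterns break out of the independence envelope", {
  bp <- generate_bivariate(120, 120, "linked", link_distance = 8,
                           linked_fraction = 1, seed = 19)
  env <- independence_envelope(bp, n_sim = 150, seed = 20)
  obs <- l_biv_minus_r(k_bivariate(bp))
  expect_true(all(obs$value[10:40] > env$upper[10:40]))
  expect_error(independence_envelope(bp, n_sim = 10), "100")
  expect_error(independence_envelope(bp, n_sim = 150,
                                     null_model = "bootstrap"))
})

test_that("both null models reproduce themselves deterministically", {
  bp <- generate_bivariate(40, 40, "independent", seed = 23)
  for (null in c("toroidal_shift", "csr")) {
    e1 <- independence_envelope(bp, n_sim = 100, null_model = null,
                                seed = 31)
    e2 <- independence_envelope(bp, n_sim = 100, null_model = null,
                                seed = 31)
    expect_identical(e1$upper, e2$upper)
    expect_equal(e1$null_model, null)
  }
})

test_that("LBI integrates the standardized curve over 10-110 nm", {
  r <- default_r_grid()
  expect_equal(lbi(radial_curve(r, rep(1, 240), "standardized"))$lbi, 100)
  expect_false(lbi(radial_curve(r, rep(1, 240), "standardized"))$significant)
  expect_equal(lbi(radial_curve(r, rep(0, 240), "standardized"))$lbi, 0)
  expect_equal(lbi(radial_curve(r, rep(2, 240), "standardized"))$lbi, 200)
  expect_true(lbi(radial_curve(r, rep(2, 240), "standardized"))$significant)
  holed <- rep(1, 240); holed[50] <- NA
  expect_error(lbi(radial_curve(r, holed, "standardized")), "undefined")
  short <- radial_curve(1:50, rep(1, 50), "standardized")
  expect_error(lbi(short), "full integration range")
})

test_that("linked image sets are significant and pooled as mean +/- SD", {
  pats <- lapply(1:4, function(i) {
    generate_bivariate(150, 150, "linked", link_distance = 8,
                       linked_fraction = 1, seed = 500 + i,
                       image_id = paste0("img", i))
  })
  study <- bivariate_study(pats, n_sim = 120, seed = 41)
  expect_equal(study$fraction_significant, 1)
  expect_gt(study$mean_lbi, 100)
  vals <- vapply(study$per_image, `[[`, numeric(1), "lbi")
  expect_equal(study$mean_lbi, mean(vals))
  expect_equal(study$sd_lbi, stats::sd(vals))
  expect_error(bivariate_study(list()), "no patterns")
})

test_that("independent image sets stay mostly below the LBI threshold", {
  pats <- lapply(1:10, function(i) {
    generate_bivariate(100, 100, "independent", seed = 700 + i,
                       image_id = paste0("ind", i))
  })
  study <- bivariate_study(pats, n_sim = 199, seed = 43)
  expect_lt(study$mean_lbi, 100)
  expect_lte(study$fraction_significant, 0.2)
})
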