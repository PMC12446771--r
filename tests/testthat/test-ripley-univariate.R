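# Univariate K(r), L(r) - r, CSR envelopes, standardization and Lmax.

test_that("K matches hand evaluation on an interior pair", {
  w <- spatial_window(0, 100, 0, 100)
  p <- point_pattern(c(40, 60), c(50, 50), w, "pair")
  k <- k_function(p)
  expect_equal(k$value[k$r < 20], rep(0, 19))
  expect_equal(k$value[k$r >= 20], rep(5000, 221))
  expect_equal(l_minus_r(k)$value[20], sqrt(5000 / pi) - 20)
  expect_equal(round(l_minus_r(k)$value[20], 3), 19.894)
})

test_that("K is zero when all pairs exceed the grid, and needs n >= 2", {
  w <- spatial_window(0, 1000, 0, 1000)
  p <- point_pattern(c(0, 500, 1000), c(0, 500, 1000), w)
  expect_equal(k_function(p)$value, rep(0, 240))
  expect_error(k_function(point_pattern(5, 5, w)), "at least 2")
})

test_that("optimized K equals the literal double-loop estimator", {
  for (cfg in list(list(seed = 101, n = 50), list(seed = 202, n = 120))) {
    p <- generate_csr(cfg$n, unit_window(), cfg$seed)
    for (corr in c("isotropic", "toroidal")) {
      expect_equal(k_function(p, correction = corr)$value,
                   oracle_k(p, correction = corr),
                   tolerance = 1e-9)
    }
  }
  # clustered pattern with coincident-prone tight spacing
  m <- generate_oligomer_mixture(c(monomer = 30, dimer = 20), spacing = 12,
                                 jitter_sd = 3, seed = 7)
  expect_equal(k_function(m)$value, oracle_k(m), tolerance = 1e-9)
})

test_that("K is non-decreasing in r across the synthetic suite", {
  pats <- list(
    generate_csr(80, seed = 1),
    generate_oligomer_mixture(c(monomer = 40, dimer = 25, trimer = 10),
                              seed = 2),
    generate_thomas(30, 4, 10, seed = 3))
  for (p in pats) {
    for (corr in c("isotropic", "toroidal")) {
      expect_true(all(diff(k_function(p, correction = corr)$value) >= 0))
    }
  }
})

test_that("mean K under CSR tracks pi r^2 with the isotropic correction", {
  w <- unit_window()
  n_sim <- 500
  ks <- withr::with_seed(42, {
    replicate(n_sim, k_function(generate_csr(170, w))$value[c(30, 70, 110)])
  })
  theo <- pi * c(30, 70, 110)^2
  se <- apply(ks, 1, stats::sd) / sqrt(n_sim)
  expect_true(all(abs(rowMeans(ks) - theo) <= 3 * se))
})

test_that("l_minus_r applies the closed-form transform", {
  r <- default_r_grid()
  zero <- radial_curve(r, rep(0, 240), "K")
  expect_equal(l_minus_r(zero)$value, -r)
  csr_exact <- radial_curve(r, pi * r^2, "K")
  expect_equal(l_minus_r(csr_exact)$value, rep(0, 240))
  expect_error(l_minus_r(radial_curve(r, rep(-1, 240), "K")),
               "non-negative")
  expect_error(l_minus_r(radial_curve(r, rep(0, 240), "L_minus_r")),
               "K or K_biv")
})

test_that("CSR envelopes are positive at working radii and seeded", {
  p <- generate_csr(170, unit_window(), seed = 9)
  env <- csr_envelope(p, n_sim = 150, seed = 33)
  expect_true(all(env$upper[10:110] > 0))
  expect_true(all(env$upper[10:110] < 20))   # order a few nm
  env2 <- csr_envelope(p, n_sim = 150, seed = 33)
  expect_identical(env$upper, env2$upper)
  expect_error(csr_envelope(p, n_sim = 50), "100")
})

test_that("the 50th-percentile CSR envelope sits near zero", {
  p <- generate_csr(170, unit_window(), seed = 4)
  env <- csr_envelope(p, n_sim = 200, percentile = 50, seed = 5)
  expect_lt(max(abs(env$upper[20:110])), 1.5)
})

test_that("standardization divides pointwise and flags tiny envelopes", {
  r <- default_r_grid()
  env <- null_envelope(r, c(1e-6, rep(2, 239)), 99, 100, "csr", 1)
  curve <- radial_curve(r, rep(4, 240), "L_minus_r")
  std <- standardize(curve, env)
  expect_true(is.na(std$value[1]))          # below the floor -> undefined
  expect_equal(std$value[-1], rep(2, 239))  # 4 / 2
  zero <- standardize(radial_curve(r, rep(0, 240), "L_minus_r"), env)
  expect_equal(zero$value[-1], rep(0, 239))
  # scale consistency: doubling curve and envelope changes nothing
  env2 <- null_envelope(r, 2 * c(1e-6, rep(2, 239)), 99, 100, "csr", 1)
  std2 <- standardize(radial_curve(r, rep(8, 240), "L_minus_r"), env2)
  expect_equal(std2$value, std$value)
  bad <- null_envelope(1:10 + 100, rep(1, 10), 99, 100, "csr", 1)
  expect_error(standardize(curve, bad), "grids do not match")
})

test_that("Lmax takes the peak with first-attainment tie-break", {
  r <- default_r_grid()
  vals <- rep(0.5, 240)
  vals[24] <- 3.2
  s <- lmax_summary(radial_curve(r, vals, "standardized"))
  expect_equal(s$lmax, 3.2)
  expect_equal(s$r_at_lmax, 24)
  expect_true(s$significant)
  # tie broken toward smaller r
  vals[80] <- 3.2
  expect_equal(lmax_summary(radial_curve(r, vals, "standardized"))$r_at_lmax,
               24)
  # boundary curve: exactly 1.0 is NOT significant (strict inequality)
  ones <- lmax_summary(radial_curve(r, rep(1, 240), "standardized"))
  expect_equal(ones$lmax, 1.0)
  expect_false(ones$significant)
  # search range respected, all-undefined errors
  expect_error(
    lmax_summary(radial_curve(r, rep(NA_real_, 240), "standardized")),
    "no defined")
  out_of_range <- c(rep(9, 9), rep(0.1, 231))
  expect_equal(
    lmax_summary(radial_curve(r, out_of_range, "standardized"))$lmax, 0.1)
})

test_that("strong dimer mixtures are uniformly significant; study pools", {
  pats <- lapply(1:6, function(i) {
    generate_oligomer_mixture(c(monomer = 30, dimer = 60), spacing = 15,
                              jitter_sd = 2, seed = 400 + i,
                              image_id = paste0("img", i))
  })
  study <- univariate_study(pats, n_sim = 150, seed = 77)
  expect_equal(study$fraction_significant, 1)
  expect_equal(study$n_images, 6)
  expect_equal(study$mean_lmax,
               mean(vapply(study$per_image, `[[`, numeric(1), "lmax")))
  expect_gt(study$mean_lmax, 1)
  expect_gt(study$sd_lmax, 0)
})

test_that("a single-image study warns and reports SD 0", {
  p <- generate_csr(60, unit_window(), seed = 3)
  expect_warning(study <- univariate_study(list(p), n_sim = 100, seed = 1),
                 "single image")
  expect_equal(study$sd_lmax, 0)
  expect_equal(study$n_images, 1)
})

test_that("CSR images rarely flag significant clustering", {
  pats <- lapply(1:10, function(i) {
    generate_csr(170, unit_window(), seed = 900 + i,
                 image_id = paste0("csr", i))
  })
  study <- univariate_study(pats, n_sim = 199, seed = 55)
  expect_lte(study$fraction_significant, 0.2)
})
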