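# Two-species coclustering: cross-K, K_biv, L_biv(r) - r, independence
# envelopes and the LBI integral.
#
# Cross estimators (A the shared window area):
#   K_bs(r) = A (n_b n_s)^-1 sum_{i in big} sum_{j in small} w_ij 1(d_ij <= r)
#   K_sb(r) = same with roles swapped (weights centred on small particles)
#   K_biv(r) = (n_b + n_s)^-1 [n_b K_sb(r) + n_s K_bs(r)]
# K_biv equals pi r^2 in expectation when the two populations are
# independent; L_biv(r) - r = sqrt(K_biv/pi) - r.

# Cross geometry: distances from each "centre" point to each "target"
# point, with isotropic weights centred on the centre species, or the
# wrap-around metric with unit weights.
cross_geometry <- function(centre, target, correction, r_max = Inf) {
  if (correction == "toroidal") {
    d <- toroidal_cross_distances(centre$x, centre$y, target$x, target$y,
                                  centre$window)
    w <- matrix(1, nrow(d), ncol(d))
  } else {
    d <- sqrt(outer(centre$x, target$x, "-")^2 +
                outer(centre$y, target$y, "-")^2)
    w <- edge_weight_matrix(centre$x, centre$y, d, centre$window, r_max)
  }
  list(d = d, w = w)
}

#' Bivariate cross K-function
#'
#' Counts particles of one gold size around particles of the other.
#' Direction `"bs"` centres the weighted count on the big (6 nm) particles
#' and counts small (2 nm) neighbours; `"sb"` swaps the roles. With the
#' toroidal correction the two directions coincide exactly.
#'
#' @param pattern A [bivariate_pattern()].
#' @param direction `"bs"` or `"sb"`.
#' @param r_grid Distance grid in nm.
#' @param correction As [k_function()].
#' @return A [radial_curve()] of kind `"K"` (nm^2), non-decreasing in r.
#' @export
k_cross <- function(pattern, direction = c("bs", "sb"),
                    r_grid = default_r_grid(),
                    correction = c("isotropic", "toroidal")) {
  stopifnot(inherits(pattern, "bivariate_pattern"))
  direction <- match.arg(direction)
  correction <- match.arg(correction)
  if (pattern$big$n < 1 || pattern$small$n < 1) {
    stop("both species need at least one particle", call. = FALSE)
  }
  geo <- if (direction == "bs") {
    cross_geometry(pattern$big, pattern$small, correction, max(r_grid))
  } else {
    cross_geometry(pattern$small, pattern$big, correction, max(r_grid))
  }
  k <- pattern$window$area / (pattern$big$n * pattern$small$n) *
    pair_sum_on_grid(as.vector(geo$d), as.vector(geo$w), r_grid)
  radial_curve(r_grid, k, "K")
}

#' Combined bivariate K-function
#'
#' Count-weighted combination of the two cross K-functions,
#' `K_biv(r) = (n_b + n_s)^-1 [n_b K_sb(r) + n_s K_bs(r)]`.
#'
#' @inheritParams k_cross
#' @return A [radial_curve()] of kind `"K_biv"`.
#' @export
k_bivariate <- function(pattern, r_grid = default_r_grid(),
                        correction = c("isotropic", "toroidal")) {
  correction <- match.arg(correction)
  k_bs <- k_cross(pattern, "bs", r_grid, correction)
  k_sb <- k_cross(pattern, "sb", r_grid, correction)
  nb <- pattern$big$n
  ns <- pattern$small$n
  radial_curve(r_grid, (nb * k_sb$value + ns * k_bs$value) / (nb + ns),
               "K_biv")
}

#' Bivariate L_biv(r) - r transform
#'
#' @param curve A [radial_curve()] of kind `"K_biv"`.
#' @return A [radial_curve()] of kind `"L_biv_minus_r"`. Zero is the
#'   independence reference; persistently negative values point toward
#'   spatial segregation of the two populations.
#' @export
l_biv_minus_r <- function(curve) {
  stopifnot(inherits(curve, "radial_curve"))
  if (curve$kind != "K_biv") {
    stop("l_biv_minus_r expects a K_biv curve", call. = FALSE)
  }
  l_minus_r(curve)
}

#' Monte Carlo independence envelope for L_biv(r) - r
#'
#' Simulates the null hypothesis that the two gold populations are
#' spatially independent. The default null applies a random toroidal shift
#' to the small-gold pattern (uniform shift vector with wrap-around, big
#' gold fixed): each species keeps its own internal clustering while the
#' cross-correlation is destroyed. The `"csr"` null instead resamples both
#' populations uniformly.
#'
#' @param pattern A [bivariate_pattern()].
#' @param n_sim Number of simulations (>= 100; default 1000).
#' @param percentile Upper percentile (default 95).
#' @param null_model `"toroidal_shift"` (default) or `"csr"`.
#' @param seed Integer seed.
#' @param r_grid Distance grid in nm.
#' @param correction As [k_function()].
#' @return A [null_envelope()].
#' @export
independence_envelope <- function(pattern, n_sim = 1000, percentile = 95,
                                  null_model = c("toroidal_shift", "csr"),
                                  seed = NULL, r_grid = default_r_grid(),
                                  correction = c("isotropic", "toroidal")) {
  stopifnot(inherits(pattern, "bivariate_pattern"))
  null_model <- match.arg(null_model)
  correction <- match.arg(correction)
  if (n_sim < 100) {
    stop("at least 100 simulations are required (n_sim >= 100)",
         call. = FALSE)
  }
  if (pattern$big$n < 1 || pattern$small$n < 1) {
    stop("both species need at least one particle", call. = FALSE)
  }
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  win <- pattern$window
  sides <- window_sides(win)
  sims <- withr::with_seed(seed, {
    t(replicate(n_sim, {
      null_pat <- if (null_model == "toroidal_shift") {
        sx <- win$x_min +
          (pattern$small$x - win$x_min + stats::runif(1, 0, sides[1])) %%
          sides[1]
        sy <- win$y_min +
          (pattern$small$y - win$y_min + stats::runif(1, 0, sides[2])) %%
          sides[2]
        bivariate_pattern(
          pattern$big,
          point_pattern(sx, sy, win, pattern$image_id))
      } else {
        bivariate_pattern(
          generate_csr(pattern$big$n, win, seed = NULL,
                       image_id = pattern$image_id),
          generate_csr(pattern$small$n, win, seed = NULL,
                       image_id = pattern$image_id))
      }
      l_biv_minus_r(k_bivariate(null_pat, r_grid, correction))$value
    }))
  })
  null_envelope(r_grid, pointwise_upper(sims, percentile),
                percentile, n_sim, null_model, seed)
}

#' LBI coclustering summary
#'
#' Integrates the envelope-standardized L_biv(r) - r curve over the fixed
#' 10-110 nm range by the trapezoidal rule on the 1-nm grid; a curve lying
#' exactly on the 95% envelope integrates to 100, so LBI values above 100
#' indicate statistically meaningful coclustering (heterodimerization
#' readout). Segregation drives LBI negative.
#'
#' @param standardized A [radial_curve()] of kind `"standardized"`, defined
#'   on the whole integration range (undefined points raise an error rather
#'   than being silently interpolated).
#' @param r_min,r_max Integration range in nm (default 10-110).
#' @param image_id Label carried into the summary.
#' @return A list of class `lbi_summary` with `lbi`, `significant`
#'   (`lbi > 100`), `image_id`, `r_min`, `r_max`.
#' @export
lbi <- function(standardized, r_min = 10, r_max = 110, image_id = "image") {
  stopifnot(inherits(standardized, "radial_curve"))
  if (standardized$kind != "standardized") {
    stop("lbi expects a standardized curve", call. = FALSE)
  }
  in_range <- standardized$r >= r_min & standardized$r <= r_max
  if (abs(sum(in_range) - (r_max - r_min + 1)) > 0) {
    stop("curve does not cover the full integration range", call. = FALSE)
  }
  vals <- standardized$value[in_range]
  if (any(is.na(vals))) {
    stop("standardized curve undefined inside the integration range",
         call. = FALSE)
  }
  integral <- sum(vals) - (vals[1] + vals[length(vals)]) / 2
  structure(
    list(lbi = integral, significant = integral > 100,
         image_id = image_id, r_min = r_min, r_max = r_max),
    class = "lbi_summary"
  )
}

#' @export
print.lbi_summary <- function(x, ...) {
  cat(sprintf("LBI = %.1f over %g-%g nm (%s) [%s]\n", x$lbi, x$r_min,
              x$r_max,
              if (x$significant) "significant coclustering" else
                "not significant", x$image_id))
  invisible(x)
}

#' Bivariate coclustering study across images
#'
#' Analyzes each sheet with its own image-matched independence envelope and
#' pools per-image LBI values as mean +/- SD, retaining per-image records
#' (each point one 1 um^2 image).
#'
#' @param patterns List of [bivariate_pattern()] objects.
#' @param n_sim,percentile,null_model,seed,r_grid,correction Passed to
#'   [independence_envelope()]; per-image seeds derived from `seed`.
#' @param r_min,r_max LBI integration range.
#' @return A list of class `bivariate_study` with `per_image` (list of
#'   `lbi_summary`), `mean_lbi`, `sd_lbi`, `n_images`,
#'   `fraction_significant`.
#' @export
bivariate_study <- function(patterns, n_sim = 1000, percentile = 95,
                            null_model = c("toroidal_shift", "csr"),
                            seed = NULL, r_grid = default_r_grid(),
                            correction = c("isotropic", "toroidal"),
                            r_min = 10, r_max = 110) {
  null_model <- match.arg(null_model)
  correction <- match.arg(correction)
  if (!length(patterns)) stop("no patterns supplied", call. = FALSE)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  seeds <- derive_seeds(seed, length(patterns))
  per_image <- vector("list", length(patterns))
  for (i in seq_along(patterns)) {
    p <- patterns[[i]]
    per_image[[i]] <- tryCatch({
      env <- independence_envelope(p, n_sim, percentile, null_model,
                                   seeds[i], r_grid, correction)
      std <- standardize(l_biv_minus_r(k_bivariate(p, r_grid, correction)),
                         env)
      lbi(std, r_min, r_max, p$image_id)
    }, error = function(e) {
      stop(sprintf("image '%s': %s", p$image_id, conditionMessage(e)),
           call. = FALSE)
    })
  }
  vals <- vapply(per_image, `[[`, numeric(1), "lbi")
  structure(
    list(per_image = per_image,
         mean_lbi = mean(vals),
         sd_lbi = if (length(vals) > 1) stats::sd(vals) else 0,
         n_images = length(vals),
         fraction_significant =
           mean(vapply(per_image, `[[`, logical(1), "significant")),
         seed = seed),
    class = "bivariate_study"
  )
}

#' @export
print.bivariate_study <- function(x, ...) {
  cat(sprintf(
    "bivariate study: %d images, LBI = %.0f +/- %.0f, %d%% significant\n",
    x$n_images, x$mean_lbi, x$sd_lbi, round(100 * x$fraction_significant)))
  invisible(x)
}
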