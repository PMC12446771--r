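# Univariate nanoclustering: K(r), L(r) - r, CSR envelopes, Lmax.
#
# Estimator (per-image):
#   K(r) = A n^-2 sum_{i != j} w_ij 1(||x_i - x_j|| <= r)
# with A the window area, n the particle count and w_ij the edge-correction
# weight of the circle centred at x_i with radius ||x_i - x_j||. L(r) - r =
# sqrt(K(r) / pi) - r is 0 in expectation under complete spatial randomness
# (CSR), positive for clustering.

# Step-function evaluation of a weighted pair sum on a grid: sum of w over
# pairs with d <= r, for each grid r. Sorting once beats an O(n^2 * |grid|)
# scan.
pair_sum_on_grid <- function(d, w, r_grid) {
  if (!length(d)) return(numeric(length(r_grid)))
  ord <- order(d)
  cw <- cumsum(w[ord])
  idx <- findInterval(r_grid, d[ord])
  ifelse(idx == 0, 0, cw[pmax(idx, 1)])
}

#' Univariate Ripley K-function
#'
#' Estimates K(r), the expected number of further particles within distance
#' r of a typical particle scaled by intensity, on the 1-nm grid. Equals
#' pi r^2 in expectation under complete spatial randomness.
#'
#' @param pattern A [point_pattern()] with at least 2 points.
#' @param r_grid Distance grid in nm (default [default_r_grid()], 1-240 nm).
#' @param correction `"isotropic"` (Ripley's unbiased weight, default) or
#'   `"toroidal"` (wrap-around metric; exactly symmetric weights).
#' @return A [radial_curve()] of kind `"K"` (units nm^2), non-decreasing
#'   in r.
#' @export
k_function <- function(pattern, r_grid = default_r_grid(),
                       correction = c("isotropic", "toroidal")) {
  stopifnot(inherits(pattern, "point_pattern"))
  correction <- match.arg(correction)
  if (pattern$n < 2) {
    stop("K-function requires at least 2 points", call. = FALSE)
  }
  geom <- pair_geometry(pattern, correction, r_max = max(r_grid))
  off <- !diag(pattern$n)
  k <- pattern$window$area / pattern$n^2 *
    pair_sum_on_grid(geom$d[off], geom$w[off], r_grid)
  radial_curve(r_grid, k, "K")
}

#' Variance-stabilized L(r) - r transform
#'
#' @param curve A [radial_curve()] of kind `"K"` or `"K_biv"`.
#' @return A [radial_curve()] of kind `"L_minus_r"` (or `"L_biv_minus_r"`)
#'   with value `sqrt(K(r)/pi) - r` at each grid point.
#' @export
l_minus_r <- function(curve) {
  stopifnot(inherits(curve, "radial_curve"))
  if (!curve$kind %in% c("K", "K_biv")) {
    stop("l_minus_r expects a K or K_biv curve", call. = FALSE)
  }
  if (any(curve$value < 0, na.rm = TRUE)) {
    stop("K values must be non-negative", call. = FALSE)
  }
  radial_curve(curve$r, sqrt(curve$value / pi) - curve$r,
               if (curve$kind == "K") "L_minus_r" else "L_biv_minus_r")
}

# Pointwise upper quantile across simulated curves (rows = simulations),
# linear interpolation between order statistics (R's default type 7).
pointwise_upper <- function(sim_matrix, percentile) {
  apply(sim_matrix, 2, stats::quantile, probs = percentile / 100,
        names = FALSE, type = 7)
}

#' Monte Carlo CSR confidence envelope for L(r) - r
#'
#' Simulates complete spatial randomness (n points uniform in the pattern's
#' window, matching the observed count), computes L(r) - r for each
#' simulation and returns the pointwise upper-percentile curve. Observed
#' curves standardized against this envelope read 1.0 at the significance
#' boundary.
#'
#' @param pattern The observed [point_pattern()] (supplies `n` and window).
#' @param n_sim Number of simulations (>= 100; default 1000).
#' @param percentile Upper percentile (default 99).
#' @param seed Integer seed (reproducibility; recorded in the envelope).
#' @param r_grid Distance grid in nm.
#' @param correction Edge correction, as [k_function()].
#' @return A [null_envelope()].
#' @export
csr_envelope <- function(pattern, n_sim = 1000, percentile = 99,
                         seed = NULL, r_grid = default_r_grid(),
                         correction = c("isotropic", "toroidal")) {
  stopifnot(inherits(pattern, "point_pattern"))
  correction <- match.arg(correction)
  if (pattern$n < 2) {
    stop("envelope requires at least 2 points", call. = FALSE)
  }
  if (n_sim < 100) {
    stop("at least 100 simulations are required (n_sim >= 100)",
         call. = FALSE)
  }
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  sims <- withr::with_seed(seed, {
    t(replicate(n_sim, {
      sim <- generate_csr(pattern$n, pattern$window, seed = NULL)
      l_minus_r(k_function(sim, r_grid, correction))$value
    }))
  })
  null_envelope(r_grid, pointwise_upper(sims, percentile),
                percentile, n_sim, "csr", seed)
}

#' Standardize a curve against a null envelope
#'
#' Divides the curve pointwise by the envelope's upper-percentile values,
#' so that 1.0 marks the confidence boundary at every r. Grid points where
#' the envelope lies below the stabilization floor `eps` (the envelope
#' approaches 0 as r -> 0, where ratios would explode) are flagged
#' undefined (`NA`) and excluded from downstream summaries.
#'
#' @param curve A [radial_curve()] (raw L(r) - r or L_biv(r) - r).
#' @param envelope A [null_envelope()] on the same grid.
#' @param eps Stabilization floor in nm (default `1e-3`).
#' @return A [radial_curve()] of kind `"standardized"`.
#' @export
standardize <- function(curve, envelope, eps = 1e-3) {
  stopifnot(inherits(curve, "radial_curve"),
            inherits(envelope, "null_envelope"))
  if (length(curve$r) != length(envelope$r) ||
      any(abs(curve$r - envelope$r) > 1e-9)) {
    stop("curve and envelope grids do not match", call. = FALSE)
  }
  ok <- envelope$upper >= eps
  value <- ifelse(ok, curve$value / envelope$upper, NA_real_)
  radial_curve(curve$r, value, "standardized")
}

#' Lmax clustering summary
#'
#' Peak of the envelope-standardized L(r) - r curve over the search range.
#' Values strictly greater than 1.0 (the standardized confidence boundary)
#' indicate statistically meaningful nanoclustering.
#'
#' @param standardized A [radial_curve()] of kind `"standardized"`.
#' @param r_min,r_max Search range in nm (default 10-240 nm; the lower
#'   bound skips the numerically unstable small-r region).
#' @param image_id Label carried into the summary.
#' @return A list of class `lmax_summary` with `lmax`, `r_at_lmax`
#'   (smallest r attaining the peak), `significant` (`lmax > 1`) and
#'   `image_id`.
#' @export
lmax_summary <- function(standardized, r_min = 10, r_max = 240,
                         image_id = "image") {
  stopifnot(inherits(standardized, "radial_curve"))
  if (standardized$kind != "standardized") {
    stop("lmax_summary expects a standardized curve", call. = FALSE)
  }
  in_range <- standardized$r >= r_min & standardized$r <= r_max
  vals <- standardized$value[in_range]
  rs <- standardized$r[in_range]
  if (all(is.na(vals))) {
    stop("no defined grid points in the Lmax search range", call. = FALSE)
  }
  peak <- max(vals, na.rm = TRUE)
  r_at <- rs[which(vals == peak)[1]]   # ties break toward smaller r
  structure(
    list(lmax = peak, r_at_lmax = r_at, significant = peak > 1.0,
         image_id = image_id),
    class = "lmax_summary"
  )
}

#' @export
print.lmax_summary <- function(x, ...) {
  cat(sprintf("Lmax = %.3f at r = %g nm (%s) [%s]\n", x$lmax, x$r_at_lmax,
              if (x$significant) "significant clustering" else
                "not significant", x$image_id))
  invisible(x)
}

#' Univariate nanoclustering study across images
#'
#' Analyzes each membrane sheet independently -- its own CSR envelope
#' matched to its particle count and window -- and pools the per-image Lmax
#' summaries as mean +/- SD, mirroring the per-sheet-then-combine design
#' used for immunogold EM data.
#'
#' @param patterns List of [point_pattern()] objects.
#' @param n_sim,percentile,seed,r_grid,correction Passed to
#'   [csr_envelope()]; per-image seeds are derived from `seed`.
#' @param r_min,r_max Lmax search range, as [lmax_summary()].
#' @return A list of class `univariate_study` with `per_image` (list of
#'   `lmax_summary`), `mean_lmax`, `sd_lmax`, `n_images`,
#'   `fraction_significant`.
#' @export
univariate_study <- function(patterns, n_sim = 1000, percentile = 99,
                             seed = NULL, r_grid = default_r_grid(),
                             correction = c("isotropic", "toroidal"),
                             r_min = 10, r_max = 240) {
  correction <- match.arg(correction)
  if (!length(patterns)) stop("no patterns supplied", call. = FALSE)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  seeds <- derive_seeds(seed, length(patterns))
  per_image <- vector("list", length(patterns))
  for (i in seq_along(patterns)) {
    p <- patterns[[i]]
    res <- tryCatch({
      env <- csr_envelope(p, n_sim, percentile, seeds[i], r_grid, correction)
      std <- standardize(l_minus_r(k_function(p, r_grid, correction)), env)
      lmax_summary(std, r_min, r_max, p$image_id)
    }, error = function(e) {
      stop(sprintf("image '%s': %s", p$image_id, conditionMessage(e)),
           call. = FALSE)
    })
    per_image[[i]] <- res
  }
  lmax <- vapply(per_image, `[[`, numeric(1), "lmax")
  if (length(lmax) == 1) {
    warning("single image: SD of Lmax reported as 0", call. = FALSE)
  }
  structure(
    list(per_image = per_image,
         mean_lmax = mean(lmax),
         sd_lmax = if (length(lmax) > 1) stats::sd(lmax) else 0,
         n_images = length(lmax),
         fraction_significant =
           mean(vapply(per_image, `[[`, logical(1), "significant")),
         seed = seed),
    class = "univariate_study"
  )
}

#' @export
print.univariate_study <- function(x, ...) {
  cat(sprintf(
    "univariate study: %d images, Lmax = %.2f +/- %.2f, %d%% significant\n",
    x$n_images, x$mean_lmax, x$sd_lmax,
    round(100 * x$fraction_significant)))
  invisible(x)
}

# Independent per-task seeds below 2^31, derived reproducibly from one seed.
derive_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1, n))
}
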