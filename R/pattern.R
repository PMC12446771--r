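#' Rectangular observation window
#'
#' Construct the rectangular observation window of a membrane sheet. All
#' coordinates are in nanometres; the canonical analysis window is the
#' 1 um^2 sheet, i.e. `spatial_window(0, 1000, 0, 1000)`.
#'
#' @param x_min,x_max,y_min,y_max Window bounds in nm.
#' @return An object of class `spatial_window` with fields `x_min`, `x_max`,
#'   `y_min`, `y_max` and the derived `area` in nm^2.
#' @examples
#' w <- spatial_window(0, 1000, 0, 1000)
#' w$area  # 1e6 nm^2 == 1 um^2
#' @export
spatial_window <- function(x_min, x_max, y_min, y_max) {
  vals <- c(x_min = x_min, x_max = x_max, y_min = y_min, y_max = y_max)
  if (any(!is.finite(vals))) {
    stop("window bounds must be finite", call. = FALSE)
  }
  if (x_max <= x_min || y_max <= y_min) {
    stop("window must have positive extent: x_max > x_min and y_max > y_min",
         call. = FALSE)
  }
  structure(
    list(x_min = x_min, x_max = x_max, y_min = y_min, y_max = y_max,
         area = (x_max - x_min) * (y_max - y_min)),
    class = "spatial_window"
  )
}

#' @export
print.spatial_window <- function(x, ...) {
  cat(sprintf("spatial window [%g, %g] x [%g, %g] nm (area %g nm^2)\n",
              x$x_min, x$x_max, x$y_min, x$y_max, x$area))
  invisible(x)
}

window_sides <- function(window) {
  c(window$x_max - window$x_min, window$y_max - window$y_min)
}

#' Gold-particle point pattern
#'
#' A set of gold-nanoparticle coordinates observed on one membrane sheet.
#'
#' @param x,y Numeric coordinate vectors in nm.
#' @param window A [spatial_window()]. If `NULL`, the axis-aligned bounding
#'   box of the points is used (users should supply the true sheet window:
#'   a bounding-box window underestimates the sampled area).
#' @param image_id Text label of the source image.
#' @return An object of class `point_pattern` with fields `x`, `y`, `n`,
#'   `window`, `image_id`.
#' @export
point_pattern <- function(x, y, window = NULL, image_id = "image") {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) {
    stop("x and y must have equal length", call. = FALSE)
  }
  if (length(x) && any(!is.finite(x) | !is.finite(y))) {
    stop("coordinates must be finite", call. = FALSE)
  }
  if (is.null(window)) {
    if (!length(x)) {
      stop("cannot infer a window from an empty pattern; supply one",
           call. = FALSE)
    }
    window <- spatial_window(min(x), max(x) + max(diff(range(x)) == 0),
                             min(y), max(y) + max(diff(range(y)) == 0))
  }
  stopifnot(inherits(window, "spatial_window"))
  tol <- 1e-9
  inside <- x >= window$x_min - tol & x <= window$x_max + tol &
    y >= window$y_min - tol & y <= window$y_max + tol
  if (!all(inside)) {
    stop(sprintf("%d point(s) fall outside the window", sum(!inside)),
         call. = FALSE)
  }
  structure(
    list(x = x, y = y, n = length(x), window = window,
         image_id = as.character(image_id)),
    class = "point_pattern"
  )
}

#' @export
print.point_pattern <- function(x, ...) {
  cat(sprintf("point pattern '%s': n = %d in %g x %g nm window\n",
              x$image_id, x$n,
              x$window$x_max - x$window$x_min,
              x$window$y_max - x$window$y_min))
  invisible(x)
}

#' Two-species (big/small gold) pattern
#'
#' Pairs the two gold-size populations labelling two distinct proteins on
#' one sheet, e.g. 6 nm ("big") and 2 nm ("small") conjugates.
#'
#' @param big,small [point_pattern()] objects sharing one window and image.
#' @return An object of class `bivariate_pattern` with fields `big`, `small`,
#'   `window`, `image_id`.
#' @export
bivariate_pattern <- function(big, small) {
  stopifnot(inherits(big, "point_pattern"), inherits(small, "point_pattern"))
  if (!identical(unclass(big$window), unclass(small$window))) {
    stop("both species must share the same window", call. = FALSE)
  }
  if (!identical(big$image_id, small$image_id)) {
    stop("both species must share the same image_id", call. = FALSE)
  }
  structure(
    list(big = big, small = small, window = big$window,
         image_id = big$image_id),
    class = "bivariate_pattern"
  )
}

#' @export
print.bivariate_pattern <- function(x, ...) {
  cat(sprintf("bivariate pattern '%s': n_b = %d big, n_s = %d small\n",
              x$image_id, x$big$n, x$small$n))
  invisible(x)
}

#' Radial summary curve
#'
#' A function of distance r on the 1-nm analysis grid; holds K(r),
#' L(r) - r, their bivariate analogues, or an envelope-standardized curve.
#' Undefined grid points (where an envelope fell below the stabilization
#' floor) are stored as `NA`.
#'
#' @param r Strictly increasing distance grid in nm with unit spacing.
#' @param value One value per grid point (`NA` marks undefined points).
#' @param kind One of `"K"`, `"L_minus_r"`, `"K_biv"`, `"L_biv_minus_r"`,
#'   `"standardized"`.
#' @return An object of class `radial_curve`.
#' @export
radial_curve <- function(r, value,
                         kind = c("K", "L_minus_r", "K_biv",
                                  "L_biv_minus_r", "standardized")) {
  kind <- match.arg(kind)
  r <- as.numeric(r)
  if (length(r) < 2 || any(abs(diff(r) - 1) > 1e-9)) {
    stop("r must be an increasing grid with 1-nm spacing", call. = FALSE)
  }
  if (length(value) != length(r)) {
    stop("value must match the grid length", call. = FALSE)
  }
  if (any(is.infinite(value))) {
    stop("curve values must be finite or NA", call. = FALSE)
  }
  structure(list(r = r, value = as.numeric(value), kind = kind),
            class = "radial_curve")
}

#' @export
print.radial_curve <- function(x, ...) {
  cat(sprintf("radial curve (%s): r = %g..%g nm, %d undefined points\n",
              x$kind, min(x$r), max(x$r), sum(is.na(x$value))))
  invisible(x)
}

#' @export
as.data.frame.radial_curve <- function(x, ...) {
  data.frame(r_nm = x$r, value = x$value)
}

#' Default analysis grid: 1 to 240 nm in 1-nm increments
#' @return Integer-valued numeric vector `1:240`.
#' @export
default_r_grid <- function() as.numeric(1:240)

#' Monte Carlo null envelope
#'
#' Pointwise upper-percentile curve of a spatial summary under a null model,
#' estimated from seeded simulations. Used to standardize observed
#' L(r) - r (99% CI, complete spatial randomness null) and L_biv(r) - r
#' (95% CI, independence null) curves.
#'
#' @param r Distance grid (as [radial_curve()]).
#' @param upper Pointwise upper-percentile values.
#' @param percentile Upper percentile used (99 or 95).
#' @param n_sim Number of simulations (>= 100).
#' @param null_model `"csr"` or `"toroidal_shift"`.
#' @param seed Integer seed used for the simulations.
#' @return An object of class `null_envelope`.
#' @export
null_envelope <- function(r, upper, percentile, n_sim, null_model, seed) {
  if (n_sim < 100) {
    stop("at least 100 simulations are required for a stable envelope",
         call. = FALSE)
  }
  if (!null_model %in% c("csr", "toroidal_shift")) {
    stop("null_model must be 'csr' or 'toroidal_shift'", call. = FALSE)
  }
  structure(
    list(r = as.numeric(r), upper = as.numeric(upper),
         percentile = percentile, n_sim = as.integer(n_sim),
         null_model = null_model, seed = seed),
    class = "null_envelope"
  )
}

#' @export
print.null_envelope <- function(x, ...) {
  cat(sprintf(
    "null envelope: %g%% upper CI, %d sims (%s null, seed %s)\n",
    x$percentile, x$n_sim, x$null_model, format(x$seed)))
  invisible(x)
}
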