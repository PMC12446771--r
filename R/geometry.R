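#' Pairwise Euclidean distance table
#'
#' @param pattern A [point_pattern()].
#' @return An `n x n` symmetric matrix of Euclidean distances in nm with a
#'   zero diagonal. Coincident points (legal: two particles can project to
#'   the same position) give off-diagonal zeros.
#' @export
pairwise_distances <- function(pattern) {
  stopifnot(inherits(pattern, "point_pattern"))
  if (pattern$n == 0) return(matrix(numeric(0), 0, 0))
  as.matrix(stats::dist(cbind(pattern$x, pattern$y)))
}

# Toroidal (wrap-around) distance matrix between two coordinate sets that
# share one window. Used by the toroidal correction, under which every pair
# weight is 1 and the metric itself removes the edge effect.
toroidal_cross_distances <- function(x1, y1, x2, y2, window) {
  sides <- window_sides(window)
  dx <- abs(outer(x1, x2, "-"))
  dx <- pmin(dx, sides[1] - dx)
  dy <- abs(outer(y1, y2, "-"))
  dy <- pmin(dy, sides[2] - dy)
  sqrt(dx^2 + dy^2)
}

toroidal_distances <- function(pattern) {
  toroidal_cross_distances(pattern$x, pattern$y, pattern$x, pattern$y,
                           pattern$window)
}

#' Ripley isotropic edge-correction weight
#'
#' Weight `w = 1 / p` where `p` is the fraction of the circle of radius
#' `distance`, centred at `point`, lying inside the rectangular window.
#' Pairs whose circle leaves the window are up-weighted to compensate for
#' neighbours that fall outside the observed sheet, making the K estimator
#' unbiased under complete spatial randomness.
#'
#' The closed form combines, by inclusion-exclusion, the arcs cut off by
#' each of the four window edges and the overlaps at the four corners; it
#' is exact whenever the circle does not engulf an entire window side
#' (always the case on the 1-240 nm grid in windows at least 480 nm wide).
#'
#' @param x,y Coordinates of the circle centre (vectorized, recycled).
#' @param distance Circle radius in nm (> 0; vectorized).
#' @param window A [spatial_window()].
#' @return Numeric weights, each >= 1.
#' @export
edge_weight <- function(x, y, distance, window) {
  stopifnot(inherits(window, "spatial_window"))
  if (any(distance <= 0)) {
    stop("distance must be positive", call. = FALSE)
  }
  m <- max(length(x), length(y), length(distance))
  x <- rep_len(x, m); y <- rep_len(y, m); r <- rep_len(distance, m)

  dl <- x - window$x_min   # distance to left edge
  dr <- window$x_max - x
  db <- y - window$y_min
  dt <- window$y_max - y

  # exterior arc for a single straight edge at perpendicular distance d
  edge_arc <- function(d, r) ifelse(d < r, 2 * acos(pmin(d / r, 1)), 0)
  # overlap of the two edge arcs meeting at a corner with leg distances a, b
  corner_arc <- function(a, b, r) {
    ifelse(a^2 + b^2 < r^2,
           acos(pmin(a / r, 1)) + acos(pmin(b / r, 1)) - pi / 2,
           0)
  }

  exterior <- edge_arc(dl, r) + edge_arc(dr, r) +
    edge_arc(db, r) + edge_arc(dt, r) -
    corner_arc(dl, db, r) - corner_arc(dl, dt, r) -
    corner_arc(dr, db, r) - corner_arc(dr, dt, r)

  inside_frac <- 1 - exterior / (2 * pi)
  if (any(inside_frac <= 0)) {
    stop("edge correction undefined: circle almost entirely outside window",
         call. = FALSE)
  }
  1 / inside_frac
}

# Weight matrix for the pair sum: entry (i, j) is the isotropic weight of
# the circle centred at point i with radius d[i, j]. Diagonal is unused by
# the estimators and set to 1. Pairs beyond r_max never enter the
# indicator sum on the analysis grid, so their weights are left at 1
# rather than evaluating the correction at radii where it degenerates.
edge_weight_matrix <- function(x, y, d, window, r_max = Inf) {
  w <- matrix(1, nrow(d), ncol(d))
  off <- d > 0 & d <= r_max
  if (any(off)) {
    idx <- which(off, arr.ind = TRUE)
    w[off] <- edge_weight(x[idx[, 1]], y[idx[, 1]], d[off], window)
  }
  w
}

# Distances and pair weights for a pattern under the requested correction.
# Returns list(d, w): n x n matrices. For "toroidal" the metric wraps and
# all weights are 1 (exactly symmetric); for "isotropic" the metric is
# Euclidean and w[i, j] is the Ripley weight centred at point i.
pair_geometry <- function(pattern, correction = c("isotropic", "toroidal"),
                          r_max = Inf) {
  correction <- match.arg(correction)
  if (correction == "toroidal") {
    d <- toroidal_distances(pattern)
    w <- matrix(1, pattern$n, pattern$n)
  } else {
    d <- pairwise_distances(pattern)
    w <- edge_weight_matrix(pattern$x, pattern$y, d, pattern$window, r_max)
  }
  list(d = d, w = w)
}
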