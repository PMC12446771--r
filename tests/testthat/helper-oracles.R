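# Independent brute-force oracles: literal evaluations of the displayed
# estimators, kept free of the package's optimized code paths
# (pair_sum_on_grid etc.) so the two routes stay independent.

unit_window <- function() spatial_window(0, 1000, 0, 1000)

# literal double-loop K(r) = A n^-2 sum_{i != j} w_ij 1(d_ij <= r)
oracle_k <- function(pattern, r_grid = default_r_grid(),
                     correction = "isotropic") {
  n <- pattern$n
  acc <- numeric(length(r_grid))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (correction == "toroidal") {
        sides <- c(pattern$window$x_max - pattern$window$x_min,
                   pattern$window$y_max - pattern$window$y_min)
        dx <- abs(pattern$x[i] - pattern$x[j])
        dy <- abs(pattern$y[i] - pattern$y[j])
        d <- sqrt(min(dx, sides[1] - dx)^2 + min(dy, sides[2] - dy)^2)
        w <- 1
      } else {
        d <- sqrt((pattern$x[i] - pattern$x[j])^2 +
                    (pattern$y[i] - pattern$y[j])^2)
        w <- if (d > 0 && d <= max(r_grid)) {
          edge_weight(pattern$x[i], pattern$y[i], d, pattern$window)
        } else 1
      }
      acc <- acc + w * (d <= r_grid)
    }
  }
  pattern$window$area / n^2 * acc
}

# literal cross-K with weights centred on the `centre` species
oracle_k_cross <- function(centre, target, r_grid = default_r_grid()) {
  acc <- numeric(length(r_grid))
  for (i in seq_len(centre$n)) {
    for (j in seq_len(target$n)) {
      d <- sqrt((centre$x[i] - target$x[j])^2 +
                  (centre$y[i] - target$y[j])^2)
      w <- if (d > 0 && d <= max(r_grid)) {
        edge_weight(centre$x[i], centre$y[i], d, centre$window)
      } else 1
      acc <- acc + w * (d <= r_grid)
    }
  }
  centre$window$area / (centre$n * target$n) * acc
}

# numeric arc-sampling oracle for the isotropic edge weight
oracle_edge_weight <- function(x, y, r, window, n_angles = 1e5) {
  th <- seq(0, 2 * pi, length.out = n_angles)
  px <- x + r * cos(th)
  py <- y + r * sin(th)
  inside <- px >= window$x_min & px <= window$x_max &
    py >= window$y_min & py <= window$y_max
  1 / mean(inside)
}

# exhaustive membership enumeration for Venn regions
oracle_venn3 <- function(a, b, c3) {
  universe <- unique(c(a, b, c3))
  tab <- table(factor(
    vapply(universe, function(el) {
      paste0(as.integer(el %in% a), as.integer(el %in% b),
             as.integer(el %in% c3))
    }, character(1)),
    levels = c("100", "010", "001", "110", "101", "011", "111")))
  as.integer(tab)
}
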