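# Local L(r) - r analysis: per-particle clustering curves and the
# monomer / dimer / higher-order-oligomer partition.

#' Per-particle local L(r) - r curves
#'
#' The local K-function of particle i,
#' `K_i(r) = A (n - 1)^-1 sum_{j != i} w_ij 1(d_ij <= r)`,
#' measures how crowded particle i's own neighbourhood is; its
#' `L_i(r) - r` transform is the per-particle analogue of the global
#' clustering curve. Averaging the local K curves over i recovers the
#' global K(r) exactly when the pair weights are symmetric (toroidal
#' correction).
#'
#' @param pattern A [point_pattern()] with at least 2 points.
#' @param r_grid Distance grid in nm.
#' @param correction As [k_function()].
#' @return A list of [radial_curve()] objects (kind `"L_minus_r"`), one per
#'   particle, each with attribute `"local_k"` holding the local K curve.
#' @export
local_l_curves <- function(pattern, r_grid = default_r_grid(),
                           correction = c("isotropic", "toroidal")) {
  stopifnot(inherits(pattern, "point_pattern"))
  correction <- match.arg(correction)
  if (pattern$n < 2) {
    stop("local L analysis requires at least 2 points", call. = FALSE)
  }
  geom <- pair_geometry(pattern, correction, r_max = max(r_grid))
  lapply(seq_len(pattern$n), function(i) {
    d <- geom$d[i, -i]
    w <- geom$w[i, -i]
    k <- pattern$window$area / (pattern$n - 1) *
      pair_sum_on_grid(d, w, r_grid)
    curve <- radial_curve(r_grid, sqrt(k / pi) - r_grid, "L_minus_r")
    attr(curve, "local_k") <- radial_curve(r_grid, k, "K")
    curve
  })
}

#' Classify particles into monomers, dimers and oligomers
#'
#' Builds the graph linking every particle pair closer than `link_radius`
#' and takes connected components (single linkage) as spatial clusters.
#' Particles are classified by the size of their component: 1 = monomer,
#' 2 = dimer, >= 3 = higher-order oligomer (nanocluster). Fractions are
#' per-particle label fractions, not per-component.
#'
#' @param pattern A [point_pattern()] with n >= 1.
#' @param link_radius Linkage distance in nm (> 0). See
#'   [choose_link_radius()] for a data-driven choice.
#' @return A list of class `oligomer_summary` with `fractions` (named
#'   `monomer` / `dimer` / `oligomer`, summing to 1), `component_sizes`
#'   (multiset of cluster sizes, summing to n), `membership` (component id
#'   per particle), `link_radius`, `image_id`.
#' @export
classify_oligomers <- function(pattern, link_radius) {
  stopifnot(inherits(pattern, "point_pattern"))
  if (link_radius <= 0) stop("link_radius must be positive", call. = FALSE)
  if (pattern$n < 1) stop("pattern is empty", call. = FALSE)
  if (pattern$n == 1) {
    membership <- 1L
  } else {
    d <- pairwise_distances(pattern)
    adj <- (d <= link_radius)
    diag(adj) <- FALSE
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    membership <- igraph::components(g)$membership
  }
  sizes <- as.integer(table(membership))
  size_of <- sizes[membership]
  fractions <- c(
    monomer = mean(size_of == 1),
    dimer = mean(size_of == 2),
    oligomer = mean(size_of >= 3)
  )
  structure(
    list(fractions = fractions, component_sizes = sizes,
         membership = as.integer(membership),
         link_radius = link_radius, image_id = pattern$image_id),
    class = "oligomer_summary"
  )
}

#' @export
print.oligomer_summary <- function(x, ...) {
  cat(sprintf(
    "oligomer summary [%s]: %.0f%% monomer, %.0f%% dimer, %.0f%% oligomer (link %g nm)\n",
    x$image_id, 100 * x$fractions["monomer"], 100 * x$fractions["dimer"],
    100 * x$fractions["oligomer"], x$link_radius))
  invisible(x)
}

#' Data-driven linkage radius for oligomer calling
#'
#' Standardizes the pattern's global L(r) - r curve against the supplied
#' CSR envelope and returns the radius of its peak (the dominant
#' clustering scale), clamped to 10-50 nm. When the pattern shows no
#' significant clustering (Lmax <= 1) the default of 30 nm -- roughly the
#' reach of a primary antibody plus gold conjugate on both partners -- is
#' returned instead.
#'
#' @param pattern A [point_pattern()].
#' @param envelope A [null_envelope()] for this pattern (99% CSR).
#' @param r_grid Distance grid in nm.
#' @param correction As [k_function()].
#' @param default Fallback radius in nm (default 30).
#' @return Linkage radius in nm, within `[10, 50]`.
#' @export
choose_link_radius <- function(pattern, envelope,
                               r_grid = default_r_grid(),
                               correction = c("isotropic", "toroidal"),
                               default = 30) {
  correction <- match.arg(correction)
  std <- standardize(l_minus_r(k_function(pattern, r_grid, correction)),
                     envelope)
  summary <- lmax_summary(std, image_id = pattern$image_id)
  if (!summary$significant) return(default)
  min(max(summary$r_at_lmax, 10), 50)
}
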