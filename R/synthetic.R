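# Seeded pattern generators emulating the structures the immunogold
# analysis assumes: CSR sheets at realistic labelling density
# (~170 particles per um^2), oligomer mixtures with fixed intra-cluster
# spacing plus labelling jitter, parent-offspring clustered processes, and
# two-species patterns that are independent, distance-linked
# (heterodimer-like) or segregated. Every generator is deterministic under
# a fixed seed; a NULL seed draws from the current RNG stream (so envelope
# loops can run inside one outer seed).

default_window <- function() spatial_window(0, 1000, 0, 1000)

with_optional_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

# wrap coordinates into the window (toroidal)
wrap_into <- function(v, lo, hi) lo + (v - lo) %% (hi - lo)

#' Generate a completely spatially random (CSR) pattern
#'
#' n points independently uniform over the window: the univariate null
#' model.
#'
#' @param n Number of points (>= 0).
#' @param window A [spatial_window()] (default the 1 um^2 sheet).
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @param image_id Label for the pattern.
#' @return A [point_pattern()].
#' @export
generate_csr <- function(n, window = default_window(), seed = NULL,
                         image_id = "csr") {
  stopifnot(n >= 0)
  with_optional_seed(seed, {
    point_pattern(stats::runif(n, window$x_min, window$x_max),
                  stats::runif(n, window$y_min, window$y_max),
                  window, image_id)
  })
}

# place one regular cluster of `size` points with side length `spacing`
# (regular polygon, random rotation) around an anchor, plus isotropic
# Gaussian jitter
place_cluster <- function(anchor, size, spacing, jitter_sd) {
  if (size == 1) {
    offs <- matrix(0, 1, 2)
  } else {
    radius <- spacing / (2 * sin(pi / size))
    theta <- stats::runif(1, 0, 2 * pi) + 2 * pi * seq_len(size) / size
    offs <- cbind(radius * cos(theta), radius * sin(theta))
  }
  if (jitter_sd > 0) {
    offs <- offs + matrix(stats::rnorm(2 * size, 0, jitter_sd), size, 2)
  }
  cbind(anchor[1] + offs[, 1], anchor[2] + offs[, 2])
}

#' Generate a monomer/dimer/oligomer mixture
#'
#' Cluster anchors are uniform in the window; the members of a size-k
#' cluster sit on a regular k-gon of side `spacing` (so nearest-neighbour
#' distance within a jitter-free cluster equals `spacing` exactly), plus
#' isotropic Gaussian labelling jitter. Anchors whose cluster would leave
#' the window are resampled (bounded retries).
#'
#' @param counts Named integer vector of cluster counts by size class,
#'   e.g. `c(monomer = 100, dimer = 30, trimer = 10)`; names may also be
#'   plain sizes (`"1"`, `"2"`, ...).
#' @param spacing Intra-cluster nearest-neighbour spacing in nm (> 0;
#'   default 12).
#' @param jitter_sd Isotropic Gaussian labelling displacement SD in nm
#'   (default 0).
#' @param window A [spatial_window()].
#' @param seed Integer seed or `NULL`.
#' @param image_id Label.
#' @param max_retries Anchor resampling budget per cluster.
#' @return A [point_pattern()] with attributes `"truth"` (data frame:
#'   `cluster`, `size` per particle) and `"truth_fractions"` (per-particle
#'   monomer/dimer/oligomer fractions of the generator).
#' @export
generate_oligomer_mixture <- function(counts, spacing = 12, jitter_sd = 0,
                                      window = default_window(),
                                      seed = NULL, image_id = "mixture",
                                      max_retries = 100) {
  stopifnot(spacing > 0, jitter_sd >= 0, all(counts >= 0))
  size_names <- c(monomer = 1, dimer = 2, trimer = 3, tetramer = 4)
  sizes <- vapply(seq_along(counts), function(i) {
    nm <- names(counts)[i]
    if (!is.null(nm) && nm %in% names(size_names)) {
      size_names[[nm]]
    } else if (!is.null(nm) && !is.na(suppressWarnings(as.integer(nm)))) {
      as.integer(nm)
    } else {
      stop("counts must be named by class (monomer/dimer/...) or size",
           call. = FALSE)
    }
  }, numeric(1))
  with_optional_seed(seed, {
    xs <- ys <- numeric(0)
    cluster_id <- size_of <- integer(0)
    cl <- 0L
    for (k in seq_along(counts)) {
      for (rep in seq_len(counts[k])) {
        cl <- cl + 1L
        ok <- FALSE
        for (try in seq_len(max_retries)) {
          anchor <- c(stats::runif(1, window$x_min, window$x_max),
                      stats::runif(1, window$y_min, window$y_max))
          pts <- place_cluster(anchor, sizes[k], spacing, jitter_sd)
          if (all(pts[, 1] >= window$x_min & pts[, 1] <= window$x_max &
                    pts[, 2] >= window$y_min & pts[, 2] <= window$y_max)) {
            ok <- TRUE
            break
          }
        }
        if (!ok) {
          stop("could not place cluster inside the window", call. = FALSE)
        }
        xs <- c(xs, pts[, 1]); ys <- c(ys, pts[, 2])
        cluster_id <- c(cluster_id, rep.int(cl, sizes[k]))
        size_of <- c(size_of, rep.int(sizes[k], sizes[k]))
      }
    }
    pat <- point_pattern(xs, ys, window, image_id)
    attr(pat, "truth") <- data.frame(cluster = cluster_id, size = size_of)
    attr(pat, "truth_fractions") <- c(
      monomer = mean(size_of == 1),
      dimer = mean(size_of == 2),
      oligomer = mean(size_of >= 3))
    pat
  })
}

#' Generate a Thomas (parent-offspring) clustered process
#'
#' Parents uniform in the window; each parent receives a
#' Poisson(`mean_offspring`) number of offspring displaced by an isotropic
#' Gaussian of SD `sigma`. Offspring are wrapped toroidally into the
#' window, which keeps the realized intensity equal to the nominal one
#' (clipping would thin the pattern near edges). As `sigma` grows the
#' process approaches CSR.
#'
#' @param parent_count Number of parent points (>= 0).
#' @param mean_offspring Mean offspring per parent (> 0).
#' @param sigma Offspring displacement SD in nm (> 0).
#' @param window A [spatial_window()].
#' @param seed Integer seed or `NULL`.
#' @param image_id Label.
#' @return A [point_pattern()] with attribute `"parents"` (parent
#'   coordinates).
#' @export
generate_thomas <- function(parent_count, mean_offspring, sigma,
                            window = default_window(), seed = NULL,
                            image_id = "thomas") {
  stopifnot(parent_count >= 0, mean_offspring > 0, sigma > 0)
  with_optional_seed(seed, {
    px <- stats::runif(parent_count, window$x_min, window$x_max)
    py <- stats::runif(parent_count, window$y_min, window$y_max)
    n_off <- stats::rpois(parent_count, mean_offspring)
    xs <- wrap_into(rep(px, n_off) + stats::rnorm(sum(n_off), 0, sigma),
                    window$x_min, window$x_max)
    ys <- wrap_into(rep(py, n_off) + stats::rnorm(sum(n_off), 0, sigma),
                    window$y_min, window$y_max)
    pat <- point_pattern(xs, ys, window, image_id)
    attr(pat, "parents") <- cbind(x = px, y = py)
    pat
  })
}

#' Generate a two-species pattern
#'
#' Emulates the scenarios of the heterodimerization analysis:
#' `"independent"` draws both species CSR; `"linked"` pairs a fraction of
#' the small particles with distinct big partners at a fixed inter-species
#' distance (plus jitter), the rest CSR -- the heterodimer-like
#' alternative; `"segregated"` confines the species to disjoint
#' half-windows.
#'
#' @param n_b,n_s Big / small particle counts (>= 1).
#' @param mode `"independent"`, `"linked"` or `"segregated"`.
#' @param link_distance Inter-species pair distance in nm (linked mode;
#'   default 8).
#' @param linked_fraction Fraction of small particles linked to a big
#'   partner (linked mode; in `[0, 1]`, default 1).
#' @param jitter_sd Isotropic Gaussian jitter SD on linked positions in nm.
#' @param window A [spatial_window()].
#' @param seed Integer seed or `NULL`.
#' @param image_id Label.
#' @return A [bivariate_pattern()]; in linked mode with attribute
#'   `"linked_pairs"` (data frame `big`, `small` of partner indices).
#' @export
generate_bivariate <- function(n_b, n_s,
                               mode = c("independent", "linked",
                                        "segregated"),
                               link_distance = 8, linked_fraction = 1,
                               jitter_sd = 0, window = default_window(),
                               seed = NULL, image_id = "bivariate") {
  mode <- match.arg(mode)
  stopifnot(n_b >= 1, n_s >= 1, linked_fraction >= 0, linked_fraction <= 1)
  with_optional_seed(seed, {
    if (mode == "segregated") {
      x_mid <- (window$x_min + window$x_max) / 2
      big <- point_pattern(
        stats::runif(n_b, window$x_min, x_mid),
        stats::runif(n_b, window$y_min, window$y_max), window, image_id)
      small <- point_pattern(
        stats::runif(n_s, x_mid, window$x_max),
        stats::runif(n_s, window$y_min, window$y_max), window, image_id)
      return(bivariate_pattern(big, small))
    }
    big <- generate_csr(n_b, window, NULL, image_id)
    if (mode == "independent") {
      return(bivariate_pattern(big, generate_csr(n_s, window, NULL,
                                                 image_id)))
    }
    n_linked <- round(linked_fraction * n_s)
    if (n_linked > n_b) {
      stop("linked_fraction * n_s exceeds n_b: no big partner available",
           call. = FALSE)
    }
    partners <- sample.int(n_b, n_linked)
    theta <- stats::runif(n_linked, 0, 2 * pi)
    sx <- big$x[partners] + link_distance * cos(theta)
    sy <- big$y[partners] + link_distance * sin(theta)
    if (jitter_sd > 0) {
      sx <- sx + stats::rnorm(n_linked, 0, jitter_sd)
      sy <- sy + stats::rnorm(n_linked, 0, jitter_sd)
    }
    free <- generate_csr(n_s - n_linked, window, NULL, image_id)
    small <- point_pattern(
      c(wrap_into(sx, window$x_min, window$x_max), free$x),
      c(wrap_into(sy, window$y_min, window$y_max), free$y),
      window, image_id)
    out <- bivariate_pattern(big, small)
    attr(out, "linked_pairs") <- data.frame(big = partners,
                                            small = seq_len(n_linked))
    out
  })
}
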