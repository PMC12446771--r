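# Proximity-map set computations: SAINT-score filtering of bait prey
# tables, fold change over control, asymmetric overlap fractions, and Venn
# partitions across baits and techniques.

# prey identity: symbol after case normalization and whitespace trimming
normalize_prey <- function(prey) toupper(trimws(as.character(prey)))

#' High-confidence prey set by SAINT-score filtering
#'
#' Filters a prey-record table to the unique prey of one bait (and
#' optionally one technique) whose SAINT score meets the threshold. The
#' comparison is inclusive (`ss >= threshold`), matching the conventional
#' "SS cut-off of >= 0.7" for BioID and ">= 0.9" for affinity-MS lists.
#'
#' @param records Data frame of prey records (see [read_prey_table()]):
#'   columns `bait`, `prey`, `ss`, optional `technique`.
#' @param bait Bait label to select.
#' @param ss_threshold SAINT-score threshold in `[0, 1]` (default 0.7).
#' @param technique Optional technique label to select.
#' @return A list of class `prey_set` with `bait`, `technique`,
#'   `threshold`, `members` (unique normalized prey identifiers). An
#'   unknown bait yields an empty set with a warning.
#' @export
filter_high_confidence <- function(records, bait, ss_threshold = 0.7,
                                   technique = NULL) {
  stopifnot(is.data.frame(records),
            ss_threshold >= 0, ss_threshold <= 1)
  keep <- records$bait == bait
  if (!any(keep)) {
    warning(sprintf("bait '%s' not present in the records", bait),
            call. = FALSE)
  }
  if (!is.null(technique) && "technique" %in% names(records)) {
    keep <- keep & records$technique == technique
  }
  keep <- keep & records$ss >= ss_threshold
  prey_set(bait, unique(normalize_prey(records$prey[keep])),
           threshold = ss_threshold,
           technique = technique %||% "any")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a prey set
#'
#' @param bait Bait label.
#' @param members Character vector of prey identifiers (normalized and
#'   deduplicated).
#' @param threshold SAINT-score threshold that produced the set.
#' @param technique Technique label.
#' @return A list of class `prey_set`.
#' @export
prey_set <- function(bait, members, threshold = NA_real_,
                     technique = "any") {
  structure(
    list(bait = bait, technique = technique, threshold = threshold,
         members = unique(normalize_prey(members))),
    class = "prey_set"
  )
}

#' @export
print.prey_set <- function(x, ...) {
  cat(sprintf("prey set %s (%s, SS >= %s): %d members\n", x$bait,
              x$technique, format(x$threshold), length(x$members)))
  invisible(x)
}

#' Fold change over a control measurement
#'
#' @param value Measured value (e.g. stimulated activity for a bait).
#' @param control_value Matched control measurement (> 0).
#' @param digits Rounding for the reported n-fold value; `NA` to skip.
#' @return A list with `ratio` (unrounded) and `fold` (rounded "n-fold"
#'   report, nearest integer by default).
#' @export
fold_change_over_control <- function(value, control_value, digits = 0) {
  if (any(control_value <= 0)) {
    stop("control_value must be positive", call. = FALSE)
  }
  ratio <- value / control_value
  list(ratio = ratio,
       fold = if (is.na(digits)) ratio else round(ratio, digits))
}

#' Asymmetric overlap fraction of two prey sets
#'
#' Percentage of the first set's members found in the second ("overlap of
#' a's proteins with those of b"); note the denominator is `|a|`, so the
#' measure is not symmetric.
#'
#' @param a,b `prey_set` objects (or character vectors); `a` non-empty.
#' @return A list with `percent` (0-100, unrounded), `percent_rounded`
#'   (nearest integer, for prose reporting), `shared` (member count in
#'   both).
#' @export
overlap_fraction <- function(a, b) {
  am <- if (inherits(a, "prey_set")) a$members else normalize_prey(a)
  bm <- if (inherits(b, "prey_set")) b$members else normalize_prey(b)
  if (!length(am)) {
    stop("overlap fraction undefined for an empty first set", call. = FALSE)
  }
  shared <- length(intersect(am, bm))
  pct <- 100 * shared / length(am)
  list(percent = pct, percent_rounded = round(pct), shared = shared)
}

#' Venn partition of two or three prey sets
#'
#' Counts every exclusive region of the Venn diagram; regions are pairwise
#' disjoint and sum to the size of the union.
#'
#' @param sets Named list of 2 or 3 `prey_set` objects or character
#'   vectors (names default to bait labels / `set1..3`).
#' @return Named integer vector of exclusive region counts; two sets give
#'   `a_only`, `b_only`, `a_and_b`; three sets give the 7 regions
#'   (`a_only`, ..., `a_b_c`).
#' @export
venn_partition <- function(sets) {
  members <- lapply(sets, function(s) {
    if (inherits(s, "prey_set")) s$members else unique(normalize_prey(s))
  })
  k <- length(members)
  if (!k %in% c(2, 3)) stop("venn_partition takes 2 or 3 sets",
                            call. = FALSE)
  nms <- names(sets)
  if (is.null(nms) || any(!nzchar(nms))) {
    nms <- vapply(seq_len(k), function(i) {
      s <- sets[[i]]
      if (inherits(s, "prey_set")) s$bait else paste0("set", i)
    }, character(1))
  }
  universe <- unique(unlist(members))
  inset <- vapply(members, function(m) universe %in% m,
                  logical(length(universe)))
  if (length(universe) == 1) inset <- matrix(inset, nrow = 1)
  if (k == 2) {
    counts <- c(sum(inset[, 1] & !inset[, 2]),
                sum(!inset[, 1] & inset[, 2]),
                sum(inset[, 1] & inset[, 2]))
    names(counts) <- c(paste0(nms[1], "_only"), paste0(nms[2], "_only"),
                       paste(nms[1], nms[2], sep = "_and_"))
  } else {
    a <- inset[, 1]; b <- inset[, 2]; cc <- inset[, 3]
    counts <- c(sum(a & !b & !cc), sum(!a & b & !cc), sum(!a & !b & cc),
                sum(a & b & !cc), sum(a & !b & cc), sum(!a & b & cc),
                sum(a & b & cc))
    names(counts) <- c(paste0(nms, "_only"),
                       paste(nms[1], nms[2], sep = "_and_"),
                       paste(nms[1], nms[3], sep = "_and_"),
                       paste(nms[2], nms[3], sep = "_and_"),
                       paste(nms, collapse = "_and_"))
  }
  counts
}

#' Cross-technique overlap of prey sets
#'
#' Intersection of the BioID and affinity-MS prey sets for one bait, with
#' the shared fraction of each technique's list.
#'
#' @param bioid,flag `prey_set` objects (or character vectors).
#' @return A list with `shared_members`, `n_shared`, `percent_of_bioid`,
#'   `percent_of_flag` (each 100 * shared / technique size; `NA` for an
#'   empty list).
#' @export
technique_overlap <- function(bioid, flag) {
  bm <- if (inherits(bioid, "prey_set")) bioid$members else
    unique(normalize_prey(bioid))
  fm <- if (inherits(flag, "prey_set")) flag$members else
    unique(normalize_prey(flag))
  shared <- intersect(bm, fm)
  list(shared_members = shared, n_shared = length(shared),
       percent_of_bioid = if (length(bm)) 100 * length(shared) / length(bm)
         else NA_real_,
       percent_of_flag = if (length(fm)) 100 * length(shared) / length(fm)
         else NA_real_)
}
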