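#' Read a coordinate table into point patterns
#'
#' Reads a delimited text table of gold-particle coordinates (one row per
#' particle) and groups rows into one pattern per image. Expected header
#' columns: `image_id`, `x_nm`, `y_nm`, optional `species` (e.g. `"2nm"` /
#' `"6nm"`), optional window bounds `win_xmin`, `win_xmax`, `win_ymin`,
#' `win_ymax`. When a `species` column is present each image yields a
#' [bivariate_pattern()]; the species whose label sorts last
#' (`"6nm" > "2nm"`) is taken as "big" unless `big_species` is given.
#'
#' @param path Path to a CSV or TSV file (delimiter inferred from the
#'   extension, or set `sep`).
#' @param sep Field separator; default infers `","` for `.csv`, `"\t"`
#'   otherwise.
#' @param big_species Species label to treat as the "big" gold population.
#' @param window A [spatial_window()] applied to every image when the table
#'   carries no window columns; if neither is present the bounding box of
#'   each image's points is used.
#' @return A named list of `point_pattern` / `bivariate_pattern` objects,
#'   one per `image_id`.
#' @export
read_pattern_table <- function(path, sep = NULL, big_species = NULL,
                               window = NULL) {
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character",
                           stringsAsFactors = FALSE, strip.white = TRUE)
  required <- c("image_id", "x_nm", "y_nm")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    stop("coordinate table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  parse_num <- function(col) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(v) | !is.finite(v))
    if (length(bad)) {
      stop(sprintf("malformed numeric value in column '%s' at data row %d: '%s'",
                   col, bad[1], tab[[col]][bad[1]]), call. = FALSE)
    }
    v
  }
  x <- parse_num("x_nm")
  y <- parse_num("y_nm")
  has_species <- "species" %in% names(tab)
  win_cols <- c("win_xmin", "win_xmax", "win_ymin", "win_ymax")
  has_window <- all(win_cols %in% names(tab))
  win_vals <- if (has_window) lapply(win_cols, parse_num)

  ids <- unique(tab$image_id)
  out <- vector("list", length(ids))
  names(out) <- ids
  for (id in ids) {
    rows <- which(tab$image_id == id)
    w <- window
    if (has_window) {
      per_img <- vapply(win_vals, function(v) {
        u <- unique(v[rows])
        if (length(u) != 1) {
          stop(sprintf("image '%s' carries inconsistent window bounds", id),
               call. = FALSE)
        }
        u
      }, numeric(1))
      w <- spatial_window(per_img[1], per_img[2], per_img[3], per_img[4])
    }
    if (has_species) {
      sp <- tab$species[rows]
      levels <- sort(unique(sp))
      if (length(levels) != 2) {
        stop(sprintf("image '%s' must have exactly 2 species, found %d",
                     id, length(levels)), call. = FALSE)
      }
      big <- if (is.null(big_species)) levels[2] else big_species
      if (!big %in% levels) {
        stop(sprintf("big_species '%s' absent from image '%s'", big, id),
             call. = FALSE)
      }
      bi <- sp == big
      if (is.null(w)) {
        w <- spatial_window(min(x[rows]), max(x[rows]),
                            min(y[rows]), max(y[rows]))
      }
      out[[id]] <- bivariate_pattern(
        point_pattern(x[rows][bi], y[rows][bi], w, id),
        point_pattern(x[rows][!bi], y[rows][!bi], w, id)
      )
    } else {
      out[[id]] <- point_pattern(x[rows], y[rows], w, id)
    }
  }
  out
}

#' Write point patterns to a coordinate table
#'
#' Inverse of [read_pattern_table()]: writes one row per particle with the
#' window bounds attached, so that reading the file back round-trips the
#' patterns.
#'
#' @param patterns A single pattern or a list of `point_pattern` /
#'   `bivariate_pattern` objects.
#' @param path Output file path (`.csv` or `.tsv`).
#' @param sep Field separator; inferred from the extension by default.
#' @return Invisibly, the data frame written.
#' @export
write_pattern_table <- function(patterns, path, sep = NULL) {
  if (inherits(patterns, c("point_pattern", "bivariate_pattern"))) {
    patterns <- list(patterns)
  }
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  rows <- lapply(patterns, function(p) {
    win <- p$window
    base <- function(pp, species) {
      if (pp$n == 0) return(NULL)
      data.frame(image_id = pp$image_id, x_nm = pp$x, y_nm = pp$y,
                 species = species,
                 win_xmin = win$x_min, win_xmax = win$x_max,
                 win_ymin = win$y_min, win_ymax = win$y_max,
                 stringsAsFactors = FALSE)
    }
    if (inherits(p, "bivariate_pattern")) {
      rbind(base(p$big, "6nm"), base(p$small, "2nm"))
    } else {
      base(p, NA_character_)
    }
  })
  df <- do.call(rbind, rows)
  if (all(is.na(df$species))) df$species <- NULL
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(df)
}

#' Read a SAINT-scored prey table
#'
#' Reads a delimited table of bait-prey records from SAINT-scored
#' proximity-MS experiments. Expected header columns: `bait`, `prey`,
#' `technique` (`BioID` / `FLAG-MS`), `ss` (SAINT score in `[0, 1]`),
#' optional `bfdr`, spectral-count columns and `fold_change`.
#'
#' @param path Path to a CSV/TSV file.
#' @param sep Field separator; inferred from the extension by default.
#' @return A data frame of prey records with validated `ss` / `bfdr`.
#' @export
read_prey_table <- function(path, sep = NULL) {
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, strip.white = TRUE)
  required <- c("bait", "prey", "ss")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    stop("prey table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"technique" %in% names(tab)) tab$technique <- "BioID"
  tab$ss <- as.numeric(tab$ss)
  if (any(is.na(tab$ss) | tab$ss < 0 | tab$ss > 1)) {
    stop("SAINT scores must be numeric in [0, 1]", call. = FALSE)
  }
  if ("bfdr" %in% names(tab)) {
    tab$bfdr <- as.numeric(tab$bfdr)
    if (any(is.na(tab$bfdr) | tab$bfdr < 0 | tab$bfdr > 1)) {
      stop("BFDR values must be numeric in [0, 1]", call. = FALSE)
    }
  }
  tab
}
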