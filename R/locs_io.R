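#' @useDynLib paintquant, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
#' @importFrom tibble tibble as_tibble
#' @keywords internal
"_PACKAGE"

# Canonical units: nm for coordinates and precision, seconds for time,
# 0-based camera frame indices. Files may store pixel units (Picasso
# convention); conversion happens only at read/write.

#' Acquisition metadata
#'
#' Describes one DNA-PAINT acquisition round: number of camera frames,
#' exposure time, camera pixel size, and imager-strand concentration
#' \eqn{c_i}. Defaults mirror a typical Exchange-PAINT acquisition
#' (20,000 frames at 100 ms, 158 nm pixels, 2 nM imager).
#'
#' @param n_frames Number of camera frames.
#' @param exposure_s Frame exposure time in seconds.
#' @param pixel_size_nm Camera pixel size in nm.
#' @param imager_concentration_M Imager concentration in mol/L.
#' @param target_name Imaged target label (e.g. `"EGFR"`).
#' @param exchange_round Exchange-PAINT round label (e.g. `"R3"`).
#' @return A list of class `acq_metadata`.
#' @export
acq_metadata <- function(n_frames = 20000L, exposure_s = 0.1,
                         pixel_size_nm = 158, imager_concentration_M = 2e-9,
                         target_name = NA_character_, exchange_round = NA_character_) {
  stopifnot(n_frames > 0, exposure_s > 0, pixel_size_nm > 0)
  structure(list(n_frames = as.integer(n_frames), exposure_s = exposure_s,
                 pixel_size_nm = pixel_size_nm,
                 imager_concentration_M = imager_concentration_M,
                 target_name = target_name, exchange_round = exchange_round),
            class = "acq_metadata")
}

loc_columns <- c("frame", "x", "y", "photons", "sx", "sy", "bg", "lpx", "lpy")
# columns stored in pixel units on disk (Picasso convention)
px_columns <- c("x", "y", "sx", "sy", "lpx", "lpy")

#' Construct a localization table
#'
#' A localization table is a tibble with one row per fitted single-molecule
#' localization: `frame` (0-based), `x`/`y` in nm, `photons`, optional PSF
#' widths `sx`/`sy` (nm), background `bg`, per-localization precision
#' `lpx`/`lpy` (nm), plus `target`, `cell_id` and `condition` labels. The
#' acquisition metadata travels as the `"acq"` attribute.
#'
#' @param df Data frame with at least `frame`, `x`, `y`, `photons`.
#' @param acq An [acq_metadata()] object.
#' @param target,cell_id,condition Label strings applied to all rows.
#' @return A `loc_table` tibble.
#' @export
loc_table <- function(df, acq = acq_metadata(), target = NA_character_,
                      cell_id = NA_character_, condition = NA_character_) {
  df <- as_tibble(df)
  mandatory <- c("frame", "x", "y", "photons")
  missing_col <- setdiff(mandatory, names(df))
  if (length(missing_col) > 0)
    stop("localization table is missing mandatory column(s): ",
         paste(missing_col, collapse = ", "), call. = FALSE)
  if (nrow(df) > 0) {
    if (any(df$frame < 0)) stop("negative frame index", call. = FALSE)
    if (any(!is.finite(df$x)) || any(!is.finite(df$y)))
      stop("non-finite coordinates", call. = FALSE)
  }
  df$frame <- as.integer(df$frame)
  if (!"target" %in% names(df)) df$target <- target
  if (!"cell_id" %in% names(df)) df$cell_id <- cell_id
  if (!"condition" %in% names(df)) df$condition <- condition
  attr(df, "acq") <- acq
  class(df) <- c("loc_table", class(df))
  df
}

#' @exportS3Method base::print
print.loc_table <- function(x, ...) {
  acq <- attr(x, "acq")
  cat(sprintf("<loc_table: %d localizations, target %s, %d frames>\n",
              nrow(x), acq$target_name %||% "?", acq$n_frames))
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a[1])) b else a

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".yaml")

#' Read a localization table
#'
#' Reads an HDF5 container holding a `locs` table (with a YAML metadata
#' sidecar next to it) or a CSV file with the same column names. Coordinates
#' and precision columns are stored in camera pixels on disk and converted
#' to nm on read.
#'
#' @param path Path to an `.hdf5`/`.h5` or `.csv` file.
#' @param pixel_size_nm Pixel size used for the pixel-to-nm conversion;
#'   defaults to the sidecar value, else 158 nm.
#' @return A [loc_table()] tibble in nm units.
#' @export
read_locs <- function(path, pixel_size_nm = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  meta <- NULL
  sp <- sidecar_path(path)
  if (file.exists(sp)) meta <- yaml::read_yaml(sp)
  if (is.null(pixel_size_nm))
    pixel_size_nm <- meta$pixel_size_nm %||% 158
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("hdf5", "h5")) {
    df <- tryCatch(rhdf5::h5read(path, "locs"),
                   error = function(e) stop("unreadable HDF5 container: ",
                                            conditionMessage(e), call. = FALSE))
    df <- as.data.frame(lapply(df, as.vector), stringsAsFactors = FALSE)
  } else {
    df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  mandatory <- c("frame", "x", "y", "photons")
  missing_col <- setdiff(mandatory, names(df))
  if (length(missing_col) > 0)
    stop("localization file is missing mandatory column(s): ",
         paste(missing_col, collapse = ", "), call. = FALSE)
  for (cc in intersect(loc_columns, names(df)))
    df[[cc]] <- as.numeric(df[[cc]])  # empty CSV columns parse as logical
  for (cc in intersect(px_columns, names(df)))
    df[[cc]] <- df[[cc]] * pixel_size_nm
  acq <- acq_metadata(
    n_frames = meta$n_frames %||% max(20000L, if (nrow(df)) max(df$frame) + 1L else 0L),
    exposure_s = meta$exposure_s %||% 0.1,
    pixel_size_nm = pixel_size_nm,
    imager_concentration_M = meta$imager_concentration_M %||% 2e-9,
    target_name = meta$target_name %||% NA_character_,
    exchange_round = meta$exchange_round %||% NA_character_)
  loc_table(df, acq = acq,
            target = meta$target_name %||% NA_character_,
            cell_id = meta$cell_id %||% NA_character_,
            condition = meta$condition %||% NA_character_)
}

#' Write a localization table
#'
#' Writes the HDF5 `locs`-table container (or CSV, by file extension) plus a
#' YAML metadata sidecar. nm columns are converted back to camera pixels so
#' that `read_locs(write_locs(t))` round-trips.
#'
#' @param table A [loc_table()].
#' @param path Output path (`.hdf5`/`.h5` or `.csv`).
#' @return `path`, invisibly.
#' @export
write_locs <- function(table, path) {
  acq <- attr(table, "acq") %||% acq_metadata()
  p <- acq$pixel_size_nm
  df <- as.data.frame(table)[, intersect(loc_columns, names(table)), drop = FALSE]
  for (cc in intersect(px_columns, names(df))) df[[cc]] <- df[[cc]] / p
  df$frame <- as.integer(df$frame)
  ext <- tolower(tools::file_ext(path))
  ok <- tryCatch({
    if (ext %in% c("hdf5", "h5")) {
      if (file.exists(path)) unlink(path)
      rhdf5::h5createFile(path)
      rhdf5::h5write(df, path, "locs")
      rhdf5::h5closeAll()
    } else {
      readr::write_csv(df, path, progress = FALSE)
    }
    TRUE
  }, error = function(e) stop("cannot write ", path, ": ",
                              conditionMessage(e), call. = FALSE))
  meta <- unclass(acq)
  meta$cell_id <- table$cell_id[1] %||% NA_character_
  meta$condition <- table$condition[1] %||% NA_character_
  meta <- meta[!vapply(meta, function(v) is.null(v) || all(is.na(v)), logical(1))]
  yaml::write_yaml(meta, sidecar_path(path))
  invisible(path)
}

# ---- cell masks -------------------------------------------------------------

shoelace_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2); d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  ((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) && ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))
}

is_simple_polygon <- function(poly) {
  n <- nrow(poly)
  if (n < 3) return(FALSE)
  for (i in seq_len(n)) {
    i2 <- if (i == n) 1L else i + 1L
    for (j in seq_len(n)) {
      j2 <- if (j == n) 1L else j + 1L
      # skip shared-vertex segment pairs
      if (length(intersect(c(i, i2), c(j, j2))) > 0) next
      if (segments_intersect(poly[i, ], poly[i2, ], poly[j, ], poly[j2, ]))
        return(FALSE)
    }
  }
  TRUE
}

#' Construct a cell mask
#'
#' A membrane mask is a simple (non-self-intersecting) closed polygon in nm;
#' its area in \eqn{\mu m^2} is the shoelace area divided by \eqn{10^6}.
#'
#' @param polygon_nm Two-column matrix of vertices (nm), implicitly closed.
#' @return A list of class `cell_mask` with `polygon_nm` and `area_um2`.
#' @export
cell_mask <- function(polygon_nm) {
  poly <- as.matrix(polygon_nm)
  storage.mode(poly) <- "double"
  if (!is_simple_polygon(poly))
    stop("mask polygon is self-intersecting or degenerate", call. = FALSE)
  area <- shoelace_area(poly) / 1e6
  if (area <= 0) stop("mask polygon has zero area", call. = FALSE)
  structure(list(polygon_nm = poly, area_um2 = area), class = "cell_mask")
}

#' Square mask helper
#' @param side_um Side length in micrometers.
#' @param origin_nm Lower-left corner (nm).
#' @return A [cell_mask()].
#' @export
square_mask <- function(side_um = 10, origin_nm = c(0, 0)) {
  s <- side_um * 1000
  cell_mask(rbind(origin_nm, origin_nm + c(s, 0), origin_nm + c(s, s),
                  origin_nm + c(0, s)))
}

#' Load / save a cell mask
#'
#' Masks are stored as JSON `{"polygon_nm": [[x, y], ...]}` with vertices in nm.
#'
#' @param path JSON file path.
#' @return [cell_mask()] for `load_mask`; `path` invisibly for `save_mask`.
#' @export
load_mask <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$polygon_nm)) stop("mask JSON lacks 'polygon_nm'", call. = FALSE)
  cell_mask(obj$polygon_nm)
}

#' @rdname load_mask
#' @param mask A [cell_mask()].
#' @export
save_mask <- function(mask, path) {
  jsonlite::write_json(list(polygon_nm = mask$polygon_nm), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Point-in-polygon test (ray casting)
#' @param x,y Coordinates (nm).
#' @param mask A [cell_mask()].
#' @return Logical vector.
#' @export
in_mask <- function(x, y, mask) {
  poly <- mask$polygon_nm
  n <- nrow(poly)
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]; xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}
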