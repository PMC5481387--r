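#' Canonical localization-table columns
#'
#' A localization table holds one row per localization with coordinates
#' (`x`, `y`, `z`) in nm and the per-dimension localization precisions
#' (`sigma_x`, `sigma_y`, `sigma_z`), i.e. the standard deviations of the
#' Gaussian fitting error, also in nm.
#'
#' @keywords internal
loc_columns <- function() c("x", "y", "z", "sigma_x", "sigma_y", "sigma_z")

#' Column-name dialects for localization tables
#'
#' Maps the file's column names onto the six canonical fields. The default
#' dialect expects the canonical names themselves; `"thunderstorm"` accepts
#' ThunderSTORM-style headers such as `"x [nm]"` and `"uncertainty_xy [nm]"`
#' era variants with per-axis uncertainties.
#'
#' @param x,y,z,sigma_x,sigma_y,sigma_z File column names for each canonical
#'   field.
#' @return A named character vector mapping canonical names to file names.
#' @examples
#' loc_dialect(x = "x [nm]", y = "y [nm]", z = "z [nm]")
#' @export
loc_dialect <- function(x = "x", y = "y", z = "z",
                        sigma_x = "sigma_x", sigma_y = "sigma_y",
                        sigma_z = "sigma_z") {
  c(x = x, y = y, z = z, sigma_x = sigma_x, sigma_y = sigma_y, sigma_z = sigma_z)
}

#' @rdname loc_dialect
#' @export
thunderstorm_dialect <- function() {
  loc_dialect(x = "x [nm]", y = "y [nm]", z = "z [nm]",
              sigma_x = "uncertainty_x [nm]", sigma_y = "uncertainty_y [nm]",
              sigma_z = "uncertainty_z [nm]")
}

#' Read a localization table from delimited text
#'
#' Reads a CSV/TSV file with a header row into a validated localization
#' tibble. Units are fixed to nanometres; no unit autodetection is attempted.
#' Rows containing non-finite coordinates or non-positive / non-finite
#' precisions are dropped with a warning rather than aborting the read, since
#' real exports routinely contain sentinel rows.
#'
#' @param path Path to a delimited text file with a header row.
#' @param dialect Named character vector from [loc_dialect()] mapping the
#'   canonical fields to the file's column names.
#' @param delim Field delimiter; `NULL` (default) lets `readr` guess.
#'
#' @return A tibble with columns `x`, `y`, `z`, `sigma_x`, `sigma_y`,
#'   `sigma_z` (all numeric, nm). An empty file yields a zero-row tibble.
#' @seealso [crop_to_roi()], [write_results()]
#' @export
read_localizations <- function(path, dialect = loc_dialect(), delim = NULL) {
  df <- if (is.null(delim)) {
    readr::read_delim(path, show_col_types = FALSE, progress = FALSE)
  } else {
    readr::read_delim(path, delim = delim, show_col_types = FALSE, progress = FALSE)
  }
  if (nrow(df) == 0 && ncol(df) == 0) {
    return(empty_localizations())
  }
  missing <- setdiff(unname(dialect), names(df))
  if (length(missing) > 0) {
    stop("localization file is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- tibble::as_tibble(df[unname(dialect)])
  names(out) <- names(dialect)
  out <- dplyr::mutate(out, dplyr::across(dplyr::everything(), as.numeric))
  validate_localizations(out)
}

empty_localizations <- function() {
  tibble::as_tibble(stats::setNames(
    rep(list(numeric(0)), 6L), loc_columns()
  ))
}

#' Validate a localization tibble
#'
#' Enforces the table invariants: all six canonical columns present and
#' numeric, all values finite, and all precisions strictly positive. Offending
#' rows are dropped with a warning reporting the count.
#'
#' @param locs A data frame with the canonical localization columns.
#' @return The validated tibble (possibly with rows removed).
#' @export
validate_localizations <- function(locs) {
  missing <- setdiff(loc_columns(), names(locs))
  if (length(missing) > 0) {
    stop("localization table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  locs <- tibble::as_tibble(locs)
  m <- as.matrix(locs[loc_columns()])
  ok <- rowSums(!is.finite(m)) == 0 &
    m[, "sigma_x"] > 0 & m[, "sigma_y"] > 0 & m[, "sigma_z"] > 0
  ok[is.na(ok)] <- FALSE
  if (any(!ok)) {
    warning(sum(!ok), " localization(s) dropped (non-finite values or ",
            "non-positive precisions)", call. = FALSE)
  }
  locs[ok, , drop = FALSE]
}

#' Crop a localization table to an ROI
#'
#' Translates coordinates by `corner` and keeps the points falling strictly
#' inside the half-open box `[0, Lx) x [0, Ly) x [0, Lz)`. Row order is
#' preserved and the operation is idempotent for `corner = c(0, 0, 0)`.
#'
#' @param locs Localization tibble (canonical columns).
#' @param roi An [roi()] object.
#' @param corner Numeric length-3 vector `(x0, y0, z0)` in nm; the ROI's
#'   lower corner in the coordinate frame of `locs`.
#' @return A tibble of the retained localizations in ROI-local coordinates.
#' @export
crop_to_roi <- function(locs, roi, corner = c(0, 0, 0)) {
  stopifnot(inherits(roi, "roi"), length(corner) == 3)
  locs <- tibble::as_tibble(locs)
  shifted <- dplyr::mutate(locs,
    x = .data$x - corner[1], y = .data$y - corner[2], z = .data$z - corner[3])
  keep <- shifted$x >= 0 & shifted$x < roi$Lx &
    shifted$y >= 0 & shifted$y < roi$Ly &
    shifted$z >= 0 & shifted$z < roi$Lz
  shifted[keep, , drop = FALSE]
}

#' Write analysis results to disk
#'
#' Emits three files under `dir`: a per-point CSV (`points.csv`, the input
#' columns plus `cluster` label and the `l3d` value at the winning radius), a
#' per-cluster CSV (`clusters.csv`) and a per-ROI summary JSON
#' (`summary.json`). All numeric output is written in full double precision.
#'
#' @param fit A [bayes_cluster()] fit.
#' @param dir Output directory; created if absent.
#' @param prefix Optional file-name prefix.
#' @return Invisibly, a named character vector of the paths written.
#' @export
write_results <- function(fit, dir, prefix = "") {
  stopifnot(inherits(fit, "bayes_cluster3d"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    points   = file.path(dir, paste0(prefix, "points.csv")),
    clusters = file.path(dir, paste0(prefix, "clusters.csv")),
    summary  = file.path(dir, paste0(prefix, "summary.json"))
  )
  readr::write_csv(generics::augment(fit), paths["points"])
  readr::write_csv(generics::tidy(fit), paths["clusters"])
  jsonlite::write_json(as.list(generics::glance(fit)), paths["summary"],
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
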