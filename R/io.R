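#' Read a long-format table of time-intensity curves
#'
#' A curve table has one row per 1 Hz sample of one replicate evaluation:
#' columns `material_id`, `panelist_id`, `replicate`, `time_s`, `intensity`.
#' Intensities are in arbitrary units on the 0--100 scale used during the
#' evaluation; times are seconds from the start of the evaluation.
#'
#' On read the rows are sorted by time within each
#' (material, panelist, replicate) group and every curve invariant is
#' enforced: at least 3 samples, strictly increasing times with a constant
#' step, and finite intensities within \[0, 100\]. Violations raise an error
#' naming the offending group; nothing is silently coerced.
#'
#' @param path Path to a CSV file (comma separator, `.` decimal, UTF-8,
#'   header required).
#' @return A tibble with columns `material_id`, `panelist_id`, `replicate`,
#'   `time_s`, `intensity`, sorted by group and time.
#' @seealso [write_ti_curves()], [validate_ti_curves()]
#' @export
read_ti_curves <- function(path) {
  df <- read_checked_csv(
    path,
    cols = c("material_id", "panelist_id", "replicate", "time_s", "intensity"),
    col_types = readr::cols(
      material_id = readr::col_character(),
      panelist_id = readr::col_character(),
      replicate = readr::col_integer(),
      time_s = readr::col_double(),
      intensity = readr::col_double()
    )
  )
  validate_ti_curves(df)
}

#' Validate a curve table against the TI-curve invariants
#'
#' @param curves Data frame with the columns of [read_ti_curves()].
#' @return The validated tibble, sorted by (material, panelist, replicate,
#'   time); raises a validation error locating the first offending curve
#'   otherwise.
#' @export
validate_ti_curves <- function(curves) {
  curves <- require_columns(
    curves, c("material_id", "panelist_id", "replicate", "time_s", "intensity")
  )
  curves <- dplyr::arrange(
    curves, .data$material_id, .data$panelist_id, .data$replicate, .data$time_s
  )
  if (nrow(curves) == 0L) {
    return(curves)
  }
  if (any(!is.finite(curves$replicate)) || any(curves$replicate < 1)) {
    abort("curve table: `replicate` must be an integer >= 1")
  }
  bad <- !is.finite(curves$intensity) | curves$intensity < 0 | curves$intensity > 100
  if (any(bad)) {
    i <- which(bad)[1]
    abort(sprintf(
      "curve table: intensity %s outside [0, 100] for material '%s', panelist '%s', replicate %d",
      format(curves$intensity[i]), curves$material_id[i],
      curves$panelist_id[i], curves$replicate[i]
    ))
  }
  check_group <- function(d, key) {
    n <- nrow(d)
    if (n < 3L) {
      abort(sprintf("curve %s has %d samples; at least 3 are required", key, n))
    }
    steps <- diff(d$time_s)
    if (any(steps <= 0) || max(steps) - min(steps) > 1e-9) {
      abort(sprintf(
        "curve %s has non-uniform time spacing (steps range %s to %s); times must increase by a constant step",
        key, format(min(steps)), format(max(steps))
      ))
    }
    invisible(NULL)
  }
  split_keys <- interaction(
    curves$material_id, curves$panelist_id, curves$replicate, drop = TRUE
  )
  for (d in split(curves, split_keys)) {
    key <- sprintf(
      "(material '%s', panelist '%s', replicate %d)",
      d$material_id[1], d$panelist_id[1], d$replicate[1]
    )
    check_group(d, key)
  }
  curves
}

#' Write a curve table to CSV in canonical column order
#'
#' @param curves Validated curve table (see [read_ti_curves()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ti_curves <- function(curves, path) {
  curves <- validate_ti_curves(curves)
  readr::write_csv(
    curves[, c("material_id", "panelist_id", "replicate", "time_s", "intensity")],
    path
  )
  invisible(path)
}

#' Read material metadata
#'
#' Materials are flavoring substances classified by their solvent and
#' volatility class: `essence` (water-soluble, high volatility), `oil`
#' (oil-soluble, low volatility) or `flavor` (intermediate polarity).
#' The `mtype` column is case-folded on read; any other value is rejected.
#'
#' @param path CSV with columns `material_id`, `name`, `mtype`, `category`.
#' @return Tibble with one row per material; `material_id` is unique.
#' @export
read_materials <- function(path) {
  df <- read_checked_csv(
    path,
    cols = c("material_id", "name", "mtype", "category"),
    col_types = readr::cols(.default = readr::col_character())
  )
  validate_materials(df)
}

#' @rdname read_materials
#' @param materials Data frame of material metadata to validate.
#' @export
validate_materials <- function(materials) {
  materials <- require_columns(
    materials, c("material_id", "name", "mtype", "category")
  )
  materials$mtype <- tolower(materials$mtype)
  bad <- !materials$mtype %in% material_types()
  if (any(bad)) {
    abort(sprintf(
      "materials table: unknown mtype '%s' for material '%s'; allowed values are %s",
      materials$mtype[which(bad)[1]], materials$material_id[which(bad)[1]],
      paste(material_types(), collapse = ", ")
    ))
  }
  dup <- duplicated(materials$material_id)
  if (any(dup)) {
    abort(sprintf(
      "materials table: duplicated material_id '%s'", materials$material_id[which(dup)[1]]
    ))
  }
  materials
}

#' @rdname read_materials
#' @export
write_materials <- function(materials, path) {
  materials <- validate_materials(materials)
  readr::write_csv(
    materials[, c("material_id", "name", "mtype", "category")], path
  )
  invisible(path)
}

#' Read visual-analog-scale (VAS) beany-intensity ratings
#'
#' One row per (material, panelist) rating of residual beany intensity,
#' stored on the 0--10 scale (the 100 mm VAS mark divided by 10).
#'
#' @param path CSV with columns `material_id`, `panelist_id`,
#'   `beany_intensity`.
#' @return Tibble of validated ratings.
#' @export
read_vas <- function(path) {
  df <- read_checked_csv(
    path,
    cols = c("material_id", "panelist_id", "beany_intensity"),
    col_types = readr::cols(
      material_id = readr::col_character(),
      panelist_id = readr::col_character(),
      beany_intensity = readr::col_double()
    )
  )
  validate_vas(df)
}

#' @rdname read_vas
#' @param vas Data frame of VAS records to validate.
#' @export
validate_vas <- function(vas) {
  vas <- require_columns(vas, c("material_id", "panelist_id", "beany_intensity"))
  bad <- !is.finite(vas$beany_intensity) |
    vas$beany_intensity < 0 | vas$beany_intensity > 10
  if (any(bad)) {
    i <- which(bad)[1]
    abort(sprintf(
      "vas table: beany_intensity %s outside [0, 10] for material '%s', panelist '%s'",
      format(vas$beany_intensity[i]), vas$material_id[i], vas$panelist_id[i]
    ))
  }
  vas
}

#' @rdname read_vas
#' @export
write_vas <- function(vas, path) {
  vas <- validate_vas(vas)
  readr::write_csv(vas[, c("material_id", "panelist_id", "beany_intensity")], path)
  invisible(path)
}

#' Read or write a materials-by-parameters matrix
#'
#' The parameter matrix has one row per material and one column per TI
#' parameter; columns are written in the canonical order of
#' [ti_parameter_names()]. A matrix restricted to a retained subset of the
#' 14 parameters (after pruning) is valid; unknown columns are not.
#'
#' @param path CSV path; first column `material_id`, remaining columns TI
#'   parameter names.
#' @return A tibble with `material_id` plus parameter columns in canonical
#'   order.
#' @export
read_parameter_matrix <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_parameter_matrix(df)
}

#' @rdname read_parameter_matrix
#' @param matrix Data frame with `material_id` plus TI-parameter columns.
#' @export
validate_parameter_matrix <- function(matrix) {
  matrix <- require_columns(matrix, "material_id")
  pcols <- setdiff(names(matrix), "material_id")
  unknown <- setdiff(pcols, ti_parameter_names())
  if (length(unknown) > 0) {
    abort(sprintf(
      "parameter matrix: unknown parameter column(s) %s; allowed columns are the 14 TI parameters",
      paste(sprintf("'%s'", unknown), collapse = ", ")
    ))
  }
  if (length(pcols) == 0) {
    abort("parameter matrix: no parameter columns present")
  }
  vals <- as.matrix(matrix[pcols])
  if (!is.numeric(vals) || any(!is.finite(vals))) {
    abort("parameter matrix: all parameter values must be finite numbers (no missing values)")
  }
  dup <- duplicated(matrix$material_id)
  if (any(dup)) {
    abort(sprintf(
      "parameter matrix: duplicated material_id '%s'", matrix$material_id[which(dup)[1]]
    ))
  }
  ord <- intersect(ti_parameter_names(), pcols)
  tibble::as_tibble(matrix[, c("material_id", ord)])
}

#' @rdname read_parameter_matrix
#' @export
write_parameter_matrix <- function(matrix, path) {
  matrix <- validate_parameter_matrix(matrix)
  readr::write_csv(matrix, path)
  invisible(path)
}

# -- internal helpers ---------------------------------------------------------

read_checked_csv <- function(path, cols, col_types) {
  header <- names(readr::read_csv(
    path, n_max = 0, show_col_types = FALSE, progress = FALSE
  ))
  missing <- setdiff(cols, header)
  if (length(missing) > 0) {
    abort(sprintf(
      "file '%s': missing required column(s) %s",
      path, paste(sprintf("'%s'", missing), collapse = ", ")
    ))
  }
  df <- readr::read_csv(path, col_types = col_types, progress = FALSE)
  problems <- readr::problems(df)
  if (nrow(problems) > 0) {
    abort(sprintf(
      "file '%s': %d parsing problem(s); first at row %d: expected %s",
      path, nrow(problems), problems$row[1], problems$expected[1]
    ))
  }
  tibble::as_tibble(df[, cols])
}

require_columns <- function(df, cols) {
  if (!is.data.frame(df)) {
    abort("expected a data frame")
  }
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "missing required column(s) %s",
      paste(sprintf("'%s'", missing), collapse = ", ")
    ))
  }
  tibble::as_tibble(df)
}
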