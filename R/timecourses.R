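#' Read well-level live/dead count time courses
#'
#' Reads a long-format CSV of live and dead cell counts over time, one row
#' per (drug, cell line, dose, replicate, time). The canonical header is
#' `drug, cell_line, dose_M, time_h, live, dead, replicate`; files with
#' other column names are remapped through `column_map`. Doses are molar and
#' a dose of 0 denotes the vehicle control; vehicle rows are retained since
#' RV and GR need them as the reference.
#'
#' @param path Path to a CSV file.
#' @param column_map Optional remapping of columns: a named list/character
#'   vector `canonical = file_column` (canonical names: `drug`, `cell_line`,
#'   `dose`, `time`, `live`, `dead`, `replicate`), or a path to a YAML or
#'   JSON file holding such a mapping. `cell_line` and `replicate` are
#'   optional in the file and default to `"unknown"` and 1.
#' @return A `grade_timecourses` tibble with columns `drug`, `cell_line`,
#'   `dose`, `replicate`, `time`, `live`, `dead`, deterministically ordered.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(drug = "d1", cell_line = "u2os", dose_M = c(0, 1e-6),
#'                      time_h = 72, live = c(4000, 900), dead = c(20, 600),
#'                      replicate = 1), f, row.names = FALSE)
#' read_timecourses(f)
#' @export
read_timecourses <- function(path, column_map = NULL) {
  if (!file.exists(path)) {
    rlang::abort(paste0("file not found: ", path), class = "druggrade_error_io")
  }
  raw <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) rlang::abort(paste0("could not parse ", path, ": ", conditionMessage(e)),
                                     class = "druggrade_error_parse")
  )
  if (nrow(raw) == 0) {
    rlang::abort("input file has no data rows.", class = "druggrade_error_empty_input")
  }
  map <- resolve_column_map(column_map)
  for (canon in c("drug", "dose", "time", "live", "dead")) {
    if (!map[[canon]] %in% names(raw)) {
      rlang::abort(sprintf("required column '%s' (for '%s') not found in %s",
                           map[[canon]], canon, path),
                   class = "druggrade_error_schema")
    }
  }
  tc <- tibble::tibble(
    drug = as.character(raw[[map[["drug"]]]]),
    cell_line = if (map[["cell_line"]] %in% names(raw)) {
      as.character(raw[[map[["cell_line"]]]])
    } else "unknown",
    dose = parse_numeric_column(raw[[map[["dose"]]]], map[["dose"]]),
    replicate = if (map[["replicate"]] %in% names(raw)) {
      as.integer(parse_numeric_column(raw[[map[["replicate"]]]], map[["replicate"]]))
    } else 1L,
    time = parse_numeric_column(raw[[map[["time"]]]], map[["time"]]),
    live = parse_numeric_column(raw[[map[["live"]]]], map[["live"]]),
    dead = parse_numeric_column(raw[[map[["dead"]]]], map[["dead"]])
  )
  as_grade_timecourses(tc)
}

default_column_map <- function() {
  c(drug = "drug", cell_line = "cell_line", dose = "dose_M", time = "time_h",
    live = "live", dead = "dead", replicate = "replicate")
}

resolve_column_map <- function(column_map) {
  map <- default_column_map()
  if (is.null(column_map)) return(as.list(map))
  if (is.character(column_map) && length(column_map) == 1L && file.exists(column_map)) {
    column_map <- if (grepl("\\.json$", column_map, ignore.case = TRUE)) {
      jsonlite::read_json(column_map, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(column_map)
    }
  }
  column_map <- unlist(column_map)
  unknown <- setdiff(names(column_map), names(map))
  if (length(unknown) > 0) {
    rlang::abort(paste0("unknown canonical column name(s) in column_map: ",
                        paste(unknown, collapse = ", ")),
                 class = "druggrade_error_schema")
  }
  map[names(column_map)] <- column_map
  as.list(map)
}

parse_numeric_column <- function(x, name) {
  if (is.numeric(x)) return(as.numeric(x))
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad) > 0) {
    rlang::abort(sprintf("column '%s' has non-numeric value '%s' at data row %d",
                         name, x[bad[1]], bad[1]),
                 class = "druggrade_error_parse")
  }
  out
}

#' Validate and classify a count time-course table
#'
#' Checks a long-format table of counts (columns `drug`, `cell_line`,
#' `dose`, `replicate`, `time`, `live`, `dead`): counts non-negative, times
#' unique within each well series. Rows are sorted deterministically by
#' (drug, cell line, dose, replicate, time).
#'
#' @param df A data frame with the canonical columns.
#' @return The validated table as a `grade_timecourses` tibble.
#' @export
as_grade_timecourses <- function(df) {
  needed <- c("drug", "cell_line", "dose", "replicate", "time", "live", "dead")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    rlang::abort(paste0("missing column(s): ", paste(missing, collapse = ", ")),
                 class = "druggrade_error_schema")
  }
  tc <- tibble::as_tibble(df)[, needed]
  if (any(tc$live < 0) || any(tc$dead < 0)) {
    rlang::abort("cell counts must be non-negative.", class = "druggrade_error_domain")
  }
  if (any(tc$dose < 0)) {
    rlang::abort("doses must be non-negative (0 = vehicle).", class = "druggrade_error_domain")
  }
  dup <- dplyr::count(tc, .data$drug, .data$cell_line, .data$dose,
                      .data$replicate, .data$time)
  if (any(dup$n > 1)) {
    rlang::abort("duplicate time point within a well series; times must be unique per well.",
                 class = "druggrade_error_domain")
  }
  tc <- dplyr::arrange(tc, .data$drug, .data$cell_line, .data$dose,
                       .data$replicate, .data$time)
  class(tc) <- c("grade_timecourses", class(tibble::tibble()))
  tc
}

#' Write time courses in the standard long CSV format
#'
#' Inverse of [read_timecourses()]: emits the canonical header
#' `drug, cell_line, dose_M, time_h, live, dead, replicate`, so that a
#' read/write round trip preserves all fields.
#'
#' @param timecourses A `grade_timecourses` table (or any data frame with
#'   the canonical columns).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_timecourses <- function(timecourses, path) {
  tc <- as_grade_timecourses(timecourses)
  out <- tibble::tibble(drug = tc$drug, cell_line = tc$cell_line,
                        dose_M = tc$dose, time_h = tc$time,
                        live = tc$live, dead = tc$dead,
                        replicate = tc$replicate)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
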