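# Domain types and CSV I/O for the two input tables: town climate records
# (one row per town, five factors) and monitoring-plot series (long format,
# one row per plot x observation year, with per-plot eligibility flags).

#' Seral stages of the succession chain
#'
#' The three observable stages, in succession order. Secondary bare land
#' precedes grassland in the conceptual chain but is never observed in the
#' monitoring data, so it is not a member of the vocabulary.
#'
#' @return Character vector `c("grassland", "shrub", "forest")`, ordered
#'   from earliest to latest stage.
#' @export
seral_stages <- function() c("grassland", "shrub", "forest")

#' Parse land-cover codes into seral stages
#'
#' The stage vocabulary is closed: any code that does not map to one of
#' the three stages is a parse error rather than a silent drop, so dirty
#' data fails loudly.
#'
#' @param x character vector of stage codes as they appear in the data.
#' @param codes named character vector mapping data codes (names, matched
#'   case-insensitively) to canonical stages (values). The default accepts
#'   the canonical names themselves.
#' @return Ordered factor with levels [seral_stages()].
#' @export
seral_stage <- function(x, codes = NULL) {
  codes <- codes %||% stats::setNames(seral_stages(), seral_stages())
  if (!all(codes %in% seral_stages())) {
    stop_nsindex("nsindex_config_error",
                 "Stage code map must target grassland/shrub/forest only.")
  }
  names(codes) <- tolower(names(codes))
  mapped <- unname(codes[tolower(as.character(x))])
  bad <- unique(as.character(x)[is.na(mapped) & !is.na(x)])
  if (length(bad)) {
    stop_nsindex("nsindex_parse_error",
                 paste0("Unknown seral stage code(s): ",
                        paste0('"', bad, '"', collapse = ", ")))
  }
  factor(mapped, levels = seral_stages(), ordered = TRUE)
}

#' Default column maps for the two input tables
#'
#' Column naming is configuration, not convention: readers accept a named
#' character vector whose names are the canonical field names and whose
#' values are the column headers actually present in the file.
#'
#' @return Named character vector (canonical field -> file column).
#' @export
town_columns <- function() {
  fields <- c("town_id", "accumulated_temperature", "annual_precipitation",
              "relative_humidity", "mean_annual_temperature", "mean_altitude")
  stats::setNames(fields, fields)
}

#' @rdname town_columns
#' @export
plot_columns <- function() {
  fields <- c("plot_id", "town_id", "year", "stage",
              "initial_grassland", "disturbance_cleared",
              "disaster_free", "protected")
  stats::setNames(fields, fields)
}

plot_flag_fields <- function() {
  c("initial_grassland", "disturbance_cleared", "disaster_free", "protected")
}

# parse a character column to numeric, failing with row indices
parse_numeric_column <- function(txt, field, rows = seq_along(txt)) {
  val <- suppressWarnings(as.numeric(txt))
  bad <- which(!is.na(txt) & is.na(val))
  if (length(bad)) {
    stop_nsindex(
      "nsindex_parse_error",
      paste0("Non-numeric value(s) in column '", field, "' at row(s) ",
             paste(rows[bad], collapse = ", "), ": ",
             paste0('"', txt[bad], '"', collapse = ", "))
    )
  }
  val
}

parse_logical_column <- function(txt, field, rows = seq_along(txt)) {
  val <- suppressWarnings(as.logical(txt))
  num <- suppressWarnings(as.numeric(txt))
  val[is.na(val) & !is.na(num)] <- num[is.na(val) & !is.na(num)] != 0
  bad <- which(!is.na(txt) & is.na(val))
  if (length(bad)) {
    stop_nsindex(
      "nsindex_parse_error",
      paste0("Non-logical value(s) in column '", field, "' at row(s) ",
             paste(rows[bad], collapse = ", "))
    )
  }
  val
}

require_columns <- function(found, wanted, what) {
  missing <- setdiff(unname(wanted), found)
  if (length(missing)) {
    stop_nsindex(
      "nsindex_schema_error",
      paste0("Missing required column(s) in ", what, ": ",
             paste(missing, collapse = ", "))
    )
  }
  invisible(TRUE)
}

read_raw_csv <- function(path) {
  if (!file.exists(path)) {
    stop_nsindex("nsindex_schema_error", paste0("File not found: ", path))
  }
  readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                  progress = FALSE)
}

#' Read and validate town climate records
#'
#' Ingests one row per town with the five zonation factors: annual
#' accumulated temperature (degree C day, the annual sum of daily mean
#' temperatures above 0 degrees C), annual precipitation (mm), relative
#' humidity (percent), mean annual temperature (degree C) and mean
#' altitude (m). Units are taken at face value; nothing is imputed.
#'
#' @param path CSV file (header row, UTF-8).
#' @param col_map canonical-field -> file-column map, see [town_columns()].
#' @return Validated tibble with canonical column names.
#' @export
read_town_records <- function(path, col_map = town_columns()) {
  raw <- read_raw_csv(path)
  require_columns(names(raw), col_map, paste0("town table '", path, "'"))
  out <- tibble(town_id = as.character(raw[[col_map[["town_id"]]]]))
  for (field in setdiff(names(town_columns()), "town_id")) {
    out[[field]] <- parse_numeric_column(raw[[col_map[[field]]]], field)
  }
  validate_town_records(out)
}

#' Validate a collection of town climate records
#'
#' Checks the domain invariants: positive accumulated temperature,
#' relative humidity in (0, 100], non-negative precipitation, and unique
#' town identifiers.
#'
#' @param towns tibble with the canonical town columns.
#' @return `towns`, invisibly usable, returned unchanged on success.
#' @export
validate_town_records <- function(towns) {
  require_columns(names(towns), town_columns(), "town records")
  if (anyDuplicated(towns$town_id)) {
    dup <- unique(towns$town_id[duplicated(towns$town_id)])
    stop_nsindex("nsindex_integrity_error",
                 paste0("Duplicate town_id: ", paste(dup, collapse = ", ")))
  }
  checks <- list(
    "accumulated_temperature must be > 0" =
      towns$accumulated_temperature > 0,
    "relative_humidity must be in (0, 100]" =
      towns$relative_humidity > 0 & towns$relative_humidity <= 100,
    "annual_precipitation must be >= 0" =
      towns$annual_precipitation >= 0
  )
  for (msg in names(checks)) {
    ok <- checks[[msg]]
    if (any(!ok, na.rm = TRUE) || anyNA(ok)) {
      stop_nsindex("nsindex_validation_error",
                   paste0(msg, " (row(s) ",
                          paste(which(!ok | is.na(ok)), collapse = ", "), ")"))
    }
  }
  towns
}

#' Write town climate records to CSV
#'
#' Writes the canonical columns in deterministic order; `read_town_records`
#' of the result returns an identical collection.
#'
#' @param towns validated town tibble.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_town_records <- function(towns, path) {
  towns <- validate_town_records(towns)
  readr::write_csv(towns[, names(town_columns())], path, progress = FALSE)
  invisible(path)
}

#' Read and validate monitoring-plot series
#'
#' Reads plot series in long format (one row per plot and observation
#' year) or wide format (one row per plot, one column per observation
#' year, via `year_columns`). Stage codes are mapped through a closed
#' vocabulary (see [seral_stage()]). Eligibility-flag columns that are
#' absent default to `TRUE` with a warning, because deposited monitoring
#' tables are typically pre-filtered to eligible samples.
#'
#' @param path CSV file.
#' @param col_map canonical-field -> file-column map, see [plot_columns()].
#' @param stage_codes optional code map passed to [seral_stage()].
#' @param year_columns optional named numeric vector for wide input:
#'   names are stage columns in the file, values the observation years.
#' @param interval expected observation spacing in years (`NULL` to only
#'   require even spacing).
#' @return Validated long tibble: `plot_id`, `town_id`, `year`, `stage`
#'   plus the four logical eligibility flags, sorted by plot and year.
#' @export
read_plot_series <- function(path, col_map = plot_columns(),
                             stage_codes = NULL, year_columns = NULL,
                             interval = 5) {
  raw <- read_raw_csv(path)
  if (is.null(year_columns)) {
    needed <- col_map[c("plot_id", "town_id", "year", "stage")]
    require_columns(names(raw), needed, paste0("plot table '", path, "'"))
    out <- tibble(
      plot_id = as.character(raw[[col_map[["plot_id"]]]]),
      town_id = as.character(raw[[col_map[["town_id"]]]]),
      year = parse_numeric_column(raw[[col_map[["year"]]]], "year"),
      stage = seral_stage(raw[[col_map[["stage"]]]], stage_codes)
    )
  } else {
    needed <- col_map[c("plot_id", "town_id")]
    require_columns(names(raw), c(needed, names(year_columns)),
                    paste0("plot table '", path, "'"))
    out <- tibble(
      plot_id = rep(as.character(raw[[col_map[["plot_id"]]]]),
                    times = length(year_columns)),
      town_id = rep(as.character(raw[[col_map[["town_id"]]]]),
                    times = length(year_columns)),
      year = rep(unname(year_columns), each = nrow(raw)),
      stage = seral_stage(unlist(lapply(names(year_columns),
                                        function(cl) raw[[cl]])),
                          stage_codes)
    )
    raw <- raw[rep(seq_len(nrow(raw)), times = length(year_columns)), ]
  }
  defaulted <- character()
  for (flag in plot_flag_fields()) {
    cl <- col_map[[flag]]
    if (!is.null(cl) && cl %in% names(raw)) {
      out[[flag]] <- parse_logical_column(raw[[cl]], flag)
    } else {
      defaulted <- c(defaulted, flag)
      out[[flag]] <- TRUE
    }
  }
  if (length(defaulted)) {
    warn(paste0("Eligibility flag column(s) absent, defaulting to TRUE ",
                "(input assumed pre-filtered to eligible plots): ",
                paste(defaulted, collapse = ", ")))
  }
  out <- arrange(out, .data$plot_id, .data$year)
  validate_plot_series(out, interval = interval)
}

#' Validate a collection of plot series
#'
#' Checks that observation years are unique, strictly increasing and
#' evenly spaced within each plot (at `interval` years if given), that
#' eligibility flags are constant within a plot, and that stages belong to
#' the closed vocabulary.
#'
#' @param plots long plot tibble.
#' @param interval expected spacing in years, or `NULL` to only require
#'   even spacing.
#' @return `plots`, sorted by plot and year.
#' @export
validate_plot_series <- function(plots, interval = 5) {
  need <- c("plot_id", "town_id", "year", "stage", plot_flag_fields())
  require_columns(names(plots), need, "plot series")
  if (!is.factor(plots$stage)) {
    plots$stage <- seral_stage(as.character(plots$stage))
  }
  plots <- arrange(plots, .data$plot_id, .data$year)
  dup <- duplicated(plots[, c("plot_id", "year")])
  if (any(dup)) {
    stop_nsindex("nsindex_integrity_error",
                 paste0("Duplicate (plot_id, year) observation(s): ",
                        paste(unique(plots$plot_id[dup]), collapse = ", ")))
  }
  checks <- plots |>
    group_by(.data$plot_id) |>
    summarise(
      spacing_ok = n() == 1L || length(unique(diff(.data$year))) == 1L,
      interval_ok = is.null(interval) || n() == 1L ||
        all(diff(.data$year) == interval),
      across(all_of(plot_flag_fields()), ~ length(unique(.x)) == 1L),
      .groups = "drop"
    )
  checks$flags_ok <- Reduce(`&`, lapply(plot_flag_fields(),
                                        function(f) checks[[f]]))
  bad_spacing <- checks$plot_id[!checks$spacing_ok | !checks$interval_ok]
  if (length(bad_spacing)) {
    stop_nsindex("nsindex_validation_error",
                 paste0("Observation years not evenly spaced",
                        if (!is.null(interval))
                          paste0(" at ", interval, "-year intervals"),
                        " for plot(s): ",
                        paste(bad_spacing, collapse = ", ")))
  }
  bad_flags <- checks$plot_id[!checks$flags_ok]
  if (length(bad_flags)) {
    stop_nsindex("nsindex_integrity_error",
                 paste0("Eligibility flags vary within plot(s): ",
                        paste(bad_flags, collapse = ", ")))
  }
  plots
}

#' Write plot series to CSV (long format)
#'
#' @param plots validated long plot tibble.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_plot_series <- function(plots, path) {
  plots <- validate_plot_series(plots, interval = NULL)
  out <- plots[, c("plot_id", "town_id", "year", "stage", plot_flag_fields())]
  out$stage <- as.character(out$stage)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Retain only eligible plot series
#'
#' A plot is eligible when it satisfies all monitoring criteria: grassland
#' land type at the first observation, early disturbance (grazing or
#' cutting) that disappeared afterwards, no significant natural disasters
#' or human intervention, protection throughout, and a first-observation
#' stage of grassland. Input order is preserved and the number of removed
#' plots is reported via `message()`.
#'
#' @param plots validated long plot tibble.
#' @return Subset of `plots` with only eligible plots. Idempotent.
#' @export
filter_eligible <- function(plots) {
  plots <- validate_plot_series(plots, interval = NULL)
  status <- plots |>
    group_by(.data$plot_id) |>
    summarise(
      eligible = all(.data$initial_grassland) &
        all(.data$disturbance_cleared) &
        all(.data$disaster_free) &
        all(.data$protected) &
        first(.data$stage) == "grassland",
      .groups = "drop"
    )
  keep <- status$plot_id[status$eligible]
  removed <- nrow(status) - length(keep)
  message(sprintf("filter_eligible: removed %d of %d plots", removed,
                  nrow(status)))
  plots[plots$plot_id %in% keep, ]
}
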