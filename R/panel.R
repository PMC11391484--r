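#' Personnel categories tracked in a workforce panel
#'
#' The four staffing categories of the provincial CDC workforce panels this
#' package analyses: healthcare (medical) technical staff, other technical
#' staff, managerial staff, and skilled-workforce (logistics) staff.
#'
#' @return Character vector of the four category labels.
#' @export
hr_categories <- function() {
  c("healthcare_technical", "other_technical", "managerial",
    "workforce_technical")
}

panel_columns <- c("province", "region", "year", "category",
                   "personnel", "population", "area")

#' Validate a provincial workforce panel
#'
#' A panel is a long-format table with one row per (province, year, category)
#' observation and columns `province`, `region`, `year`, `category`,
#' `personnel` (headcount), `population` (thousands of residents) and `area`
#' (square kilometres). `as_hr_panel()` checks the panel invariants and
#' returns a validated tibble of class `hr_panel` carrying its region scheme
#' as an attribute:
#'
#' * `personnel >= 0`, `population > 0`, `area > 0` on every row;
#' * `category` drawn from [hr_categories()];
#' * `(province, year, category)` unique;
#' * every province covered by `scheme`, with the `region` column matching
#'   the scheme's assignment.
#'
#' Violations are reported with the offending row numbers.
#'
#' @param data A data frame with the seven panel columns (extra columns are
#'   dropped).
#' @param scheme A [region_scheme()] covering the panel's provinces.
#'   Defaults to [default_region_scheme()].
#' @return A tibble of class `hr_panel` with attribute `scheme`.
#' @examples
#' df <- tibble::tibble(
#'   province = c("Shanghai", "Tibet"), region = c("Eastern", "Western"),
#'   year = 2020L, category = "healthcare_technical",
#'   personnel = c(2242, 1110), population = c(24871, 3648),
#'   area = c(6340, 1228400)
#' )
#' panel <- as_hr_panel(df)
#' @export
as_hr_panel <- function(data, scheme = default_region_scheme()) {
  stopifnot(inherits(scheme, "region_scheme"))
  if (!is.data.frame(data)) {
    abort("`data` must be a data frame.", class = "hrequity_schema_error")
  }
  missing_cols <- setdiff(panel_columns, names(data))
  if (length(missing_cols)) {
    abort(paste0("Panel is missing required columns: ",
                 paste(missing_cols, collapse = ", ")),
          class = "hrequity_schema_error")
  }
  data <- tibble::as_tibble(data)[panel_columns]
  data$province <- as.character(data$province)
  data$region   <- as.character(data$region)
  data$category <- as.character(data$category)
  data$year     <- as.integer(data$year)
  data$personnel  <- as.numeric(data$personnel)
  data$population <- as.numeric(data$population)
  data$area       <- as.numeric(data$area)

  problems <- character()
  flag <- function(bad, what) {
    if (any(bad, na.rm = TRUE)) {
      rows <- which(bad | is.na(bad))
      problems <<- c(problems, paste0(
        "rows ", paste(head(rows, 10), collapse = ", "),
        if (length(rows) > 10) ", ..." else "", ": ", what))
    }
  }
  flag(is.na(data$personnel) | data$personnel < 0,
       "`personnel` must be a non-negative count")
  flag(is.na(data$population) | data$population <= 0,
       "`population` must be > 0 (thousands of residents)")
  flag(is.na(data$area) | data$area <= 0,
       "`area` must be > 0 (square kilometres)")
  flag(!data$category %in% hr_categories(),
       paste0("`category` must be one of: ",
              paste(hr_categories(), collapse = ", ")))
  if (length(problems)) {
    abort(c("Invalid panel rows.", setNames(problems, rep("x", length(problems)))),
          class = "hrequity_value_error")
  }

  dup <- duplicated(data[c("province", "year", "category")])
  if (any(dup)) {
    abort(paste0("Duplicate (province, year, category) rows: ",
                 paste(head(which(dup), 10), collapse = ", ")),
          class = "hrequity_uniqueness_error")
  }

  uncovered <- setdiff(unique(data$province), names(scheme$assignment))
  if (length(uncovered)) {
    abort(paste0("Provinces not covered by the region scheme: ",
                 paste(uncovered, collapse = ", ")),
          class = "hrequity_assignment_error")
  }
  expected <- region_of(scheme, data$province)
  mismatch <- data$region != expected
  if (any(mismatch)) {
    abort(paste0("`region` disagrees with the scheme assignment on rows: ",
                 paste(head(which(mismatch), 10), collapse = ", ")),
          class = "hrequity_assignment_error")
  }

  structure(data, scheme = scheme,
            class = c("hr_panel", class(tibble::tibble())))
}

#' Read a provincial workforce panel from CSV
#'
#' Expects a UTF-8, comma-delimited file with a header row naming the seven
#' panel columns (in any order); the result is validated with
#' [as_hr_panel()].
#'
#' @param path Path of the CSV file.
#' @param scheme A [region_scheme()]; defaults to the built-in three-region
#'   scheme for mainland China.
#' @return A validated `hr_panel` tibble.
#' @seealso [write_panel()] for the inverse; the pair round-trips exactly.
#' @export
read_panel <- function(path, scheme = default_region_scheme()) {
  if (!file.exists(path)) {
    abort(paste0("Panel file not found: ", path), class = "hrequity_io_error")
  }
  header <- names(readr::read_csv(path, n_max = 0, col_types = readr::cols(),
                                  progress = FALSE, show_col_types = FALSE))
  missing_cols <- setdiff(panel_columns, header)
  if (length(missing_cols)) {
    abort(paste0("Panel CSV is missing required columns: ",
                 paste(missing_cols, collapse = ", ")),
          class = "hrequity_schema_error")
  }
  data <- readr::read_csv(
    path,
    col_types = readr::cols(
      province = readr::col_character(),
      region = readr::col_character(),
      year = readr::col_integer(),
      category = readr::col_character(),
      personnel = readr::col_double(),
      population = readr::col_double(),
      area = readr::col_double(),
      .default = readr::col_skip()
    ),
    progress = FALSE
  )
  as_hr_panel(data, scheme = scheme)
}

#' Write a panel to CSV
#'
#' Values are written at full precision so that `read_panel()` reproduces the
#' panel field-for-field; an empty panel yields a header-only file.
#'
#' @param panel An `hr_panel` (or any data frame with the panel columns).
#' @param path Destination file path.
#' @return Invisibly, `panel`.
#' @export
write_panel <- function(panel, path) {
  df <- tibble::as_tibble(as.data.frame(panel))[panel_columns]
  readr::write_csv(df, path, progress = FALSE)
  invisible(panel)
}

#' @export
print.hr_panel <- function(x, ...) {
  scheme <- attr(x, "scheme")
  cat("<hr_panel> ", length(unique(x$province)), " provinces, years ",
      if (nrow(x)) paste0(min(x$year), "-", max(x$year)) else "(none)",
      ", ", length(unique(x$category)), " categories\n", sep = "")
  NextMethod()
}

panel_scheme <- function(panel, scheme = NULL) {
  scheme %||% attr(panel, "scheme") %||% default_region_scheme()
}

# One (year, category) cross-section with one row per province.
panel_slice <- function(panel, year, category, call = rlang::caller_env()) {
  stopifnot(length(year) == 1, length(category) == 1)
  slice <- dplyr::filter(tibble::as_tibble(panel),
                         .data$year == !!year, .data$category == !!category)
  if (nrow(slice) == 0) {
    abort(paste0("Panel has no rows for year ", year, ", category '",
                 category, "'."),
          class = "hrequity_empty_slice_error", call = call)
  }
  if (anyDuplicated(slice$province)) {
    abort("Cross-section has duplicated provinces.",
          class = "hrequity_uniqueness_error", call = call)
  }
  slice
}
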