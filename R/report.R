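#' Run the full allocation-equity report over a panel
#'
#' Orchestrates the whole analysis and writes the five standard table shapes
#' of a health-resource equity study as CSV files:
#'
#' * `staffing_growth.csv` — total personnel per year, nationally and per
#'   region, with chain growth rates (2 dp);
#' * `hrdi_by_province.csv` — densities (4 dp), HRDI (4 dp) and rank per
#'   province and category for the report year, provinces ordered by
#'   descending HRDI within region blocks;
#' * `hrdi_by_region.csv` — national and regional HRDI (4 dp) per category,
#'   one column per year;
#' * `gini_series.csv` — weighted Gini (3 dp) and its equity band per
#'   category, year and weighting;
#' * `theil_components.csv` / `theil_contributions.csv` — Theil index with
#'   between/within components (4 dp) and contribution percentages (2 dp).
#'
#' Rounding happens only at serialisation; the returned bundle holds full
#' precision, so every written value is re-derivable from the panel with the
#' corresponding function ([chain_growth()], [density_table()],
#' [regional_hrdi()], [panel_gini()], [panel_theil()]). The report is a pure
#' function of (panel, scheme): repeated runs write identical files.
#'
#' @param panel A validated `hr_panel`, or a path to a panel CSV.
#' @param out_dir Directory for the CSV files (created if needed).
#' @param scheme Optional [region_scheme()] or path to a scheme JSON;
#'   defaults to the panel's own scheme.
#' @param report_year Year used for the per-province density table; default
#'   the panel's latest year.
#' @param quiet Suppress the per-value Gini band log lines.
#' @return Invisibly, an `hr_report` list with elements `growth`,
#'   `density`, `regional_hrdi`, `gini`, `theil_components`,
#'   `theil_contributions` (full-precision tibbles) and `files`.
#' @export
run_report <- function(panel, out_dir, scheme = NULL,
                       report_year = NULL, quiet = FALSE) {
  if (is.character(scheme)) scheme <- read_region_scheme(scheme)
  if (is.character(panel)) {
    panel <- read_panel(panel, scheme = scheme %||% default_region_scheme())
  }
  scheme <- panel_scheme(panel, scheme)
  panel <- as_hr_panel(tibble::as_tibble(panel), scheme = scheme)
  report_year <- report_year %||% max(panel$year)
  years <- sort(unique(panel$year))
  categories <- intersect(hr_categories(), unique(panel$category))

  growth <- panel |>
    tibble::as_tibble() |>
    dplyr::summarise(level = sum(.data$personnel),
                     .by = c("region", "year")) |>
    dplyr::bind_rows(
      panel |>
        tibble::as_tibble() |>
        dplyr::summarise(level = sum(.data$personnel), .by = "year") |>
        dplyr::mutate(region = "National")
    ) |>
    dplyr::mutate(region = factor(.data$region,
                                  levels = c("National", scheme$groups))) |>
    dplyr::arrange(.data$region, .data$year)
  growth <- if (length(years) >= 2) {
    chain_growth(growth, by = "region")
  } else {
    dplyr::mutate(growth, chain_growth_pct = NA_real_)
  }
  growth <- dplyr::rename(growth, personnel = "level")

  density <- purrr::map(categories, function(cat) {
    density_table(panel, report_year, cat) |>
      dplyr::mutate(category = cat, year = report_year)
  }) |>
    dplyr::bind_rows() |>
    dplyr::mutate(region = factor(.data$region, levels = scheme$groups)) |>
    dplyr::arrange(.data$category, .data$region, dplyr::desc(.data$hrdi)) |>
    dplyr::mutate(region = as.character(.data$region)) |>
    dplyr::select("category", "year", "region", "province", "pop_density",
                  "area_density", "hrdi", "rank")

  regional <- tidyr::expand_grid(category = categories, year = years) |>
    dplyr::mutate(rows = purrr::map2(
      .data$category, .data$year,
      function(cat, yr) {
        dplyr::select(regional_hrdi(panel, yr, cat, scheme = scheme),
                      "region", "hrdi")
      }
    )) |>
    tidyr::unnest("rows")

  gini_series <- panel_gini(panel, weighting = c("population", "area"),
                            categories = categories, years = years)
  if (!quiet) {
    purrr::pwalk(gini_series, function(category, year, weighting, gini, band) {
      message(sprintf("G(%s, %d, by %s) = %.3f [%s]",
                      category, year, weighting, gini, band))
    })
  }

  theil_components <- panel_theil(panel, categories = categories,
                                  years = years, scheme = scheme)
  theil_contributions <- panel_theil_contributions(
    panel, categories = categories, years = years, scheme = scheme)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(
    growth = file.path(out_dir, "staffing_growth.csv"),
    density = file.path(out_dir, "hrdi_by_province.csv"),
    regional_hrdi = file.path(out_dir, "hrdi_by_region.csv"),
    gini = file.path(out_dir, "gini_series.csv"),
    theil_components = file.path(out_dir, "theil_components.csv"),
    theil_contributions = file.path(out_dir, "theil_contributions.csv")
  )
  round_cols <- function(df, digits) {
    dplyr::mutate(df, dplyr::across(dplyr::all_of(names(digits)),
                                    ~ round(.x, digits[dplyr::cur_column()])))
  }
  readr::write_csv(round_cols(growth, c(chain_growth_pct = 2)),
                   files[["growth"]], na = "", progress = FALSE)
  readr::write_csv(
    round_cols(density, c(pop_density = 4, area_density = 4, hrdi = 4)),
    files[["density"]], progress = FALSE)
  readr::write_csv(
    regional |>
      dplyr::mutate(hrdi = round(.data$hrdi, 4)) |>
      tidyr::pivot_wider(names_from = "year", values_from = "hrdi"),
    files[["regional_hrdi"]], progress = FALSE)
  readr::write_csv(round_cols(gini_series, c(gini = 3)),
                   files[["gini"]], progress = FALSE)
  readr::write_csv(
    round_cols(theil_components,
               c(total = 4, between = 4, within = 4,
                 omega_between_pct = 2, omega_within_pct = 2)),
    files[["theil_components"]], progress = FALSE)
  readr::write_csv(round_cols(theil_contributions, c(contribution_pct = 2)),
                   files[["theil_contributions"]], progress = FALSE)

  invisible(structure(
    list(growth = growth, density = density, regional_hrdi = regional,
         gini = gini_series, theil_components = theil_components,
         theil_contributions = theil_contributions, files = files),
    class = "hr_report"
  ))
}

#' @export
print.hr_report <- function(x, ...) {
  cat("<hr_report>\n  tables:",
      paste(setdiff(names(x), "files"), collapse = ", "),
      "\n  files written:\n")
  for (f in x$files) cat("   -", f, "\n")
  invisible(x)
}
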