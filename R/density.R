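#' Health resource density index (HRDI)
#'
#' The HRDI summarises the allocation level of a health resource in a region
#' by combining its density per resident and per unit of land area:
#'
#' \deqn{HRDI_i = \sqrt{\frac{HR_i}{A_i} \cdot \frac{HR_i}{P_i}}
#'             = \frac{HR_i}{\sqrt{A_i P_i}}}
#'
#' where \eqn{HR_i} is the headcount, \eqn{P_i} the resident population (in
#' thousands) and \eqn{A_i} the land area (in square kilometres). It is the
#' geometric mean of the population density (staff per thousand residents)
#' and the geographic density (staff per km\eqn{^2}), so it always lies
#' between the two and is linear in the headcount.
#'
#' @param personnel Non-negative headcount(s).
#' @param population Resident population(s), thousands; must be positive.
#' @param area Land area(s), square kilometres; must be positive.
#' @return Numeric vector of HRDI values.
#' @examples
#' hrdi(2242, population = 24871, area = 6340)
#' hrdi_from_densities(0.0901, 0.3557)  # Shanghai healthcare staff, 2020
#' @export
hrdi <- function(personnel, population, area) {
  if (any(is.na(population)) || any(population <= 0)) {
    abort("`population` must be positive.", class = "hrequity_value_error")
  }
  if (any(is.na(area)) || any(area <= 0)) {
    abort("`area` must be positive.", class = "hrequity_value_error")
  }
  if (any(is.na(personnel)) || any(personnel < 0)) {
    abort("`personnel` must be non-negative.", class = "hrequity_value_error")
  }
  sqrt((personnel / area) * (personnel / population))
}

#' @description `hrdi_from_densities()` computes the same index directly from
#'   the two densities, so published density columns can be used as inputs
#'   without recovering raw headcounts.
#' @param pop_density Staff per thousand residents (\eqn{HR_i/P_i}).
#' @param area_density Staff per square kilometre (\eqn{HR_i/A_i}).
#' @rdname hrdi
#' @export
hrdi_from_densities <- function(pop_density, area_density) {
  if (any(is.na(pop_density)) || any(pop_density < 0) ||
      any(is.na(area_density)) || any(area_density < 0)) {
    abort("Densities must be non-negative.", class = "hrequity_value_error")
  }
  sqrt(pop_density * area_density)
}

#' Per-province density table for one cross-section
#'
#' Builds the standard per-province allocation table for a single `(year,
#' category)` slice: both densities, the HRDI, and a 1-based descending rank
#' of the HRDI. Ties in the HRDI are broken by province name (ascending), so
#' ranks are always a permutation of `1:n`.
#'
#' @param panel A validated `hr_panel`.
#' @param year Calendar year of the slice.
#' @param category One of [hr_categories()].
#' @return A tibble with columns `province`, `region`, `personnel`,
#'   `pop_density`, `area_density`, `hrdi`, `rank`, sorted by rank.
#' @export
density_table <- function(panel, year, category) {
  slice <- panel_slice(panel, year, category)
  slice |>
    dplyr::mutate(
      pop_density = .data$personnel / .data$population,
      area_density = .data$personnel / .data$area,
      hrdi = hrdi(.data$personnel, .data$population, .data$area)
    ) |>
    dplyr::arrange(dplyr::desc(.data$hrdi), .data$province) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::select("province", "region", "personnel", "pop_density",
                  "area_density", "hrdi", "rank")
}

#' Regional and national HRDI aggregates
#'
#' Aggregates a `(year, category)` slice to each region of the scheme and to
#' the nation: personnel, population and area are summed within the region
#' and the HRDI of the summed quantities is reported. (The index of pooled
#' totals, not the mean of provincial indices.)
#'
#' @inheritParams density_table
#' @param scheme Optional [region_scheme()]; defaults to the panel's own.
#' @param national_label Label used for the all-province aggregate row.
#' @return A tibble with columns `region`, `personnel`, `population`,
#'   `area`, `hrdi`; the national row first, then the scheme's groups in
#'   order.
#' @export
regional_hrdi <- function(panel, year, category, scheme = NULL,
                          national_label = "National") {
  scheme <- panel_scheme(panel, scheme)
  slice <- panel_slice(panel, year, category)
  by_region <- slice |>
    dplyr::summarise(
      personnel = sum(.data$personnel),
      population = sum(.data$population),
      area = sum(.data$area),
      .by = "region"
    )
  national <- slice |>
    dplyr::summarise(
      region = national_label,
      personnel = sum(.data$personnel),
      population = sum(.data$population),
      area = sum(.data$area)
    )
  dplyr::bind_rows(national, by_region) |>
    dplyr::mutate(
      region = factor(.data$region, levels = c(national_label, scheme$groups)),
      hrdi = hrdi(.data$personnel, .data$population, .data$area)
    ) |>
    dplyr::arrange(.data$region) |>
    dplyr::mutate(region = as.character(.data$region))
}
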