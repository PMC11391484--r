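#' Published workforce totals of China's provincial CDCs, 2016-2020
#'
#' The national and regional headcount series (in thousands of persons) of
#' China CDC human resources over 2016-2020, as published in the official
#' yearbook-derived summary, together with the published chain growth rates.
#' The published 2016 growth rates refer to 2015 levels that are not part of
#' the series, so only the 2017-2020 rates can be recomputed from these
#' levels.
#'
#' @return A tibble with columns `year`, `region` (`"National"`,
#'   `"Eastern"`, `"Central"`, `"Western"`), `personnel_thousands`, and
#'   `published_growth_pct`.
#' @examples
#' cdc_staff_totals() |>
#'   dplyr::filter(region == "National") |>
#'   dplyr::rename(level = personnel_thousands) |>
#'   chain_growth(by = "region")
#' @export
cdc_staff_totals <- function() {
  tibble::tribble(
    ~year, ~region, ~personnel_thousands, ~published_growth_pct,
    2016L, "National", 191.627,  0.37,
    2016L, "Eastern",   67.639,  0.09,
    2016L, "Central",   61.425, -0.34,
    2016L, "Western",   62.536,  1.47,
    2017L, "National", 190.730, -0.47,
    2017L, "Eastern",   66.180, -2.16,
    2017L, "Central",   60.931, -0.80,
    2017L, "Western",   63.619,  1.73,
    2018L, "National", 187.826, -1.52,
    2018L, "Eastern",   64.790, -2.10,
    2018L, "Central",   59.797, -1.86,
    2018L, "Western",   63.239, -0.60,
    2019L, "National", 187.564, -0.14,
    2019L, "Eastern",   64.324, -0.72,
    2019L, "Central",   59.224, -0.96,
    2019L, "Western",   64.016,  1.23,
    2020L, "National", 194.425,  3.66,
    2020L, "Eastern",   68.329,  6.23,
    2020L, "Central",   59.908,  1.15,
    2020L, "Western",   66.188,  3.39
  )
}

#' Published 2020 provincial density table of China's CDC workforce
#'
#' The published per-province allocation table for 2020: staff per thousand
#' residents (`pop_density`), staff per square kilometre (`area_density`),
#' the published HRDI and the published within-category rank, for all 31
#' provinces and all four categories of [hr_categories()]. Because the
#' density columns are printed rounded to 4 decimal places, an HRDI
#' recomputed from them can differ from the published HRDI by a few units in
#' the fourth decimal for coarsely printed cells (the propagated rounding
#' half-width is `0.5 * (5e-5/p + 5e-5/q) * HRDI + 5e-5`).
#'
#' @return A tibble with columns `province`, `region`, `category`,
#'   `pop_density`, `area_density`, `hrdi`, `rank` (124 rows).
#' @examples
#' shanghai <- dplyr::filter(cdc_hrdi_2020(),
#'                           province == "Shanghai",
#'                           category == "healthcare_technical")
#' hrdi_from_densities(shanghai$pop_density, shanghai$area_density)
#' @export
cdc_hrdi_2020 <- function() {
  path <- system.file("extdata", "cdc_hrdi_2020.csv", package = "hrequity",
                      mustWork = TRUE)
  readr::read_csv(path, col_types = "cccdddi", progress = FALSE)
}

#' Published Theil components of China's CDC workforce, 2016-2020
#'
#' The published total Theil index and its between-/within-region components
#' for each staffing category, year and weighting (population or geographic
#' area). The printed components satisfy `total = between + within` up to
#' the 4-decimal rounding of each entry (within 2e-4).
#'
#' @return A tibble with columns `category`, `weighting`, `year`, `total`,
#'   `between`, `within` (40 rows).
#' @export
cdc_theil_components <- function() {
  long <- function(category, weighting, total, between, within) {
    tibble::tibble(category = category, weighting = weighting,
                   year = 2016:2020, total = total, between = between,
                   within = within)
  }
  dplyr::bind_rows(
    long("healthcare_technical", "population",
         c(0.0367, 0.0388, 0.0391, 0.0415, 0.0424),
         c(0.0129, 0.0149, 0.0166, 0.0180, 0.0188),
         c(0.0238, 0.0239, 0.0225, 0.0234, 0.0235)),
    long("healthcare_technical", "area",
         c(0.6093, 0.6036, 0.6023, 0.5939, 0.6103),
         c(0.3324, 0.3227, 0.3149, 0.3094, 0.3138),
         c(0.2768, 0.2810, 0.2874, 0.2845, 0.2965)),
    long("other_technical", "population",
         c(0.0648, 0.0574, 0.0616, 0.0548, 0.0589),
         c(0.0083, 0.0042, 0.0053, 0.0018, 0.0019),
         c(0.0565, 0.0532, 0.0564, 0.0531, 0.0570)),
    long("other_technical", "area",
         c(0.8672, 0.8326, 0.8530, 0.8035, 0.8131),
         c(0.5319, 0.4933, 0.4906, 0.4765, 0.4837),
         c(0.3353, 0.3393, 0.3624, 0.3270, 0.3294)),
    long("managerial", "population",
         c(0.1009, 0.1093, 0.1059, 0.1110, 0.1167),
         c(0.0160, 0.0245, 0.0224, 0.0217, 0.0261),
         c(0.0849, 0.0848, 0.0835, 0.0893, 0.0906)),
    long("managerial", "area",
         c(0.7133, 0.6694, 0.6692, 0.6892, 0.6580),
         c(0.3433, 0.3121, 0.3235, 0.3237, 0.3162),
         c(0.3700, 0.3574, 0.3457, 0.3654, 0.3418)),
    long("workforce_technical", "population",
         c(0.1217, 0.1285, 0.1331, 0.1459, 0.1432),
         c(0.0273, 0.0321, 0.0323, 0.0362, 0.0392),
         c(0.0944, 0.0964, 0.1008, 0.1097, 0.1040)),
    long("workforce_technical", "area",
         c(0.7974, 0.7969, 0.8010, 0.8260, 0.8172),
         c(0.3835, 0.3777, 0.3755, 0.3686, 0.3711),
         c(0.4139, 0.4191, 0.4254, 0.4575, 0.4461))
  )
}
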