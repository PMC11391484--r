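#' Chain (period-over-period) growth rates of a yearly series
#'
#' The chain growth rate for year \eqn{t} is
#' \eqn{100 (L_t - L_{t-1}) / L_{t-1}} percent, where \eqn{L_t} is the
#' series level. The first year of the series has no predecessor and gets
#' `NA`. Levels may be headcounts or thousands — the scale cancels.
#'
#' @param series A data frame with columns `year` and `level`; if grouped
#'   (see [dplyr::group_by()]) or if `by` names grouping columns, growth is
#'   computed within each group.
#' @param by Optional character vector of grouping columns in `series`.
#' @return A tibble with the input columns plus `chain_growth_pct`, ordered
#'   by year within group.
#' @examples
#' chain_growth(tibble::tibble(year = 2019:2020, level = c(187.564, 194.425)))
#' @export
chain_growth <- function(series, by = NULL) {
  series <- tibble::as_tibble(series)
  if (!all(c("year", "level") %in% names(series))) {
    abort("`series` must have columns `year` and `level`.",
          class = "hrequity_schema_error")
  }
  by <- by %||% setdiff(names(series), c("year", "level"))
  one <- function(df) {
    df <- dplyr::arrange(df, .data$year)
    if (nrow(df) < 2) {
      abort("Chain growth needs at least two years.",
            class = "hrequity_value_error")
    }
    if (anyDuplicated(df$year) || any(diff(df$year) != 1)) {
      abort("Years must be consecutive and unique (no interpolation).",
            class = "hrequity_value_error")
    }
    prev <- dplyr::lag(df$level)
    if (any(prev == 0, na.rm = TRUE)) {
      abort("Chain growth is undefined after a zero level.",
            class = "hrequity_value_error")
    }
    df$chain_growth_pct <- 100 * (df$level - prev) / prev
    df
  }
  if (length(by)) {
    series |>
      dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
      dplyr::group_modify(~ one(.x)) |>
      dplyr::ungroup()
  } else {
    one(series)
  }
}
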