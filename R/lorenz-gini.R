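#' Lorenz curve and Gini coefficient for grouped (weighted) data
#'
#' Units (provinces) are sorted by resource intensity `values/weights`
#' ascending; the curve's abscissa cumulates weight shares (population or
#' area) and the ordinate cumulates resource shares, giving points
#' \eqn{(X_i, Y_i)} from \eqn{(0,0)} to \eqn{(1,1)}. The sort rule keeps the
#' curve under the equality diagonal. Units with identical intensity are
#' merged into one segment (the trapezoid sum is unchanged).
#'
#' The Gini coefficient is twice the area between the diagonal and the
#' curve, computed with the trapezoid rule over all segments including the
#' one leaving the origin:
#' \deqn{G = 1 - \sum_{i=0}^{n-1} (X_{i+1}-X_i)(Y_{i+1}+Y_i)}
#' so a perfectly proportional allocation gives exactly \eqn{G = 0} and full
#' concentration in one of `n` equally weighted units gives \eqn{(n-1)/n}.
#'
#' @param values Non-negative per-unit resource amounts (headcounts) with a
#'   positive total.
#' @param weights Positive per-unit weights (population or area).
#' @param weighting Optional label recorded on the result, conventionally
#'   `"population"` or `"area"`.
#' @return `lorenz()` returns a `lorenz` object (points, `gini`, `n`,
#'   `weighting`) with [tidy()], [glance()] and [autoplot()] methods;
#'   `lorenz_points()` the points tibble; `gini()` the coefficient alone.
#' @examples
#' gini(c(25, 75), weights = c(500, 500))
#' lorenz(c(25, 75), weights = c(500, 500)) |> tidy()
#' @export
lorenz <- function(values, weights, weighting = NA_character_) {
  check_distribution(values, weights)
  ratio <- values / weights
  merged <- tibble::tibble(ratio = ratio, v = values, w = weights) |>
    dplyr::summarise(v = sum(.data$v), w = sum(.data$w), .by = "ratio") |>
    dplyr::arrange(.data$ratio)
  points <- tibble::tibble(
    x = c(0, cumsum(merged$w) / sum(merged$w)),
    y = c(0, cumsum(merged$v) / sum(merged$v))
  )
  g <- 1 - sum(diff(points$x) * (head(points$y, -1) + tail(points$y, -1)))
  structure(
    list(points = points, gini = g, n = length(values),
         weighting = weighting),
    class = "lorenz"
  )
}

#' @rdname lorenz
#' @export
lorenz_points <- function(values, weights) {
  lorenz(values, weights)$points
}

#' @rdname lorenz
#' @export
gini <- function(values, weights) {
  lorenz(values, weights)$gini
}

check_distribution <- function(values, weights, call = rlang::caller_env()) {
  if (length(values) < 1 || length(values) != length(weights)) {
    abort("`values` and `weights` must have equal positive length.",
          class = "hrequity_value_error", call = call)
  }
  if (any(is.na(weights)) || any(weights <= 0)) {
    abort("`weights` must be positive.", class = "hrequity_value_error",
          call = call)
  }
  if (any(is.na(values)) || any(values < 0)) {
    abort("`values` must be non-negative.", class = "hrequity_value_error",
          call = call)
  }
  if (sum(values) <= 0) {
    abort("Degenerate distribution: total resource is zero.",
          class = "hrequity_degenerate_error", call = call)
  }
  invisible(TRUE)
}

#' Classify a Gini coefficient into conventional equity bands
#'
#' The conventional reading of health-resource Gini values: below 0.3 is the
#' best average state, 0.3 up to 0.4 is normal, 0.4 (the "warning line")
#' through 0.6 is a warning state, and above 0.6 is highly unequal.
#'
#' @param g Numeric vector of Gini values in `[0, 1]`.
#' @return Character vector of band labels.
#' @examples
#' classify_gini(c(0.15, 0.35, 0.4, 0.65))
#' @export
classify_gini <- function(g) {
  if (any(is.na(g)) || any(g < 0) || any(g > 1)) {
    abort("Gini values must lie in [0, 1].", class = "hrequity_value_error")
  }
  dplyr::case_when(
    g < 0.3 ~ "best average state",
    g < 0.4 ~ "normal",
    g <= 0.6 ~ "warning",
    TRUE ~ "highly unequal"
  )
}

#' Gini series over a panel
#'
#' Computes the weighted Gini coefficient of the personnel distribution for
#' every requested (category, year, weighting) combination of a panel, with
#' provinces as units and population (thousands) or land area (km^2) as the
#' weight.
#'
#' @param panel A validated `hr_panel`.
#' @param weighting One or both of `"population"` and `"area"`.
#' @param categories Categories to include; default all present.
#' @param years Years to include; default all present.
#' @return A tibble with columns `category`, `year`, `weighting`, `gini`,
#'   `band` ([classify_gini()] of each value).
#' @export
panel_gini <- function(panel, weighting = c("population", "area"),
                       categories = NULL, years = NULL) {
  weighting <- match.arg(weighting, several.ok = TRUE)
  categories <- categories %||% sort(unique(panel$category))
  years <- years %||% sort(unique(panel$year))
  grid <- tidyr::expand_grid(category = categories, year = years,
                             weighting = weighting)
  grid |>
    dplyr::mutate(gini = purrr::pmap_dbl(
      list(.data$category, .data$year, .data$weighting),
      function(category, year, weighting) {
        slice <- panel_slice(panel, year, category)
        gini(slice$personnel, slice[[weighting]])
      }
    )) |>
    dplyr::mutate(band = classify_gini(.data$gini))
}

#' Lorenz curve of one panel cross-section
#'
#' @inheritParams density_table
#' @param weighting `"population"` or `"area"`.
#' @return A `lorenz` object.
#' @export
panel_lorenz <- function(panel, year, category,
                         weighting = c("population", "area")) {
  weighting <- match.arg(weighting)
  slice <- panel_slice(panel, year, category)
  lorenz(slice$personnel, slice[[weighting]], weighting = weighting)
}

#' @export
print.lorenz <- function(x, ...) {
  cat("<lorenz> n = ", x$n,
      if (!is.na(x$weighting)) paste0(", weighting = ", x$weighting),
      "\n  Gini = ", format(x$gini, digits = 4),
      " (", classify_gini(max(0, min(1, x$gini))), ")\n", sep = "")
  invisible(x)
}

#' @export
#' @method tidy lorenz
tidy.lorenz <- function(x, ...) x$points

#' @export
#' @method glance lorenz
glance.lorenz <- function(x, ...) {
  tibble::tibble(gini = x$gini, n = x$n, weighting = x$weighting,
                 band = classify_gini(max(0, min(1, x$gini))))
}
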