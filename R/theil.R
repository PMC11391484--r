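#' Theil index of a weighted allocation
#'
#' The Theil entropy index of a resource allocation across `n` units, with
#' weight shares \eqn{\xi_i} (population or area) and resource shares
#' \eqn{\eta_i}:
#' \deqn{T = \sum_{i=1}^{n} \xi_i \ln(\xi_i / \eta_i)}
#' (natural logarithm). \eqn{T = 0} iff the allocation is proportional
#' (\eqn{\eta_i = \xi_i} for all `i`); larger values mean worse equity. The
#' index is unbounded above: a unit holding weight but essentially no
#' resource drives it arbitrarily large, and a unit with positive weight and
#' exactly zero resource makes it infinite, which is raised as an error
#' rather than smoothed away (see `drop_zero` in [theil_decompose()]).
#'
#' @param values Non-negative per-unit resource amounts, positive total.
#' @param weights Positive per-unit weights.
#' @return The index value (non-negative scalar).
#' @examples
#' theil(c(25, 75), weights = c(500, 500))
#' @export
theil <- function(values, weights) {
  check_distribution(values, weights)
  xi <- weights / sum(weights)
  eta <- values / sum(values)
  if (any(xi > 0 & eta == 0)) {
    abort("Theil index is infinite: a unit has positive weight but zero resource. Drop or merge zero-resource units explicitly.",
          class = "hrequity_infinite_index_error")
  }
  sum(xi * log(xi / eta))
}

#' Theil index with between-/within-region decomposition
#'
#' Splits the total Theil index exactly into a between-group and a
#' within-group component over the groups of a region scheme:
#' \deqn{T = T_{inter} + T_{intra}, \quad
#'       T_{inter} = \sum_j \xi_j \ln(\xi_j/\eta_j), \quad
#'       T_{intra} = \sum_j \xi_j T_j}
#' where \eqn{\xi_j, \eta_j} are the group-level weight and resource shares
#' and \eqn{T_j} is the Theil index computed within group `j` on shares
#' renormalised to the group. The additivity is an algebraic identity of the
#' entropy decomposition and holds to machine precision. Contribution rates
#' are \eqn{\omega_{intra} = T_{intra}/T}, \eqn{\omega_{inter} =
#' T_{inter}/T}, and per-group shares \eqn{100\,\xi_j T_j / T} (which sum to
#' \eqn{100\,\omega_{intra}}).
#'
#' @inheritParams theil
#' @param groups Group label per unit (character or factor), or a
#'   [region_scheme()] together with `province` names.
#' @param province Optional province names, required when `groups` is a
#'   `region_scheme`.
#' @param weighting Optional label recorded on the result.
#' @param drop_zero If `TRUE`, units with zero resource are removed (with a
#'   warning) and shares renormalised instead of raising the
#'   infinite-index error.
#' @return A `theil_decomposition` object with elements `total`, `between`,
#'   `within`, `by_group` (tibble: group, `xi`, `eta`, `theil_g`,
#'   `contribution_pct`), `omega_within`, `omega_between`, `n`, `weighting`.
#'   Has [tidy()] and [glance()] methods.
#' @examples
#' theil_decompose(c(1, 2, 3, 4), weights = c(2, 3, 1, 4),
#'                 groups = c("a", "a", "b", "b"))
#' @export
theil_decompose <- function(values, weights, groups, province = NULL,
                            weighting = NA_character_, drop_zero = FALSE) {
  if (inherits(groups, "region_scheme")) {
    if (is.null(province)) {
      abort("`province` is required when `groups` is a region_scheme.",
            class = "hrequity_value_error")
    }
    groups <- region_of(groups, province)
  }
  groups <- as.character(groups)
  if (length(groups) != length(values)) {
    abort("`groups` must have one label per unit.",
          class = "hrequity_value_error")
  }
  check_distribution(values, weights)
  if (drop_zero && any(values == 0)) {
    keep <- values > 0
    warn(paste0("Dropping ", sum(!keep),
                " zero-resource unit(s); shares renormalised."))
    values <- values[keep]; weights <- weights[keep]; groups <- groups[keep]
  }
  xi <- weights / sum(weights)
  eta <- values / sum(values)
  if (any(xi > 0 & eta == 0)) {
    abort("Theil index is infinite: a unit has positive weight but zero resource (use `drop_zero = TRUE` to remove such units).",
          class = "hrequity_infinite_index_error")
  }

  parts <- tibble::tibble(group = groups, v = values, w = weights) |>
    dplyr::summarise(
      theil_g = theil(.data$v, .data$w),
      v = sum(.data$v), w = sum(.data$w),
      .by = "group"
    ) |>
    dplyr::mutate(xi = .data$w / sum(.data$w),
                  eta = .data$v / sum(.data$v))
  between <- sum(parts$xi * log(parts$xi / parts$eta))
  within <- sum(parts$xi * parts$theil_g)
  total <- between + within

  by_group <- parts |>
    dplyr::mutate(contribution_pct =
                    if (total > 0) 100 * .data$xi * .data$theil_g / total
                    else NA_real_) |>
    dplyr::select("group", "xi", "eta", "theil_g", "contribution_pct")

  structure(
    list(total = total, between = between, within = within,
         by_group = by_group,
         omega_within = if (total > 0) within / total else NA_real_,
         omega_between = if (total > 0) between / total else NA_real_,
         n = length(values), weighting = weighting),
    class = "theil_decomposition"
  )
}

#' Contribution rates of a Theil decomposition
#'
#' Expresses the between- and within-region components and each region's
#' within-component as percentages of the total index.
#'
#' @param x A `theil_decomposition` from [theil_decompose()].
#' @return A tibble with columns `term` (`"between"`, `"within"`, then one
#'   row per group), `level` (`"component"` or `"group"`), and
#'   `contribution_pct`.
#' @export
contribution_rates <- function(x) {
  stopifnot(inherits(x, "theil_decomposition"))
  if (!is.finite(x$total) || x$total <= 0) {
    abort("Contribution rates are undefined at perfect equality (T = 0).",
          class = "hrequity_undefined_contribution_error")
  }
  tibble::tibble(
    term = c("between", "within", x$by_group$group),
    level = c("component", "component", rep("group", nrow(x$by_group))),
    contribution_pct = c(100 * x$omega_between, 100 * x$omega_within,
                         x$by_group$contribution_pct)
  )
}

#' Theil index series over a panel
#'
#' Computes the Theil index and its between-/within-region decomposition for
#' every requested (category, year, weighting) combination of a panel.
#'
#' @inheritParams panel_gini
#' @param scheme Optional [region_scheme()]; defaults to the panel's own.
#' @param drop_zero Passed to [theil_decompose()].
#' @return A tibble with columns `category`, `year`, `weighting`, `total`,
#'   `between`, `within`, `omega_between_pct`, `omega_within_pct`.
#' @seealso [panel_theil_contributions()] for the per-region shares.
#' @export
panel_theil <- function(panel, weighting = c("population", "area"),
                        categories = NULL, years = NULL, scheme = NULL,
                        drop_zero = FALSE) {
  panel_theil_impl(panel, weighting, categories, years, scheme,
                   drop_zero)$components
}

#' Per-region Theil contribution shares over a panel
#'
#' @inheritParams panel_theil
#' @return A long tibble with columns `category`, `year`, `weighting`,
#'   `region`, `contribution_pct`; within each (category, year, weighting)
#'   the shares sum to `100 * omega_within`.
#' @export
panel_theil_contributions <- function(panel,
                                      weighting = c("population", "area"),
                                      categories = NULL, years = NULL,
                                      scheme = NULL, drop_zero = FALSE) {
  panel_theil_impl(panel, weighting, categories, years, scheme,
                   drop_zero)$contributions
}

panel_theil_impl <- function(panel, weighting, categories, years, scheme,
                             drop_zero) {
  weighting <- match.arg(weighting, c("population", "area"),
                         several.ok = TRUE)
  scheme <- panel_scheme(panel, scheme)
  categories <- categories %||% sort(unique(panel$category))
  years <- years %||% sort(unique(panel$year))
  grid <- tidyr::expand_grid(category = categories, year = years,
                             weighting = weighting)
  fits <- purrr::pmap(
    list(grid$category, grid$year, grid$weighting),
    function(category, year, weighting) {
      slice <- panel_slice(panel, year, category)
      theil_decompose(slice$personnel, slice[[weighting]],
                      groups = scheme, province = slice$province,
                      weighting = weighting, drop_zero = drop_zero)
    }
  )
  components <- grid |>
    dplyr::mutate(
      total = purrr::map_dbl(fits, "total"),
      between = purrr::map_dbl(fits, "between"),
      within = purrr::map_dbl(fits, "within"),
      omega_between_pct = 100 * purrr::map_dbl(fits, "omega_between"),
      omega_within_pct = 100 * purrr::map_dbl(fits, "omega_within")
    )
  contributions <- grid |>
    dplyr::mutate(by_group = purrr::map(fits, "by_group")) |>
    tidyr::unnest("by_group") |>
    dplyr::rename(region = "group") |>
    dplyr::select("category", "year", "weighting", "region",
                  "contribution_pct")
  list(components = components, contributions = contributions)
}

#' @export
print.theil_decomposition <- function(x, ...) {
  cat("<theil_decomposition> n = ", x$n,
      if (!is.na(x$weighting)) paste0(", weighting = ", x$weighting),
      "\n  T = ", format(x$total, digits = 4),
      " = between ", format(x$between, digits = 4),
      " + within ", format(x$within, digits = 4), "\n", sep = "")
  if (is.finite(x$total) && x$total > 0) {
    cat("  contribution: between ",
        sprintf("%.1f%%", 100 * x$omega_between), ", within ",
        sprintf("%.1f%%", 100 * x$omega_within), "\n", sep = "")
  }
  invisible(x)
}

#' @export
#' @method tidy theil_decomposition
tidy.theil_decomposition <- function(x, ...) x$by_group

#' @export
#' @method glance theil_decomposition
glance.theil_decomposition <- function(x, ...) {
  tibble::tibble(
    total = x$total, between = x$between, within = x$within,
    omega_between = x$omega_between, omega_within = x$omega_within,
    n = x$n, weighting = x$weighting
  )
}
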