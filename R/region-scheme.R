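#' Region schemes: grouping provinces into economic regions
#'
#' A region scheme maps every province in a panel to one of `k` disjoint
#' groups (economic regions). All grouped statistics — regional density
#' aggregates and the between-/within-region Theil decomposition — consume a
#' scheme. The built-in default is the conventional three-way partition of
#' mainland China's 31 provincial units by per-capita GDP: an Eastern region
#' of 11 provinces, a Central region of 8, and a Western region of 12.
#'
#' @param assignment Named character vector mapping province name to group
#'   label, e.g. `c(Shanghai = "Eastern", Tibet = "Western")`.
#' @param groups Character vector of group labels in presentation order.
#'   Defaults to the distinct assignment values in order of appearance.
#' @return A `region_scheme` object: a list with elements `groups` (ordered
#'   labels) and `assignment` (named character vector).
#' @examples
#' scheme <- region_scheme(c(A = "North", B = "North", C = "South"))
#' region_of(scheme, c("C", "A"))
#' @export
region_scheme <- function(assignment, groups = NULL) {
  if (is.list(assignment)) assignment <- unlist(assignment)
  if (!is.character(assignment) || is.null(names(assignment)) ||
      any(names(assignment) == "")) {
    abort("`assignment` must be a named character vector (province -> group).",
          class = "hrequity_scheme_error")
  }
  if (anyDuplicated(names(assignment))) {
    dup <- unique(names(assignment)[duplicated(names(assignment))])
    abort(paste0("Provinces assigned more than once: ",
                 paste(dup, collapse = ", ")),
          class = "hrequity_scheme_error")
  }
  groups <- groups %||% unique(unname(assignment))
  if (!all(assignment %in% groups)) {
    bad <- setdiff(unique(assignment), groups)
    abort(paste0("Assignment uses group labels not in `groups`: ",
                 paste(bad, collapse = ", ")),
          class = "hrequity_scheme_error")
  }
  if (!all(groups %in% assignment)) {
    empty <- setdiff(groups, assignment)
    abort(paste0("Empty groups are not allowed: ",
                 paste(empty, collapse = ", ")),
          class = "hrequity_scheme_error")
  }
  structure(list(groups = groups, assignment = assignment),
            class = "region_scheme")
}

#' @description `default_region_scheme()` returns the three-region scheme for
#'   mainland China's 31 provincial-level units (11 Eastern, 8 Central, 12
#'   Western).
#' @rdname region_scheme
#' @export
default_region_scheme <- function() {
  eastern <- c("Beijing", "Tianjin", "Hebei", "Liaoning", "Shanghai",
               "Jiangsu", "Zhejiang", "Fujian", "Shandong", "Guangdong",
               "Hainan")
  central <- c("Shanxi", "Jilin", "Heilongjiang", "Anhui", "Jiangxi",
               "Henan", "Hubei", "Hunan")
  western <- c("Chongqing", "Sichuan", "Guizhou", "Yunnan", "Tibet",
               "Shaanxi", "Gansu", "Qinghai", "Ningxia", "Xinjiang",
               "Guangxi", "Inner Mongolia")
  region_scheme(
    setNames(rep(c("Eastern", "Central", "Western"),
                 c(length(eastern), length(central), length(western))),
             c(eastern, central, western)),
    groups = c("Eastern", "Central", "Western")
  )
}

#' Look up the region of one or more provinces
#'
#' @param scheme A [region_scheme()].
#' @param province Character vector of province names.
#' @return Character vector of group labels, same length as `province`.
#' @export
region_of <- function(scheme, province) {
  stopifnot(inherits(scheme, "region_scheme"))
  missing <- setdiff(unique(province), names(scheme$assignment))
  if (length(missing)) {
    abort(paste0("Provinces not covered by the region scheme: ",
                 paste(missing, collapse = ", ")),
          class = "hrequity_assignment_error")
  }
  unname(scheme$assignment[province])
}

#' Read or write a region scheme as JSON
#'
#' The on-disk form is `{"groups": [...], "assignment": {"<province>":
#' "<group>"}}`, so schemes for other countries or groupings can be supplied
#' without touching code.
#'
#' @param path File path of the JSON document.
#' @return `read_region_scheme()` returns a [region_scheme()];
#'   `write_region_scheme()` invisibly returns `scheme`.
#' @export
read_region_scheme <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$assignment)) {
    abort("Region scheme JSON must contain an `assignment` object.",
          class = "hrequity_scheme_error")
  }
  region_scheme(unlist(doc$assignment), groups = doc$groups)
}

#' @param scheme A [region_scheme()] to serialise.
#' @rdname read_region_scheme
#' @export
write_region_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "region_scheme"))
  jsonlite::write_json(
    list(groups = scheme$groups, assignment = as.list(scheme$assignment)),
    path, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(scheme)
}

#' @export
print.region_scheme <- function(x, ...) {
  sizes <- table(factor(x$assignment, levels = x$groups))
  cat("<region_scheme> ", length(x$assignment), " provinces in ",
      length(x$groups), " groups\n", sep = "")
  for (g in x$groups) cat("  ", g, ": ", sizes[[g]], " provinces\n", sep = "")
  invisible(x)
}

#' @export
format.region_scheme <- function(x, ...) {
  paste0("<region_scheme: ", length(x$assignment), " provinces, ",
         length(x$groups), " groups>")
}
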