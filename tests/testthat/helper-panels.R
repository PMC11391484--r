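tiny_scheme <- function() {
  region_scheme(c(A = "North", B = "North", C = "South", D = "South"),
                groups = c("North", "South"))
}

tiny_panel <- function(personnel = c(100, 200, 300, 400),
                       population = c(1000, 2000, 3000, 4000),
                       area = c(10, 20, 30, 40),
                       year = 2020L,
                       category = "healthcare_technical") {
  grid <- tidyr::expand_grid(year = as.integer(year), category = category)
  rows <- purrr::pmap(grid, function(year, category) {
    tibble::tibble(province = c("A", "B", "C", "D"),
                   region = c("North", "North", "South", "South"),
                   year = year, category = category,
                   personnel = personnel, population = population,
                   area = area)
  })
  as_hr_panel(dplyr::bind_rows(rows), tiny_scheme())
}
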