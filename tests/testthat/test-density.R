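test_that("hrdi is the geometric mean of the two densities", {
  # published worked cells: geometric mean of printed density columns
  expect_equal(round(hrdi_from_densities(0.0901, 0.3557), 4), 0.1790)
  expect_equal(round(hrdi_from_densities(0.0366, 0.0218), 4), 0.0282)
  # equal densities: geometric mean is the common value
  expect_equal(hrdi_from_densities(0.25, 0.25), 0.25)
  # headcount form agrees with the density form
  expect_equal(hrdi(120, population = 2400, area = 900),
               hrdi_from_densities(120 / 2400, 120 / 900))
  expect_equal(hrdi(0, 10, 10), 0)
  expect_error(hrdi(10, population = 0, area = 5),
               class = "hrequity_value_error")
  expect_error(hrdi(10, population = 5, area = -1),
               class = "hrequity_value_error")
  expect_error(hrdi(-1, population = 5, area = 5),
               class = "hrequity_value_error")
})

test_that("hrdi is linear in personnel and bounded by the two densities", {
  set.seed(41)
  for (i in 1:25) {
    hr <- stats::runif(1, 0, 5000)
    p <- stats::runif(1, 10, 1e5)
    a <- stats::runif(1, 10, 1e6)
    c_ <- stats::runif(1, 0.1, 10)
    expect_equal(hrdi(c_ * hr, p, a), c_ * hrdi(hr, p, a))
    dens <- c(hr / p, hr / a)
    h <- hrdi(hr, p, a)
    expect_gte(h, min(dens) - 1e-12)
    expect_lte(h, max(dens) + 1e-12)
  }
})

test_that("density_table ranks descending with stable tie-breaking", {
  panel <- tiny_panel(personnel = c(100, 200, 300, 400))
  tab <- density_table(panel, 2020, "healthcare_technical")
  expect_setequal(tab$rank, 1:4)
  expect_true(all(diff(tab$hrdi) <= 0))
  expect_equal(tab$hrdi^2, tab$pop_density * tab$area_density)

  # all provinces identical: ranks fall back to province order
  flat <- tiny_panel(personnel = rep(10, 4), population = rep(100, 4),
                     area = rep(10, 4))
  tab <- density_table(flat, 2020, "healthcare_technical")
  expect_equal(tab$province, c("A", "B", "C", "D"))
  expect_equal(tab$rank, 1:4)

  expect_error(density_table(panel, 1999, "healthcare_technical"),
               class = "hrequity_empty_slice_error")
})

test_that("31-province slices rank as a permutation of 1..31", {
  panel <- generate_panel(generator_config(seed = 11, years = 2020))
  tab <- density_table(panel, 2020, "healthcare_technical")
  expect_equal(sort(tab$rank), 1:31)
  expect_equal(nrow(tab), 31)
})

test_that("regional_hrdi aggregates pooled sums, not mean indices", {
  panel <- tiny_panel()
  reg <- regional_hrdi(panel, 2020, "healthcare_technical")
  expect_equal(reg$region, c("National", "North", "South"))
  north <- dplyr::filter(tibble::as_tibble(panel), region == "North")
  expect_equal(reg$hrdi[reg$region == "North"],
               hrdi(sum(north$personnel), sum(north$population),
                    sum(north$area)))
  expect_equal(reg$hrdi[reg$region == "National"],
               hrdi(sum(panel$personnel), sum(panel$population),
                    sum(panel$area)))

  # two identical provinces in a group: pooled index equals each province's
  twin <- tiny_panel(personnel = c(50, 50, 120, 80),
                     population = c(500, 500, 800, 700),
                     area = c(30, 30, 55, 44))
  reg <- regional_hrdi(twin, 2020, "healthcare_technical")
  expect_equal(reg$hrdi[reg$region == "North"], hrdi(50, 500, 30))
})

test_that("a single-province group's regional hrdi equals its own", {
  scheme <- region_scheme(c(Solo = "Alone", X = "Rest", Y = "Rest"),
                          groups = c("Alone", "Rest"))
  df <- tibble::tibble(province = c("Solo", "X", "Y"),
                       region = c("Alone", "Rest", "Rest"),
                       year = 2020L, category = "managerial",
                       personnel = c(7, 20, 30), population = c(70, 100, 200),
                       area = c(7, 11, 13))
  reg <- regional_hrdi(as_hr_panel(df, scheme), 2020, "managerial")
  expect_equal(reg$hrdi[reg$region == "Alone"], hrdi(7, 70, 7))
})
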