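test_that("run_report writes the five table shapes, re-derivable from the panel", {
  panel <- generate_panel(generator_config(
    seed = 17, years = 2019:2020,
    categories = c("healthcare_technical", "managerial")))
  out <- withr::local_tempdir()
  rep <- suppressMessages(run_report(panel, out))

  expect_true(all(file.exists(rep$files)))

  # growth table: recomputable from panel sums
  nat <- dplyr::filter(rep$growth, region == "National")
  totals <- tibble::as_tibble(panel) |>
    dplyr::summarise(level = sum(personnel), .by = "year")
  expect_equal(sort(nat$personnel), sort(totals$level))

  # density table cells re-derivable via density_table
  d20 <- dplyr::filter(rep$density, category == "managerial")
  ref <- density_table(panel, 2020, "managerial")
  expect_setequal(d20$hrdi, ref$hrdi)
  # provinces ordered by descending hrdi within region blocks
  blocks <- split(d20, cumsum(!duplicated(d20$region)))
  for (b in blocks) expect_true(all(diff(b$hrdi) <= 0))

  # gini and theil grids match the module functions at full precision
  expect_equal(rep$gini,
               panel_gini(panel))
  expect_equal(rep$theil_components, panel_theil(panel))
  expect_true(all(abs(rep$theil_components$between +
                        rep$theil_components$within -
                        rep$theil_components$total) < 1e-10))

  # written CSVs follow the stated rounding conventions
  gcsv <- readr::read_csv(rep$files[["gini"]], show_col_types = FALSE)
  expect_equal(gcsv$gini, round(rep$gini$gini, 3))
  tcsv <- readr::read_csv(rep$files[["theil_components"]],
                          show_col_types = FALSE)
  expect_equal(tcsv$total, round(rep$theil_components$total, 4))
})

test_that("reports are byte-identical across repeated runs", {
  panel <- generate_panel(generator_config(seed = 23, years = 2020,
                                           categories = "managerial"))
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  r1 <- suppressMessages(run_report(panel, out1))
  r2 <- suppressMessages(run_report(panel, out2))
  for (nm in names(r1$files)) {
    expect_identical(readLines(r1$files[[nm]]), readLines(r2$files[[nm]]))
  }
})

test_that("run_report accepts file paths for panel and scheme", {
  panel <- tiny_panel(year = 2019:2020)
  pan_path <- withr::local_tempfile(fileext = ".csv")
  sch_path <- withr::local_tempfile(fileext = ".json")
  write_panel(panel, pan_path)
  write_region_scheme(tiny_scheme(), sch_path)
  out <- withr::local_tempdir()
  rep <- suppressMessages(run_report(pan_path, out, scheme = sch_path))
  expect_equal(nrow(rep$regional_hrdi), 2 * 3)  # 2 years x (National + 2)
})

test_that("proportional panels report zero population-weighted Gini cells", {
  panel <- generate_panel(generator_config(
    gamma = 1, sigma_e = 0, round_personnel = FALSE,
    years = 2019:2020, categories = "healthcare_technical", seed = 33))
  out <- withr::local_tempdir()
  rep <- suppressMessages(run_report(panel, out))
  pop <- dplyr::filter(rep$gini, weighting == "population")
  expect_equal(pop$gini, rep(0, nrow(pop)), tolerance = 1e-12)
  gcsv <- readr::read_csv(rep$files[["gini"]], show_col_types = FALSE)
  expect_equal(gcsv$gini[gcsv$weighting == "population"], rep(0, nrow(pop)))
})
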