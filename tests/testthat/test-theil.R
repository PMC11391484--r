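test_that("theil evaluates the entropy sum over weight and resource shares", {
  # two units, xi = (1/2, 1/2), eta = (1/4, 3/4):
  # T = 0.5 ln 2 + 0.5 ln(2/3)
  expect_equal(theil(c(25, 75), weights = c(500, 500)),
               0.5 * log(2) + 0.5 * log(2 / 3))
  # proportional allocation and single units are exactly zero
  w <- c(2, 5, 3)
  expect_equal(theil(4 * w, w), 0)
  expect_equal(theil(10, 3), 0)
  expect_error(theil(c(1, 0), c(1, 1)),
               class = "hrequity_infinite_index_error")
})

test_that("decomposition matches brute-force component sums", {
  # 4 units in 2 groups, weight shares (.2,.3,.1,.4), resource (.1,.2,.3,.4)
  v <- c(.1, .2, .3, .4)
  w <- c(.2, .3, .1, .4)
  grp <- c("g1", "g1", "g2", "g2")
  dec <- theil_decompose(v, w, grp)

  expect_equal(dec$total, sum(w * log(w / v)), tolerance = 1e-14)
  # brute-force between term on group aggregates
  wj <- c(.5, .5); vj <- c(.3, .7)
  expect_equal(dec$between, sum(wj * log(wj / vj)), tolerance = 1e-14)
  # brute-force within term: group-renormalised entropy sums
  t1 <- sum((w[1:2] / .5) * log((w[1:2] / .5) / (v[1:2] / .3)))
  t2 <- sum((w[3:4] / .5) * log((w[3:4] / .5) / (v[3:4] / .7)))
  expect_equal(dec$within, 0.5 * t1 + 0.5 * t2, tolerance = 1e-14)
  expect_equal(dec$total, dec$between + dec$within)
  expect_equal(dec$by_group$theil_g, c(t1, t2))
})

test_that("degenerate groupings collapse to one component", {
  # internally proportional groups: all within terms vanish
  w <- c(1, 2, 3, 6)
  v <- c(2, 4, 1, 2)   # v = 2w within g1, v = w/3 within g2
  dec <- theil_decompose(v, w, c("g1", "g1", "g2", "g2"))
  expect_equal(dec$within, 0)
  expect_equal(dec$total, dec$between)

  # group aggregates proportional to group weights: between term vanishes
  v <- c(1, 2, 2, 4)   # both groups hold value shares equal to weight shares
  w <- c(2, 1, 4, 2)
  dec <- theil_decompose(v, w, c("g1", "g1", "g2", "g2"))
  expect_equal(dec$between, 0)
  expect_equal(dec$total, dec$within)
})

test_that("contribution rates split the total and sum per group", {
  # published component magnitudes: within .0238 + between .0129 = .0367
  dec <- theil_decompose(c(.1, .2, .3, .4), c(.2, .3, .1, .4),
                         c("a", "a", "b", "b"))
  rates <- contribution_rates(dec)
  expect_equal(rates$contribution_pct[rates$term == "within"],
               100 * dec$within / dec$total)
  expect_equal(sum(rates$contribution_pct[rates$level == "group"]),
               100 * dec$omega_within)
  expect_equal(sum(rates$contribution_pct[rates$level == "component"]), 100)

  expect_equal(round(100 * 0.0238 / 0.0367, 1), 64.9)
  expect_equal(round(100 * 0.0129 / 0.0367, 1), 35.1)

  flat <- theil_decompose(c(1, 1), c(1, 1), c("a", "b"))
  expect_error(contribution_rates(flat),
               class = "hrequity_undefined_contribution_error")
})

test_that("theil is scale- and permutation-invariant", {
  set.seed(92)
  for (i in 1:30) {
    inst <- random_instance(sample(2:10, 1))
    t0 <- theil(inst$values, inst$weights)
    expect_equal(theil(3.7 * inst$values, inst$weights), t0)
    perm <- sample(seq_along(inst$values))
    expect_equal(theil(inst$values[perm], inst$weights[perm]), t0)
    expect_gte(t0, 0)
  }
})

test_that("zero-resource units error unless dropped explicitly", {
  v <- c(0, 1, 2, 3)
  w <- c(1, 1, 1, 1)
  expect_error(theil_decompose(v, w, c("a", "a", "b", "b")),
               class = "hrequity_infinite_index_error")
  expect_warning(
    dec <- theil_decompose(v, w, c("a", "a", "b", "b"), drop_zero = TRUE),
    "zero-resource")
  expect_equal(dec$n, 3)
  expect_equal(dec$total, theil(v[-1], w[-1]))
})

test_that("panel_theil mirrors unit-level decomposition and region schemes", {
  panel <- tiny_panel(personnel = c(110, 180, 350, 360))
  tab <- panel_theil(panel, weighting = "population")
  slice <- tibble::as_tibble(panel)
  dec <- theil_decompose(slice$personnel, slice$population,
                         groups = tiny_scheme(), province = slice$province)
  expect_equal(tab$total, dec$total)
  expect_equal(tab$omega_within_pct, 100 * dec$omega_within)
  contrib <- panel_theil_contributions(panel, weighting = "population")
  expect_equal(sum(contrib$contribution_pct), tab$omega_within_pct)
})

test_that("expected Theil rises with generator noise dispersion", {
  mean_T <- function(sigma) {
    ts <- purrr::map_dbl(1:12, function(r) {
      panel <- generate_panel(generator_config(
        years = 2020, categories = "healthcare_technical",
        sigma_e = sigma, seed = 5000 + 100 * sigma + r))
      slice <- tibble::as_tibble(panel)
      theil(slice$personnel, slice$population)
    })
    mean(ts)
  }
  ms <- purrr::map_dbl(c(0.1, 0.5, 1.0), mean_T)
  expect_true(all(diff(ms) > 0))
})
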