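# Decade-series mechanics: geometric interpolation, backcasting, cumulation,
# lagged ratios and shares.

test_that("annualize: closed-form geometric values and anchor preservation", {
  s <- decade_series(c(1965, 1975), c(100, 200))
  a <- annualize(s)
  expect_equal(a$years, 1965:1975)
  expect_equal(a$values[a$years == 1970], 100 * 2^(5 / 10), tolerance = 1e-12)
  expect_equal(round(a$values[a$years == 1970], 2), 141.42)  # frozen oracle
  expect_equal(a$values[c(1, 11)], c(100, 200))  # anchors exact
  flat <- annualize(decade_series(c(1965, 1975), c(100, 100)))
  expect_equal(flat$values, rep(100, 11))
})

test_that("annualize: zero handling and linear mode", {
  z <- decade_series(c(1965, 1975, 1985), c(0, 0, 0))
  expect_equal(annualize(z)$values, rep(0, 21))
  mixed <- decade_series(c(1965, 1975), c(0, 100))
  expect_error(annualize(mixed), "degenerate ratio")
  lin <- annualize(mixed, mode = "linear")
  expect_equal(lin$values, seq(0, 100, 10))
  expect_error(annualize(decade_series(1965, 100)), "two anchors")
})

test_that("annualize is scale-equivariant", {
  s <- decade_series(seq(1955, 1985, 10), c(80, 120, 90, 200))
  a1 <- annualize(s)
  s3 <- decade_series(s$years, 3.7 * s$values)
  expect_equal(annualize(s3)$values, 3.7 * a1$values, tolerance = 1e-12)
})

test_that("backcast: closed form, flat series, no-op and commuting", {
  s <- decade_series(c(1955, 1965), c(100, 200))
  b <- backcast(s, 1950)
  expect_equal(b$years[1], 1950)
  expect_equal(b$values[1], 100 * 2^(-5 / 10), tolerance = 1e-12)
  expect_equal(round(b$values[1], 2), 70.71)  # frozen oracle
  flat <- backcast(decade_series(c(1955, 1965), c(50, 50)), 1948)
  expect_equal(flat$values, rep(50, 18))
  # backcast to the first anchor year is the identity on the annualized series
  expect_equal(backcast(s, 1955)$values, annualize(s)$values)
  # decade-then-backcast commutes with annualize-then-backcast
  s2 <- decade_series(seq(1955, 1995, 10), c(80, 120, 90, 200, 160))
  expect_equal(backcast(s2, 1950)$values,
               backcast(annualize(s2), 1950)$values, tolerance = 1e-12)
  expect_error(backcast(s, 1960), "must not exceed")
})

test_that("cumulate_decades: arity, linearity and published rows", {
  expect_equal(cumulate_decades(c(235, 305, 335, 341, 302, 286)), 18040)
  expect_equal(cumulate_decades(c(0.7, 4.2, 11, 20, 26, 30)), 919)
  expect_equal(cumulate_decades(rep(0, 6)), 0)
  expect_error(cumulate_decades(1:5), "six")
  expect_error(cumulate_decades(1:7), "six")
  set.seed(11)
  x <- runif(6); y <- runif(6)
  expect_equal(cumulate_decades(2 * x + 3 * y),
               2 * cumulate_decades(x) + 3 * cumulate_decades(y),
               tolerance = 1e-12)
})

test_that("lagged_cigarettes_per_death: period mode, identity, guards", {
  uk <- sales_series("UK", period_start = 1940, period_end = 2000,
                     period_total = 7.0e12)
  rep <- lagged_cigarettes_per_death(
    uk, list(start = 1960, end = 2020, total = 9310, unit = "thousand"))
  expect_equal(rep$deaths_per_million_cigarettes, 1.33, tolerance = 1e-9)
  expect_equal(rep$million_cigarettes_per_death *
                 rep$deaths_per_million_cigarettes, 1, tolerance = 1e-12)
  # sticks-per-death x deaths-per-million-cigarettes == 1e6
  expect_equal(rep$cigarettes_per_death * rep$deaths_per_million_cigarettes,
               1e6, tolerance = 1e-6)
  expect_error(
    lagged_cigarettes_per_death(
      uk, list(start = 1959, end = 2020, total = 9310, unit = "thousand")),
    "alignment error")
  expect_error(
    lagged_cigarettes_per_death(
      uk, list(start = 1960, end = 2020, total = 0)),
    "ratio undefined")
  zero <- sales_series("Z", period_start = 1940, period_end = 2000,
                       period_total = 0)
  expect_warning(
    zrep <- lagged_cigarettes_per_death(
      zero, list(start = 1960, end = 2020, total = 10)),
    "zero cigarette sales")
  expect_equal(zrep$cigarettes_per_death, 0)
})

test_that("lagged_cigarettes_per_death: annual mode alignment", {
  sales <- sales_series("S", years = 1960:1962, sticks = c(1e9, 1e9, 2e9))
  deaths <- annual_series(1980:1982, c(1000, 1000, 2000), unit = "deaths")
  rep <- lagged_cigarettes_per_death(sales, deaths, lag = 20)
  expect_equal(rep$cigarettes_per_death, 4e9 / 4000)
  off <- annual_series(1981:1983, c(1, 1, 1), unit = "deaths")
  expect_error(lagged_cigarettes_per_death(sales, off, lag = 20),
               "alignment error")
})

test_that("share_of_total matches published shares", {
  expect_equal(format_percent(share_of_total(c(18040, 6100, 1640), 41339)),
               62.4)
  expect_equal(format_percent(share_of_total(41339, 180730)), 22.9)
  expect_equal(share_of_total(1:5, 1:5), 100)
  expect_error(share_of_total(1, 0), "division by zero")
})

test_that("decade_series and sales_series validate their invariants", {
  expect_error(decade_series(c(1965, 1974), c(1, 2)), "10 years apart")
  expect_error(decade_series(c(1965, 1975), c(1, -2)), ">= 0")
  expect_error(sales_series("X"), "supply annual")
  expect_error(sales_series("X", years = 1960:1961, sticks = c(1e9, 1e9),
                            period_start = 1960, period_end = 1961,
                            period_total = 5e9),
               "inconsistent")
  ok <- sales_series("X", years = 1960:1961, sticks = c(1e9, 1e9),
                     period_start = 1960, period_end = 1961,
                     period_total = 2e9)
  expect_equal(ok$period_total, 2e9)
})
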