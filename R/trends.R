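# Time-series mechanics for decade-spaced mortality estimates: geometric
# annualization (constant annual growth ratio within each decade), backcasting
# with the earliest interval's ratio, cumulation of decadal totals, and lagged
# cigarettes-per-death ratios. Every series carries a unit label; mixing units
# is a hard error, not a silent coercion.

#' Decade-spaced series
#'
#' Ordered (anchor year, value) pairs spaced exactly ten years apart, with
#' stratum labels. This is the shape of published decadal mortality estimates
#' (e.g. anchors 1955, 1965, ..., 2015).
#'
#' @param years Strictly increasing anchor years, spaced 10 apart.
#' @param values Non-negative values at the anchors.
#' @param country,sex,metric Stratum labels (free text).
#' @param unit Unit label, e.g. \code{"thousand"}; travels with the series.
#' @return An object of class \code{decade_series}.
#' @export
decade_series <- function(years, values, country = NA_character_,
                          sex = NA_character_, metric = NA_character_,
                          unit = "count") {
  years <- as.numeric(years); values <- as.numeric(values)
  if (length(years) != length(values) || length(years) < 1) {
    stop("`years` and `values` must be equal-length and non-empty", call. = FALSE)
  }
  if (length(years) > 1 && any(diff(years) != 10)) {
    stop("anchor years must be strictly increasing and spaced 10 years apart",
         call. = FALSE)
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("anchor values must be finite and >= 0", call. = FALSE)
  }
  structure(list(years = years, values = values, country = country, sex = sex,
                 metric = metric, unit = unit), class = "decade_series")
}

#' Annual series
#'
#' Yearly (year, value) pairs; the product of [annualize()] and [backcast()].
#'
#' @param years Consecutive calendar years.
#' @param values Values, one per year.
#' @inheritParams decade_series
#' @return An object of class \code{annual_series}.
#' @export
annual_series <- function(years, values, country = NA_character_,
                          sex = NA_character_, metric = NA_character_,
                          unit = "count") {
  years <- as.numeric(years); values <- as.numeric(values)
  if (length(years) != length(values) || length(years) < 1) {
    stop("`years` and `values` must be equal-length and non-empty", call. = FALSE)
  }
  if (length(years) > 1 && any(diff(years) != 1)) {
    stop("annual series years must be consecutive", call. = FALSE)
  }
  structure(list(years = years, values = values, country = country, sex = sex,
                 metric = metric, unit = unit), class = "annual_series")
}

#' @export
print.decade_series <- function(x, ...) {
  cat(sprintf("Decade series [%s/%s/%s, unit=%s]\n",
              x$country, x$sex, x$metric, x$unit))
  print(stats::setNames(x$values, x$years)); invisible(x)
}

#' @export
print.annual_series <- function(x, ...) {
  cat(sprintf("Annual series %d-%d [%s/%s/%s, unit=%s]\n",
              min(x$years), max(x$years), x$country, x$sex, x$metric, x$unit))
  print(stats::setNames(x$values, x$years)); invisible(x)
}

#' Annualize a decade series
#'
#' Fills each decade interval with a constant annual growth ratio
#' \eqn{r = (v_{next}/v_{prev})^{1/10}} — the conventional reading of "annual
#' rate of change" for mortality series — so that anchor years reproduce their
#' anchor values exactly. A \code{"linear"} mode (equal annual increments) is
#' provided for series containing zero anchors, where a growth ratio is
#' degenerate.
#'
#' @param series A [decade_series()].
#' @param mode \code{"geometric"} (default) or \code{"linear"}.
#' @return An [annual_series()] spanning first to last anchor year.
#' @export
#' @examples
#' s <- decade_series(c(1965, 1975), c(100, 200))
#' annualize(s)$values[6]  # 1970: 100 * 2^(5/10) = 141.42
annualize <- function(series, mode = c("geometric", "linear")) {
  stopifnot(inherits(series, "decade_series"))
  mode <- match.arg(mode)
  if (length(series$years) < 2) {
    stop("annualization needs at least two anchors", call. = FALSE)
  }
  v <- series$values
  if (mode == "geometric") {
    degenerate <- (v[-length(v)] == 0) != (v[-1] == 0)
    if (any(degenerate)) {
      stop("degenerate ratio: a zero anchor adjacent to a nonzero one; ",
           "use mode = \"linear\"", call. = FALSE)
    }
  }
  years <- seq(series$years[1], series$years[length(series$years)])
  values <- numeric(length(years))
  for (i in seq_len(length(v) - 1)) {
    span <- series$years[i] + 0:10
    idx <- match(span, years)
    if (mode == "geometric") {
      if (v[i] == 0) {         # flat zero interval (both anchors zero)
        seg <- rep(0, 11)
      } else {
        r <- (v[i + 1] / v[i])^(1 / 10)
        seg <- v[i] * r^(0:10)
      }
    } else {
      seg <- v[i] + (v[i + 1] - v[i]) * (0:10) / 10
    }
    values[idx] <- seg
  }
  # reproduce anchors exactly (guard against fp drift at interval joins)
  values[match(series$years, years)] <- v
  annual_series(years, values, series$country, series$sex, series$metric,
                series$unit)
}

#' Backcast a series before its first anchor
#'
#' Extends the series backwards to \code{to_year} by applying the earliest
#' interval's constant annual ratio in reverse — i.e. years before the first
#' anchor change at the same annual rate as documented between the first two
#' anchors.
#'
#' @param series A [decade_series()] or [annual_series()].
#' @param to_year Calendar year to extend back to (at or before the first
#'   year).
#' @param mode Passed to [annualize()] for decade input; for linear mode the
#'   first interval's annual increment is applied in reverse.
#' @return An [annual_series()] spanning \code{to_year} to the last year.
#' @export
#' @examples
#' s <- decade_series(c(1955, 1965), c(100, 200))
#' backcast(s, 1950)$values[1]  # 100 * 2^(-5/10) = 70.71
backcast <- function(series, to_year, mode = c("geometric", "linear")) {
  mode <- match.arg(mode)
  if (inherits(series, "decade_series")) series <- annualize(series, mode)
  stopifnot(inherits(series, "annual_series"))
  first <- series$years[1]
  if (to_year > first) {
    stop("`to_year` must not exceed the first year of the series", call. = FALSE)
  }
  if (to_year == first) return(series)
  if (length(series$years) < 2) {
    stop("backcasting needs at least two years to define a rate", call. = FALSE)
  }
  n_back <- first - to_year
  v1 <- series$values[1]; v2 <- series$values[2]
  if (mode == "geometric") {
    if ((v1 == 0) != (v2 == 0)) {
      stop("degenerate ratio: zero adjacent to nonzero in the first interval; ",
           "use mode = \"linear\"", call. = FALSE)
    }
    pre <- if (v1 == 0) rep(0, n_back) else v1 * (v2 / v1)^(-(n_back:1))
  } else {
    pre <- pmax(0, v1 - (v2 - v1) * (n_back:1))
  }
  annual_series(c(seq(to_year, first - 1), series$years),
                c(pre, series$values), series$country, series$sex,
                series$metric, series$unit)
}

#' Cumulate six decadal totals into a period total
#'
#' A period total over six decades is ten times the sum of the six decade
#' midpoint totals (midpoints 1965, 1975, 1985, 1995, 2005, 2015 standing for
#' 1960--2020).
#'
#' @param decadal_values Numeric vector of exactly six decade totals.
#' @return \code{10 * sum(decadal_values)}, in the input's unit.
#' @export
#' @examples
#' cumulate_decades(c(235, 305, 335, 341, 302, 286))  # 18040
cumulate_decades <- function(decadal_values) {
  if (!is.numeric(decadal_values) || length(decadal_values) != 6) {
    stop("exactly six decadal values are required (midpoints 1965-2015)",
         call. = FALSE)
  }
  10 * sum(decadal_values)
}

#' Cigarette sales series
#'
#' Sales in absolute sticks, either annual or as a period total (or both; when
#' both are given they must agree).
#'
#' @param country Country label.
#' @param years,sticks Optional annual resolution: calendar years and sticks
#'   sold per year.
#' @param period_start,period_end,period_total Optional period total: first
#'   and last calendar year covered and total sticks over the period.
#' @return An object of class \code{sales_series}.
#' @export
sales_series <- function(country, years = NULL, sticks = NULL,
                         period_start = NULL, period_end = NULL,
                         period_total = NULL) {
  has_annual <- !is.null(years)
  has_period <- !is.null(period_total)
  if (!has_annual && !has_period) {
    stop("supply annual sales, a period total, or both", call. = FALSE)
  }
  if (has_annual) {
    stopifnot(length(years) == length(sticks))
    if (any(sticks < 0)) stop("cigarettes_sold must be >= 0", call. = FALSE)
  }
  if (has_period) {
    stopifnot(length(period_total) == 1, period_start <= period_end)
    if (period_total < 0) stop("period total must be >= 0", call. = FALSE)
  }
  if (has_annual && has_period) {
    in_period <- years >= period_start & years <= period_end
    s <- sum(sticks[in_period])
    if (abs(s - period_total) > 1e-6 * max(1, period_total)) {
      stop(sprintf("period total (%.6g) inconsistent with annual sum (%.6g)",
                   period_total, s), call. = FALSE)
    }
  }
  structure(list(country = country, years = years, sticks = sticks,
                 period_start = if (has_period) period_start else
                   if (has_annual) min(years) else NULL,
                 period_end = if (has_period) period_end else
                   if (has_annual) max(years) else NULL,
                 period_total = if (has_period) period_total else sum(sticks)),
            class = "sales_series")
}

#' Lagged cigarettes-per-death ratio
#'
#' Relates cumulative cigarette sales to cumulative smoking-attributable
#' deaths occurring \code{lag} years later (default 20 — the typical delay
#' between smoking uptake and fatal disease). Two modes:
#' \itemize{
#'   \item period mode: the sales period total against a deaths period total
#'     whose window is the sales window shifted by \code{+lag} years;
#'   \item annual mode: an annual deaths series aligned year-by-year against
#'     sales \code{lag} years earlier.
#' }
#'
#' @param sales A [sales_series()].
#' @param deaths Either a list \code{list(start, end, total, unit)} of period
#'   deaths, or an [annual_series()] of deaths.
#' @param lag Lag in years (default 20).
#' @return A list of class \code{lag_ratio_report}:
#'   \code{cigarettes_per_death} (sticks), \code{million_cigarettes_per_death},
#'   \code{deaths_per_million_cigarettes}, window metadata and notes.
#' @export
lagged_cigarettes_per_death <- function(sales, deaths, lag = 20) {
  stopifnot(inherits(sales, "sales_series"))
  unit_mult <- function(unit) {
    switch(unit, count = 1, deaths = 1, thousand = 1e3, million = 1e6,
           stop(sprintf("unknown deaths unit: %s", unit), call. = FALSE))
  }
  if (inherits(deaths, "annual_series")) {
    if (is.null(sales$years)) {
      stop("alignment error: annual deaths need annual sales", call. = FALSE)
    }
    want <- sales$years + lag
    if (!all(want %in% deaths$years)) {
      stop(sprintf(
        "alignment error: deaths window must cover %d-%d (sales window + %d)",
        min(want), max(want), lag), call. = FALSE)
    }
    d_total <- sum(deaths$values[match(want, deaths$years)]) *
      unit_mult(deaths$unit)
    s_total <- sum(sales$sticks)
    windows <- list(sales = range(sales$years), deaths = range(want))
  } else {
    req <- c("start", "end", "total")
    if (!is.list(deaths) || !all(req %in% names(deaths))) {
      stop("period deaths must be list(start, end, total[, unit])", call. = FALSE)
    }
    unit <- if (is.null(deaths$unit)) "deaths" else deaths$unit
    if (is.null(sales$period_total)) {
      stop("alignment error: sales series has no period total", call. = FALSE)
    }
    if (deaths$start != sales$period_start + lag ||
        deaths$end != sales$period_end + lag) {
      stop(sprintf(
        "alignment error: deaths window %d-%d != sales window %d-%d shifted by %d",
        deaths$start, deaths$end, sales$period_start, sales$period_end, lag),
        call. = FALSE)
    }
    d_total <- deaths$total * unit_mult(unit)
    s_total <- sales$period_total
    windows <- list(sales = c(sales$period_start, sales$period_end),
                    deaths = c(deaths$start, deaths$end))
  }
  if (d_total == 0) {
    stop("ratio undefined: zero deaths in the lagged window", call. = FALSE)
  }
  if (s_total == 0) {
    warning("zero cigarette sales against nonzero deaths: ratio is 0",
            call. = FALSE)
  }
  cpd <- s_total / d_total
  structure(list(country = sales$country, lag = lag,
                 cigarettes = s_total, deaths = d_total,
                 cigarettes_per_death = cpd,
                 million_cigarettes_per_death = cpd / 1e6,
                 deaths_per_million_cigarettes = d_total / (s_total / 1e6),
                 windows = windows),
            class = "lag_ratio_report")
}

#' @export
print.lag_ratio_report <- function(x, ...) {
  cat(sprintf(
    "Lagged cigarettes-per-death [%s, lag %dy]: %.3f million cigarettes/death; %.2f deaths/million cigarettes\n",
    x$country, x$lag, x$million_cigarettes_per_death,
    x$deaths_per_million_cigarettes))
  invisible(x)
}

#' Share of one series total in another
#'
#' \code{100 * sum(numerator) / sum(denominator)}; e.g. the male share of
#' all smoking-attributable deaths.
#'
#' @param numerator,denominator Numeric vectors (or series objects with a
#'   \code{values} element) in the same unit.
#' @return Percentage, unrounded.
#' @export
share_of_total <- function(numerator, denominator) {
  val <- function(x) if (is.list(x) && !is.null(x$values)) x$values else x
  num <- val(numerator); den <- val(denominator)
  if (sum(den) == 0) stop("division by zero: denominator total is 0",
                          call. = FALSE)
  100 * sum(num) / sum(den)
}

#' Read decade/annual series from a long-format CSV
#'
#' Expected columns: \code{country, sex, metric, year, value, unit}. Rows are
#' grouped by (country, sex, metric); each group must carry a single unit and
#' is returned as a [decade_series()] when its years are decade-spaced, else
#' an [annual_series()].
#'
#' @param path Path to the CSV file.
#' @return Named list of series, names \code{country.sex.metric}.
#' @export
read_series_csv <- function(path) {
  df <- read_schema_csv(path, c("country", "sex", "metric", "year", "value",
                                "unit"), "series")
  df$year <- coerce_numeric(df$year, "year", path)
  df$value <- coerce_numeric(df$value, "value", path)
  groups <- split(df, list(df$country, df$sex, df$metric), drop = TRUE)
  lapply(groups, function(g) {
    g <- g[order(g$year), ]
    if (length(unique(g$unit)) != 1) {
      stop(sprintf("unit mismatch within series %s/%s/%s: %s",
                   g$country[1], g$sex[1], g$metric[1],
                   paste(unique(g$unit), collapse = " vs ")), call. = FALSE)
    }
    maker <- if (nrow(g) > 1 && all(diff(g$year) == 10)) decade_series
             else annual_series
    maker(g$year, g$value, g$country[1], g$sex[1], g$metric[1], g$unit[1])
  })
}
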