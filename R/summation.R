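# End-to-end report bundle: cumulative attributable totals per country/sex,
# avoidable-fraction and cessation-reduction tables from an RR table, and
# lagged cigarettes-per-death reports. Outputs are plain CSV stamped with
# method metadata; identical config yields byte-identical files (timestamps
# stay in the log stream).

#' Read cigarette sales period totals from CSV
#'
#' Expected columns: \code{country, start_year, end_year, total_sticks}
#' (absolute sticks over the period). Optional annual files use
#' [read_series_csv()] with metric \code{"sales"} instead.
#'
#' @param path Path to the CSV file.
#' @return Named list of [sales_series()], one per country.
#' @export
read_sales_csv <- function(path) {
  df <- read_schema_csv(path, c("country", "start_year", "end_year",
                                "total_sticks"), "sales")
  df$start_year <- coerce_numeric(df$start_year, "start_year", path)
  df$end_year <- coerce_numeric(df$end_year, "end_year", path)
  df$total_sticks <- coerce_numeric(df$total_sticks, "total_sticks", path)
  out <- lapply(seq_len(nrow(df)), function(i) {
    sales_series(df$country[i], period_start = df$start_year[i],
                 period_end = df$end_year[i], period_total = df$total_sticks[i])
  })
  stats::setNames(out, df$country)
}

#' Load a run configuration from JSON
#'
#' Fields: \code{mortality_series} (long series CSV of decadal deaths),
#' optional \code{rr} (RR CSV), optional \code{sales} (period-total CSV),
#' \code{out_dir}, \code{lag} (default 20), \code{seed} (default 1),
#' \code{decades} (six midpoint years, default 1965--2015). Paths are resolved
#' relative to the JSON file. JSON only: no YAML parser is available in the
#' supported stack.
#'
#' @param path Path to a JSON config file.
#' @return A validated config list of class \code{run_config}.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (!file.exists(p)) p <- file.path(base, p)
    p
  }
  cfg$mortality_series <- resolve(cfg$mortality_series)
  cfg$rr <- resolve(cfg$rr)
  cfg$sales <- resolve(cfg$sales)
  as_run_config(cfg)
}

#' Build a run configuration from R
#'
#' @param mortality_series Path to the long-format series CSV.
#' @param rr Optional path to an RR CSV.
#' @param sales Optional path to a sales period-total CSV.
#' @param out_dir Output directory (created if needed).
#' @param lag Lag in years for the cigarettes-per-death report.
#' @param decades Six decade-midpoint years to cumulate over.
#' @param seed Integer seed (stamped into metadata; the summation itself is
#'   deterministic).
#' @return A config list of class \code{run_config}.
#' @export
run_config <- function(mortality_series, rr = NULL, sales = NULL,
                       out_dir = tempdir(), lag = 20,
                       decades = seq(1965, 2015, 10), seed = 1L) {
  as_run_config(list(mortality_series = mortality_series, rr = rr,
                     sales = sales, out_dir = out_dir, lag = lag,
                     decades = decades, seed = seed))
}

as_run_config <- function(cfg) {
  problems <- character()
  if (is.null(cfg$mortality_series)) {
    problems <- c(problems, "mortality_series is required")
  } else if (!file.exists(cfg$mortality_series)) {
    problems <- c(problems, paste("mortality_series not found:",
                                  cfg$mortality_series))
  }
  for (f in c("rr", "sales")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]])) {
      problems <- c(problems, sprintf("%s not found: %s", f, cfg[[f]]))
    }
  }
  if (is.null(cfg$out_dir)) cfg$out_dir <- tempdir()
  if (is.null(cfg$lag)) cfg$lag <- 20
  if (!is.numeric(cfg$lag) || cfg$lag < 0) {
    problems <- c(problems, "lag must be a non-negative number")
  }
  if (is.null(cfg$decades)) cfg$decades <- seq(1965, 2015, 10)
  if (length(cfg$decades) != 6) {
    problems <- c(problems, "decades must list six midpoint years")
  }
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (length(problems)) {
    stop("invalid run config:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

#' Run the full summation pipeline
#'
#' From decadal death series (and optional RR and sales inputs) produces:
#' \itemize{
#'   \item \code{cumulative_totals.csv} — 1960--2020-style cumulative totals
#'     per country/sex/metric, plus both-sex and grand totals;
#'   \item \code{avoidable_fractions.csv} — per RR row, the avoidable
#'     proportion among smokers (percent, one decimal);
#'   \item \code{cessation_reduction.csv} — per RR row with a former-smoker
#'     RR, the reduction in excess risk (percent, one decimal);
#'   \item \code{lag_ratio.csv} — lagged cigarettes-per-death per country.
#' }
#' Every row carries \code{version} and flag metadata. Identical configs give
#' byte-identical CSVs.
#'
#' @param config A [run_config()] (or path to a JSON config).
#' @return Invisibly, a list with the four tables and the paths written.
#' @export
run_summation <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  ver <- pkg_version()
  paths <- list()

  series <- read_series_csv(config$mortality_series)
  cum <- data.frame()
  for (s in series) {
    if (!inherits(s, "decade_series")) next
    idx <- match(config$decades, s$years)
    if (anyNA(idx)) {
      stop(sprintf("series %s/%s/%s lacks decade midpoint(s) %s",
                   s$country, s$sex, s$metric,
                   paste(config$decades[is.na(idx)], collapse = ", ")),
           call. = FALSE)
    }
    cum <- rbind(cum, data.frame(
      country = s$country, sex = s$sex, metric = s$metric,
      period = sprintf("%d-%d", min(config$decades) - 5, max(config$decades) + 5),
      total = cumulate_decades(s$values[idx]), unit = s$unit,
      stringsAsFactors = FALSE))
  }
  if (nrow(cum)) {
    both <- stats::aggregate(total ~ country + metric + period + unit,
                             data = cum, FUN = sum)
    both$sex <- "both"
    grand <- stats::aggregate(total ~ metric + period + unit, data = cum,
                              FUN = sum)
    grand$sex <- "both"; grand$country <- "all"
    cum <- rbind(cum, both[names(cum)], grand[names(cum)])
    message(sprintf("cumulative totals: %d series cumulated", length(series)))
  } else {
    warning("no decade series found: cumulative totals are empty (zero rows)",
            call. = FALSE)
    cum <- data.frame(country = character(), sex = character(),
                      metric = character(), period = character(),
                      total = numeric(), unit = character())
  }
  cum$version <- rep(ver, nrow(cum))
  paths$cumulative_totals <- file.path(config$out_dir, "cumulative_totals.csv")
  utils::write.csv(cum, paths$cumulative_totals, row.names = FALSE)

  af_tab <- red_tab <- NULL
  if (!is.null(config$rr)) {
    rrs <- read_rr_table(config$rr)
    af_tab <- data.frame(rrs, stringsAsFactors = FALSE)
    af_tab$avoidable_percent <-
      format_percent(100 * attributable_fraction(rrs$rr_current))
    af_tab$version <- ver
    paths$avoidable_fractions <- file.path(config$out_dir,
                                           "avoidable_fractions.csv")
    utils::write.csv(af_tab, paths$avoidable_fractions, row.names = FALSE)

    has_f <- !is.na(rrs$rr_former)
    red_tab <- data.frame(rrs[has_f, , drop = FALSE], stringsAsFactors = FALSE)
    if (nrow(red_tab)) {
      red_tab$reduction_percent <- format_percent(
        100 * excess_risk_reduction(red_tab$rr_former, red_tab$rr_current))
    } else {
      red_tab$reduction_percent <- numeric()
    }
    red_tab$version <- ver
    paths$cessation_reduction <- file.path(config$out_dir,
                                           "cessation_reduction.csv")
    utils::write.csv(red_tab, paths$cessation_reduction, row.names = FALSE)
    message(sprintf("risk tables: %d avoidable rows, %d reduction rows",
                    nrow(af_tab), nrow(red_tab)))
  }

  lag_tab <- NULL
  if (!is.null(config$sales) && nrow(cum)) {
    sales <- read_sales_csv(config$sales)
    rows <- list()
    for (cc in names(sales)) {
      hit <- cum[cum$country == cc & cum$sex == "both" &
                   cum$metric == "attributable", , drop = FALSE]
      if (!nrow(hit)) next
      mult <- switch(hit$unit[1], thousand = 1e3, million = 1e6, 1)
      s <- sales[[cc]]
      rep <- lagged_cigarettes_per_death(
        s, list(start = s$period_start + config$lag,
                end = s$period_end + config$lag,
                total = hit$total[1] * mult, unit = "deaths"),
        lag = config$lag)
      note <- if (rep$million_cigarettes_per_death > 1.2 ||
                  rep$million_cigarettes_per_death < 1.0)
        "outside 1.0-1.2 million cigarettes/death band" else ""
      rows[[cc]] <- data.frame(
        country = cc, lag_years = config$lag,
        cigarettes = rep$cigarettes, deaths = rep$deaths,
        million_cigarettes_per_death =
          round(rep$million_cigarettes_per_death, 3),
        deaths_per_million_cigarettes =
          round(rep$deaths_per_million_cigarettes, 1),
        note = note, version = ver, stringsAsFactors = FALSE)
      message(sprintf(
        "lag ratio [%s]: %.3f million cigarettes/death (%.1f deaths/million)",
        cc, rep$million_cigarettes_per_death,
        rep$deaths_per_million_cigarettes))
    }
    lag_tab <- do.call(rbind, rows)
    if (!is.null(lag_tab)) {
      paths$lag_ratio <- file.path(config$out_dir, "lag_ratio.csv")
      utils::write.csv(lag_tab, paths$lag_ratio, row.names = FALSE)
    }
  }

  invisible(list(cumulative_totals = cum, avoidable_fractions = af_tab,
                 cessation_reduction = red_tab, lag_ratio = lag_tab,
                 paths = paths))
}

#' Write an attribution result to CSV
#'
#' @param result An \code{attribution_result} from [attribute_all()].
#' @param path Output CSV path.
#' @return Invisibly, the path.
#' @export
write_attribution_csv <- function(result, path) {
  stopifnot(inherits(result, "attribution_result"))
  df <- as.data.frame(result)
  meta <- attr(result, "method")
  df$halving <- meta$halve_non_lung
  df$version <- meta$version
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Load a synthetic-cohort configuration from JSON
#'
#' JSON mirror of [synthetic_cohort_config()]: object with \code{strata}
#' (array of stratum objects), \code{baseline_never_rates}, \code{rr_current},
#' \code{rr_former} (objects keyed by cause), \code{noise}, \code{seed},
#' \code{year}.
#'
#' @param path Path to the JSON file.
#' @param seed Optional seed overriding the file's.
#' @return A [synthetic_cohort_config()].
#' @export
read_synthetic_config <- function(path, seed = NULL) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  synthetic_cohort_config(
    strata = as.data.frame(cfg$strata, stringsAsFactors = FALSE),
    baseline_never_rates = unlist(cfg$baseline_never_rates),
    rr_current = unlist(cfg$rr_current),
    rr_former = if (!is.null(cfg$rr_former)) unlist(cfg$rr_former) else NULL,
    noise = if (!is.null(cfg$noise)) cfg$noise else "none",
    seed = if (!is.null(seed)) seed else
      if (!is.null(cfg$seed)) cfg$seed else 1L,
    year = if (!is.null(cfg$year)) cfg$year else 2000L)
}
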