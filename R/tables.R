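# Tabular containers and CSV ingestion. All readers validate schema and
# controlled vocabularies up front and report offending rows by line number;
# unknown labels are errors, never guesses.

#' Controlled vocabulary of death causes
#'
#' Cause labels recognized throughout the package. \code{all_causes} is a
#' stratum total, never attributed directly.
#' @export
smoking_causes <- c("lung_cancer", "other_cancers", "coronary_heart_disease",
                    "cerebrovascular", "aortic_other_arterial", "diabetes",
                    "influenza_pneumonia_tb", "copd", "other", "all_causes")

# normalize sex labels to the controlled vocabulary; unknowns are errors
normalize_sex <- function(sex, context = "input") {
  key <- tolower(trimws(as.character(sex)))
  map <- c(male = "male", m = "male", males = "male", men = "male",
           female = "female", f = "female", females = "female", women = "female")
  out <- unname(map[key])
  if (anyNA(out)) {
    bad <- unique(sex[is.na(out)])
    stop(sprintf("unknown sex label(s) in %s: %s", context,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  out
}

# read a mandatory-header CSV; thousands separators and empty files rejected
read_schema_csv <- function(path, required, context) {
  if (!file.exists(path)) {
    stop(sprintf("%s file not found: %s", context, path), call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s file %s lacks column(s): %s", context, path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df
}

# numeric coercion with per-row diagnostics (header is line 1)
coerce_numeric <- function(x, col, context, allow_na = FALSE) {
  raw <- trimws(as.character(x))
  raw[raw == ""] <- NA_character_
  out <- suppressWarnings(as.numeric(raw))
  bad <- which(!is.na(raw) & is.na(out))
  if (length(bad)) {
    stop(sprintf("%s: column `%s` is not numeric at line(s) %s",
                 context, col, paste(bad + 1L, collapse = ", ")), call. = FALSE)
  }
  if (!allow_na && anyNA(out)) {
    bad <- which(is.na(out))
    stop(sprintf("%s: column `%s` has missing values at line(s) %s",
                 context, col, paste(bad + 1L, collapse = ", ")), call. = FALSE)
  }
  out
}

#' Relative-risk table for current and former smokers
#'
#' One row per (cause, sex, age band): the smoker:never-smoker relative risk
#' for current smokers, and optionally for former smokers. Age bands are
#' half-open \code{[age_lo, age_hi)}; an open-ended band has \code{age_hi =
#' Inf}. Bands within one (cause, sex) table must not overlap.
#'
#' @param cause Character, from [smoking_causes].
#' @param sex \code{"male"} or \code{"female"} (common synonyms accepted).
#' @param age_lo,age_hi Numeric band edges in years; \code{age_hi} may be
#'   \code{NA}/\code{Inf} for the open-ended band.
#' @param rr_current Relative risk among current smokers (> 0).
#' @param rr_former Optional relative risk among former smokers (> 0 or NA).
#' @return A \code{data.frame} of class \code{rr_table}.
#' @export
rr_table <- function(cause, sex, age_lo, age_hi, rr_current, rr_former = NA_real_) {
  df <- data.frame(cause = as.character(cause),
                   sex = normalize_sex(sex, "rr table"),
                   age_lo = as.numeric(age_lo),
                   age_hi = as.numeric(age_hi),
                   rr_current = as.numeric(rr_current),
                   rr_former = as.numeric(rr_former),
                   stringsAsFactors = FALSE)
  df$age_hi[is.na(df$age_hi)] <- Inf
  validate_rr_table(df)
  class(df) <- c("rr_table", "data.frame")
  df
}

validate_rr_table <- function(df) {
  bad_cause <- setdiff(unique(df$cause), smoking_causes)
  if (length(bad_cause)) {
    stop(sprintf("unknown cause label(s): %s", paste(bad_cause, collapse = ", ")),
         call. = FALSE)
  }
  if (any(!is.finite(df$rr_current) | df$rr_current <= 0)) {
    stop("invalid relative risk: rr_current must be finite and > 0", call. = FALSE)
  }
  if (any(!is.na(df$rr_former) & df$rr_former <= 0)) {
    stop("invalid relative risk: rr_former must be > 0 when present", call. = FALSE)
  }
  if (any(df$age_lo >= df$age_hi)) {
    stop("age bands must satisfy age_lo < age_hi", call. = FALSE)
  }
  for (key in split(df, paste(df$cause, df$sex))) {
    key <- key[order(key$age_lo), ]
    if (nrow(key) > 1 && any(key$age_lo[-1] < key$age_hi[-nrow(key)])) {
      stop(sprintf("overlapping age bands for cause %s, sex %s",
                   key$cause[1], key$sex[1]), call. = FALSE)
    }
  }
  invisible(df)
}

#' Read a relative-risk table from CSV
#'
#' Expected columns: \code{cause, sex, age_lo, age_hi, rr_current, rr_former}.
#' An empty \code{age_hi} encodes the open-ended band; empty \code{rr_former}
#' is permitted (no former-smoker estimate for that cell).
#'
#' @param path Path to the CSV file.
#' @return An [rr_table()].
#' @export
read_rr_table <- function(path) {
  df <- read_schema_csv(path, c("cause", "sex", "age_lo", "age_hi", "rr_current"),
                        "RR table")
  if (!"rr_former" %in% names(df)) df$rr_former <- NA_real_
  rr_table(cause = df$cause, sex = df$sex,
           age_lo = coerce_numeric(df$age_lo, "age_lo", path),
           age_hi = coerce_numeric(df$age_hi, "age_hi", path, allow_na = TRUE),
           rr_current = coerce_numeric(df$rr_current, "rr_current", path),
           rr_former = coerce_numeric(df$rr_former, "rr_former", path,
                                      allow_na = TRUE))
}

#' Stratified mortality table
#'
#' Death counts (and optional populations) keyed by country, sex, age band,
#' cause and calendar year — the vital-statistics unit the attribution engine
#' consumes. Counts are carried as real numbers internally and rounded only at
#' report time.
#'
#' @param country Country label.
#' @param sex \code{"male"}/\code{"female"}.
#' @param age_lo,age_hi Age band edges in years (half-open; \code{age_hi} may
#'   be NA/Inf).
#' @param cause Cause label from [smoking_causes].
#' @param year Calendar year.
#' @param deaths Non-negative death count.
#' @param population Optional positive person count (denominator for rates).
#' @return A \code{data.frame} of class \code{mortality_table}.
#' @export
mortality_table <- function(country, sex, age_lo, age_hi, cause, year, deaths,
                            population = NA_real_) {
  df <- data.frame(country = as.character(country),
                   sex = normalize_sex(sex, "mortality table"),
                   age_lo = as.numeric(age_lo), age_hi = as.numeric(age_hi),
                   cause = as.character(cause), year = as.integer(year),
                   deaths = as.numeric(deaths),
                   population = as.numeric(population),
                   stringsAsFactors = FALSE)
  df$age_hi[is.na(df$age_hi)] <- Inf
  bad_cause <- setdiff(unique(df$cause), smoking_causes)
  if (length(bad_cause)) {
    stop(sprintf("unknown cause label(s): %s", paste(bad_cause, collapse = ", ")),
         call. = FALSE)
  }
  if (any(!is.finite(df$deaths) | df$deaths < 0)) {
    stop("deaths must be non-negative", call. = FALSE)
  }
  if (any(!is.na(df$population) & df$population <= 0)) {
    stop("population must be > 0 when present", call. = FALSE)
  }
  check_cause_totals(df)
  class(df) <- c("mortality_table", "data.frame")
  df
}

# cause-specific deaths must not exceed the all_causes total, where both exist
check_cause_totals <- function(df) {
  strata <- split(df, list(df$country, df$sex, df$age_lo, df$age_hi, df$year),
                  drop = TRUE)
  for (s in strata) {
    tot <- s$deaths[s$cause == "all_causes"]
    if (length(tot)) {
      spec_sum <- sum(s$deaths[s$cause != "all_causes"])
      if (spec_sum > tot[1] * (1 + 1e-9)) {
        stop(sprintf(
          "cause-specific deaths (%.6g) exceed all_causes total (%.6g) for %s/%s ages [%s,%s) year %d",
          spec_sum, tot[1], s$country[1], s$sex[1], s$age_lo[1], s$age_hi[1],
          s$year[1]), call. = FALSE)
      }
    }
  }
  invisible(df)
}

#' Read a mortality table from CSV
#'
#' Expected columns: \code{country, sex, age_lo, age_hi, cause, year, deaths,
#' population} (population may be empty). Dialect: comma-separated, UTF-8,
#' header row mandatory, \code{.} decimal separator; thousands separators are
#' rejected.
#'
#' @param path Path to the CSV file.
#' @return A [mortality_table()].
#' @export
read_mortality_table <- function(path) {
  df <- read_schema_csv(path, c("country", "sex", "age_lo", "age_hi", "cause",
                                "year", "deaths"), "mortality")
  if (!"population" %in% names(df)) df$population <- NA_real_
  mortality_table(country = df$country, sex = df$sex,
                  age_lo = coerce_numeric(df$age_lo, "age_lo", path),
                  age_hi = coerce_numeric(df$age_hi, "age_hi", path,
                                          allow_na = TRUE),
                  cause = df$cause,
                  year = coerce_numeric(df$year, "year", path),
                  deaths = coerce_numeric(df$deaths, "deaths", path),
                  population = coerce_numeric(df$population, "population", path,
                                              allow_na = TRUE))
}

#' Reference rates for the lung-cancer index
#'
#' Per (sex, age band): the never-smoker lung-cancer death rate in the target
#' population, and the current-smoker and never-smoker lung-cancer rates from
#' a large reference prospective study. Stored internally as deaths per
#' person-year. The study smoker rate must exceed the study never rate —
#' otherwise the index has no signal to scale against.
#'
#' @param sex \code{"male"}/\code{"female"}.
#' @param age_lo,age_hi Age band edges (half-open).
#' @param never_rate_population Never-smoker lung-cancer rate in the target
#'   population.
#' @param smoker_rate_study Current-smoker lung-cancer rate in the reference
#'   study.
#' @param never_rate_study Never-smoker lung-cancer rate in the reference study.
#' @param per Denominator the supplied rates are expressed against (1 for
#'   per person-year, 1e5 for per 100,000 person-years). Default 1.
#' @return A \code{data.frame} of class \code{reference_rates}, rates per
#'   person-year.
#' @export
reference_rates <- function(sex, age_lo, age_hi, never_rate_population,
                            smoker_rate_study, never_rate_study, per = 1) {
  stopifnot(is.numeric(per), length(per) == 1, per > 0)
  df <- data.frame(sex = normalize_sex(sex, "reference rates"),
                   age_lo = as.numeric(age_lo), age_hi = as.numeric(age_hi),
                   never_rate_population = as.numeric(never_rate_population) / per,
                   smoker_rate_study = as.numeric(smoker_rate_study) / per,
                   never_rate_study = as.numeric(never_rate_study) / per,
                   stringsAsFactors = FALSE)
  df$age_hi[is.na(df$age_hi)] <- Inf
  if (any(df$never_rate_population < 0) || any(df$never_rate_study < 0)) {
    stop("never-smoker rates must be >= 0", call. = FALSE)
  }
  if (any(df$smoker_rate_study <= df$never_rate_study)) {
    stop("invalid reference: smoker_rate_study must exceed never_rate_study",
         call. = FALSE)
  }
  class(df) <- c("reference_rates", "data.frame")
  df
}

#' Read reference rates from CSV
#'
#' Expected columns: \code{sex, age_lo, age_hi, never_rate_population,
#' smoker_rate_study, never_rate_study}. Rates are per 100,000 person-years by
#' default (\code{per = 1e5}), the usual vital-statistics dialect.
#'
#' @param path Path to the CSV file.
#' @param per Rate denominator used in the file (default 1e5).
#' @return A [reference_rates()] object (internally per person-year).
#' @export
read_reference_rates <- function(path, per = 1e5) {
  df <- read_schema_csv(path, c("sex", "age_lo", "age_hi",
                                "never_rate_population", "smoker_rate_study",
                                "never_rate_study"), "reference rates")
  reference_rates(sex = df$sex,
                  age_lo = coerce_numeric(df$age_lo, "age_lo", path),
                  age_hi = coerce_numeric(df$age_hi, "age_hi", path,
                                          allow_na = TRUE),
                  never_rate_population = coerce_numeric(
                    df$never_rate_population, "never_rate_population", path),
                  smoker_rate_study = coerce_numeric(
                    df$smoker_rate_study, "smoker_rate_study", path),
                  never_rate_study = coerce_numeric(
                    df$never_rate_study, "never_rate_study", path),
                  per = per)
}
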