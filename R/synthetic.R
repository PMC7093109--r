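# Seeded synthetic vital statistics with retained ground truth. The generator
# states the world the indirect method assumes: within each stratum a fixed
# current/former/never split, never-smoker baseline cause-specific rates, and
# multiplicative relative risks; one-year cycles, no competing-risk depletion
# (populations large, per-cause risks small). Optional Poisson noise on counts.
# All randomness flows from the config seed; the caller's RNG state is left
# untouched.

#' Configuration for the synthetic cohort generator
#'
#' @param strata \code{data.frame} with columns \code{country, sex, age_lo,
#'   age_hi, population, prevalence_current, prevalence_former} (one row per
#'   stratum; \code{prevalence_current + prevalence_former <= 1}).
#' @param baseline_never_rates Named numeric vector: never-smoker death rate
#'   per person-year for each cause (names from [smoking_causes], no
#'   \code{all_causes}).
#' @param rr_current Named numeric vector of current-smoker RRs, same causes.
#' @param rr_former Named numeric vector of former-smoker RRs, same causes;
#'   defaults to 1 for every cause (former smokers at baseline risk).
#' @param noise \code{"none"} (expected counts, real-valued) or
#'   \code{"poisson"} (seeded Poisson draws around the expectation).
#' @param seed Integer seed; sole source of randomness.
#' @param year Calendar year stamped on the output (cosmetic).
#' @return An object of class \code{synthetic_cohort_config}.
#' @export
synthetic_cohort_config <- function(strata, baseline_never_rates, rr_current,
                                    rr_former = NULL,
                                    noise = c("none", "poisson"),
                                    seed = 1L, year = 2000L) {
  noise <- match.arg(noise)
  problems <- character()
  need <- c("country", "sex", "age_lo", "age_hi", "population",
            "prevalence_current", "prevalence_former")
  miss <- setdiff(need, names(strata))
  if (length(miss)) {
    problems <- c(problems, paste("strata lacks column(s):",
                                  paste(miss, collapse = ", ")))
  } else {
    if (any(strata$population <= 0)) problems <- c(problems, "population must be > 0")
    p <- strata$prevalence_current + strata$prevalence_former
    if (any(strata$prevalence_current < 0) || any(strata$prevalence_former < 0) ||
        any(p > 1)) {
      problems <- c(problems,
                    "prevalences must be >= 0 with prevalence_current + prevalence_former <= 1")
    }
  }
  causes <- names(baseline_never_rates)
  if (is.null(causes) || any(causes == "all_causes") ||
      length(setdiff(causes, smoking_causes))) {
    problems <- c(problems,
                  "baseline_never_rates must be named by non-total causes from `smoking_causes`")
  }
  if (any(baseline_never_rates < 0)) problems <- c(problems, "rates must be >= 0")
  if (is.null(rr_former)) {
    rr_former <- stats::setNames(rep(1, length(causes)), causes)
  }
  if (!setequal(names(rr_current), causes) || !setequal(names(rr_former), causes)) {
    problems <- c(problems, "rr_current and rr_former must cover the same causes as baseline_never_rates")
  } else {
    rr_current <- rr_current[causes]; rr_former <- rr_former[causes]
    if (any(rr_current <= 0) || any(rr_former <= 0)) {
      problems <- c(problems, "relative risks must be > 0")
    }
  }
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    problems <- c(problems, "seed must be a single integer")
  }
  if (length(problems)) {
    stop("invalid synthetic config:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  }
  structure(list(strata = strata, baseline_never_rates = baseline_never_rates,
                 rr_current = rr_current, rr_former = rr_former, noise = noise,
                 seed = as.integer(seed), year = as.integer(year)),
            class = "synthetic_cohort_config")
}

# run code under a seeded RNG without disturbing the caller's state
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate stratified vital statistics with known ground truth
#'
#' Expected deaths for cause c in a stratum of size \eqn{P} with never rate
#' \eqn{N_c}, current/former prevalences \eqn{p_c, p_f} and RRs
#' \eqn{RR_c, RR_f}:
#' \deqn{E = P N_c [p_c RR_c + p_f RR_f + (1 - p_c - p_f)]}
#' Observed deaths equal \eqn{E} exactly (\code{noise = "none"}) or are
#' Poisson draws with mean \eqn{E}. The ground-truth table retains the
#' current- and former-smoker excess components and the generating current
#' prevalence (the quantity the SIR targets). An \code{all_causes} row (sum
#' over causes) is appended per stratum.
#'
#' @param config A [synthetic_cohort_config()].
#' @return A list of class \code{simulated_vital_stats}: \code{mortality}
#'   (a [mortality_table()]), \code{truth} (per cell: expected deaths, true
#'   attributable splits, true SIR), and \code{config}.
#' @export
simulate_vital_stats <- function(config) {
  stopifnot(inherits(config, "synthetic_cohort_config"))
  st <- config$strata
  causes <- names(config$baseline_never_rates)
  grid <- merge(cbind(st, .s = seq_len(nrow(st))),
                data.frame(cause = causes, stringsAsFactors = FALSE))
  grid <- grid[order(grid$.s, match(grid$cause, causes)), ]
  N <- config$baseline_never_rates[grid$cause]
  rrc <- config$rr_current[grid$cause]
  rrf <- config$rr_former[grid$cause]
  p_c <- grid$prevalence_current; p_f <- grid$prevalence_former
  expected <- grid$population * N * (p_c * rrc + p_f * rrf + (1 - p_c - p_f))
  exc_current <- grid$population * N * p_c * (rrc - 1)
  exc_former <- grid$population * N * p_f * (rrf - 1)

  observed <- if (config$noise == "poisson") {
    with_seed(config$seed, stats::rpois(length(expected), expected))
  } else expected

  truth <- data.frame(country = grid$country, sex = grid$sex,
                      age_lo = grid$age_lo, age_hi = grid$age_hi,
                      cause = grid$cause, year = config$year,
                      expected_deaths = expected,
                      true_attributable_current = exc_current,
                      true_attributable_former = exc_former,
                      true_attributable = exc_current + exc_former,
                      true_sir = p_c, stringsAsFactors = FALSE)

  # per-stratum all_causes totals appended so the table validates as vital stats
  tot <- stats::aggregate(observed,
                          by = list(.s = grid$.s), FUN = sum)
  mort_df <- data.frame(country = grid$country, sex = grid$sex,
                        age_lo = grid$age_lo, age_hi = grid$age_hi,
                        cause = grid$cause, year = config$year,
                        deaths = as.numeric(observed),
                        population = grid$population,
                        stringsAsFactors = FALSE)
  tot_df <- data.frame(country = st$country, sex = st$sex,
                       age_lo = st$age_lo, age_hi = st$age_hi,
                       cause = "all_causes", year = config$year,
                       deaths = tot$x[match(seq_len(nrow(st)), tot$.s)],
                       population = st$population, stringsAsFactors = FALSE)
  mort_df <- rbind(mort_df, tot_df)
  mortality <- mortality_table(mort_df$country, mort_df$sex, mort_df$age_lo,
                               mort_df$age_hi, mort_df$cause, mort_df$year,
                               mort_df$deaths, mort_df$population)
  structure(list(mortality = mortality, truth = truth, config = config),
            class = "simulated_vital_stats")
}

#' Reference rates matching a generator configuration
#'
#' Builds the [reference_rates()] a noiseless round trip needs: study never
#' rate = the generating never-smoker lung-cancer rate, study smoker rate =
#' never rate x the generating current-smoker lung RR, population never rate =
#' the same never rate. With these references and \code{rr_former = 1}, the
#' SIR recovered from noiseless simulated data equals the generating current
#' prevalence exactly.
#'
#' @param config A [synthetic_cohort_config()] containing a
#'   \code{lung_cancer} cause.
#' @return A [reference_rates()] with one band per stratum (sex, age band).
#' @export
reference_rates_from_config <- function(config) {
  stopifnot(inherits(config, "synthetic_cohort_config"))
  if (!"lung_cancer" %in% names(config$baseline_never_rates)) {
    stop("config has no lung_cancer cause", call. = FALSE)
  }
  st <- unique(config$strata[c("sex", "age_lo", "age_hi")])
  n <- config$baseline_never_rates[["lung_cancer"]]
  reference_rates(sex = st$sex, age_lo = st$age_lo, age_hi = st$age_hi,
                  never_rate_population = n,
                  smoker_rate_study = n * config$rr_current[["lung_cancer"]],
                  never_rate_study = n, per = 1)
}

#' RR table matching a generator configuration
#'
#' Current/former RRs of the config expanded over every stratum, for feeding
#' [attribute_all()] in round-trip tests.
#'
#' @inheritParams reference_rates_from_config
#' @return An [rr_table()].
#' @export
rr_table_from_config <- function(config) {
  stopifnot(inherits(config, "synthetic_cohort_config"))
  st <- unique(config$strata[c("sex", "age_lo", "age_hi")])
  causes <- names(config$baseline_never_rates)
  grid <- merge(st, data.frame(cause = causes, stringsAsFactors = FALSE))
  rr_table(cause = grid$cause, sex = grid$sex, age_lo = grid$age_lo,
           age_hi = grid$age_hi,
           rr_current = config$rr_current[grid$cause],
           rr_former = config$rr_former[grid$cause])
}

#' Simulate cigarette sales from prevalence and population
#'
#' Yearly sticks sold = population x smoking prevalence x sticks per smoker
#' per day x 365. Anchored to the daily-amount scale of national smoking
#' surveys (about 14 sticks/day among daily smokers in 2015).
#'
#' @param years Calendar years.
#' @param prevalence Smoking prevalence per year (proportion in [0, 1]).
#' @param population Persons per year.
#' @param sticks_per_smoker_per_day Mean daily cigarettes per smoker.
#' @param country Country label.
#' @return A [sales_series()] with annual resolution.
#' @export
simulate_sales <- function(years, prevalence, population,
                           sticks_per_smoker_per_day, country = "synthetic") {
  if (any(prevalence < 0) || any(prevalence > 1)) {
    stop("prevalence must lie in [0, 1]", call. = FALSE)
  }
  if (any(population < 0) || any(sticks_per_smoker_per_day < 0)) {
    stop("population and sticks_per_smoker_per_day must be >= 0", call. = FALSE)
  }
  sticks <- population * prevalence * sticks_per_smoker_per_day * 365
  sales_series(country, years = years, sticks = sticks)
}
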