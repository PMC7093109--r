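# Independent oracles. These deliberately avoid the package's closed-form
# code paths: root finding by bisection, per-individual enumeration, and a
# shared scenario builder for round-trip tests.

# invert (rr - 1)/rr = af by bisection on rr in (lo, hi)
oracle_rr_from_af <- function(af, lo = 1e-9, hi = 1e6, tol = 1e-12) {
  f <- function(rr) (rr - 1) / rr - af
  stopifnot(f(lo) < 0, f(hi) > 0)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

# per-individual microsimulation of one stratum: every individual carries an
# explicit smoking status and per-cause hazard; deaths and smoker-excess
# deaths are summed over individuals (expected-value enumeration, noiseless).
# `never_rates`, `rr` are named per-cause vectors; n_smokers must be integer.
oracle_microsim <- function(pop, n_smokers, never_rates, rr) {
  stopifnot(pop <= 1e5, n_smokers == round(n_smokers), n_smokers <= pop)
  status <- rep(c(TRUE, FALSE), c(n_smokers, pop - n_smokers))
  out <- lapply(names(never_rates), function(cc) {
    hazard <- ifelse(status, never_rates[[cc]] * rr[[cc]], never_rates[[cc]])
    excess <- ifelse(status, never_rates[[cc]] * (rr[[cc]] - 1), 0)
    data.frame(cause = cc, deaths = sum(hazard), attributable = sum(excess),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# a small two-stratum generator scenario reused across tests
toy_config <- function(noise = "none", seed = 1L,
                       prevalence_former = c(0, 0), rr_former = NULL) {
  strata <- data.frame(
    country = "Synthia", sex = c("male", "female"),
    age_lo = 35, age_hi = 70, population = c(100000, 80000),
    prevalence_current = c(0.30, 0.25),
    prevalence_former = prevalence_former,
    stringsAsFactors = FALSE)
  synthetic_cohort_config(
    strata = strata,
    baseline_never_rates = c(lung_cancer = 1.4e-4,
                             coronary_heart_disease = 4e-3,
                             other_cancers = 3e-3),
    rr_current = c(lung_cancer = 21, coronary_heart_disease = 3,
                   other_cancers = 1.8),
    rr_former = rr_former, noise = noise, seed = seed)
}

extdata <- function(...) {
  system.file("extdata", ..., package = "smokemort", mustWork = TRUE)
}

# printed decadal estimates (thousands), decade midpoints 1965..2015, and the
# published cumulative cells they are checked against
published_decades <- function() {
  series <- read_series_csv(extdata("decade_deaths.csv"))
  lapply(series, function(s) s$values[match(seq(1965, 2015, 10), s$years)])
}
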