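# Closed-form risk algebra shared by the attribution and reporting layers.
# Conventions: relative risks (RR) are dimensionless ratios against a
# never-smoker reference of 1; fractions are proportions in [0, 1) unless a
# protective exposure (RR < 1) pushes them negative, which is legal and flagged.

#' Attributable fraction among the exposed
#'
#' Proportion of deaths among smokers that would not occur at never-smoker
#' death rates: \code{(rr - 1) / rr}. At RR = 3 this is 2/3 — two-thirds of
#' deaths among persistent smokers are in excess of the never-smoker baseline.
#'
#' @param rr Numeric vector of relative risks (> 0). The never-smoker
#'   reference is implicitly 1.
#' @return Numeric vector of attributable fractions in \eqn{(-\infty, 1)}.
#'   Values are negative for protective exposures (RR < 1); these are returned
#'   as-is with a warning rather than clamped, because some conditions (e.g.
#'   endometrial cancer) genuinely show RR < 1 for smoking.
#' @seealso [rr_from_af()] for the algebraic inverse, [population_af()] for
#'   the population-level (Levin) form.
#' @export
#' @examples
#' attributable_fraction(3)     # 0.667: two-thirds avoidable at never rates
#' attributable_fraction(1.2)   # 0.167: one in six
attributable_fraction <- function(rr) {
  check_rr(rr)
  af <- (rr - 1) / rr
  if (any(af < 0)) {
    warning("protective exposure (rr < 1): negative attributable fraction returned",
            call. = FALSE)
  }
  af
}

#' Relative risk implied by an attributable fraction
#'
#' Inverse of [attributable_fraction()]: solves \code{(rr - 1)/rr = af} for
#' \code{rr}, giving \code{1 / (1 - af)}. Useful to recover the relative risks
#' behind published avoidable-proportion tables.
#'
#' @param af Numeric vector of attributable fractions, each < 1.
#' @return Numeric vector of relative risks.
#' @export
#' @examples
#' rr_from_af(0.93)  # ~14.3: RR behind a 93% avoidable proportion
rr_from_af <- function(af) {
  if (!is.numeric(af)) stop("`af` must be numeric", call. = FALSE)
  if (any(!is.finite(af)) || any(af >= 1)) {
    stop("invalid fraction: `af` must be finite and < 1", call. = FALSE)
  }
  1 / (1 - af)
}

#' Excess risk as a percentage
#'
#' \code{(rr - 1) * 100}: risk above the never-smoker baseline, quoted as a
#' percentage (RR 1.2 carries a 20% excess; RR 3 a 200% excess).
#'
#' @inheritParams attributable_fraction
#' @return Numeric vector of excess-risk percentages.
#' @export
excess_risk_percent <- function(rr) {
  check_rr(rr)
  (rr - 1) * 100
}

#' Reduction in excess risk among former versus current smokers
#'
#' Fraction of the current-smoker excess risk avoided by quitting:
#' \code{1 - (rr_former - 1) / (rr_current - 1)}. With the worked all-cause
#' values (former RR 1.2 against current RR 3) the reduction is 0.90 — a
#' quitter before 40 sheds 90% of the continuing smoker's excess.
#'
#' @param rr_former Relative risk among former smokers (never-smoker = 1).
#' @param rr_current Relative risk among continuing smokers; must not equal 1
#'   (no excess to reduce).
#' @return Numeric vector of reductions: 1 when the former-smoker RR is back
#'   at baseline, 0 when quitting confers no benefit. Inputs with
#'   \code{rr_former < 1} or \code{rr_former > rr_current} are computed anyway
#'   (yielding values outside [0, 1]) with a warning, so that published RR
#'   tables containing such cells pass through unaltered.
#' @export
#' @examples
#' excess_risk_reduction(1.2, 3)    # 0.90
#' excess_risk_reduction(3.3, 21)   # 0.885 (lung cancer, quit by 40)
excess_risk_reduction <- function(rr_former, rr_current) {
  check_rr(rr_former, "rr_former")
  check_rr(rr_current, "rr_current")
  if (any(rr_current == 1)) {
    stop("undefined reduction: rr_current == 1 leaves no excess risk to reduce",
         call. = FALSE)
  }
  out_of_domain <- rr_former < 1 | rr_former > rr_current | rr_current < 1
  if (any(out_of_domain)) {
    warning("rr_former < 1, rr_current < 1 or rr_former > rr_current: ",
            "reduction outside [0, 1] returned", call. = FALSE)
  }
  1 - (rr_former - 1) / (rr_current - 1)
}

#' Population life-expectancy loss from an exposure
#'
#' Prevalence-weighted life-expectancy arithmetic: \code{prevalence *
#' years_lost_per_exposed}. A 15% smoking prevalence at 10 years lost per
#' smoker costs the population 1.5 years of average life expectancy.
#'
#' @param prevalence Proportion of the population exposed, in [0, 1].
#' @param years_lost_per_exposed Average years of life lost per exposed
#'   person (>= 0).
#' @return Average years of life expectancy lost per person in the population.
#' @export
population_le_loss <- function(prevalence, years_lost_per_exposed) {
  if (!is.numeric(prevalence) || any(!is.finite(prevalence)) ||
      any(prevalence < 0) || any(prevalence > 1)) {
    stop("invalid proportion: `prevalence` must lie in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(years_lost_per_exposed) ||
      any(!is.finite(years_lost_per_exposed)) ||
      any(years_lost_per_exposed < 0)) {
    stop("`years_lost_per_exposed` must be non-negative", call. = FALSE)
  }
  prevalence * years_lost_per_exposed
}

#' Anchor table of life-years gained by age at smoking cessation
#'
#' Long-term smokers who quit at 30, 40, 50, or 60 gain about 10, 9, 6, and 4
#' years of life expectancy relative to continuing smokers; those are the
#' default anchors. Anchors must have strictly increasing quit ages and
#' non-increasing gains (quitting later never gains more).
#'
#' @param quit_age Strictly increasing numeric vector of quit ages (years).
#' @param years_gained Non-increasing numeric vector of life-years gained.
#' @return An object of class \code{cessation_gain_table}.
#' @export
cessation_gain_table <- function(quit_age = c(30, 40, 50, 60),
                                 years_gained = c(10, 9, 6, 4)) {
  if (length(quit_age) != length(years_gained) || length(quit_age) < 1) {
    stop("`quit_age` and `years_gained` must be equal-length, non-empty",
         call. = FALSE)
  }
  if (any(diff(quit_age) <= 0)) {
    stop("`quit_age` anchors must be strictly increasing", call. = FALSE)
  }
  if (any(diff(years_gained) > 0)) {
    stop("`years_gained` must be non-increasing in quit age", call. = FALSE)
  }
  structure(list(quit_age = as.numeric(quit_age),
                 years_gained = as.numeric(years_gained)),
            class = "cessation_gain_table")
}

#' @export
print.cessation_gain_table <- function(x, ...) {
  cat("Cessation gain anchors (quit age -> life-years gained):\n")
  cat(paste0("  ", x$quit_age, " -> ", x$years_gained, collapse = "\n"), "\n")
  invisible(x)
}

#' Life-years gained for a given quit age
#'
#' Looks up the cessation gain at \code{quit_age} in an anchor table. With
#' \code{interpolate = FALSE} (default) the age must be exactly an anchor —
#' the anchors are the only stated values. With \code{interpolate = TRUE},
#' gains between anchors are linearly interpolated; extrapolation beyond the
#' anchor range is refused either way.
#'
#' @param quit_age Age at cessation, years.
#' @param table A [cessation_gain_table()].
#' @param interpolate Allow linear interpolation between anchors?
#' @return Years of life expectancy gained.
#' @export
#' @examples
#' years_gained_by_quit_age(40)                      # 9
#' years_gained_by_quit_age(45, interpolate = TRUE)  # 7.5
years_gained_by_quit_age <- function(quit_age, table = cessation_gain_table(),
                                     interpolate = FALSE) {
  stopifnot(inherits(table, "cessation_gain_table"))
  if (!is.numeric(quit_age) || length(quit_age) != 1 || !is.finite(quit_age)) {
    stop("`quit_age` must be a single finite number", call. = FALSE)
  }
  rng <- range(table$quit_age)
  if (quit_age < rng[1] || quit_age > rng[2]) {
    stop(sprintf("quit age %s outside anchor range [%s, %s]; no extrapolation",
                 quit_age, rng[1], rng[2]), call. = FALSE)
  }
  hit <- match(quit_age, table$quit_age)
  if (!is.na(hit)) return(table$years_gained[hit])
  if (!interpolate) {
    stop(sprintf("quit age %s is not an anchor; set `interpolate = TRUE`",
                 quit_age), call. = FALSE)
  }
  stats::approx(table$quit_age, table$years_gained, xout = quit_age)$y
}

#' Percent change between two values
#'
#' \code{(v_end - v_start) / v_start * 100}, at full precision. User-facing
#' reports round percentages to one decimal (see [format_percent()]); the
#' unrounded value is returned here.
#'
#' @param v_start Baseline value(s); must be nonzero.
#' @param v_end Final value(s).
#' @return Percent change, unrounded.
#' @export
#' @examples
#' percent_change(23.1, 15.2)  # -34.199...; prints as -34.2
percent_change <- function(v_start, v_end) {
  if (!is.numeric(v_start) || !is.numeric(v_end)) {
    stop("`v_start` and `v_end` must be numeric", call. = FALSE)
  }
  if (any(v_start == 0)) {
    stop("division by zero: `v_start` must be nonzero", call. = FALSE)
  }
  (v_end - v_start) / v_start * 100
}

#' Format a percentage to the reporting precision
#'
#' All percentages in emitted tables are rounded to one decimal; internal
#' computation keeps full precision.
#'
#' @param x Numeric percentages.
#' @param digits Decimal places (default 1).
#' @return Numeric, rounded.
#' @export
format_percent <- function(x, digits = 1) round(x, digits)

# shared RR validation: positive, finite, numeric
check_rr <- function(rr, name = "rr") {
  if (!is.numeric(rr) || length(rr) == 0) {
    stop(sprintf("`%s` must be a non-empty numeric vector", name), call. = FALSE)
  }
  if (any(!is.finite(rr)) || any(rr <= 0)) {
    stop(sprintf("invalid relative risk: `%s` must be finite and > 0", name),
         call. = FALSE)
  }
  invisible(rr)
}
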