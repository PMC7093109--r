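# Lung-cancer-indexed indirect attribution. The engine follows the classic
# two-step logic: (1) index each stratum's never-smoker-adjusted lung-cancer
# mortality against smoker/never rates from a reference prospective study to
# obtain a synthetic smoking prevalence (the Smoking Impact Ratio, SIR);
# (2) feed that SIR into the Levin population-attributable-fraction formula,
# cause by cause, optionally after halving non-lung excess risks as a guard
# against confounding.

#' Smoking Impact Ratio (SIR)
#'
#' Synthetic smoking prevalence of a population stratum, obtained by indexing
#' its lung-cancer mortality — with the never-smoker component subtracted —
#' to the smoker/never-smoker lung-cancer rates of a reference prospective
#' study:
#' \deqn{SIR = (C_L - N_L) / (S^*_L - N^*_L)}
#' where \eqn{C_L} is the observed population lung-cancer rate, \eqn{N_L} the
#' population never-smoker rate, and \eqn{S^*_L, N^*_L} the study smoker and
#' never rates. Values are clamped to [0, 1]; clamping is flagged, never
#' silent.
#'
#' @param observed_lung_rate Observed lung-cancer death rate(s) in the
#'   population stratum, deaths per person-year.
#' @param refs A [reference_rates()] row set (a single band, or vectors
#'   recycled against `observed_lung_rate`).
#' @return Numeric vector of SIRs in [0, 1], with a logical attribute
#'   \code{"clamped"} marking entries that were floored at 0 or capped at 1.
#' @export
smoking_impact_ratio <- function(observed_lung_rate, refs) {
  stopifnot(inherits(refs, "reference_rates"))
  if (!is.numeric(observed_lung_rate) || any(!is.finite(observed_lung_rate)) ||
      any(observed_lung_rate < 0)) {
    stop("`observed_lung_rate` must be finite and >= 0", call. = FALSE)
  }
  raw <- (observed_lung_rate - refs$never_rate_population) /
    (refs$smoker_rate_study - refs$never_rate_study)
  sir <- pmin(1, pmax(0, raw))
  structure(sir, clamped = raw < 0 | raw > 1)
}

#' Halve an excess relative risk
#'
#' Conservative convention used for non-lung causes in indirect attribution:
#' replace RR with \code{1 + (rr - 1)/2}, halving the excess over the
#' never-smoker baseline to guard against residual confounding.
#'
#' @inheritParams attributable_fraction
#' @return Relative risks with halved excess.
#' @export
halve_excess_rr <- function(rr) {
  check_rr(rr)
  1 + (rr - 1) / 2
}

#' Population attributable fraction with a synthetic prevalence
#'
#' Levin's formula with the SIR standing in for the smoking prevalence:
#' \deqn{PAF = p (RR - 1) / (p (RR - 1) + 1)}
#' At \code{sir = 1} this collapses to the attributable fraction among the
#' exposed, \code{(RR - 1)/RR}.
#'
#' @param sir Synthetic prevalence(s) in [0, 1].
#' @param rr Relative risk(s), > 0.
#' @return Population attributable fraction(s).
#' @export
population_af <- function(sir, rr) {
  check_rr(rr)
  if (!is.numeric(sir) || any(!is.finite(sir)) || any(sir < 0) || any(sir > 1)) {
    stop("`sir` must lie in [0, 1]", call. = FALSE)
  }
  sir * (rr - 1) / (sir * (rr - 1) + 1)
}

#' Smoking-attributable lung-cancer deaths by never-rate subtraction
#'
#' Lung cancer is attributed directly: expected never-smoker deaths
#' (never rate x population) are subtracted from the observed count, floored
#' at zero.
#'
#' @param observed_deaths Observed lung-cancer deaths in the stratum.
#' @param refs A single-band [reference_rates()] (its
#'   \code{never_rate_population} is used).
#' @param population Person count of the stratum.
#' @return Attributable deaths (real-valued), with attribute
#'   \code{"floored"} flagging strata where the zero floor was applied.
#' @export
attributable_deaths_lung <- function(observed_deaths, refs, population) {
  stopifnot(inherits(refs, "reference_rates"))
  if (any(is.na(population))) {
    stop("missing denominator: `population` is required to expected-count the never-smoker rate",
         call. = FALSE)
  }
  if (any(observed_deaths < 0) || any(population < 0)) {
    stop("inputs must be non-negative", call. = FALSE)
  }
  raw <- observed_deaths - refs$never_rate_population * population
  structure(pmax(0, raw), floored = raw < 0)
}

#' Attribute stratified deaths to smoking, all causes
#'
#' Runs the full indirect method over a [mortality_table()]. Per stratum
#' (country, sex, age band, year): the SIR comes from that stratum's
#' lung-cancer rate; lung-cancer deaths are attributed by never-rate
#' subtraction ([attributable_deaths_lung()]); every other cause contributes
#' \code{deaths x population_af(sir, rr')}, where \code{rr'} is the cause's
#' current-smoker RR, excess-halved when \code{halve_non_lung} is on (the
#' default, matching the conservative published convention).
#' \code{all_causes} rows are carried through untouched as totals.
#'
#' @param mortality A [mortality_table()]; every stratum needs a lung-cancer
#'   row with population.
#' @param rrs An [rr_table()] covering every non-lung cause present.
#' @param refs [reference_rates()] covering every (sex, age band) present.
#' @param halve_non_lung Halve the excess RR of non-lung causes? Default TRUE.
#' @return A \code{data.frame} of class \code{attribution_result}: one row per
#'   attributed cell with columns \code{sir}, \code{population_af},
#'   \code{attributable_deaths} and flag columns \code{clamped_sir},
#'   \code{halved_rr}, \code{negative_floor}; method metadata in
#'   \code{attr(, "method")}.
#' @export
attribute_all <- function(mortality, rrs, refs, halve_non_lung = TRUE) {
  stopifnot(inherits(mortality, "mortality_table"), inherits(rrs, "rr_table"),
            inherits(refs, "reference_rates"))
  work <- mortality[mortality$cause != "all_causes", , drop = FALSE]
  if (!nrow(work)) {
    stop("mortality table has no attributable cause rows", call. = FALSE)
  }

  strata_key <- function(df) paste(df$country, df$sex, df$age_lo, df$age_hi,
                                   df$year, sep = "|")
  ref_key <- function(df) paste(df$sex, df$age_lo, df$age_hi, sep = "|")
  rr_key <- function(df) paste(df$cause, df$sex, df$age_lo, df$age_hi, sep = "|")

  # coverage checks up front: every stratum needs reference rates + lung row
  # with population; every non-lung cause needs an RR entry
  keys <- unique(strata_key(work))
  lung <- work[work$cause == "lung_cancer", , drop = FALSE]
  missing_lung <- setdiff(keys, strata_key(lung))
  if (length(missing_lung)) {
    stop("coverage error: no lung_cancer row for stratum(s): ",
         paste(missing_lung, collapse = "; "), call. = FALSE)
  }
  if (anyNA(lung$population)) {
    stop("missing denominator: lung_cancer rows need `population` for stratum(s): ",
         paste(strata_key(lung)[is.na(lung$population)], collapse = "; "),
         call. = FALSE)
  }
  missing_ref <- setdiff(unique(ref_key(work)), ref_key(refs))
  if (length(missing_ref)) {
    stop("coverage error: no reference rates for (sex|age_lo|age_hi): ",
         paste(missing_ref, collapse = "; "), call. = FALSE)
  }
  nonlung <- work[work$cause != "lung_cancer", , drop = FALSE]
  missing_rr <- setdiff(unique(rr_key(nonlung)), rr_key(rrs))
  if (length(missing_rr)) {
    stop("coverage error: no RR entry for (cause|sex|age_lo|age_hi): ",
         paste(missing_rr, collapse = "; "), call. = FALSE)
  }

  # per-stratum SIR from the lung-cancer rate
  ref_idx <- match(ref_key(lung), ref_key(refs))
  lung_rate <- lung$deaths / lung$population
  sir <- smoking_impact_ratio(lung_rate, refs[ref_idx, , drop = FALSE])
  sir_tab <- data.frame(key = strata_key(lung), sir = as.numeric(sir),
                        clamped = attr(sir, "clamped"),
                        ref_idx = ref_idx, stringsAsFactors = FALSE)

  out <- work
  m <- match(strata_key(out), sir_tab$key)
  out$sir <- sir_tab$sir[m]
  out$clamped_sir <- sir_tab$clamped[m]
  out$population_af <- NA_real_
  out$attributable_deaths <- NA_real_
  out$halved_rr <- FALSE
  out$negative_floor <- FALSE

  is_lung <- out$cause == "lung_cancer"
  if (any(is_lung)) {
    lref <- refs[sir_tab$ref_idx[m[is_lung]], , drop = FALSE]
    att <- attributable_deaths_lung(out$deaths[is_lung], lref,
                                    out$population[is_lung])
    out$attributable_deaths[is_lung] <- pmin(as.numeric(att), out$deaths[is_lung])
    out$negative_floor[is_lung] <- attr(att, "floored")
    obs <- out$deaths[is_lung]
    out$population_af[is_lung] <- ifelse(obs > 0,
                                         out$attributable_deaths[is_lung] / obs, 0)
  }
  if (any(!is_lung)) {
    i <- which(!is_lung)
    rr <- rrs$rr_current[match(rr_key(out[i, ]), rr_key(rrs))]
    if (halve_non_lung) rr <- halve_excess_rr(rr)
    paf <- population_af(out$sir[i], rr)
    out$population_af[i] <- paf
    out$attributable_deaths[i] <- out$deaths[i] * paf
    out$halved_rr[i] <- halve_non_lung
  }

  class(out) <- c("attribution_result", "data.frame")
  attr(out, "method") <- list(method = "smoking_impact_ratio",
                              halve_non_lung = halve_non_lung,
                              version = pkg_version())
  out
}

#' @export
print.attribution_result <- function(x, ...) {
  meta <- attr(x, "method")
  cat(sprintf("Smoking-attributable deaths (%s, excess halving for non-lung: %s)\n",
              meta$method, if (isTRUE(meta$halve_non_lung)) "on" else "off"))
  print.data.frame(x, ...)
  invisible(x)
}

pkg_version <- function() {
  as.character(utils::packageVersion("smokemort"))
}
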