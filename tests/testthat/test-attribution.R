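# Lung-cancer-indexed attribution: SIR algebra, the Levin step, and the
# full engine against hand arithmetic, the generator's ground truth and a
# per-individual microsimulation oracle.

ref1 <- function(npop = 1.4e-4, sstudy = 2.94e-3, nstudy = 1.4e-4) {
  reference_rates("male", 35, 70, npop, sstudy, nstudy, per = 1)
}

test_that("smoking_impact_ratio: trivial anchors, clamping, errors", {
  r <- ref1()
  expect_equal(as.numeric(smoking_impact_ratio(1.4e-4, r)), 0)
  expect_equal(as.numeric(smoking_impact_ratio(2.94e-3, r)), 1)
  # generator construction: observed = p*S + (1-p)*N gives SIR = p
  p <- 0.30
  obs <- p * 2.94e-3 + (1 - p) * 1.4e-4
  expect_equal(as.numeric(smoking_impact_ratio(obs, r)), p, tolerance = 1e-12)
  # clamping is flagged, never silent
  lo <- smoking_impact_ratio(1e-5, r)
  expect_equal(as.numeric(lo), 0)
  expect_true(attr(lo, "clamped"))
  hi <- smoking_impact_ratio(5e-3, r)
  expect_equal(as.numeric(hi), 1)
  expect_true(attr(hi, "clamped"))
  expect_error(reference_rates("male", 35, 70, 1e-4, 1e-4, 2e-4),
               "invalid reference")
})

test_that("halve_excess_rr halves the excess, not the ratio", {
  expect_equal(halve_excess_rr(1), 1)
  expect_equal(halve_excess_rr(3), 2)
  expect_equal(halve_excess_rr(21), 11)
  expect_error(halve_excess_rr(0), "invalid relative risk")
})

test_that("population_af: endpoints, Levin collapse, microsimulation oracle", {
  expect_equal(population_af(0, 3), 0)
  expect_equal(population_af(1, 3), attributable_fraction(3), tolerance = 1e-12)
  # microsim oracle: 1e5 individuals, half smokers at RR 3 -> half the deaths
  # are excess
  ms <- oracle_microsim(1e5, 5e4, c(chd = 1e-3), c(chd = 3))
  expect_equal(ms$attributable / ms$deaths, 0.5, tolerance = 1e-12)
  expect_equal(population_af(0.5, 3), 0.5, tolerance = 1e-12)
  expect_error(population_af(1.2, 3), "\\[0, 1\\]")
  expect_error(population_af(0.5, -1), "invalid relative risk")
})

test_that("attributable_deaths_lung: subtraction, floor and flags", {
  r <- ref1(npop = 0)
  expect_equal(as.numeric(attributable_deaths_lung(120, r, 1e5)), 120)
  r2 <- ref1(npop = 1e-3)
  expect_equal(as.numeric(attributable_deaths_lung(100, r2, 1e5)), 0)
  expect_false(attr(attributable_deaths_lung(100, r2, 1e5), "floored"))
  fl <- attributable_deaths_lung(50, r2, 1e5)
  expect_equal(as.numeric(fl), 0)
  expect_true(attr(fl, "floored"))
  expect_error(attributable_deaths_lung(50, r2, NA), "missing denominator")
})

test_that("attribute_all matches hand arithmetic on a single-stratum toy", {
  # 100 lung deaths observed, 10 expected at never rates, 300 CHD deaths,
  # sir = 1, rr_chd = 3, halving off -> 90 lung + 200 CHD attributable
  pop <- 1e5
  refs <- reference_rates("male", 35, 70, 1e-4, 1e-3, 1e-4, per = 1)
  mort <- mortality_table("X", "male", 35, 70,
                          c("lung_cancer", "coronary_heart_disease"),
                          2000, c(100, 300), pop)
  rrs <- rr_table("coronary_heart_disease", "male", 35, 70, rr_current = 3)
  res <- attribute_all(mort, rrs, refs, halve_non_lung = FALSE)
  lung <- res[res$cause == "lung_cancer", ]
  chd <- res[res$cause == "coronary_heart_disease", ]
  expect_equal(lung$sir, 1)  # observed rate equals study smoker rate
  expect_equal(lung$attributable_deaths, 90)
  expect_equal(chd$attributable_deaths, 200, tolerance = 1e-9)
  expect_false(any(res$halved_rr))
  expect_identical(attr(res, "method")$halve_non_lung, FALSE)
})

test_that("attribute_all with rr = 1 everywhere attributes nothing non-lung", {
  cfg <- toy_config()
  cfg$rr_current[c("coronary_heart_disease", "other_cancers")] <- 1
  sim <- simulate_vital_stats(cfg)
  res <- attribute_all(sim$mortality, rr_table_from_config(cfg),
                       reference_rates_from_config(cfg),
                       halve_non_lung = FALSE)
  expect_equal(res$attributable_deaths[res$cause != "lung_cancer"],
               rep(0, 4), tolerance = 1e-12)
})

test_that("sir = 1 + halving off reduces to deaths x attributable_fraction", {
  pop <- 1e5
  refs <- reference_rates("male", 35, 70, 1e-4, 1e-3, 1e-4, per = 1)
  mort <- mortality_table("X", "male", 35, 70,
                          c("lung_cancer", "coronary_heart_disease", "copd"),
                          2000, c(100, 300, 50), pop)
  rrs <- rr_table(c("coronary_heart_disease", "copd"), "male", 35, 70,
                  rr_current = c(3, 25))
  res <- attribute_all(mort, rrs, refs, halve_non_lung = FALSE)
  for (cc in c("coronary_heart_disease", "copd")) {
    rr <- rrs$rr_current[rrs$cause == cc]
    expect_equal(res$attributable_deaths[res$cause == cc],
                 mort$deaths[mort$cause == cc] * attributable_fraction(rr),
                 tolerance = 1e-12)
  }
})

test_that("halving is conservative: never more attributable than unhalved", {
  cfg <- toy_config()
  sim <- simulate_vital_stats(cfg)
  rrs <- rr_table_from_config(cfg)
  refs <- reference_rates_from_config(cfg)
  on_ <- attribute_all(sim$mortality, rrs, refs, halve_non_lung = TRUE)
  off <- attribute_all(sim$mortality, rrs, refs, halve_non_lung = FALSE)
  nl <- on_$cause != "lung_cancer"
  expect_true(all(on_$attributable_deaths[nl] <=
                    off$attributable_deaths[nl] + 1e-12))
  expect_true(all(on_$halved_rr[nl]))
  # lung route is untouched by the flag
  expect_equal(on_$attributable_deaths[!nl], off$attributable_deaths[!nl])
})

test_that("attributable deaths stay within [0, observed] across random cases", {
  set.seed(7)
  for (i in 1:20) {
    p <- runif(1, 0, 0.6)
    cfg <- toy_config()
    cfg$strata$prevalence_current <- c(p, p / 2)
    sim <- simulate_vital_stats(cfg)
    res <- attribute_all(sim$mortality, rr_table_from_config(cfg),
                         reference_rates_from_config(cfg),
                         halve_non_lung = sample(c(TRUE, FALSE), 1))
    expect_true(all(res$attributable_deaths >= 0))
    expect_true(all(res$attributable_deaths <= res$deaths + 1e-9))
    expect_true(all(res$sir >= 0 & res$sir <= 1))
  }
})

test_that("coverage errors name the missing keys", {
  pop <- 1e5
  refs <- reference_rates("male", 35, 70, 1e-4, 1e-3, 1e-4, per = 1)
  mort <- mortality_table("X", "male", 35, 70,
                          c("lung_cancer", "coronary_heart_disease"),
                          2000, c(100, 300), pop)
  expect_error(
    attribute_all(mort, rr_table("copd", "male", 35, 70, 2), refs),
    "coverage error.*coronary_heart_disease")
  refs_f <- reference_rates("female", 35, 70, 1e-4, 1e-3, 1e-4, per = 1)
  expect_error(
    attribute_all(mort, rr_table("coronary_heart_disease", "male", 35, 70, 3),
                  refs_f),
    "coverage error.*male")
  mort_nolung <- mortality_table("X", "male", 35, 70,
                                 "coronary_heart_disease", 2000, 300, pop)
  expect_error(
    attribute_all(mort_nolung,
                  rr_table("coronary_heart_disease", "male", 35, 70, 3), refs),
    "no lung_cancer row")
  mort_nopop <- mortality_table("X", "male", 35, 70,
                                c("lung_cancer", "coronary_heart_disease"),
                                2000, c(100, 300))
  expect_error(
    attribute_all(mort_nopop,
                  rr_table("coronary_heart_disease", "male", 35, 70, 3), refs),
    "missing denominator")
})

test_that("Poisson SIR recovery stays within 3 delta-method SEs (seeded)", {
  # smaller companion to the 1,000-replicate acceptance run
  cfg <- toy_config(noise = "poisson")
  n_rep <- 200
  hits <- 0
  lung_idx <- function(sim) sim$mortality$cause == "lung_cancer" &
    sim$mortality$sex == "male"
  refs <- reference_rates_from_config(toy_config())
  expected <- 1e5 * 1.4e-4 * (1 + 0.3 * 20)
  se <- sqrt(expected) / (1e5 * (refs$never_rate_population[1] * 20))
  for (i in seq_len(n_rep)) {
    cfg$seed <- i
    sim <- simulate_vital_stats(cfg)
    d <- sim$mortality$deaths[lung_idx(sim)]
    sir <- as.numeric(smoking_impact_ratio(d / 1e5, refs[1, ]))
    if (abs(sir - 0.3) <= 3 * se) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.97)
})
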