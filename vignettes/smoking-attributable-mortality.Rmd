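---
title: "Methods: lung-cancer-indexed attribution of mortality to smoking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lung-cancer-indexed attribution of mortality to smoking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smokemort)
```

## The problem

National vital statistics record deaths by cause, age, sex and year, but not
by smoking status, so the mortality burden of smoking cannot be read off a
death register directly. The indirect method implemented here exploits the
fact that lung cancer is almost a biomarker of cigarette exposure: lung-cancer
death rates among never-smokers are low, similar across high-income countries,
and approximately constant over recent decades, while rates among smokers are
an order of magnitude higher. A population's never-smoker-adjusted lung-cancer
mortality therefore indexes how much smoke it has absorbed, and that index can
be carried over to the other diseases smoking causes.

## The model

### Risk algebra (`riskmath`)

For a relative risk $RR$ of death among smokers versus otherwise similar
never-smokers:

* attributable fraction among the exposed: $AF = (RR - 1)/RR$, the share of
  smoker deaths that would not occur at never-smoker rates (`attributable_fraction()`,
  inverse `rr_from_af()`);
* excess risk: $(RR - 1) \times 100\%$ (`excess_risk_percent()`);
* cessation benefit: the former-versus-current reduction in excess risk,
  $1 - (RR_f - 1)/(RR_c - 1)$ (`excess_risk_reduction()`). With the worked
  all-cause values $RR_f = 1.2$, $RR_c = 3$, quitting before 40 avoids 90% of
  the continuing smoker's excess;
* population life-expectancy arithmetic: prevalence $\times$ years lost per
  exposed person (`population_le_loss()`), e.g. $0.15 \times 10 = 1.5$ years;
* cessation gain anchors: quitting at 30/40/50/60 gains about 10/9/6/4 years
  (`cessation_gain_table()`, `years_gained_by_quit_age()`).

Negative attributable fractions (protective exposures, $RR < 1$) are returned
with a warning and never clamped: a few conditions genuinely show $RR < 1$ and
silently flooring them would corrupt input tables. Likewise
`excess_risk_reduction()` computes through $RR_f > RR_c$ or $RR_f < 1$ cells
(flagging them) because published former-smoker RR tables can contain such
entries. Percentages are reported to one decimal (`format_percent()`); full
precision is kept internally.

### The Smoking Impact Ratio (`attribution`)

For each stratum (country, sex, age band, year) with observed lung-cancer
death rate $C_L$, population never-smoker lung rate $N_L$, and reference-study
smoker/never rates $S^*_L$, $N^*_L$:

$$SIR = \frac{C_L - N_L}{S^*_L - N^*_L}$$

The SIR acts as a synthetic smoking prevalence: the prevalence that, at the
reference study's risk gradient, would produce the observed lung-cancer
mortality. It is clamped to $[0, 1]$ with a flag — negative or super-unity
synthetic prevalences are meaningless, but clamping is never silent.

Attribution then proceeds per cause:

* lung cancer directly, by subtracting expected never-smoker deaths:
  $\max(0,\; D_L - N_L \times \text{population})$;
* every other cause through Levin's population attributable fraction with the
  SIR as prevalence: $PAF = \frac{SIR (RR - 1)}{SIR (RR - 1) + 1}$, applied to
  the cause's death count.

**Excess-risk halving.** For non-lung causes the excess $RR - 1$ is halved
($RR' = 1 + (RR-1)/2$) before entering the PAF, a conservative guard against
residual confounding. The convention is a first-class flag
(`halve_non_lung`, default `TRUE` since published totals of this kind describe
themselves as conservative), recorded in the output metadata; both modes are
tested. Halving can only lower attributable deaths (monotone conservatism — a
tested property).

Strata are matched on exact (sex, age band) keys. RRs are never interpolated
across age bands: published RR tables use coarse bands and re-binning would
invent information. Death counts are carried as reals and rounded only at
report time.

### Trends mechanics (`trends`)

Published attributable-death estimates come as decade-spaced anchors (1955,
1965, …, 2015, in thousands). The package provides:

* `annualize()`: within each decade, values follow a constant annual growth
  ratio $r = (v_{t+10}/v_t)^{1/10}$. Geometric interpolation is the default
  because "annual rate of change" conventionally means a multiplicative rate
  for mortality series; a linear mode exists for series containing zeros
  (the Canada female 1955 anchor is 0), where a growth ratio is degenerate.
* `backcast()`: years before the first anchor are filled by applying the first
  interval's annual ratio in reverse (e.g. extending a 1955 anchor to 1950
  with the 1955–1965 rate).
* `cumulate_decades()`: a six-decade period total is $10 \times$ the sum of
  the six decade-midpoint totals (1965–2015 standing for 1960–2020). The
  published footnote lists "1986" among the midpoints; this is treated as a
  typo for 1985, keeping the uniform 1965…2015 grid. Similarly the last
  female anchor is printed as 2013 in the source table and is carried at the
  2015 grid point.
* `lagged_cigarettes_per_death()`: cumulative sticks sold divided by
  cumulative attributable deaths lagged 20 years (the typical delay between
  uptake and fatal disease), reported both as million cigarettes per death and
  deaths per million cigarettes. Only period totals of sales are published,
  so the default mode aligns period aggregates (sales window $+20$ years $=$
  deaths window); an annual mode exists for synthetic data. Absolute — not
  per-capita — totals are used deliberately: absolute sales map to absolute
  future deaths.

**Known data inconsistency.** The published US male cumulative total (68,760
thousand) is not $10\times$ the sum of its own printed decade values
(68,780), and the both-sex grand total inherits the 20-thousand gap. The
package reports the computed values; the corresponding acceptance
expectations fail by design rather than being weakened. All attributable
cells (18,040; 11,430; 6,100; 3,210; 1,640; 919; grand total 41,339 thousand
≈ 41.3 million) reproduce exactly.

The Canada whole-period ratio (3.2 trillion sticks / 2,559 thousand deaths =
1.25 million cigarettes per death) falls slightly outside the published
"1.0 to 1.2" band, which was computed on a narrower lagged window whose annual
sales are not published; the report notes the discrepancy in its output
metadata instead of hiding it.

## The synthetic-data generator (`synthetic_data`)

`simulate_vital_stats()` states the world the indirect method assumes: within
each stratum a fixed current/former/never split $(p_c, p_f)$, never-smoker
baseline rates $N_c$ per cause, multiplicative relative risks, one-year cycles
and no competing-risk depletion (populations large, per-cause risks small).
Expected deaths per cause cell are

$$E = P \, N_c \left[ p_c RR_c + p_f RR_f + (1 - p_c - p_f) \right],$$

observed either exactly (`noise = "none"`) or as Poisson draws with mean $E$.
All randomness flows from the config seed and the caller's RNG state is
restored afterwards. The ground-truth table retains the current- and
former-smoker excess components and the generating $p_c$.

Former smokers are included deliberately even though the SIR conflates them
with current smokers: with $p_f > 0$ and $RR_f > 1$ the recovered SIR is
$p_c + p_f (RR_f^{lung} - 1)/(RR_c^{lung} - 1)$, which lets tests *quantify*
the bias the indirect method incurs where former-smoker prevalence is high
rather than hide it. Exact-recovery tests therefore set $p_f = 0$ or
$RR_f = 1$.

What the generator does **not** emulate: birth-cohort dynamics of uptake and
cessation over calendar time, age drift within bands, cause misclassification,
and certification-quality differences between countries. A green
parameter-recovery test establishes that the estimator inverts the generative
model it assumes — not that real vital statistics satisfy that model.

Default scales mirror the application domain: never-smoker lung-cancer rates
around 14 per 100,000 person-years, current-smoker lung RR around 21 (the
mature-epidemic magnitude), all-cause-style RR near 3, prevalences near 0.3,
stratum populations of $10^5$–$10^6$ so that expected lung counts are in the
hundreds — the regime where national vital statistics operate.
`simulate_sales()` converts prevalence and population to sticks at about 14
cigarettes per daily smoker per day, the observed 2015 scale.

## Numerical and design choices

* **Geometric vs linear interpolation** — geometric by default (see above); a
  zero anchor adjacent to a nonzero one is a hard error directing the caller
  to linear mode, never a silent fallback.
* **SIR clamping** — to $[0,1]$, flagged. With Poisson noise and expected cell
  counts ≥ 500 clamping is essentially never triggered, so the estimator's
  mean bias stays below 1% (tested over 1,000 seeded replicates).
* **Tolerances** — closed-form identities are tested at $10^{-9}$ relative or
  tighter; the microsimulation-oracle equivalence of `attribute_all()` holds
  to $10^{-9}$ because both sides are exact expectation arithmetic.
* **Units** — every series carries a unit label; unit mismatches are hard
  errors. Rates enter CSV files per 100,000 person-years (the vital-statistics
  dialect) and are stored internally per person-year.
* **Determinism** — identical config and seed give byte-identical CSV outputs;
  timestamps are confined to the log stream.
* **JSON-only configs** — the supported stack ships no YAML parser, so run and
  simulation configs are JSON.

## Worked example

```{r example}
# cumulative attributable deaths, US males, decade totals in thousands
cumulate_decades(c(235, 305, 335, 341, 302, 286))

# cessation: quit before 40 at RR 1.2 vs continuing at RR 3
excess_risk_percent(1.2)
excess_risk_percent(3.0)
100 * excess_risk_reduction(1.2, 3.0)

# lagged cigarettes-per-death, UK period totals
uk <- sales_series("UK", period_start = 1940, period_end = 2000,
                   period_total = 7.0e12)
lagged_cigarettes_per_death(
  uk, list(start = 1960, end = 2020, total = 9310, unit = "thousand"))
```

## Limitations

* The reference relative risks and study rates behind the published avoidable
  proportions are not part of the package (they are user-supplied input), so
  those published tables are verified by round-trip consistency
  (`rr_from_af()` ∘ `attributable_fraction()`), not end-to-end recomputation.
* The lagged-ratio analysis at annual resolution cannot be checked against
  published figures because annual sales are not published; only period-total
  ratios are reproduced.
* No second-hand-smoke attribution, no confidence intervals on RRs (point
  values only), and no dynamic cohort simulation.
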