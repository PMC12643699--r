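---
title: "Methods: disproportionality signal detection and time-to-onset modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality signal detection and time-to-onset modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
library(dplyr)
```

## The model of the data

A spontaneous report database is a collection of case reports, each
naming one or more suspect drugs and one or more adverse events coded as
MedDRA preferred terms (PTs). The report — not the drug mention or the PT
occurrence — is the statistical unit throughout: a report contributes at
most once to any (drug, event) cell however often a drug or PT repeats
within it, and at SOC granularity a report counts once per system organ
class regardless of how many of its PTs map there. For a pair (D, E) the
2×2 table is

|            | event E | other events |
|------------|---------|--------------|
| drug D     | a       | b            |
| other drugs| c       | d            |

with `N = a + b + c + d` the size of the cleaned database, identical
across all pairs from one collection. "Drug D" means D appears in a
suspect role; the default is primary or secondary suspect
(`role_cod` PS or SS), configurable to PS-only, because concomitant and
interacting entries describe background medication rather than the
suspected cause. The comparator is the full cleaned database, including
reports of the other study drugs; `exclude_drugs` lets an analysis remove
them when the study drugs would otherwise contaminate each other's
baseline (a real effect — see the calibration section).

## The four algorithms

**ROR and PRR.** The reporting odds ratio `ad/(bc)` with the Wald interval
`exp(ln ROR ± z·√(1/a+1/b+1/c+1/d))` (`z = 1.96` by default, configurable)
and the proportional reporting ratio `[a/(a+b)]/[c/(c+d)]` with the
Pearson χ² statistic `N(ad−bc)²/((a+b)(c+d)(a+c)(b+d))` (Yates correction
available, off by default). When any cell is zero the ROR gets the
Haldane–Anscombe 0.5 correction on all four cells — on by default for the
ROR only, because PRR, IC and EBGM remain defined at zero cells and
correcting them would silently change defined values. With the correction
disabled, a zero-cell ROR is returned as `NA` with an `ror_undefined`
flag, and an undefined statistic never fires a threshold rule.

**BCPNN IC.** The closed-form shrinkage variant of the information
component: `E = (a+b)(a+c)/N`, `IC = log2((a+0.5)/(E+0.5))`, and
`IC025 = IC − 3.3(a+0.5)^{−1/2} − 2.4(a+0.5)^{−1}`. This is the
modern closed-form approximation to the original credible interval; it is
finite for all `a ≥ 0`, including `a = 0`.

**MGPS EBGM.** DuMouchel's gamma–Poisson shrinker:
`a ~ Poisson(λE)` with `λ ~ w·Γ(α₁,β₁) + (1−w)·Γ(α₂,β₂)` (shape/rate).
Marginally each count is a two-component negative-binomial mixture; the
five hyperparameters maximize the summed marginal log-likelihood over all
pairs of one granularity. The fit is quasi-Newton (BFGS) on
`(log α₁, log β₁, log α₂, log β₂, logit w)` from the conventional start
`(0.2, 0.1, 2.0, 4.0, 1/3)` plus two deterministic perturbations; the
best optimum wins, a relative tolerance of 1e-12 governs convergence, and
non-finite likelihood excursions are rejected inside the objective.
At least 20 pairs with positive expected count are required — below that
an empirical prior is meaningless and the fit errors rather than
extrapolates. The prior is fitted per granularity (PT-level scoring uses
a PT-level fit, SOC-level its own), because the empirical prior must
describe the cell universe it scores.

The posterior of λ given `a` is again a gamma mixture with components
`Γ(αⱼ+a, βⱼ+E)` and weights proportional to the prior weight times the
component's negative-binomial likelihood. `EBGM = 2^{E[log2 λ | a]}` is
computed from digammas in closed form; `EBGM05` is the 5th posterior
percentile found by bisection on the posterior CDF to an absolute
tolerance of 1e-8 (a test verifies it against direct quadrature of the
posterior density to 1e-6). `E = 0` (a drug or event absent from the
universe) still yields a proper posterior because the prior rates are
positive; only negative or non-finite expected counts return `NA`.

**Decision rules.** Defaults: ROR `a ≥ 3` and lower CI strictly > 1; PRR
`a ≥ 3`, `PRR ≥ 2`, `χ² ≥ 4`; BCPNN `IC025 > 0` (strict); MGPS `a ≥ 3`,
`EBGM05 ≥ 2`. A pair is a signal when at least one rule fires
(`any_of_four`). All cut-offs are arguments of `signal_thresholds()`;
these are the standard published values for the four-algorithm family,
and the strict-versus-inclusive boundaries are tested explicitly.

A note on IC versus EBGM: for large counts both converge to the observed/
expected ratio (IC to its log2), so a table whose printed IC is
log2(EBGM) row for row is consistent with either an independent IC or one
derived from the MGPS fit. Both routes exist here (`ic_score()` computes
the closed-form BCPNN independently of the prior), so either convention
can be reproduced.

One caution a user should know: IC and EBGM are *not* monotone in `a`
when `b, c, d` are held fixed, because the expected count
`(a+b)(a+c)/N` grows quadratically in `a`; the observed/expected ratio
peaks near `a ≈ √(bc)` and declines beyond it. Real pair tables live far
below that point (`a ≪ √(bc)`), and the monotonicity property is tested
in that regime.

## Weibull time-to-onset

Time-to-onset is `event date − earliest full-precision therapy start` for
the drug within the report, in whole days. Records are excluded, with
per-reason tallies, when either date is missing or partial (YYYYMM or
YYYY) or the difference is negative — day arithmetic on month-precision
dates would fabricate up to 30 days of error, so partial dates are
flagged during ETL and consumed only by stages that tolerate them.

The two-parameter Weibull with shape β and scale α (days) has
log-likelihood
`ℓ(α, β) = n ln β − nβ ln α + (β−1)Σ ln tᵢ − Σ (tᵢ/α)^β`.
The scale is profiled out in closed form, `α̂(β) = (Σtᵢ^β/n)^{1/β}`, and
the one-dimensional profile score for β is solved by Newton iteration
(tolerance 1e-10, moment start `β₀ = π/(sd(ln t)·√6)` from the
extreme-value representation). Times are pre-scaled by their geometric
mean so `t^β` stays well conditioned; the estimate is scale-equivariant
to 1e-8 by test. Wald 95% CIs come from the numerically evaluated
observed information on `(ln α, ln β)`, transformed back. The sample is
treated as complete — spontaneous reports only contain observed onsets,
so there is no censoring model.

Numerical edge cases: zero-day onsets (same-day infusion reactions are
real and common) would unbound the likelihood for β < 1, so `t = 0` maps
to half a day by default (`zero_handling = "exclude"` drops them
instead); an all-identical sample has no information about β and errors
as degenerate; fewer than 10 positive values errors rather than returning
a meaningless interval. The hazard classification reads the shape CI:
entirely below 1 is *early failure* (incidence declining with time on
treatment), entirely above 1 *wear-out*, straddling 1 *random*; an
undefined CI is *indeterminate*.

## The synthetic generator

`simulate_faers()` emulates the data a FAERS extraction yields for a
three-drug chemotherapy study, with every quantity a test might need
recorded in a truth manifest. Per report: 1–3 suspect drugs (first PS,
rest SS) drawn by exposure weight; each event occurs with probability
`background × max(relative rate over the report's drugs)`, capped at 1;
an event date uniform over 2004–2024; per-drug therapy starts
back-calculated from Weibull onset draws floored to whole days;
sex/age/weight/country from mixtures with realistic missingness (ages
emitted in mixed units — years, months, decades — to exercise
harmonization); a configured fraction of date fields degraded to YYYYMM
or YYYY; and a configured fraction of cases re-emitted whole under a new
primaryid with a later receipt date to exercise the dedup rule.

Default study conditions: paclitaxel/vincristine/irinotecan at exposures
0.45/0.25/0.30; a 35-PT vocabulary across the major organ classes with
background rates of 1–9%; thirteen planted pairs at relative rates
between 3.4 and 9 (the magnitudes a chemotherapy signal study reports);
per-drug onset distributions Weibull(0.64, 61.23), (0.54, 46.75),
(0.72, 52.99) days — the published early-failure parameter range for
these drugs; 5% duplicates; 5% partial dates. These defaults are the
conditions the test-suite measures under; they are set once, not tuned.

Two deliberate simplifications matter for interpreting green tests.
First, reports may carry **zero reactions**: event draws are independent
Bernoullis, so a planted pair's `a`-cell is exactly binomial and the
generator's recovery tests have a closed-form oracle; forcing a minimum
of one reaction per report would be more FAERS-like but would break that
exactness. Second, in the default universe the three study drugs *are*
most of the comparator, so disproportionality statistics are strongly
attenuated relative to a real database where target drugs are a sliver of
the whole (a planted rate of 6.9 shows an ROR near 2). That attenuation
is a property of the study design, not an error; calibration and
sensitivity are therefore measured on purpose-built universes — an
all-null configuration (≥50 pairs, 20,000 reports) for the false-positive
rate and a ten-drug, disjoint-signal configuration for planted recovery —
where the criterion's stated regime (relative rate 5, expected `a ≥ 20`)
actually holds. The generator also does not model concomitant-medication
confounding, reporting delays by country, or any correlation between
events within a report beyond the shared drug set; passing tests say
nothing about robustness to those features of real data.

## Problem sizes and determinism

All randomness flows from a single integer seed per run. The test suite
works at sizes chosen to make each property measurable in seconds on one
core: statistic-oracle equivalence at 1,000 random tables, MGPS refit at
5,000 cells, null calibration and planted sensitivity at 20,000 reports,
Weibull recovery at 100 replicates of n = 5,000 per shape, and
end-to-end determinism at 50,000 reports (two full runs compared by file
checksum; no artifact embeds a timestamp, so reruns are byte-identical).

## Known limitations

MedDRA is licensed, so the PT→SOC dictionary is an input file (a small
synthetic demo dictionary ships under `inst/extdata/`); there is no
LLT→PT rollup. Drug-name normalization is an exact-match synonym table
after case-folding and whitespace collapse, not an NLP encoder — variant
spellings not in the map pass through unmapped (counted, not guessed).
Deduplication is by case ID with latest-receipt-date retention and a
largest-primaryid tie-break; no probabilistic record linkage. MGPS is
unstratified (no age/sex strata in the expected counts), there is no
multiple-testing adjustment beyond the threshold rules, and the Weibull
fit assumes a complete, uncensored, single-population sample — a mixture
of early infusion reactions and late cumulative toxicity will fit an
averaged shape.
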