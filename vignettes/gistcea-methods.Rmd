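---
title: "Model and methods behind gistcea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods behind gistcea}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`gistcea` implements a deterministic Markov cohort model comparing two
first-line treatment policies for metastatic gastrointestinal stromal tumor
(GIST): empirical low-dose imatinib for everyone, versus one-time targeted
gene testing (TGT) with *KIT* exon-directed dose selection. This vignette is
the package's own account of the model: its structure, assumptions, tunable
parameters, the synthetic survival fixtures, and the numerical and design
choices made where the methodology was genuinely open.

## State space and strategies

Each genomic subpopulation (*KIT* exon 11, *KIT* exon 9, other variants)
moves through an ordered sequence of treatment-line states, then best
supportive care (BSC), then death (absorbing):

| strategy  | genotype  | line sequence                                |
|-----------|-----------|----------------------------------------------|
| empirical | all       | imatinib 400 → imatinib 800 → sunitinib → BSC |
| TGT       | exon 9    | imatinib 800 → sunitinib → BSC                |
| TGT       | exon 11, other | same as empirical                        |

Every transition to the next line — including the 400→800 mg dose
escalation — is a disease-progression event: it incurs the one-time
progression cost (during the first three model years) and one utility
decrement. Entry into BSC is a progression event for cost purposes, but the
BSC utility is the absolute 0.577, not a further subtraction. Every tested
patient pays the TGT cost once at cycle 0, including those whose management
is unchanged; this is what universal testing costs. Death is possible from
every alive state.

The cohort runs in 2-month cycles (the standard disease-reassessment
interval) over a 10-year horizon, i.e. 60 cycles; both are configurable,
and the horizon must divide into whole cycles.

## From survival curves to transition probabilities

Survival inputs are point series \(S(t)\) per endpoint (PFS, OS) ×
genotype × drug, interpolated piecewise-linearly on the survival scale —
the least-assumption choice for noisy digitized step curves. Cycle
probabilities are conditional survival drops,
\(p_i = 1 - S(t_{i+1})/S(t_i)\), so an exponential curve yields a constant
schedule (memorylessness), and reconstructing \(\prod_i (1-p_i)\) recovers
the curve at cycle boundaries exactly.

PFS events include death, and no published decomposition into
progression-only and death hazards exists for these inputs. We convert
both schedules to rates under a constant-hazard-within-cycle assumption
(\(r = -\ln(1-p)/T\)) and subtract: \(r_{prog} = \max(0, r_{PFS} -
r_{OS})\), clamping at zero (with a warning) in cycles where noise pushes
the OS hazard above the PFS hazard. Clamping guarantees valid
probabilities; `run_cohort()` additionally rejects any cycle where
progression plus death probability would exceed 1.

Two clocks run simultaneously. Each line's progression schedule is indexed
by *time in that line*, because second- and third-line trial curves are
measured from the start of that therapy; the cohort engine expands each
line state into time-in-state tunnel cells (a small C++ kernel, the
approach compiled cohort engines in health-economics packages use).
Death is indexed by *model time* and always follows the first-line drug's
OS curve for the genotype — OS outcomes in the source trials reflect whole
treatment sequences, not single lines. Trial follow-up is taken to cover
the first 36 months exactly; from month 36 the per-cycle death probability
is replaced by the constant value implied by a registry-style conditional
monthly death probability (`extend_longterm()`). The extension applies to
OS only; PFS curves carry their own tails.

## Costs, utilities, discounting

All costs are 2019 US dollars from a payer perspective. Per cycle, on
beginning-of-cycle occupancy:

* annual drug costs pro-rated to the cycle (imatinib 400: $57,690;
  imatinib 800: exactly 2× that; sunitinib: $86,726), plus line-matched
  "other medical" costs ($2,315 imatinib lines, $3,344 sunitinib) and BSC
  at $9,403/yr;
* expected adverse-event costs: the monthly AE probability (0.033 / 0.065 /
  0.031 for imatinib 400 / 800 / sunitinib) converted to a per-cycle
  probability times a one-time event cost ($296 imatinib, $160 sunitinib).
  AEs carry no disutility and do not stop treatment;
* the one-time progression cost ($46,548) on that cycle's progression flow,
  only for cycles starting before month 36;
* QALYs from state utilities: 0.935 metastatic, minus 0.12 per prior
  progression (0.935/0.815/0.695 along the empirical path), 0.577 in BSC,
  0 when dead, clamped at 0 if a configuration drives them negative.

Costs and QALYs are discounted at 3%/yr from each cycle's start time. No
half-cycle correction is applied by default — this matches the common
default of the commercial tool this class of model is usually built in —
but `half_cycle_correction = TRUE` switches to averaging beginning- and
end-of-cycle occupancy. The imatinib cost is a market-share-weighted mean
of brand and generic prices; only the 50/50 mean is published, so the
default brand/generic pair ($110,656, $4,724) is chosen symmetric about it
(consistent with real-world acquisition-cost spreads), reproduces the mean
exactly at 50%, and is config-exposed. Scenario runs at 0% and 100%
generic share reuse the same two prices.

Decisions route through net monetary benefit differences
(`NMB = λ·QALY − cost`), which remain well-behaved where the ICER is
undefined or sign-pathological; `icer()` classifies dominance before
dividing and reports "cost-only" rather than erroring when QALYs tie.

## The synthetic trial generator

The source survival data are Kaplan–Meier figures from two trials (an
imatinib dose-randomization with genotype subgroups, and a second-line
sunitinib study) that exist only as published images; their digitized
point series are not redistributable. `generate_fixture_trials()`
therefore generates stand-in curves: one exponential hazard per
genotype × drug × endpoint, sampled monthly to 180 months, optionally
perturbed with seeded Gaussian noise on the log-survival scale
(default SD 0.03, emulating digitization error), capped at 1 and
re-monotonized with a simple running minimum.

Default hazards come from median survival typical of those trial
populations — PFS medians of 24/22 months (exon 11 on 400/800 mg), 6 vs 19
months (exon 9 — the clinical crux), 12 months (other), 5/19/8 months on
sunitinib; OS medians of 60/30/36 months on imatinib, equal across doses
within genotype — chosen once as the package's study conditions. The
generator validates any user spec against the qualitative structure the
model depends on (exon 9 does better on 800 mg; exon 11 slowest to
progress on 400 mg; OS dose-equivalence) and refuses specs that violate
it. The long-term conditional monthly death probability (0.015/month) is
likewise a labelled synthetic default standing in for a registry estimate.

What the fixtures do **not** emulate: censoring and number-at-risk decay,
step-function granularity, non-proportional or non-constant hazards, cure
fractions, and cross-trial population differences (sunitinib rows are an
independent block; no cross-trial consistency is imposed). Passing tests
therefore demonstrate that the machinery is correct — conservation, closed
forms, invariances, seeded reproducibility — not that any particular
published ICER is reproduced; absolute results on real digitized curves
will differ.

## Sensitivity analyses

**One-way / threshold.** `one_way()` re-runs the full deterministic model
over a parameter grid and locates the decision flip by bisection on the
NMB difference to a $1 tolerance, using the grid endpoints as the bracket.
Two parameter paths have linked semantics: exon 9 prevalence rescales the
other two prevalences proportionally (the triple must sum to 1), and the
imatinib 400 mg cost drags the 800 mg cost (always 2×) and the
brand/generic prices with it.

**Horizon and market share.** `horizon_sweep()` truncates or extends the
run; because costs concentrate early while QALY gains keep accruing, the
ICER declines with horizon on fixtures with the expected structure (a
property the test suite asserts). `market_share_scenario()` recomputes
drug costs from the price pair and share.

**PSA.** `psa()` samples every uncertain parameter per iteration: costs
from gamma and utilities from beta distributions, moment-matched
(gamma: shape \((m/s)^2\), scale \(s^2/m\); beta:
\(\nu = m(1-m)/s^2 - 1\)) with SD = 20% of the mean by default
(`sd_fraction`, overridable per parameter); adverse-event probabilities
from betas with SDs derived from their reported 95% CIs (no published SDs
exist for them); the utility decrement as a beta on its magnitude with the
sign reapplied. Transition-probability uncertainty has no published form
either; our documented choice is a mean-1 beta-scaled hazard multiplier
(\(2\,\mathrm{Beta}(a,a)\), \(a\) set so the SD equals `sd_fraction`) per
progression schedule, and one per *genotype* for death schedules so OS
dose-equivalence survives sampling; products are clamped to \([0,1]\) and
the whole mechanism can be switched off. Draws are vectorized up front
from a single seed, so results are bit-reproducible and the caller's RNG
state is untouched. The CEAC is evaluated on a $0–200,000 grid in $1,000
steps.

Two boundary rules are worth knowing. A requested beta SD at or above the
feasibility bound \(\sqrt{m(1-m)}\) — which a 40% relative SD hits for the
0.935 utility — is capped at 99% of the bound with a warning, so the
`psa_sd_sweep()` over 10–40% runs everywhere. And infeasible draws cannot
occur by construction (gamma and beta are sampled on their supports), so
no resampling loop is needed.

## Problem sizes and tolerances

The package's own test and reporting scale, chosen to keep a full run
interactive: 60-cycle base case; 10,000 PSA iterations by default (CE
probability SE < 0.5%; `default_parameters(psa_iterations = 1e5)` gives
the source-scale run); 10,000-point dense grids as the independent oracle
for threshold searches; 20 seeds for the noisy parameter-recovery suite.
Key tolerances: mass conservation 1e-9, closed-form accrual oracles 1e-6,
moment-matching identities 1e-12, bisection $1 on NMB.

## Known limitations

Regorafenib (third-line in current guidelines) is excluded — no
genotype-stratified trial data. Treatment discontinuation, dose
reductions, and individual-level heterogeneity are not modelled. BSC
retains only the BSC cost (no drug-era "other medical" costs), and AE
probabilities do not apply in BSC; both are undocumented in the source
methodology and set here by explicit choice. The model inherits every
limitation of the synthetic fixtures listed above, and headline results
from analyses built on the real digitized curves are not reproducible
from this package without supplying those curves via `survival_curve()`.
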