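---
title: "Crossover DDI alerts under patient identity linkage: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Crossover DDI alerts under patient identity linkage: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(durlink)
library(dplyr)
```

## The problem

Pharmacy benefit managers (PBMs) screen every incoming prescription claim
against the patient's medication history before dispensing — prospective drug
utilization review (DUR) — and reject claims that would complete a serious
drug-drug interaction (DDI). The screen is only as good as the history it can
see. In the US, the working identifier on a claim is the payor-assigned
*beneficiary identifier*, which changes whenever the patient changes payor or
benefit. A system keyed on that identifier treats a record from a new payor
as a new patient, so a fill made under last year's insurance is invisible to
this year's screen.

Some PBMs instead resolve claims to a *unique patient identifier* (UPI) by
deterministic demographic matching. An alert whose precipitating fill sits
under a different insurance identifier than the triggering fill — discoverable
only through the UPI — is a **crossover alert**. The crossover fraction of
all serious-DDI alerts measures, directly, what identifier-keyed review
misses inside a single PBM; scaled by the PBM's market share it yields a
national estimate of alerts missed for lack of shared identity and history.

`durlink` implements that whole measurement as a reusable, testable pipeline:
a synthetic claims generator with known ground truth, both linkage regimes,
the DUR screen, alert disposition classification, stratified rate tables,
bivariate/logistic analysis helpers, and the national projection arithmetic.

## The measurement chain

1. **Linkage regimes.** `link_by_beneficiary()` keys identity on
   `(payor_id, beneficiary_id)`. `link_by_upi()` runs ordered deterministic
   matching passes (default: normalized first + last name + birth date + sex;
   then first initial + last name + birth date + postal code) and takes the
   transitive closure: claims sharing a key in any pass share an identity.
   The component's identity key is its minimum claim id, so runs are stable.
   No probabilistic scoring is used — the regime under study is deterministic
   matching, and transparent passes make results reproducible.

2. **Screening.** `run_pdur()` processes claims in fill-date order. A
   historical fill precipitates an alert against an incoming claim when it
   is strictly earlier (same-day ties broken by claim id, so a pair is
   counted once), within the `history_window`, still on hand
   (`fill_date + days_supply >= as_of`) when `require_active_supply`, and
   its therapeutic class forms a SERIOUS pair with the incoming class. One
   alert is emitted per (triggering, precipitating) pair; denominators
   downstream count alerts, not triggering claims.

3. **Crossover.** An alert is flagged crossover when its two claims carry
   different `(payor_id, beneficiary_id)` pairs. With clean demographics the
   UPI ledger minus the beneficiary ledger *is* the crossover set — that
   set-difference identity is the core of the design and is asserted in the
   test suite rather than assumed.

4. **Dispositions.** `classify_outcomes()` looks in the half-open window
   `(alert_date, alert_date + 14]` for a re-dispense of the same drug
   (OVERRIDE), else a different drug in the same `condition_group`
   (REPLACEMENT), else ABANDONMENT. Precedence is OVERRIDE > REPLACEMENT.

5. **Projection.** With market share `m`, the *proportionality factor*
   `P = 1/m − 1` scales the observed crossover rate `c` to the population
   the PBM does not see: projected additional rate `c·P`, annual national
   volume `A`, undetected alerts `U = A·c·P`, and contraindicated
   dispensings `D = U·(a + r)` where `a` and `r` are the abandonment and
   replacement proportions (overridden alerts would have been dispensed
   regardless).

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `history_window` | 90 | days | most maintenance fills carry at most a 90-day supply, so older fills are no longer active therapy; configurable because the studied system's lookback is not public |
| `require_active_supply` | TRUE | — | a lapsed supply cannot co-occur with the new fill |
| `outcome_window` | 14 | days | dispositions are defined within 14 days of the alert |
| `annual_transition_prob` | 0.20 | /patient-year | consistent with observed ~19%/yr PBM cohort attrition |
| `january_concentration` | 0.70 | fraction | open-enrollment plan changes take effect January 1 |
| `age_triggers` | 19: 0.6, 26: 0.5, 65: 0.9 | prob. at birthday | ageing off family plans; Medicare eligibility |
| `offbenefit_classes` | ED: 0.10 | prob./fill | non-covered ED products filled under cash/coupon identifiers |
| `ddi_plant_rate` | 0.15 | /patient | density of planted serious interacting pairs |
| `fills_per_year` | 3 | /patient-year | background chronic-therapy stream |

The off-benefit rate and the January concentration have no published values;
they were fixed once so that the simulated alert stream reproduces the
qualitative structure reported for real retail DUR data — crossover alerts
roughly 2–2.5 times as likely in January as in other months, decaying
through the first quarter, and ED-involved alerts substantially more likely
to cross identifiers — and are not tuned per experiment.

## What the generator emulates, and what it does not

`generate_population()` gives every patient enrollment spans that tile the
3-year horizon (defaults mirror a September 2016 – August 2019 window). Span
boundaries come from annual payor transitions (January-concentrated except
for Medicaid, whose enrollment is year-round) and age-triggered transitions
at 19/26/65; every boundary issues a fresh beneficiary identifier, and
payors map to a fixed pool of PBMs, covering all three real-world transition
modes (patient changes payor across PBMs, payor changes PBM, patient changes
payor within one PBM). Patients 65+ are enrolled in Medicare Part D.

`simulate_claims()` draws a background of mutually non-interacting
chronic-therapy fills plus planted interacting pairs timed to satisfy the
screening predicate, records every claim under the active span's
identifiers (or a per-(patient, class) cash identifier for off-benefit
fills), and derives the ground-truth alert ledger by an exhaustive
within-patient pair scan — a code path independent of the screening engine,
so engine-vs-truth comparisons are genuine two-route checks.

Deliberate simplifications: no deaths, births or uninsured gaps (spans tile
the horizon); demographics are drawn from fixed pools, so matching-key
collisions between distinct patients are possible in principle but
negligibly rare at tested sizes; dispensing behavior does not respond to
alerts (the stream represents attempted fills, so most synthetic alerts are
"abandoned" unless resolution fills are present); fill dates are uniform
rather than refill-cyclic; and no pharmacologic dose/duration logic exists —
interactions are class-pair lookups. Passing tests therefore demonstrate
the *identity and accounting* machinery — which alerts exist under which
identity regime, and how rates and projections follow — not pharmacologic or
behavioral realism.

For calibration experiments, `simulate_claims(crossover_share = x)` places
each planted pair on a patient with at least two spans and forces it to
straddle an identifier boundary with probability exactly `x` (otherwise
both fills sit inside one span), so the true cross-identifier share of
interacting pairs is Binomial(`x`) and the pipeline's estimated crossover
rate can be checked against a known target.

## Numerical and design choices

* **Reporting rounding** is half-away-from-zero (`round_half_up()`), applied
  only at the last step; internal arithmetic is full precision. The
  proportionality factor is conventionally reported at two decimals and is
  used at that precision in the downstream chain, matching how such figures
  are printed and quoted.
* **Same-day fills**: the precipitating claim must be strictly earlier, or
  same-day with the smaller claim id — deterministic and double-count-free.
* **Outcome window is half-open**: the rejected triggering fill (day 0)
  cannot resolve its own alert; day 14 is the last qualifying day.
* **Replacements** are defined by the catalog's explicit `condition_group`
  equivalence map, and a replacement is not required to be non-interacting
  (the studied definition does not say; the choice is configurable in
  spirit by editing the catalog's groups).
* **Reference weighting** in `annualize_national_alerts()` standardizes
  stratum alert volumes by national-vs-observed *population* shares
  (`w_s / q_s`). Weighting by alert shares would be vacuous — the observed
  share cancels — so the table requires `pop_share` explicitly. Published
  weighted national figures (e.g. a weighted annual alert volume) rest on
  unpublished weight tables; they are accepted as inputs rather than
  reverse-engineered, and the unweighted figure is always computed.
* **Projection ambiguity**: "projected crossover percentage" can mean the
  additional rate `c·P` or the total under full exchange `c/m`.
  `project_national()` returns both (`projected_additional_rate`,
  `projected_total_rate`); the printed headline figure corresponds to `c·P`.
* **Degenerate inputs**: zero churn and zero planting produce empty ledgers
  and a zero projection; a claim date outside every span aborts generation
  (it would indicate a span-logic bug); all-missing demographics become
  logged singleton identities; separation or non-convergence in the
  logistic fit is surfaced in a `diagnostic` column.
* **Statistics** use the standard R machinery (`chisq.test` without
  continuity correction by default, Welch `t.test` by default, `glm`
  binomial with Wald intervals), matching the bivariate-plus-logistic
  analysis style of the study design; the multinomial robustness model is
  out of scope.

## Problem sizes

The bundled tests run the full identity/screening stack at 10,000 patients
(~90,000 claims), verify engine-vs-oracle equivalence exhaustively below
1,000 claims, recover planted cross-identifier shares of 1% and 5% over 20
seeded replicates, and check logistic OR coverage over 50 replicates of
n = 100,000. These sizes give binomial tolerances a comfortable factor below
the effects being tested while keeping a full run in a few minutes.

## A worked run

```{r, eval = FALSE}
cfg <- run_config(seed = 1, n_patients = 5000, out_dir = "runs/demo")
out <- run_pipeline(cfg)
out$counters
out$projection

# seasonal pattern of crossover alerts
monthly_crossover_series(out$alerts_upi, out$dispositions, out$claims)

# the published projection arithmetic, recomputed from printed inputs
worked_example_projection()[c("proportionality_factor",
                              "projected_crossover_pct",
                              "projected_january_pct",
                              "contraindicated_annual")]
```

## Known limitations

The synthetic stream is far denser in interactions and churn-driven
crossover than real claims (simulated crossover rates are a few percent,
versus ~1% in large real systems), so absolute synthetic rates are not
estimates of real-world quantities — only the identities, monotonicities
and recovery properties are. Linkage quality under perturbation depends on
the two default passes; real master-patient-index stacks use more passes
and richer fields. The projection assumes transition destinations are
proportional to market share and that the unobserved population behaves
like the observed one; both assumptions are inherited from the study design
and are not testable from inside one PBM's data.
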