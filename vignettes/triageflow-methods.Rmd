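---
title: "Models and methods behind triageflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind triageflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triageflow)
```

`triageflow` models a children's hospital outpatient department that
digitised its triage: a mobile app walks the triage nurse through danger
signs, eleven symptoms, five signs and four vital signs, a cascade of
rules turns the answers into a three-level urgency category, and a ward
dashboard lets clinicians call children in severity order instead of
arrival order. The quality-improvement question is whether this shortens
the time from the end of triage to intravenous antibiotics (IVA). This
vignette explains each model, its assumptions, the tunable parameters,
and the design choices made where more than one reasonable construction
existed.

## 1. The triage cascade

`classify()` runs four stages:

1. **Danger signs** (unconsciousness, convulsions, obvious respiratory
   distress, cyanosis, severe trauma, suspected neonatal sepsis in the
   default list). The first one present — in configured order — forces
   `EMERGENCY` and short-circuits everything else. Conservative triage:
   no later stage can ever downgrade a danger sign.
2. **Logistic admission risk** over age (months), temperature (°C),
   respiratory rate, SpO₂ (percent) and the presence of cough, difficulty
   breathing, chest indrawing, lethargy, irritability and diarrhea:
   `risk = plogis(intercept + Σ βⱼ xⱼ)`. Applied from
   `ipsi$min_age_months` (3) upward, closed below. Two probability
   cut-offs map the risk to priority (≥ 0.15) or emergency (≥ 0.50).
3. **Additive respiratory severity** for children under
   `risc$max_age_months` (24, open above) showing at least one configured
   lower-respiratory indication: integer points for low SpO₂, chest
   indrawing, wheezing, feeding inability, low weight for age, and HIV
   status (the point table carries an explicit `unknown` row). Cut-offs
   at 3 (priority) and 5 (emergency) points.
4. **Single-vital-sign thresholds**, age-banded (bands tile `[0, ∞)`
   months, closed below/open above; gaps or overlaps are configuration
   errors): each breached cut-off flags priority or emergency.

Stages 2–4 are evaluated for *every* child (not only when earlier stages
abstain), and the final category is the maximum severity over all flags,
with the trigger naming the first stage in cascade order that attained
it. Running the vital thresholds in parallel rather than as a fallback is
the safer reading of a cascade diagram that does not state the
alternative, and it makes the category monotone in every input.

**Missingness.** Nurses may skip any entry. A skipped predictor makes the
corresponding score *absent* rather than imputed, and absent scores
contribute no severity. This means a child with missing vitals can only
be escalated by what was observed — the platform's behaviour, and the
conservative one given that imputation at triage time has no data to
stand on.

**The shipped defaults are reconstructions.** The deployed platform's
exact coefficient vector, point values and cut-offs are not public; the
YAML default (`cascade-default.yaml`, `provenance: reconstructed
defaults`) carries plausible values in the spirit of the WHO ETAT/IMCI
thresholds, with the documented applicability bounds (3 months, 2 years)
and conservatively ordered cut-offs. Any analysis of a real deployment
must replace this file. Nothing in the package hard-codes a clinical
number.

## 2. The department simulator

`generate_population()` draws arrivals from a non-homogeneous Poisson
process. The hourly profile is morning-heavy (relative weights 0.15
overnight, 6 from 08:00–12:00, tapering through the afternoon): the
department is open around the clock, but families overwhelmingly arrive
after opening, and this is what produces the mid-day congestion that the
observed waiting times imply. Demographics match the registration
cohort: age log-normal with median 24 months (IQR ≈ 9–53), 55% male,
weight and height grown from age with multiplicative noise, district
frequencies from the registration table. Presentations are *constructed
per intended category* — emergency children carry a danger sign,
priority children breach exactly one priority-level vital, non-urgent
children stay below every trigger — and each construction is verified by
`classify()`, so the realised category mix reproduces the configured mix
(pre: 32/426/5240 of 5,698; post: 215/402/4487 of 5,104) up to binomial
error.

`simulate_department()` then queues everyone for three consultation
rooms. Waits and durations are log-normal, parameterised by
median/IQR via the method of quantiles (`lnorm_from_quantiles()`):
registration→triage 7 (3–15) and triage 4 (2–5) minutes as observed;
consultation 15 (10–22), treatment 12 (8–18) and an
order-to-administration delay of 8 (4–16) minutes as package defaults
chosen once so that the simulated first-come-first-served department
produces an overall time-to-IVA median near the observed ~51 minutes.
One RNG stream per sub-process (arrivals, demographics, presentations,
service times, adherence, treatment draws) keeps components independent
under a single seed.

**Queue disciplines and adherence.** Under `fcfs` a freed room takes the
longest-waiting child. Under `triage_priority`, each time a room frees,
staff consult the dashboard *for that decision* with probability
`adherence[category of the due child]`: a followed emergency is
transferred to the treatment room (bypassing consultation), a followed
priority child takes the room ahead of earlier arrivals, and an ignored
dashboard reverts that decision to first-come-first-served. Modelling
adherence per service decision rather than per patient is deliberate:
the adherence *measurement* (below) scores seen-events, and only a
per-decision mechanism makes each scored event correspond to one
independent Bernoulli draw, so that simulating with adherence 0.78/0.40
and measuring the log recovers those rates. With adherence 0 the two
disciplines produce identical service orders; with adherence 1 the
severity ordering is strict. The real platform measured adherence as an
outcome; inverting it into a mechanism is a modelling idealisation, and
the package documents it as such.

Emergencies are transferred at decision epochs, not instantaneously, so
an adherent emergency still waits the few minutes until a room next
frees; their antibiotics then need only the treatment-room queue (with
non-preemptive emergency priority) and the order-to-administration
delay, which is what produces simulated post-phase emergency medians of
roughly 10–18 minutes against ~50 under first-come-first-served.

`assign_treatments()` draws IVA receipt per category and phase from the
observed proportions (e.g. emergency post 88/215) and runs the single
treatment room.

## 3. The evaluation pipeline

**Exclusions** (`apply_exclusions()`): among IVA recipients, drop
records with no triage time, an interval above five hours (intentional
delays), or antibiotics before triage (children taken straight to the
treatment room, triaged after). Demographic implausibilities (age
missing/negative, height outside 25–200 cm, weight outside 1–150 kg)
are flagged, not dropped, since they do not invalidate a time interval.
The filter is idempotent.

**Medians and shifts** (`compare_medians()`): type-7 (linear
interpolation) quantiles throughout — the convention must be fixed
somewhere, and type-7 is R's default. The shift estimate is the phase
coefficient of a τ = 0.5 quantile regression, with a rank-inversion 95%
interval (normal-theory sandwich fallback beyond n = 5000, where rank
inversion is impractical); the Hodges–Lehmann estimate and interval are
reported alongside because the two summarise "median difference"
differently and the platform's users should see both. Mann–Whitney tests
are exact (no ties, both arms ≤ 20) or tie-corrected normal otherwise.

**Odds ratios** (`odds_ratio()`): sample OR with a Woolf log-scale
interval, 0.5 continuity correction only when a cell is empty, Fisher
exact p. Proportion comparisons expose both the chi-squared and Fisher
routes, since the one-hour-bundle comparison conventionally uses
chi-squared while small stratum tables need Fisher.

**Segmented interrupted time series** (`fit_segmented()`): quantile
regression at τ = 0.5 of the individual triage-to-IVA intervals on
`{1, week, post, (week − T)·post}`, with T the interruption in continuous
weeks and the implementation gap simply absent from the data. Individual
observations, not weekly means: with ~850 points the weekly means would
hide the within-week spread that dominates this outcome. The
counterfactual projection uses the pre-segment coefficients only.
p-values use the Huber sandwich (`se = "nid"`). On data of this size and
noise the level- and slope-change estimates are individually imprecise —
the package's parameter-recovery test shows unbiasedness over 200
replicates at the published effect magnitudes (a ~2-minute level drop,
a slope steepening of ~48 s/week) rather than pretending per-fit
precision. `segmented_rq` objects carry `print`, `summary`, `coef`,
`predict` (fitted or counterfactual), `residuals` and `plot` (weekly
boxplots with fitted and counterfactual overlays).

**Adherence replay** (`prioritization_adherence()`): at each seen-event
the waiting set is every triaged, not-yet-seen child; the *due* child is
the top of the severity-then-triage-time ordering (ties by patient id).
Events are attributed to the due child's category — "adherence in
emergency cases" means the cases where an emergency child was due. Three
event classes are excluded as uninformative: sole-waiter events (the
order was forced), events where the due child was seen within the
tolerance anyway (their own event records the outcome), and — by default
— *concordant* events where the due child is also the longest-waiting
child, because severity and arrival order then agree and the event
cannot distinguish dashboard use from habit. Concordance does not depend
on what staff did, so the exclusion is outcome-independent and the
remaining events form an unbiased binomial sample of the genuine
conflict decisions; without it, a department simulated at 40% priority
adherence measures near 50%. The 5-minute default tolerance models
patient movement and dashboard refresh in real logs; on simulated logs,
whose timestamps are exact, the closure check runs at tolerance 0.

**Weekly summaries** (`weekly_summary()`) reproduce the feedback
reports: per-week volumes, median triage duration and time-to-IVA,
category counts, and the dashboard's warning tally (urgent children
waiting over an hour unseen).

## 4. Synthetic per-patient data

`synthetic_iva_dataset()` stands in for the study's per-patient
supplementary CSV: per phase and category it draws triage-to-IVA
intervals log-normal, matched to the published medians and IQRs, adds a
small additive weekly trend (−8 s/week pre, −56 s/week post, centred on
each phase midpoint so the phase medians stay put), truncates regular
draws below the five-hour cap, and optionally plants the three known
artifact groups (1 missing triage time, 12 over-cap, 28 negative). It
reproduces printed summary statistics; it does *not* reproduce real
arrival ordering, case-mix correlations between category and time, or
seasonality — so pipeline tests on it demonstrate computational
correctness, not clinical generalisation.

## 5. Problem sizes and reproducibility

The test suite and the acceptance script run the simulator at the full
study scale (two 11-week phases, ~5,100–5,700 children each) once per
discipline, and use 1–2-week horizons for the many property checks; the
segmented-regression recovery uses 200 replicates of n = 800. All
randomness flows from a single integer seed through named sub-streams,
and every CLI run writes a manifest (package version, seed, MD5 digests
of inputs and configurations).

## 6. Known limitations

* The cascade defaults are reconstructions; results under them
  characterise the *implementation*, not any deployed coefficient set.
* The simulator has no ward, no mortality, no cost, no staff rosters,
  and no antipyretic-in-triage pathway; the last is a documented
  confounder of measured adherence in real deployments.
* Post-phase case-mix inflation of the emergency category (32 → 215) is
  taken as given via the per-phase category mix; the simulator takes no
  position on whether it reflects algorithm sensitivity or case mix.
* Quantile-regression rank-inversion intervals become expensive beyond a
  few thousand observations; the package falls back to sandwich
  intervals there.
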