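# triageflow

Digital pediatric triage, outpatient-flow simulation, and
time-to-antibiotic quality-improvement evaluation, in one R package.

Sepsis is the leading killer of children under five in low-resource
settings, and guidelines call for intravenous antibiotics (IVA) within an
hour of presentation. A digital triage platform — a mobile app collecting
danger signs, symptoms, signs and vital signs, feeding a ward dashboard
that ranks waiting children — is one way to get the sickest children
treated first. `triageflow` implements the three pieces such a platform
and its evaluation need:

1. **The triage cascade** (`classify()`): danger signs short-circuit to
   *emergency*; otherwise a logistic admission-risk model
   (inverse-logit of `β0 + βᵀx` over age, temperature, respiratory rate,
   SpO₂ and six signs/symptoms; applied from 3 months of age), an additive
   respiratory-severity point score (for children under 2 years with
   lower-respiratory indications), and age-banded single-vital-sign
   cut-offs each map to *emergency*/*priority*; the final category is the
   maximum severity attained, with the first stage reaching it recorded as
   the trigger. Every coefficient and threshold is data, shipped as an
   explicitly labelled *reconstructed* YAML default
   (`inst/extdata/cascade-default.yaml`).

2. **A discrete-event simulator of the outpatient department**
   (`generate_population()`, `simulate_department()`,
   `assign_treatments()`): a morning-peaked Poisson arrival process,
   registration→triage wait (median 7 min, IQR 3–15) and triage duration
   (median 4, IQR 2–5), three consultation rooms and one treatment room,
   under first-come-first-served versus dashboard-priority queueing with
   *imperfect adherence*: each time a room frees, staff follow the
   dashboard for the due child with a per-category probability (defaults
   0.78 emergency, 0.40 priority).

3. **The evaluation pipeline** (`apply_exclusions()`,
   `compare_medians()`, `odds_ratio()`, `time_bracket_distribution()`,
   `prioritization_adherence()`, `weekly_summary()`, `fit_segmented()`):
   exclusion filtering of IVA times (missing triage time, interval over
   five hours, antibiotics before triage), median/IQR comparisons with a
   τ = 0.5 quantile-regression shift estimate and Mann–Whitney test,
   Woolf-interval odds ratios with Fisher exact p, the one-hour bundle
   summaries, the prioritization-adherence replay, and segmented quantile
   regression of the interrupted time series
   `Q₀.₅(t) = b0 + b1·week + b2·post + b3·(week − T)·post`
   with a counterfactual projection of the pre-trend.

## A worked example

Classify one febrile toddler under the shipped cascade:

```r
library(triageflow)
cfg <- default_cascade_config()
child <- triage_presentation(
  age = 18, sex = "female", weight = 8.9,
  temperature = 38.9, heart_rate = 152, respiratory_rate = 48, spo2 = 91,
  symptoms = c(cough = "present", difficulty_breathing = "present",
               diarrhea = "absent", inability_to_drink_or_eat = "absent",
               wheezing = "present"),
  signs = c(chest_indrawing = "present", lethargy = "absent",
            irritability = "absent"),
  hiv_status = "negative")
classify(child, cfg)
#> PRIORITY (trigger: ipsi)  [admission risk 0.479; respiratory severity 3]
```

The admission-risk model (0.479, above the 0.15 priority cut-off) fires
first; the severity score (3 points: low SpO₂ would add more, here chest
indrawing and wheezing) and the SpO₂ band agree at priority level.

Run the evaluation pipeline over a synthetic per-patient dataset built
from published stratum summaries (538 pre-phase antibiotic recipients
including the known data artifacts):

```r
d  <- synthetic_iva_dataset(seed = 1, artifacts = TRUE)
ex <- apply_exclusions(d[d$phase == "pre", ])
ex$report
#> Antibiotic recipients: 538
#>   excluded: 41 (7.6%) -- 1 missing triage time, 12 over cap, 28 antibiotics before triage
#>   analyzed: 497
rec <- apply_exclusions(d)$records
tta <- rec$iv_antibiotics_time - rec$triage_end
compare_medians(tta[rec$phase == "pre"], tta[rec$phase == "post"])
#> pre : median 49.6 (IQR 26.8-89.3), n = 497
#> post: median 44.8 (IQR 21.9-87.5), n = 351
#> shift (median regression): -4.8 min (95% CI -11.1 to 2.5)
#> Hodges-Lehmann: -5.8 (-10.9 to -0.4); Mann-Whitney p = 0.0363
```

`evaluate_log()` bundles all of this — exclusions, overall and
per-category medians, odds ratios, time brackets, adherence and the
segmented fit — into one report object, and
`inst/cli/triageflow.R` exposes `validate-config`, `triage`, `simulate`
and `evaluate` subcommands for shell use.

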