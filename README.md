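# ladose

Maximum safe local anesthetic doses, and a harness for grading dose
recommendations against them.

**Research use only — not a medical device. Never use this package to dose
a patient.**

## The problem

Local anesthetics (lidocaine, ropivacaine, levobupivacaine, …) have a
narrow therapeutic window: doses above the individual maximum risk local
anesthetic systemic toxicity (LAST), up to seizures and cardiovascular
collapse. The safe maximum is patient-specific — it depends on body
habitus and on how fast the patient clears the drug — yet dose
recommendations in the wild (apps, heuristics, increasingly chatbots) are
often produced with no such safeguards. `ladose` provides:

* a transparent implementation of a conservative **maximum-safe-dose rule
  chain** (weight-based, risk-adjusted, volume-aware), with the full rule
  trace attached to every result;
* an **evaluation pipeline** that classifies candidate doses as safe or
  unsafe against reference maxima and summarises overdose rates and
  exceedance statistics per respondent, per drug, and for drug mixtures;
* **ordinal (Likert) aggregation** of reviewer ratings with a two-rater
  Cronbach's α;
* a seeded **synthetic vignette generator** with simulated respondents and
  known ground truth, so the whole pipeline is testable at any scale;
* the bundled per-vignette table and consensus ratings of a published
  evaluation of three conversational AI chatbots, so its summary
  statistics can be recomputed from scratch.

## The dose model

For actual weight AW (kg), height and sex: BMI = AW/h² and the Devine
ideal body weight IBW = 50 kg (male) or 45.5 kg (female) + 2.3 kg per inch
over 60 in. The *calculation weight* CW is chosen by five exhaustive,
mutually exclusive branches (AW when lean and lighter than IBW; otherwise
IBW; 70 kg when both AW and IBW exceed 70) and capped at 70 kg. Six risk
factors — age ≥ 70 y, GFR < 50 mL/min, prothrombin time < 50 %,
LVEF ≤ 30 %, pregnancy, major CYP1A2/3A inhibitors — multiply the dose by
0.8 (one factor) or 0.7 (two or more):

    max (mg) = CW × dose_limit (mg/kg) × adjustment
    max (mL) = floor( max (mg) / concentration (mg/mL) )

A candidate dose is an **overdose** iff it *strictly* exceeds the maximum
in its own unit. Per-kg dose limits are configuration
(`inst/extdata/drug_catalogue.yaml`, documented literature defaults), not
hard-coded constants. Mixtures of two anesthetics share one toxicity
budget fractionally: Σ dose_i / max_i = 1.

## Worked example

```r
library(ladose)
p <- patient_record(age = 72, sex = "female", height_cm = 160, weight_kg = 85,
                    gfr = 40)
max_safe_dose(p, default_drug_catalogue()$ropivacaine)
#> <dose_result> ropivacaine (comprehensive): 110.00 mg = 14 mL at 7.5 mg/mL
#>   - BMI = 33.20 kg/m2; IBW (Devine) = 52.38 kg
#>   - CW rule 5: CW = 52.38 kg (cap 70 kg)
#>   - risk factors: 2 (age>=70, renal) -> adjustment x0.7
#>   - max = 52.38 kg x 3 mg/kg x 0.7 = 110.00 mg
#>   - volume: floor(110.00 mg / 7.5 mg/mL) = 14 mL
#>   research use only - not for clinical decision-making
```

Reading the trace: the patient is heavier than 70 kg but her ideal body
weight is 52.38 kg, so rule 5 selects IBW as calculation weight; age and
renal dysfunction are two clearance-impairing factors, shrinking the
maximum by 30 % to 110 mg of ropivacaine — 14 whole millilitres of a
7.5 mg/mL solution. Any recommendation above either number is an overdose.

End-to-end on synthetic data:

```r
run <- run_pipeline(tempdir(), n = 100, seed = 42, quiet = TRUE)
run$summary$overall   # unsafe rates and exceedance moments per simulated respondent
```

A thin command-line front end with `compute-dose`, `simulate`, `evaluate`,
`qualitative` and `reproduce` subcommands lives at
`inst/cli/dosecheck.R`.

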