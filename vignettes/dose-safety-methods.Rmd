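---
title: "Maximum safe local anesthetic doses: calculation rules, evaluation metrics and synthetic vignettes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Maximum safe local anesthetic doses: calculation rules, evaluation metrics and synthetic vignettes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ladose)
library(dplyr)
```

`ladose` is a research tool, not a medical device. Nothing it prints should
be used to dose a patient.

## The clinical problem

Local anesthetics (LAs) have a narrow therapeutic window: exceeding the
maximum safe dose risks local anesthetic systemic toxicity (LAST), with
seizures and cardiovascular collapse at the severe end. The maximum is not
a fixed number per drug — it scales with a patient-specific weight, and it
shrinks when the patient's capacity to clear the drug is reduced. This
package implements a conservative, fully explicit rule chain for that
maximum, and an evaluation harness for grading *any* source of dose
recommendations (a clinician cohort, a calculator app, a language model)
against it.

## The comprehensive dose rule

For a patient with actual weight $AW$ (kg), height and sex, the chain is:

1. **Anthropometrics.** $BMI = AW / h^2$ (kg/m², $h$ in metres) and ideal
   body weight by the Devine formula,
   $IBW = 50\,\mathrm{kg}\ (\text{male})\ \text{or}\ 45.5\,\mathrm{kg}\ (\text{female}) + 2.3\,\mathrm{kg} \times (\text{inches} - 60)$.
2. **Calculation weight.** Exactly one of five branches fires:
   $CW = AW$ if $AW \le 70$, $BMI < 30$, $IBW > AW$;
   $CW = IBW$ if $AW \le 70$, $BMI < 30$, $IBW \le AW$;
   $CW = IBW$ if $AW \le 70$, $BMI \ge 30$;
   $CW = 70$ if $AW > 70$, $IBW > 70$;
   $CW = IBW$ if $AW > 70$, $IBW \le 70$ — and $CW$ is capped at 70 kg.
   The cap embodies the design philosophy: prefer the lowest defensible
   maximum.
3. **Risk adjustment.** Six factors mark impaired LA clearance: age ≥ 70 y,
   GFR < 50 mL/min, prothrombin time < 50 %, LVEF ≤ 30 %, pregnancy, and a
   major CYP1A2/3A inhibitor among the medications. One factor multiplies
   the maximum by 0.8; two or more by 0.7.
4. **Dose and volume.** $\max(\mathrm{mg}) = CW \times \text{limit}_{\mathrm{mg/kg}} \times \text{adjustment}$;
   when a solution concentration is known the equivalent volume is
   $\lfloor \max(\mathrm{mg}) / c \rfloor$ millilitres — floored, so the
   administered volume never carries more drug than the mg maximum. mg
   values are never rounded; only the mL conversion is floored.

Two *simplified* modes, $AW \times$ limit and $IBW \times$ limit, are
common bedside heuristics and are retained as secondary reference
definitions (`mode = "simplified_aw"` / `"simplified_ibw"`).

```{r}
p <- patient_record(age = 72, sex = "female", height_cm = 160, weight_kg = 85,
                    gfr = 40)
max_safe_dose(p, default_drug_catalogue()$ropivacaine)
```

### Parameters and their provenance

* **Per-kg dose limits** are *configuration*, not constants of the method:
  the bundled `drug_catalogue.yaml` ships documented literature defaults
  (lidocaine 4.5, levobupivacaine 2, ropivacaine 3 mg/kg) that users should
  review for their own context. Concentrations (10, 2.5, 7.5 mg/mL) are
  common commercial preparations.
* **Devine constants** (50 / 45.5 kg + 2.3 kg/in over 60 in) are the
  standard published form. The formula was never validated below 60 in
  (152.4 cm); we extrapolate the line down to 130 cm with a warning — the
  extrapolated IBW falls below the base constant, which is conservative —
  and refuse heights below 130 cm rather than return nonsense.
* **Thresholds** sit exactly on their stated side: $AW \le 70$ inclusive,
  $BMI \ge 30$ into the obese branch, GFR/PT strictly below 50, LVEF ≤ 30
  inclusive.
* **Mixtures.** When two LAs share one procedure, the package uses
  fractional additive toxicity: component $i$ receives proportion $p_i$ of
  its *own* stand-alone maximum, so the budget fractions
  $\sum_i \text{dose}_i/\text{max}_i$ sum to 1. This is the standard
  clinical convention for combined LA toxicity; the combination rule was a
  genuinely open design point and is tested as a conservation law rather
  than against an external table.

## Grading candidate recommendations

A candidate answer is a value, a range, or an abstention. Ranges are
normalized to their **lowest** advised dose; abstentions are excluded from
every denominator. A candidate is **unsafe** iff it *strictly* exceeds the
reference in its own unit — a recommendation exactly at the maximum is
safe, and a mL answer is compared with the floored maximum volume. The
strictness is forced by the bundled data themselves: a chatbot answer equal
to the reference was tallied as safe there.

For unsafe cases two exceedance measures are kept: percent,
$(c - r)/r \times 100$, and absolute, $c - r$ in the vignette's printed
unit. Summaries report the unsafe rate over *provided* answers, the mean
and sample SD ($n-1$) of percent exceedance over unsafe cases, and
per-drug absolute statistics that **pool mg and mL numerically**. That
pooling looks odd but is the reporting convention of the source data (a
lidocaine mean of "129" averages a 230 mg and a 27.75 mL exceedance); a
unit-consistent alternative (`unit_consistent = TRUE`, converting through
the concentration) is provided and left off in reproduction runs.

```{r}
rep <- reproduce_published_results()
rep
all(rep$pass)
```

All `r nrow(reproduce_published_results())` summary statistics recompute
from the bundled 10-vignette table (checksummed at load; an edited fixture
is a hard error) and round to their published values.

## Qualitative aggregation

Two reviewers score eight dose-adaptation criteria on a 5-point Likert
scale (1 = very poor … 5 = very good). Per criterion the consensus is the
median; with two raters one level apart that median is a half-integer, and
the package rounds **half-up**, toward the better rating — the source
convention states only "rounded to the nearest integer", so the tie rule is
ours, documented, with `tie = "half_even"` available for sensitivity
analysis. The overall rating is the unweighted mean of criterion consensus
values, rounded the same way; unweighted is the minimal reading and
reproduces both published "poor" overall labels as well as Gemini's "fair".

Inter-rater reliability uses Cronbach's $\alpha$ with the **raters as the
two test components** scored across items,
$\alpha = \frac{k}{k-1}\left(1 - \frac{\sum_i s_i^2}{s_T^2}\right)$ with
sample variances. The raw two-rater matrices behind the published
$\alpha = 0.87$ are not available, so $\alpha$ is property-tested
(identical raters give exactly 1; independent raters drift to 0 as the item
count grows; a worked 2×4 matrix matches a spreadsheet-style oracle) rather
than reproduced. Constant rater totals make $\alpha$ undefined and raise an
explicit error instead of returning a number.

## The synthetic vignette generator

The bundled evaluation table fixes only 10 vignettes; the generator exists
so every pipeline stage can be exercised at arbitrary scale with known
ground truth. It emulates the *structure* of the questionnaire — adult
patients with varying anthropometrics, the six risk factors, single-agent
and two-agent mixture questions, mg and mL framing — not any real
vignette's content.

Defaults, chosen once as a plausible adult surgical population and fixed:
age 18–90 y, height 145–200 cm, weight 40–140 kg, equal sexes; per-patient
prevalences renal 0.10, hepatic 0.08, heart failure 0.08, CYP inhibitor
0.15, pregnancy 0.10 among women ≤ 45; mixtures 0.30; mL framing 0.50.
Organ markers are reported only when abnormal, mirroring vignettes that
state abnormalities explicitly. For $n \ge 10$ the first ten vignettes are
fixed coverage templates guaranteeing all five CW branches, 0/1/2+ risk
factors, both question units and both mixture states; the remainder are
sampled. Everything is reproducible byte-for-byte from `(n, config, seed)`,
and generation never perturbs the caller's RNG stream.

Simulated respondents are parameterised by abstention, range-phrasing and
unit-confusion probabilities plus a multiplicative bias on the true
reference — either lognormal around a centre, or a two-point version that
overdoses with an exact probability (used for calibration tests: the
evaluated unsafe rate must recover the programmed probability within three
binomial standard errors at $n = 1000$). The generator records each
response's ground-truth safety label *before* any unit flip, so evaluation
output can be audited case by case: with unit confusion disabled the labels
must agree everywhere; with it enabled, disagreements may occur only on
flipped cases.

What passing these tests shows — and does not. They demonstrate that the
rule engine, grading and summaries are internally consistent and that the
pipeline recovers known parameters from data it generated itself. Real
clinical answers are messier: free-text doses, implicit units, partial
abstentions ("consult a specialist, but roughly…"), and vignette phrasing
effects are outside the generator's behaviour space.

## Numerical choices and edge cases

* All dose arithmetic is double precision; the single mL conversion floors
  after rounding the quotient at 10⁻⁹ to keep exact divisions (210/7.5)
  from descending a whole millilitre on a 1-ulp error.
* Reported rates and statistics round half-up to integers only at the
  reporting boundary; internal values stay unrounded.
* Zero unsafe cases yield absent (`NA`) exceedance moments, never zeros; a
  single unsafe case has a mean but no sample SD.
* An empty or all-abstention response set summarises without error
  (`n_provided = 0`, rate `NA`).
* Problem sizes used by the test-suite: a ~50,000-point branch grid, 10,000
  random rule-engine points against a literal-transcription oracle, and
  1000-vignette synthetic panels — sizes at which the binomial checks are
  sharp while the whole suite stays interactive.

## Known limitations

* The bundled reference doses are inputs transcribed from the published
  table; the per-vignette patient details behind them are not public, so
  those ten reference values are *data*, not something the engine
  recomputes (the engine is instead verified on its own examples,
  properties and synthetic panels). Likewise the published secondary
  overdose rates under IBW/AW-only references are not recomputable from the
  bundled table; `secondary_reference_analysis()` implements the mechanism
  and is validated on synthetic panels.
* No pediatric dosing, no pharmacokinetic modelling beyond the printed rule
  set, no inference about drug interactions beyond list membership.
* The qualitative module aggregates exactly two raters; weighted kappa or
  ICC alternatives are out of scope.
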