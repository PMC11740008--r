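# protontwin

Digital-twin adaptive proton SBRT planning with patient-specific setup
margins, in R.

## The problem

Two-fraction prostate SBRT (26 Gy total; optionally a 32 Gy simultaneous
integrated boost to the dominant lesion) leaves no room for a badly aligned
fraction. Proton robust optimization absorbs setup and range uncertainty by
optimizing over scenarios, but clinics feed it a *constant* CTV setup
uncertainty — typically 5 mm in every direction and 3 mm posteriorly — that
is conservative for most patients. `protontwin` implements a plan-of-the-day
alternative built on three components:

1. **A margin model.** Seven translation-invariant geometric features per
   image (femoral bounding-box vertex distances and angles relative to the
   CTV center of mass) feed three per-axis Gaussian-process regressions that
   predict the treatment-day relative CTV position with uncertainty
   `sigma`. Margins are `|mu - planning position|` per axis at offsets
   `{-0.5, 0, +0.5, +1.0} sigma`, clamped to `[1.5, 5.0]` mm.
2. **A candidate plan pool.** One clinical plan (constant margins) plus four
   digital-twin plans per planning image, each robustly checked over the
   standard 21 scenarios (nominal + 6 cardinal shifts x range scales
   `1, 1 +/- 3.5%`). Dose comes from a surrogate engine (target coverage
   plus sigmoidal falloff) that stands in for the proprietary TPS.
3. **Scored selection.** Every candidate is evaluated on the anatomy of the
   day (femur-aligned) through 12 dose-volume metrics — CTV V100 and D98,
   hot spot D0.03cc, dose falloff D2cm, Paddick conformity, bladder-neck
   V100 and mean dose, bladder V14.6/V20.8, rectum V13/V17.6 and the
   trial-specific high-dose rectum volume — and an adapted ProKnow score
   (piecewise-linear points per metric; the CTV V100 function awards
   `2 points / %` between 15 points at 90% and a 35-point cap at 100%).
   The highest-scoring plan is delivered; fraction 2 pools five new plans
   with the five carried from fraction 1.

A fully parameterized synthetic pelvic cohort (analytic structures, known
linear-Gaussian motion model, planning-to-fraction COM shifts spanning
2.1-13.2 mm) makes every stage testable without clinical data.

## Worked example

```r
library(protontwin)

# a synthetic patient and a margin model trained on a 40-patient cohort
cohort <- generate_cohort(cohort_config())        # 30 train / 10 test
tt     <- training_table(cohort, "train", mode = "planning")
model  <- fit_gpr(tt$X, tt$Y, seed = 1)

pat <- materialize_patient(cohort, cohort$test_ids[1])
cfg <- run_config("2STAR")
rec <- run_two_fraction_workflow(pat, model, cfg)
rec
```

```
treatment_record P008 (2STAR): Fx1 -> DT(Fx1)+1.0sigma, Fx2 -> DT(Fx1)-0.5sigma
  cumulative score: DT 101.00 vs clinical 99.18
```

The record stores, per fraction, the pool labels, every candidate's total
score on the anatomy of the day, the selection, and the selected and clinical
metric bundles; `cumulative` holds the course evaluation on the planning
frame. Across the ten demonstration patients:

```r
res <- run_cohort_trial(cohort, model, cfg)
mean(res$summary$dt_bladderneck_v100)        # 17.6
mean(res$summary$clinical_bladderneck_v100)  # 38.1
mean(res$summary$dt_ctv_v100)                # 96.3
mean(res$summary$clinical_ctv_v100)          # 97.4
```

Digital-twin selection cuts the mean bladder-neck V100 from 38.1% to 17.6%
at essentially unchanged CTV coverage — smaller, patient-specific margins
spare the structure most tied to bladder toxicity while the per-fraction
evaluation keeps coverage honest.

Individual pieces are usable on their own:

```r
fn <- default_scoring_functions("2STAR")$ctv_v100
score_metric(98.59, fn)   # 32.18
score_metric(87.59, fn)   # 0 (below the 90% failure threshold)
clamp_margin(0.8)         # 1.5
nrow(enumerate_scenarios(clinical_margin_set()))  # 21
```

## Command line

```sh
Rscript inst/cli/protontwin.R simulate  --n 40 --seed 1 --out sim/
Rscript inst/cli/protontwin.R train     --features sim/features.csv --seed 1 --out model.json
Rscript inst/cli/protontwin.R run-trial --n 40 --seed 1 --trial 2STAR --out trial/
Rscript inst/cli/protontwin.R report    --summary trial/summary.csv --out fig/
```

Structure sets are exchanged as NIfTI volumes plus a JSON manifest (the
manifest's grid is authoritative); feature tables as CSV; models and scoring
configurations as JSON.

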