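# natremia

Predicting the plasma sodium response to crystalloid intravenous fluid
therapy in SIADH (syndrome of inappropriate antidiuretic hormone
secretion), for nephrologists, intensivists and clinical-physiology
researchers who need a quantitative answer to the bed-side question:
*will this saline bolus raise or lower the plasma sodium?*

In SIADH the urine osmolality is elevated and relatively fixed, so a
bolus of normal saline can paradoxically *lower* the plasma sodium: the
solute is excreted in concentrated urine and the electrolyte-free water is
retained. The package implements two closed-form predictors of the sodium
change after a bolus of volume $V_i$ (L):

* the **Voets equation**, from the electrolyte-free water balance of
  infusate input versus urine output:

  $$\Delta [Na^+]_p = [Na^+]_p \frac{V_i}{TBW}\left(1.7\frac{O_i}{O_u} - 1\right)$$

  with $[Na^+]_p$ the pre-infusion plasma sodium (mmol/L), $TBW$ total
  body water (L), $O_i$ infusate tonicity (mmol/L) and $O_u$ urine
  osmolality (mOsmol/L). Sign change at the critical urine osmolality
  $1.7\,O_i$ (523.6 mOsmol/L for 0.9% saline).

* the **Adrogué–Madias equation**, volume-generalized from its classic
  1 L form, a pure redistribution (two-compartment mass balance) that
  ignores urine output:

  $$\Delta [Na^+]_p = \frac{V_i([Na^+]_i - [Na^+]_p)}{TBW + V_i}$$

It also ships the published 15-measurement SIADH validation cohort, the
validation statistics used to compare the models on it (Pearson r, exact
t-based p-values, residual summaries, Fisher-z sample-size calculation), a
seeded synthetic-cohort generator, and a command-line interface.

**Not for unsupervised clinical use.** These are first-order steady-state
approximations, validated only in SIADH and only for potassium-free NaCl
crystalloids; they encode no correction-rate safety limits.

## Worked example

```r
library(natremia)

# measurement 1 of the bundled cohort: 1.5 L normal saline, TBW 34 L,
# plasma sodium 133 mmol/L, urine osmolality 766 mOsmol/L
st <- patient_state(tbw = 34, na_plasma = 133, urine_osm = 766)
ev <- infusion_event(1.5, infusate(0.9))

predict_sodium(st, ev, "voets")
#>  model na_initial delta_na na_final
#>  voets        133     -1.9    131.1
predict_sodium(st, ev, "am")
#>           model na_initial delta_na na_final
#>  adrogue_madias        133     +0.9    133.9
```

The urine (766 mOsmol/L) is more concentrated than the critical 523.6
mOsmol/L for normal saline, so the urine-aware model predicts a sodium
*fall* of 1.9 mmol/L — the measured change was −2 — while the
redistribution model predicts a rise. Across the whole cohort:

```r
validate_cohort(siadh_cohort(), "voets")
#> <validation_report> model voets, n = 15
#>   Pearson r = 0.94, two-sided p = < 0.001 (t test, df 13)
#>   residuals (predicted - measured): MAE 0.33, bias +0.06 mmol/L
validate_cohort(siadh_cohort(), "adrogue_madias")
#> <validation_report> model adrogue_madias, n = 15
#>   Pearson r = 0.50, two-sided p = 0.058 (t test, df 13)
#>   residuals (predicted - measured): MAE 1.06, bias +0.88 mmol/L

sample_size_for_correlation(0.70, alpha = 0.05, power = 0.80)
#> n = 13 (raw 13.43) to detect r = 0.70, two-sided alpha = 0.05, power = 0.8 [nearest]
```

## Command line

```sh
Rscript inst/cli/natremia.R predict --na 133 --tbw 34 --volume 1.5 \
    --percent 0.9 --urine-osm 766 --model both
Rscript inst/cli/natremia.R validate --paper-cohort --model both --json
Rscript inst/cli/natremia.R samplesize --r 0.70
Rscript inst/cli/natremia.R simulate --n 100 --seed 7 --out synthetic.csv
```

(After installation the launcher lives at
`system.file("cli", "natremia.R", package = "natremia")`.)

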