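# txace

A lifetime cost-effectiveness (cost-utility) model of **tranexamic acid
(TXA) versus no-TXA**, in addition to usual care, for adults with **acute
gastrointestinal bleeding (AGIB)**, from a UK health-service perspective.

TXA is cheap (~£30 per patient including administration), but the largest
randomised evidence found no reduction in 28-day all-cause mortality
(risk ratio 1.03, 95% CI 0.92–1.16). `txace` turns that evidence into a
decision analysis: does treating AGIB with TXA represent value for money,
and how certain can we be?

## The model

A two-state (*alive*/*dead*) Markov cohort model, entered at mean age 58.1
and run to age 100:

* **days 1–28** — daily cycles with a trial-period death curve
  (control-arm cumulative risk 0.0916 = 548/5981); the treatment effect is
  the risk ratio applied to the cumulative 28-day risk, shape preserved,
  and acts only in this window;
* **days 29–365** — daily general-population mortality at the attained age,
  SMR-adjusted on the hazard scale (SMR 5.21 in the first year after a
  bleed: `q' = 1 − (1 − q)^SMR`);
* **years 2+** — annual cycles with SMR 1.74.

Survivors carry utility 0.735 with age decrements; costs cover TXA
administration, inpatient stay, procedures, transfusions and a declining
post-discharge monitoring schedule; costs and QALYs are discounted at 3.5%
p.a. Results are reported as incremental cost-effectiveness ratios
(ICER = ΔC/ΔE) and incremental net monetary benefit
(INMB = λ·ΔQALY − ΔC at λ = £20 000/QALY), with probabilistic uncertainty
summarised by a cost-effectiveness acceptability curve (CEAC) and
cost-effectiveness plane quadrant shares over 10 000 Monte Carlo draws.

See `vignette("txa-cost-effectiveness")` for the full methods account.

## Worked example

```r
library(txace)

params <- default_parameters()   # full base-case parameterisation
res <- run_model(params)         # deterministic lifetime model, both arms
print(res)
#> Cost-effectiveness result (TXA vs no-TXA)
#>                    no-TXA          TXA
#>   cost (GBP)    18 883.97    18 823.71
#>   LYs              12.818       12.779
#>   QALYs             9.150        9.122
#>   incremental: cost -60.26, LY -0.0387, QALY -0.0276
#>   ICER: 1 556.31/LY, 2 180.41/QALY (SW quadrant)
#>   INMB at 20 000.00 GBP/QALY: -492.49
```

TXA is slightly **cheaper and slightly less effective** (south-west
quadrant): forgoing it buys back 0.028 QALYs per patient at £2180 per QALY —
far below the £20 000 threshold — so the negative INMB says TXA is *not*
cost-effective.

```r
psa <- run_psa(params, n_draws = 500, seed = 1)   # 10 000 in the full analysis
print(psa)
#> PSA with 500 draws (seed 1)
#>   mean incrementals: cost -43.02, LY -0.0377, QALY -0.0270
#>   P(TXA cost-effective): 35.8% at 20000, 35.0% at 30000
#>   quadrants: NE 17%, SE 16%, NW 31%, SW 36%
```

The decision is genuinely uncertain (~36% probability TXA is
cost-effective at £20 000/QALY), because the mortality CI does not exclude
a benefit. Scenario analyses (`run_dsa()`) show the conclusion flips only
if TXA actually reduces mortality (RR 0.92 gives a TXA-favouring ICER of
~£1250/QALY), and `meta_analysis_params()` shows the pre-trial
meta-analytic evidence (risk 71/850, RR 0.60) would have called TXA almost
certainly cost-effective — a caution about acting on bias-prone pooled
estimates.

A thin command-line front end wraps the same functions:

```sh
Rscript scripts/txace.R base-case
Rscript scripts/txace.R psa --n-draws 10000 --seed 1 --out-dir out
Rscript scripts/txace.R simulate-trial --n-per-arm 6000 --seed 7 --out-dir out
```

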