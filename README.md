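# gpmoist

Measurement and closed-loop control of germination-paper water content, as
a desk-scale simulation package.

Germination paper (GP) is the absorbent substrate of root-phenotyping and
germination studies: plants grow on vertically mounted sheets whose lower
edge draws nutrient solution from a small tank. For water-deficit studies
the *gravimetric water content* `W` (g water per g dry paper, saturating
around 1.8–2.0 g/g) must be measured and regulated, but the electrical
measurement of wet paper is extremely noisy and irrigation is only
available in discrete 5–30 mL fills every 2 h. `gpmoist` implements the
full sensing-and-control chain for this problem:

* **Sensor** — capacitor-discharge resistance measurement,
  `Q(t) = Q0 exp(-t/RC)`, logarithmic calibration curves
  `W = a ln Q + b` per contact position, and a banded heteroscedastic
  error model whose whole-range mean absolute deviation calibrates to the
  raw channel's 0.44 g/g.
* **Evaporation model** — Penman-derived affine humidity dependence lumped
  into the fitted sheet law
  `E(H, W) = s_r[(c1 H + c2) ln(m W) − c3 H + c4]` (g/h).
* **Estimator** — a per-sheet scalar Kalman filter: predict through the
  water balance `m W' = m W + I − E·T0`, correct with in-range raw
  readings (`K = P/(P+r)`, band-based `r`), censored "rail" updates from
  saturated out-of-range readings.
* **Controllers** — a discrete PI,
  `u_k = u_{k−1} + g (e_k − 0.6 e_{k−1})`, and a horizon-3 MPC that
  exhaustively searches the quantized action set {0, 5, …, 30} mL with
  evaporation feed-forward; individual and group modes (one command from
  the mean of two measured sheets, applied to all five of a group).
* **Experiment runner** — the two-level deficit protocol (reference
  0.89 g/g for 5 days, then 0.56 g/g for 4 days), twice-daily gravimetric
  sampling, and control-quality metrics (max |e|, integral of squared
  error, median/mean/sd), all evaluated against the true state.
* **Synthetic generators** — sheet cohorts with saturation and
  evaporation heterogeneity, bounded-random-walk ambient humidity,
  calibration data. No external data are needed anywhere.

## Worked example

Simulate one sheet under MPC for the full nine-day protocol and summarize:

```r
library(gpmoist)

log <- run_experiment(
  cohort = make_cohort(1, seed = 42, sdlog = 0),   # one nominal sheet
  mode   = control_mode("individual", "sheet1"),
  cfg    = controller_config("MPC"),
  seed   = 42, q = 0.02^2
)
summarize_experiment(log)
#> <metrics_report> per sheet (deviations at gravimetric instants, g/g):
#>  sheet_id  n max_abs_e A_quad median_e mean_e   sd_e
#>    sheet1 18    0.0833  0.538   0.0345 0.0185 0.0485
filter_accuracy(log)
#> [1] 0.08327216
```

The sheet tracks both reference levels to within 0.083 g/g at every
twice-daily weighing (`max_abs_e`), with an integral of squared error of
0.54 (g/g)² h over the run; the Kalman estimate stays within 0.083 g/g of
the truth wherever the truth lies in the sensor's effective range, against
a raw channel whose in-range readings err by up to 0.18 g/g here (and by
0.44 g/g on average over the full range). Group control of a heterogeneous
five-sheet cohort (`make_cohort(5, …)`, `control_mode("group", …)`) shows
the open-loop sheets drifting to large persistent offsets — see the
methods vignette (`vignettes/gpmoist-methods.Rmd`) for why a single shared
command cannot compensate sheet-to-sheet evaporation spread.

A command-line front end wraps the same functions:

```sh
inst/cli/gpmoist simulate  --config run.yaml --out results/
inst/cli/gpmoist calibrate --points points.csv --position 1
inst/cli/gpmoist report    --log results/log.csv
```

Configs are YAML (`default_run_config()`, `write_run_config()`); logs and
metrics are plain CSV.

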