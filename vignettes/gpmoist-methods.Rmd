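---
title: "Models and methods behind gpmoist"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gpmoist}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpmoist)
```

`gpmoist` is a desk-scale simulator and control toolkit for the gravimetric
water content of germination paper (GP), the absorbent substrate used in
root-phenotyping and germination studies. A sheet (about 45 g dry mass)
hangs between Perspex plates with its lower edge in a small nutrient tank
that can be filled at discrete times with 5–30 mL; water leaves the sheet
by evaporation. The package reproduces the whole measurement-and-control
chain in software: the capacitor-discharge moisture sensor, its calibration
curves and error structure, a water-balance model with a humidity-dependent
evaporation term, a scalar Kalman filter, and quantized irrigation control
(discrete PI and a model predictive controller), in individual and group
modes. This vignette explains each model, the tunable parameters and their
defaults, and the design decisions taken where the physical system
under-determines the software.

## 1. The measurement channel

Wet paper conducts; dry paper does not. The sensor charges a bank of four
series capacitors (6300 µF each, effective $C = 1575$ µF; the default
initial charge corresponds to a 24 V supply) and discharges it through the
sheet for $t = 180$ s. The remaining charge follows the RC law

$$Q(t) = Q_0\, e^{-t/(RC)}, \qquad R = \frac{t}{C \ln (Q_0/Q)},$$

so the sheet's resistance — and through it the water content — is read off
the remaining charge. `remaining_charge()` and `resistance_from_charge()`
are exact inverses; a reading of $Q = Q_0$ (no measurable discharge) returns
an explicit infinite-resistance sentinel rather than an error.

Water content is obtained from a **characteristic curve**
$W = a \ln Q + b$, fitted per contact position by `fit_calibration()`
(ordinary least squares of $W$ on $\ln Q$). Two contact positions with
different electrode spacing cover different water-content windows:

* position 1 (wet range): effective range 0.80–1.64 g/g,
* position 2 (dry range): effective range 0.45–0.66 g/g.

The package's default curves are synthetic: log-linear curves anchored so
that each effective range maps onto a plausible fraction of the initial
charge (position 1: 95 % down to 35 % of $Q_0$; position 2: 90 % to 50 %).
Real deployments would replace them via `fit_calibration()` /
`cli_calibrate()`.

### Error structure and the 0.44 g/g calibration

Accuracy is banded in $W$ (`default_accuracy_bands()`): inside the
effective ranges the maximal deviation of an automated reading from the
gravimetric truth is 0.16–0.31 g/g, in adjacent closed bands up to
0.69 g/g, and in the remaining *exceedance* bands only a lower bound
(> 0.67 g/g) is known. Band edges tile the whole axis; the reported
breakpoints leave small gaps (1.64/1.67, 1.01/1.02, …) which we close at
their midpoints.

`simulate_raw_measurement()` draws:

* **closed bands** — truth plus zero-mean Gaussian noise with
  $\sigma = \text{accuracy}/2$, truncated at $\pm$accuracy, so a stated
  maximal deviation is never exceeded (inverse-CDF sampling, no rejection
  loop);
* **exceedance bands** — these lie outside the effective range, where the
  channel is *saturated* rather than merely noisy: on the dry side almost
  no charge drains and the curve pins at its low rail, on the wet side the
  bank empties and the curve pins high. Readings are drawn half-normally
  beyond the rail (`effective range limit ∓ 0.05 g/g`) on the side the
  sheet is actually on, with spread `EXCEEDANCE_SD = 1.75` g/g.

The constant 1.75 is a documented calibration: with truth uniform on
0.45–1.8 g/g and both positions weighted equally, the closed bands
contribute $0.3614 \sum_i w_i\,\text{acc}_i = 0.174$ to the mean absolute
deviation sum (0.3614 is the mean-absolute factor of a $2\sigma$-truncated
Gaussian), and the half-normal rail spread is chosen so that the total
mean absolute deviation is ≈ 0.44 g/g — the unfiltered accuracy of the raw
channel. A Monte-Carlo check in the test suite verifies 0.43–0.44.

Two consequences of the rail model matter downstream. First, a saturated
reading can never masquerade as a valid in-range measurement (a
truth-centred Gaussian with the same calibrated spread would land inside
the acceptance window about a quarter of the time and corrupt the filter).
Second, a rejected reading still tells the system *which side* of the
effective range the sheet is on; both the fallback position rule and the
censored filter update below exploit this.

### Position switching

The physical system does not dictate how the two contact positions are
scheduled. The package uses: position 1 when the current estimate is at or
above 0.73 g/g (the midpoint between the two effective ranges), else
position 2; and after an out-of-range reading the next measurement uses
`fallback_position()` — the position whose effective range is nearest the
rejected reading. Without the fallback, a sheet that crosses the dead zone
(0.66–0.80 g/g) while the estimate lags can be measured blind indefinitely.

## 2. Evaporation

Potential evaporation follows a Penman-type form; with constant radiation,
wind and temperature terms it lumps (`lump_penman()`) to the affine law
$E_{pot} = C_1 + C_2 (1 - H/100)$, decreasing in relative humidity $H$.
The sheet's evaporation model (`gp_evaporation()`) is the fitted
logarithmic law

$$E(H, W) = s_r \left[ (c_1 H + c_2) \ln (m\,W) - c_3 H + c_4 \right],
\quad \text{in g/h},$$

with $m$ the dry mass in gram, coefficients
$c_1 = -0.038292758$, $c_2 = 2.901962527$, $c_3 = -0.096373808$,
$c_4 = 7.18246835$, and output clamped at zero. The model is increasing in
$W$ throughout the 21–33 % operating humidity range (that requires
$c_1 H + c_2 > 0$, enforced at construction) and decreasing in $H$ once
$m W \gtrsim 12.4$ g.

`rate_scale` ($s_r$, default **0.5**) is a deliberate calibration: taken at
face value in g/h the model loses more water per 2 h interval at the wet
operating point (≈ 33 g) than the largest admissible fill (30 mL) could
replace, and no quantized irrigation policy could hold a reference — the
time base of the fitted rates is not recoverable from the reported
constants. The default halves the rate so that the per-interval loss
(≈ 17 g at $W = 0.89$, $H = 27$ %) sits inside the controllable 5–30 mL
band, while preserving the humidity and water-content dependence exactly.
Plant transpiration (< 1 g/h at the relevant growth stages) is neglected;
an additive `uptake_g_per_h` term (default 0, capped at 1) is available for
sensitivity studies. `fit_evap_params()` refits all four coefficients by
least squares on the basis $\{H \ln mW, \ln mW, H, 1\}$ and requires at
least two humidity levels (otherwise $c_1, c_3$ are unidentifiable).

## 3. The plant simulator

`step_water_balance()` advances one sheet by one interval $T_0$:

$$m\,W_{k} = m\,W_{k-1} + I_{k-1} - \mu\, E(H, W_{k-1})\, T_0
  \; (+\,\text{noise}),$$

clamped to $[0, W_{max}]$. Absorption is resolved within one interval:
below 0.67 g/g the sheet takes the full offered volume (the tank empties in
under 2 h there); above, it is capacity-limited by the head-space
$(W_{max} - W)\,m$. Each step optionally adds zero-mean Gaussian process
noise (default sd 0.02 g/g per step) representing drafts, temperature
swings and within-sheet redistribution.

`make_cohort()` generates sheet-to-sheet heterogeneity: saturation
$W_{max} \sim U(1.78, 2.00)$ g/g and a per-sheet evaporation multiplier
$\mu \sim \text{lognormal}(0, \sigma_{\log} = 0.1)$. The multiplier is what
makes identically irrigated sheets drift apart, an effect the real
substrate shows strongly. Note its leverage: at equilibrium
$\mu E(W) T_0 = I$, and because $E$ depends on $W$ only logarithmically,
$\partial W / \partial \ln \mu \approx -W\,[\ln(mW) + (c_4 - c_3 H)/(c_1 H
+ c_2)] \approx -8$ g/g near the 0.89 g/g operating point — a 10 %
evaporation difference moves a sheet's open-loop equilibrium by almost
0.8 g/g. Section 7 discusses what this implies for group control.

Ambient humidity is a reflected Gaussian random walk on the control grid,
bounded to the observed 21–33 % range (`humidity_trajectory()`; sd 1
percentage point per 2 h, zero volatility gives a constant 27 %). The
simulator does **not** model within-sheet spatial gradients (each sheet is
one well-mixed compartment), plant growth, nutrient dynamics, or tank
levels.

## 4. State estimation

Each measured sheet carries a scalar Kalman filter (`kalman_state()`):

* **predict** (`kf_predict()`): propagate through the balance model with
  the *nominal* ($\mu = 1$) evaporation term evaluated at the current
  estimate, unit state-transition Jacobian ($\partial E/\partial W$ is
  second-order at these magnitudes), $P \mathrel{+}= q$;
* **update** (`kf_update()`): standard scalar gain $K = P/(P + r)$ with
  $r = (\text{band accuracy}/2)^2$ taken from the band containing the raw
  value. Out-of-range readings are skipped — the step stays predict-only,
  which is also how unmeasured sampling slots are handled. The first
  in-range reading initializes the filter ($\hat W_0$ = reading, $P_0$ = its
  band variance).
* **rail update** (`kf_rail_update()`, used by the closed loop): a reading
  beyond a range limit is treated as censored at that limit; if the
  estimate sits on the wrong side, a scalar update toward the boundary is
  applied with the boundary band's variance. This one-sided (Tobit-style)
  correction is what lets an estimate stranded across the dead zone
  re-converge; a filter that discards out-of-range readings entirely can
  run open-loop for days.

Two process-noise defaults are deliberate. The bare-filter default
$q = (0.02)^2$ (g/g)² per step matches the plant's own process noise and is
right for a nominal sheet — it is what the measurement-accuracy figures are
quoted at. The closed-loop default in `run_experiment()` is
$q = 0.02^2 + 0.037^2$: under the default 10 % evaporation heterogeneity
the filter's nominal model is wrong by about
$0.1 \times 17\,\text{g} / 45\,\text{g} \approx 0.037$ g/g per step, and a
filter that pretends otherwise weighs its (biased) model too heavily — the
steady tracking bias of a scalar filter under per-step model error $d$ is
$d\,(1-K)/K$, which the larger $q$ cuts from ≈ 3.5 d to ≈ 1.4 d. This is a
noise *specification*, not a tuning knob: it restates the generator's own
disturbance budget.

## 5. Control

The controlled plant is modelled as a discrete integrator with zero-order
hold: one interval of irrigation $I$ (mL ≡ g) raises $W$ by $I/T_1$ with
$T_1 = m = 45$ g, so the integrator gain converts mass to g/g — the only
dimensionally consistent reading of the transfer-function constant.
`plant_model_step()` optionally subtracts the modelled evaporation as a
known disturbance (feed-forward).

**Discrete PI** (`pi_step()`): $u_k = u_{k-1} + g\,(e_k - 0.6\,e_{k-1})$
— a unit-gain PI transfer function with zero 0.6 — scaled by a volume gain
$g = 45$ mL per g/g (the natural choice $g = m$, making a 1 g/g error ask
for the mass that would correct it in one step). The raw output is clamped
to the actuator range (anti-windup) and then projected onto the quantized
action set $\{0, 5, \ldots, 30\}$ mL, nearest value, ties toward the
smaller volume. The *raw* value is fed back as $u_{k-1}$, so quantization
is an output stage and does not accumulate in the integrator.

**MPC** (`mpc_step()`): exhaustive enumeration of all action sequences over
a horizon of 3 steps (bounded at 4; $7^3 = 343$ sequences), each simulated
through the integrator model with evaporation feed-forward (flag
`use_feedforward`, default on), cost $\sum (\text{ref} - \hat W)^2$ with no
input penalty, ties toward smaller volumes. Enumeration is exact by
construction — the test suite checks it against an independently coded
brute-force oracle — and trivially cheap at this action-set size. The
controller sees the future reference over its horizon, so it begins
descending toward a lower set-point one interval early; the PI, which sees
only the current error, cannot.

**Group control** (`group_step()`): one command from the mean of the
measured sheets' filtered estimates (two per group), applied identically to
all five sheets of the group; unmeasured sheets are thereby open-loop. If
no valid estimate is available in a step the previous command is held.

**Start-up**: until a filter produces its first estimate, the loop
irrigates open-loop with the feed-forward fill that balances modelled
evaporation at the reference, and the PI integrator is parked at that value
(bumpless transfer). Starting from a zero command instead loses the sheet
whenever the first reading happens to reject: one unirrigated 2 h interval
costs ≈ 0.35 g/g.

## 6. Protocol and metrics

The default protocol (`gp_protocol()`) holds the reference at 0.89 g/g for
five days, then 0.56 g/g for four days, with $T_0 = 2$ h. Sheets are
"weighed" (true state sampled) twice daily; the weighings are offset 6 h
from midnight so that none coincides with the instant the reference steps —
the metrics then measure regulation quality, not the unavoidable
within-interval transient of a step change (the sheet needs about one
interval to shed the 0.33 g/g difference, well inside the 12 h between
weighings).

`summarize_experiment()` evaluates the control deviation
$e = w - W_{grav}$ **against the true (gravimetric) state**, never the
estimate, and reports per sheet the maximal $|e|$, the integral of squared
error (trapezoidal, in (g/g)² h — reported ISE magnitudes for such runs carry no stated unit,
so absolute ISE magnitudes are reported but not interpreted further),
median, mean and standard deviation. For group runs a pooled summary uses
seven weighings per sheet from the first reference phase after a 1.5-day
settling period ($t$ = 30–102 h); both median and mean are reported since
the two conventions circulate.

## 7. What the simulation shows — and what it cannot

With the defaults above, typical results over seeded replicates are:
filtered measurement accuracy ≈ 0.11–0.15 g/g maximal in-range error for a
nominal sheet (against ≈ 0.44 g/g raw); individual closed-loop control
≈ 0.2–0.3 g/g maximal deviation at the weighings for PI, slightly better
for MPC, limited by the 5 mL actuator quantum (0.11 g/g per fill), the
banded measurement noise, and the per-sheet model bias.

Group control is different in kind: the three unmeasured sheets of a group
receive a command computed for the measured pair, and the multiplier
sensitivity derived in Section 3 places their equilibria ~8 g/g per unit
log-multiplier away from the reference. Under the default 10 % spread that
is 0.5–1.0 g/g of persistent deviation for the worst sheet of a group —
two orders above the actuator quantum — and no controller acting through a
single shared command can remove it. Physical test rigs that achieve tight
group control therefore imply substrate batches far more uniform (≈ 1 %
effective evaporation spread) than the sheet-to-sheet variability this
generator deliberately emulates; the simulation makes the tension between
those two observations quantitative rather than resolving it. Passing
closed-loop tests here says the control chain is implemented coherently; it
does not certify performance on real substrate, whose error structure,
spatial gradients and drift the generator only caricatures.

## 8. Numerical choices and problem sizes

Tolerances: curve and coefficient fits recover noiseless synthetic data to
1e-6 or better; the filter matches a batch weighted-least-squares oracle to
1e-8; the discharge/resistance pair round-trips to 1e-9 relative. Ties in
quantization and MPC enumeration resolve toward smaller volumes
(deterministically, via lexicographic enumeration order). Degenerate
inputs: zero-water sheets evaporate nothing; saturated sheets refuse
inflow; calibration with fewer than 3 points, equal charges, or a single
humidity level errors out early. All stochastic entry points take explicit
seeds; a run is bitwise-reproducible from its seed.

The shipped test suite and the acceptance script size their simulations to
run in minutes on one core: 9-day trajectories (108 control intervals),
cohorts of 1–5 sheets, 20–100 seeded replicates per figure, 30–50
replicates for Monte-Carlo property checks — enough for the medians and
percentiles reported to be stable to well under the tolerances they are
compared at.
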