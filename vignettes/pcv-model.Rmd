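---
title: "A pneumatic model of pressure-controlled ventilation of a lung simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A pneumatic model of pressure-controlled ventilation of a lung simulator}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcvsim)
```

## The model

`pcvsim` treats a pressure-controlled ventilation (PCV) circuit as a pure
pneumatic system with three elements:

1. **An ideal pressure source.** The ventilator output is the canonical PCV
   trapezoid: a linear rise from EPAP to IPAP over the rise time $T_r$, a
   plateau at IPAP until the inspiratory time $T_i$, a linear fall back to
   EPAP over the same $T_r$, and EPAP for the remainder of the cycle
   (period $60/\mathrm{BPM}$ s). Real ventilators produce rounded, slightly
   asymmetric waveforms; the ideal trapezoid is the reference input here and
   the noisy fixture generator (below) stands in for measured recordings.

2. **A single equivalent throttle.** All flow restriction — tube, airway, or
   the narrow inlet of a mechanical test lung — is lumped into one orifice of
   diameter $d$ and effective area $A_e = \pi d^2/4$. Flow through it is
   compressible converging-nozzle flow. At PCV working pressures (a few tens
   of cmH2O, i.e. a few kPa above atmospheric) the downstream/upstream
   pressure ratio $\phi = p_d/p_u$ stays far above the critical ratio
   $b = (2/(\kappa+1))^{\kappa/(\kappa-1)} \approx 0.528$, so the flow is
   always subsonic and the nozzle law is well approximated by
   $$ q = 0.0048\, n_i A_e p_u \sqrt{\phi(1-\phi)} \quad
      [\mathrm{kg\,s^{-1}};\ A_e\ \mathrm{m^2},\ p\ \mathrm{Pa\ absolute}], $$
   with $n_i = +1$ into the lung and $-1$ out of it. The coefficient is an
   adopted constant of the model; over $\phi \in [0.528, 0.995]$ at room
   temperature it agrees with the exact isentropic law
   (`mass_flow_exact()`) to better than 3% (the suite measures about 1.6%).
   Standard-state volume flow uses the coefficient $0.004 = 0.0048/\rho_{std}$
   with $\rho_{std} = 1.2\ \mathrm{kg\,m^{-3}}$, so $q = \rho_{std} Q$ holds
   exactly.

3. **An isothermal variable-volume container.** The lung is a gas volume $V$
   at absolute pressure $p$ with constant compliance $C = dV/dp$.
   Differentiating $pV = mRT$ under the isothermal assumption and eliminating
   $dV$ with $dV = C\,dp$ gives
   $$ \frac{dp}{dt} = \frac{R T q V}{V^2 + C m R T}
      \;=\; \frac{R T q}{V + C p} \quad (m = pV/RT). $$
   The pneumatic capacity $Cp$ (about 10 L at the defaults) dominates the
   resident volume $V$, which is why the unknown initial volume $V_0$ barely
   matters (see below).

Alongside the dynamics, the throttle's **respiratory resistance** is
bookkept with the Darcy friction model
$$ R_r = \frac{8 \lambda l\, |q|}{\pi^2 d^5}, $$
where the friction coefficient $\lambda$ follows a three-branch
Moody-diagram law in the Reynolds number $Re = 4|q|/(\pi d \mu)$: laminar
$64/Re$ below 2000, a linear transition from 0.032 to 0.045 between 2000 and
3000, and $0.045 - 0.015\,(Re-3000)/10^4$ above. The law is continuous at
both joints, and in the laminar range the Darcy expression collapses
algebraically to the Poiseuille closed form $128\mu l/(\pi d^4)$, which
`resistance()` uses directly so that $R_r$ stays finite and constant as the
flow vanishes — matching the observation that measured respiratory
resistance levels off near zero flow.

### Two notions of "pressure loss"

The model contains two distinct quantities that both deserve the name:

* the **actual throttle drop** $|p_{vent} - p_{lung}|$ implied by the orifice
  flow law — this is what the `p_loss` column of a simulated trace reports;
* the **Darcy estimate** $R_r |Q|$ (`pressure_loss()`), the product of the
  friction-model resistance and the flow.

They are different models of the same restriction and do not coincide at
high flow (the Darcy product is several times smaller at the flow peaks).
Conflating them would make the resistance trace inconsistent with the
published fluctuation ranges, so the package keeps both, explicitly named.

## Integration

The closed loop reduces to a scalar ODE in the lung pressure, with volume
slaved to pressure through $dV = C\,dp$. `simulate_pcv()` integrates it with
a hand-rolled fixed-step classical Runge–Kutta (RK4) scheme, drive pressure
evaluated on a half-step grid. A fixed step keeps traces bit-stable and
reproducible across platforms; the test suite cross-checks the integrator
against `deSolve::ode(method = "rk4")` on the same right-hand side (they
agree to ~1e-10 Pa) and verifies grid convergence (halving `dt` moves every
summary statistic by well under 0.2%).

Numerical choices worth noting:

* **Step size.** Default `dt = 1e-4` s, with a hard validity bound
  `dt <= Tr/20` so the pressure ramps are always resolved.
* **Finite-time equilibrium.** The orifice law is a square root in the
  pressure difference, so the lung reaches the drive pressure in finite time
  rather than asymptotically. At the default step the residual chatter
  around equilibrium is ~1e-8 Pa and harmless; the single-step primitive
  `lung_step()` additionally clamps at the drive pressure so a coarse step
  cannot overshoot.
* **Transients.** Runs start from $p_{lung} =$ EPAP, simulate 4 cycles and
  discard the first; convergence to a periodic steady state is checked by
  comparing the peak pressure of the last two cycles (0.1% criterion) and
  failure flags the trace and warns.
* **Resistance at near-zero flow.** Summary extrema of $R_r$ exclude samples
  with $|Q| < 1$ mL/s, where the value is pinned at the laminar floor.

## Parameters, units, defaults

| Parameter | Unit | Default | Meaning |
|---|---|---|---|
| IPAP / EPAP | cmH2O gauge | 22 / 4 | waveform plateaus |
| BPM | min⁻¹ | 20 | cycle period 60/BPM |
| $T_i$ / $T_r$ | s | 1 / 0.2 | inspiratory time, rise time |
| $C$ | mL/cmH2O | 10 | respiratory compliance |
| $d$ | mm | 3.2 | equivalent orifice diameter |
| $l$ | mm | 10 | throttle length (resistance bookkeeping only) |
| $V_0$ | L | 1 | resident gas volume at run start |
| `dt` | s | 1e-4 | RK4 step |

The ventilator defaults are the baseline operating point of the bench system
the model describes. Gas constants are air at room temperature
($\kappa = 1.4$, $R = 287$ J kg⁻¹ K⁻¹, $T = 293.15$ K,
$\mu = 1.82\times10^{-5}$ Pa s, $\rho_{std} = 1.2$ kg m⁻³,
$p_{atm} = 101325$ Pa). Two parameters are genuine modelling choices rather
than measured quantities:

* **Throttle length $l$.** Not a measurable anatomical length; it scales the
  Darcy resistance only. The default 10 mm is calibrated once so that the
  laminar floor at $d = 3.2$ mm equals 0.72 cmH2O/(L/s), the observed
  low-flow resistance plateau. It is exposed as an ordinary config key.
* **Initial volume $V_0$.** The dynamics depend on $V + Cp$ and $Cp \approx
  10$ L dominates, so the default 1 L is uncritical: the test suite's grid
  and sensitivity checks pass unchanged for any reasonable value.

## Compliance estimation

`estimate_compliance()` recovers $C$ from a trace's inspiratory windows. The
intuitive desk calculation
$$ C \approx \frac{\int_{insp} Q\,dt}{\Delta p_{lung}} $$
(method `"volume_ratio"`) systematically **overestimates** the true
compliance, by a factor $\approx (1 + V/(C\bar p))\cdot \bar p/(\rho_{std}RT)$
— about 11% at the defaults — because part of the delivered gas is compressed
into the resident volume instead of expanding the container, and because the
flow channel reports standard-state volume. The default `"mass_balance"`
method inverts the isothermal mass balance
$$ \rho_{std} R T \int Q\,dt = (C\bar p + \bar V)\,\Delta p $$
and recovers the configured compliance to a few tenths of a percent on
noiseless traces and within a few percent under realistic sensor noise.
Both methods are kept because the naive ratio is what a clinician computes
at the bedside from tidal volume and pressure swing.

```{r compliance, eval = FALSE}
tr <- simulate_pcv(simulation_config())
estimate_compliance(tr)                          # ~9.96 mL/cmH2O
estimate_compliance(tr, method = "volume_ratio") # ~11.2 mL/cmH2O (biased)
```

## Parameter sweeps and thresholds

`sweep_parameter()` re-simulates with one parameter varied at a time
(IPAP, EPAP, BPM, $T_i$, $T_r$, $C$, $d$) and `threshold_find()` scans a
sorted value set for the boundary at which the peak lung pressure still
reaches IPAP (within 2% by default; equality at the boundary counts as
reaching). For compliance the threshold is the largest reaching value, for
diameter the smallest; the finder infers the direction from the scanned
peak-pressure trend. Under the default settings the scans reproduce the
expected behaviour: peak pressure rises with IPAP, minimum pressure rises
with EPAP, BPM and $T_i$ leave the peak essentially unchanged (< 2%), the
compliance threshold in $\{5, 10, 15\}$ mL/cmH2O is 10, and the diameter
threshold in $\{2.4, 3.2, 4.0\}$ mm is 3.2.

## Synthetic recordings

`generate_recording()` overlays seeded Gaussian noise (defaults: 0.2 cmH2O
on the pressure channels, 0.02 L/s on flow — the order of magnitude of raw
bench-sensor scatter) on a clean simulated trace. It emulates the *amplitude*
of measurement noise but not its structure: real recordings carry
high-frequency periodic components, sensor drift, leakage, and a
pressure-dependent (nonlinear) compliance, none of which are modelled. Tests
that pass on these fixtures therefore demonstrate estimator robustness to
uncorrelated noise, not validity on hardware data. `smooth_series()` offers
a centred moving average (edge-replicated, odd window) as a simple
denoising step.

## Known limitations

* Constant compliance: real test lungs stiffen with pressure, which is the
  main source of discrepancy between this model and bench measurements.
* Single compartment, single throttle: no airway network, no separate
  exhalation-valve path (expiration is reverse flow through the same
  orifice), no tube resistance (negligible next to a 3.2 mm inlet), no
  inertance.
* Isothermal ideal gas, no leakage, no humidity.
* The quantitative resistance extrema depend on the drive waveform; the
  ideal trapezoid reproduces published fluctuation ranges to within ~10%,
  inside the tolerance appropriate for an unpublished fitted waveform.

## Problem sizes used in the tests

Physics-facing tests run the full default configuration (4 cycles of 3 s at
`dt = 1e-4`, i.e. 120 000 steps, ~0.6 s of CPU); structural and I/O tests use
2 cycles at `dt = 1e-3`. Sweep-direction and recovery properties use
`dt = 2e-4`, where grid convergence shows all summaries are already within
0.1% of the fine-grid values.
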