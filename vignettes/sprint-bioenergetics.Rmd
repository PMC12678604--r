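---
title: "Modelling sprint bioenergetics with sprintergetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling sprint bioenergetics with sprintergetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sprintergetics)
```

Sprint races are too short for the steady states that direct metabolic
measurement needs, so the energetics of a 100--400 m race must be
inferred indirectly. This package implements a complete chain of such
inferences: from split tables to velocity profiles, from kinematics to
instantaneous metabolic power via the equivalent-slope cost of
accelerated running, from a power series to its aerobic,
anaerobic-lactic and anaerobic-alactic components, from per-race
anaerobic energies to maximal anaerobic capacities, and — inverting
the whole chain — from a capacity pair to simulated race times.

This vignette documents the model, its assumptions, the tunable
parameters, the numerical choices, and what the synthetic-data tests
do and do not establish.

## Kinematic model

During the acceleration phase, velocity is assumed to rise
exponentially to a peak velocity $v_f$ (m s$^{-1}$) with time constant
$\tau$ (s):

$$v(t) = v_f\,(1 - e^{-t/\tau}), \qquad
  a(t) = \frac{v_f}{\tau}\,e^{-t/\tau},$$

with $t$ the time since movement onset (the reaction time is
subtracted from all gun times; when a measured reaction time is
unavailable, 0.15 s — a typical elite value — is assumed).
`fit_acceleration()` estimates $(\tau, v_f)$ from interval-average
velocities placed at interval time-midpoints, by damped
(Levenberg–Marquardt) least squares through `minpack.lm`. Two
estimator properties matter in practice:

* Chord averages are not midpoint values. Over a wide early interval
  (say the first 10 m, ≈1.7 s) the average velocity of the convex
  rise differs from the midpoint velocity by several tenths of a
  m s$^{-1}$, so even noiseless *path-timed* splits are recovered only
  to within a few percent in $\tau$. The synthetic generator therefore
  offers a `midpoint_consistent` timing mode in which the data match
  the estimator's model exactly and recovery is exact to solver
  precision; that mode is what the noiseless-recovery test uses.
* Deceleration-phase intervals bias $v_f$ downward when included in
  the fit. `adjust_peak_velocity()` replaces $v_f$ with the highest
  measured instantaneous velocity (if available) or the highest
  interval-average velocity, and never lowers it — only the downward
  bias is being corrected. For 200/400 m races, `fit_range_m` can
  restrict the fit to the first 200 m, where the rise model holds.

After the peak — located at the time-midpoint of the fastest interval
— runners are assumed to decelerate linearly to a final velocity
derived from the last interval's average velocity by linear
interpolation. The resulting profile is evaluated on a uniform grid
(`dt = 0.01` s by default) and integrated by the trapezoidal rule
throughout. At that step size the integral of a pure-acceleration
profile matches its closed form
$v_f\,[T - \tau(1 - e^{-T/\tau})]$ to well below 0.01%.

Note that a parameter set need not be able to cover its nominal race
distance: the women's 100 m reference parameters integrate to less
than 100 m over the net race time, exactly as the corresponding
modelled race does. `sprint_velocity_profile()` treats a distance
target beyond the pure-acceleration bound as an error rather than
silently accelerating past $v_f$.

## From kinematics to metabolic power

Accelerating on flat ground is energetically equivalent to running at
constant speed up a slope equal to the *equivalent slope* $ES = a/g$,
with an effective body weight inflated by the *equivalent mass*
$EM = \sqrt{ES^2 + 1}$. The default cost variant evaluates the
gradient energy-cost polynomial of running

$$C(ES) = 155.4\,ES^5 - 30.4\,ES^4 - 43.3\,ES^3 + 46.3\,ES^2 +
  19.5\,ES + 3.6 \quad (\mathrm{J\,kg^{-1}\,m^{-1}})$$

at the equivalent slope and multiplies by $EM$. The polynomial is
calibrated on moderate gradients only, so beyond $|ES| > 0.45$
(configurable as `es_linear_limit`) it is continued linearly with
matched value and slope; early-sprint accelerations reach $ES \approx
1$, well into the extrapolated region, which is why peak-power values
should be read with a few percent of model uncertainty. The
alternative `minetti_pavei` variant is a closed form fitted directly
on sprint accelerations up to about 8 m s$^{-2}$:
$C_{AR} = 0.102\,\sqrt{a^2 + 96.2}\,(4.03\,a + 3.6\,e^{-0.408\,a})$.
Both variants reduce to ≈3.6 J kg$^{-1}$ m$^{-1}$ at $a = 0$.

Air resistance adds $0.01\,v^2$ J kg$^{-1}$ m$^{-1}$ (the
speed-squared drag form). After the peak, the cost is fixed at the
flat-running value 3.8 J kg$^{-1}$ m$^{-1}$: decelerating sprinters
are slowing because they cannot sustain power, with posture and
centre-of-mass mechanics essentially those of level running.
Instantaneous metabolic power is cost × velocity; basal metabolism is
*not* added (all powers are above rest). The cost switch at the peak
produces a genuine discontinuity in the power series; it is recorded
in the series metadata (`discontinuity_at`), never smoothed.

## The three-pathway power model

Total modelled power is the sum of three independent pathways:

$$P_{tot}(t) = P_{al}(t) + P_{la}(t) + P_{aer}(t)$$

* **Aerobic**: $P_{aer}(t) = (MAP - BMR)(1 - e^{-t/k_{aer}})$ with
  maximal aerobic power $MAP$ = 24.5 (men) / 21.0 (women)
  W kg$^{-1}$, basal rate $BMR$ = 1.2 W kg$^{-1}$ and $k_{aer}$ =
  23 s. Its integral has a closed form used by `aerobic_energy()`.
* **Anaerobic lactic (glycolytic)**:
  $P_{la}(t) = P_{la,max}\,k_{norm}\,(1 - e^{-t/k_1})\,e^{-t/k_2}$
  with $k_1$ = 2.75 s, $k_2$ = 35 s. The normalization constant
  $k_{norm} = 1/[(1 - e^{-t^*/k_1})e^{-t^*/k_2}]$ with
  $t^* = k_1 \ln(1 + k_2/k_1)$ makes the amplitude equal the curve's
  maximum (≈7.2 s into the race with the defaults).
* **Anaerobic alactic (phosphocreatine)**:
  $P_{al}(t) = P_{al,max}\, e^{-(\ln t - \mu_{al})^2 / (2\sigma_{al}^2)}$,
  a log-normal bell with $\mu_{al}$ = 1 (peak at $e^1 \approx 2.7$ s)
  and $\sigma_{al}$ = 0.4. The width parameter is stored as a
  magnitude; it only ever enters squared.

With the shape constants fixed, the model is *linear* in the two
anaerobic amplitudes, so `fit_amplitudes()` solves a non-negative
linear least-squares problem (exactly, by clamp-and-refit on two
variables) rather than a generic non-linear fit; on self-generated
series recovery is exact to machine precision, and under additive
Gaussian noise it is unbiased. Adjusted $R^2$ uses $p = 2$ free
parameters on the observed sample count.

A caveat established by the package's own tests: a power series
derived *densely* from kinematics has a large early transient (peak
power within the first second) that no combination of these bell
shapes can follow, so amplitude fits against dense kinematics-derived
series have poor $R^2$ by construction. Meaningful decompositions of
real races come from the sparser split-level sampling of the source
data, or from the capacity route below.

## Duration-dependent anaerobic capacities

Even maximal races do not empty the anaerobic stores. The energy
actually drawn from each store is modelled as a function of net race
duration $T$:

* alactic:
  $E_{al}(T) = E_{al,max}\,e^{-(\ln T - 1.75)^2/(2 \cdot 1.5^2)}$,
  equivalently an average-power model $E_{al}(T)/T$ whose maximum
  sits at $e^{1.75 - 1.5^2} \approx 0.61$ s — phosphocreatine
  splitting is fastest at contraction onset — while the drawn energy
  itself peaks at $T = e^{1.75} \approx 5.7$ s;
* lactic:
  $E_{la}(T) = E_{la,max}\,k_{norm,2}\,
  (1 - e^{-(T-3)/20})\,e^{-(T-3)/1500}$ for $T > 3$ s and zero below
  the 3 s onset (glycolytic energy is negligible in the first
  seconds), peaking at $3 + 20\ln(76) \approx 90$ s, consistent with
  peak blood-lactate accumulation in races of 50–100 s.

Both models are linear in their capacity, so `fit_alactic_capacity()`
and `fit_lactic_capacity()` use the closed-form least-squares
amplitude $\sum y_i m_i / \sum m_i^2$; fits are exactly
scale-equivariant. All durations are net of reaction time
($T = $ finish time $- 0.15$ s by default), the convention under
which the package reproduces the reference capacity estimates.

Lactic energy converts to blood-lactate accumulation at 62.7
J kg$^{-1}$ per mmol L$^{-1}$ for men (20.9 J mL$^{-1}$ O$_2$ × 3.0
mL O$_2$ kg$^{-1}$ per mmol L$^{-1}$) and 2.7 × 20.9 = 56.43 for
women — the product of the underlying constants is used. Theoretical
capacity ranges (alactic 310–390 / 230–292 J kg$^{-1}$; lactic
940–1250 J kg$^{-1}$) are used for warnings only and never constrain
a fit.

## The inverse model

`reconstruct_kinematics()` inverts a power series step by step:
starting from rest, each step finds the next velocity whose implied
acceleration and metabolic power match the target, with the
accelerated-running cost while $a > 0$ and the flat cost while
$a \le 0$, and accelerations bounded by ±12 m s$^{-2}$. Two
numerical choices matter:

* **Discretization.** Matching the endpoint power of each step is
  first-order accurate and leaves ≈0.1% distance error at
  `dt = 0.01` s. The default `midpoint` scheme matches the step
  average of the target using the mid-step velocity (second order),
  and — because averaging across a known discontinuity would corrupt
  the one step that straddles it — falls back to endpoint matching on
  exactly that step. The forward→inverse round trip then reproduces
  distance to ≈0.0006%, comfortably within the 0.01% the method is
  expected to achieve.
* **Branch selection.** Near the phase transition one power value can
  be matched either by a low-acceleration step (the accelerated cost
  tends to ≈3.6 as $a \to 0$) or by a flat-cost (3.8) deceleration.
  Series derived from kinematics carry their cost-switch time, and
  the inversion switches branches exactly there, mirroring the
  forward convention. Model-generated series carry no switch time;
  for them the deceleration branch is preferred whenever it can match
  the target within the acceleration bound, which keeps the inversion
  stable through the long power decline of a race.

`capacity_power_series()` chains the availability models with the
pathway shapes: energies at duration $T$ become amplitudes by
dividing by the unit-amplitude shape integrals (the shapes are linear
in their amplitudes), plus the aerobic rise.
`optimize_capacities()` then finds the capacity pair minimizing the
sum of squared relative distance errors across a set of performances
(Nelder–Mead over log-capacities for positivity, three restarts
against local minima), and `simulate_race_time()` bisects on duration
(tolerance 0.005 s, durations resolved to the grid step) for the
smallest time whose reconstructed distance reaches the target.

### A structural limitation of capacity estimation

The stepwise inversion is energy-consistent: velocity can only be
built from power actually present in the series. Because the alactic
bell peaks at ≈2.7 s, a capacity-implied power series delivers only
≈90 J kg$^{-1}$ before 3 s, whereas a real sprinter's kinematic power
expends ≈300 J kg$^{-1}$ over the same window. A model series built
from capacities in the published reference range therefore
reconstructs several percent short over 100 m, and the optimizer
compensates by inflating the short-race-dominant alactic capacity
(to ≈510 J kg$^{-1}$ for the men's reference triple) while the
lactic capacity stays within a few percent of its reference value
and the per-event distance errors settle around 0.3%. Relative
quantities that pass through the full pipeline consistently —
per-event errors, and simulated times at other distances (within
≈1% for 60–300 m) — are robust to this; the absolute alactic
capacity from `optimize_capacities()` is not, and should be read as
pipeline-specific. `check_capacity_ranges()` warns when estimates
leave the theoretical ranges.

## Synthetic data

`make_split_table()` regenerates split tables from acceleration-model
parameters: exponential rise to 99.5% of $v_f$ (the `peak_fraction`
handoff is the package's convention for parameter-only profiles),
then a linear deceleration chosen so the forward profile covers the
race distance in the net race time; cumulative times come from
inverting the profile's distance–time map, and optional Gaussian
noise (default off; 0.1–0.2 m s$^{-1}$ is a realistic timing error
for 10 m splits) perturbs interval-average velocities under a fixed
seed. Equal seeds give identical tables.

What passing tests on these fixtures establish: correctness of the
estimators and the forward/inverse chain under the model's own
assumptions. What they do not establish: behaviour under real split
data, whose velocity profiles deviate from the exponential-plus-linear
idealization (wind, bends, lane draw, pacing), and whose reaction
times differ from the 0.15 s default. No wind or curvature modelling
is attempted.

## Problem sizes and run times

All analyses run on a 0.01 s grid. A full capacity optimization on a
100/200/400 m triple takes a few seconds on one core (the stepwise
inversion is compiled); a race-time simulation takes well under a
second per distance. The test suite's simulation studies use 50–60
noise seeds, which is enough to pin the estimator means to the
tolerances tested.

## Worked example

```{r example, eval = FALSE}
# synthetic men's 100 m split table from the bundled parameters
ref <- sprint_parameters()$table1$male$`100`
st <- make_split_table(fixture_spec(tau = ref$tau, v_f = ref$v_f,
                                    total_distance = 100,
                                    finish_time = ref$finish_time))
fit <- adjust_peak_velocity(fit_acceleration(st), st)
pr <- build_velocity_profile(fit, st)
ps <- metabolic_power(pr)
ps

# capacity estimation from the reference per-race energies
fit_alactic_capacity(c(9.43, 19.04, 43.91), c(362, 239, 170))
fit_lactic_capacity(c(9.43, 19.04, 43.91), c(364, 790, 1189))

# race-time simulation from a capacity pair
caps <- athlete_capacities(MAP = 24.5, E_al_max = 328, E_la_max = 1460)
simulate_race_time(60, caps)
```
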