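---
title: "Modelling strain-actuated microfluidic pumping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling strain-actuated microfluidic pumping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strainpump)
```

## The device and the physical idea

A skin-strain-actuated micropump is a valveless elastomer (PDMS) chip: a
compliant actuator chamber flanked by two *pumping channels* of deliberately
different aspect ratio $AR = h/w$, optionally continuing into identical
*observation channels* whose liquid meniscus is read out by imaging. Cyclic
skin strain, applied orthogonally to the channel axes, deforms every
cross-section as

$$w' = w(1+\varepsilon), \qquad h' = h(1-\nu\varepsilon),$$

with Poisson ratio $\nu = 0.5$ for incompressible PDMS, so the deformed
aspect ratio is $AR' = \gamma AR$ with $\gamma = (1-\nu\varepsilon)/(1+\varepsilon)$.
The hydraulic resistance of a rectangular duct, in the single-term
lubrication approximation and written with $a=\min(w,h)$, $b=\max(w,h)$ so
one expression covers both regimes, is

$$R = \frac{12\,\mu L}{\bigl(1-0.63\,a/b\bigr)\,a^3 b}.$$

Under tension a clearly low-AR channel becomes *more* resistive and a
clearly high-AR channel *less* resistive. This asymmetry in strain-induced
deformation rectifies an oscillating flow: with the strain applied, the
actuator's dilatation draws its stroke volume preferentially through the
(momentarily less resistive) high-AR branch; with the strain released, the
volume returns split by the symmetric rest resistances. The net volume moved
per cycle, normalised by the stroke volume $V_{total}$, is the *pumping
efficiency*

$$PE \;=\; \frac{R'_{LAR}}{R'_{LAR}+R'_{HAR}} \;-\; \frac{R_{LAR}}{R_{LAR}+R_{HAR}},$$

the difference of the high-AR branch's current-divider fractions between the
strained and relaxed phases. Note the *cross*-resistance in the numerator:
the branch with the lower resistance carries the larger flow. `flow_split()`
implements exactly this physical divider, and a brute-force test splits unit
stroke volumes through it to confirm the identity. Transport is always
reported signed; in this package positive PE means net right-to-left
transport, and the high-AR side always loses volume to the low-AR side for
clearly asymmetric pairs.

Two resistance routes are provided and agree to second order in strain
(verified by a quadratic-shrink property test): the **exact** route deforms
the geometry and re-evaluates $R$, and the **approximate** route applies the
first-order ratios

$$\frac{R'_{LAR}}{R_{LAR}} \approx \frac{1-0.63\,AR}{1-0.63\,\gamma AR}\,\frac{1}{1-\varepsilon/2},
\qquad
\frac{R'_{HAR}}{R_{HAR}} \approx \frac{1-0.63/AR}{1-0.63/(\gamma AR)}\,\frac{1}{1+5\varepsilon/2}.$$

The exact route is the default; the approximate route is what the published
heat-map numbers correspond to, and is selected explicitly where those are
reproduced.

## What the quasi-static model predicts

```{r sweep}
sweep <- pe_sweep(0.1, 10, n_grid = 101, strain = 0.1, model = "approximate")
max(abs(sweep$pe))
```

On a $101\times101$ log-spaced grid of aspect-ratio pairs in $[0.1, 10]$
with equal cross-sectional areas, at 10% strain, the maximum $|PE|$ is about
0.063 (printed as 0.06), reached near the antisymmetric corner
$(AR, 1/AR) = (0.1, 10)$; the equal-AR diagonal is identically zero, and the
map is antisymmetric under swapping the sides. For the canonical
antisymmetric pair $AR = 3$ and $1/3$ at 10% strain the models give

```{r pair}
pair <- pump_config(left = channel(600, 200, 5000),
                    right = channel(200, 600, 5000))
c(exact = pumping_efficiency(pair, 0.1),
  approximate = pumping_efficiency(pair, 0.1, model = "approximate"))
```

both rounding to 0.05. $PE$ is independent of $V_{total}$, grows
monotonically with strain over the working range, and is diluted
monotonically by any identical series resistance added to both branches
(which is why observation channels, while enabling the readout, are
detrimental to pumping).

### Behaviour near $AR = 1$, a documented caveat

The deformed-resistance ratio is *not* monotone in $AR$ through unity.
Stretching a near-square channel grows its cross-sectional area (by a factor
$(1+\varepsilon)(1-\nu\varepsilon) > 1$) and therefore *lowers* its
resistance even on the low-AR side; and a channel whose deformed shape lands
near square picks up a resistance bump from the $(1-0.63\,a/b)$ factor. Two
consequences, both verified numerically and reflected in how the tests are
phrased:

* the rule "low-AR resistance rises under tension" holds only for
  $AR \lesssim 0.4$ (to first order, the threshold solves
  $0.945\,AR/(1-0.63\,AR) = 1/2$), and symmetrically for the high-AR side;
* pairs with both aspect ratios in roughly $[0.4, 1.8]$ can pump weakly in
  the reverse (low-AR to high-AR) direction. The direction invariant is
  therefore asserted for clearly asymmetric pairs
  ($AR_{low} \le 0.4$, $AR_{high} \ge 1.5$).

The approximate ratios additionally have a branch discontinuity exactly at
$AR = 1$; by convention the package routes $AR = 1$ through the low-AR
branch, and the sweep grid snaps values within $10^{-9}$ of unity to exactly
1 so that the intended diagonal and unity samples are not perturbed by
round-off onto the wrong branch.

### Unequal side areas

Scaling the right side's width and height by 1.5 (as in the published
unequal-area map) lowers the attainable maximum $|PE|$ and moves the
optimum's high-AR coordinate toward unity (from 10 to about 3.3 in the exact
model) — the lower-resistance side no longer needs an extreme aspect ratio
to carry its share. In this divider model the relaxation happens on the
*unscaled* branch's coordinate of the global optimum; the published
description attributes it to the scaled channel, which the model does not
reproduce literally.

## The transient lumped network

The quasi-static picture assumes each half-cycle completes. To study what
happens when it does not, the actuator is modelled as a compliant chamber
with a dilatation source, giving the single-state network

$$C\,\dot P = -V_0\beta\,\dot\varepsilon - P\left(\frac{1}{R_L}+\frac{1}{R_R}\right),
\qquad \dot V_i = P/R_i, \qquad \dot x_i = \dot V_i/A_{obs,i},$$

where each branch resistance is the strained pumping-channel resistance
(exact route) plus the observation channel's per-length resistance times its
liquid-filled length $x_i$. The stroke volume is $V_{total} = V_0\beta
\varepsilon_{max}$ and the relaxation time constant $\tau = C\,R_{parallel}$.
Capillary pressure at the menisci and the downstream air column are
neglected; outlets sit at atmospheric pressure. The strain waveform is a
trapezoid (ramp–hold–release–wait); zero-duration ramps are ideal steps,
applied as instantaneous pressure jumps $-V_0\beta\,\Delta\varepsilon/C$,
matching the quasi-static model's infinitesimal-application assumption.

**Parameters and defaults.** The published experiments do not pin the
actuator's internal dimensions, so $V_0$, $\beta$ and $C$ are free model
inputs. The defaults — $V_0 = 10\ \mu L$, $\beta = 2$,
$C = 0.0015\ \mu L/Pa$ — were chosen once so that, with the default
benchtop-like pump (`default_pump()`: AR 3 and 1/3 pumping channels of
$200\times600\ \mu m$ cross-section and 5 mm length, $500\times200\ \mu m
\times 40$ mm observation channels half-filled, 28 mPa·s working liquid),
the time constant is about two seconds and the stroke volume is
$1\ \mu L$ at 5% strain, the reported operating scale. Default ramps are
1 s (device strained "in a second" on the bench); waits default to 15 s,
the observed stabilization time.

**Numerics.** Integration is fixed-step classical Runge–Kutta (deSolve,
method `"rk4"`) with step $\le \tau/100$, chosen for determinism — the
system is not stiff. The linear invariant $CP + V_0\beta\varepsilon + V_L +
V_R$ is preserved exactly by RK4, so the volume-conservation residual along
any trace is pure round-off (observed $\sim10^{-14}$, contract $10^{-6}$
relative per cycle). A step response against the closed-form RC decay agrees
to $\sim10^{-8}$. A meniscus leaving $[0, L_{obs}]$ halts the run with a
`samp_dynamic_range` warning and truncates the trace.

**What the dynamics reproduce.** With full stabilization between cycles
(step strain, waits $\ge 20\tau$) the per-cycle PE equals the quasi-static
divider PE to well within 1%. Denying stabilization degrades it: averaged
per-cycle PE falls from single stabilized actuations to 10 back-to-back
cycles to 20 back-to-back cycles, the observed trend. With 1 s ramps
comparable to $\tau$ the per-cycle PE is several-fold below the quasi-static
value even with full waits — much of the return flow occurs while the
channels are still partially strained and cancels — consistent with the
reported factor-of-several theory–experiment gap attributed to strain-rate
dynamics.

**A result the model does not reproduce.** Over hundreds of actuations the
physical observation-channel device measured *sublinear* cumulative
displacement, attributed to the growing series-resistance imbalance as one
meniscus advances and the other retreats. In this lumped network that
explanation does not follow: with identical observation channels the total
series resistance is conserved (one side gains exactly the filled length the
other loses), and the first-order effect of the imbalance on the divider
difference is positive — simulated increments *grow* weakly (≈ +2.5% over
60 cycles) rather than shrink. The linearity comparison still holds and is
what the tests assert: the continuous design's cumulative series fits a line
with $R^2 \ge 0.999$ (constant increments by construction) and at least as
well as the observation-channel design's. The measured sublinearity must
involve effects outside this network (capillary pressure, non-rectangular
printed cross-sections), which are listed as limitations below.

## Strain projection for on-body placement

Digital image correlation of the skin yields pointwise principal Lagrangian
strains: magnitudes $M_1, M_2$ and orthogonal unit directions
$\hat u_1, \hat u_2$. For a sensor whose orientation (the line orthogonal to
its reservoirs) is $\hat s$, the resultant strain at a point is the
magnitude-weighted sum of signed projections

$$\varepsilon_R = M_1(\hat u_1\cdot\hat s) + M_2(\hat u_2\cdot\hat s),$$

and $\langle\varepsilon_R\rangle$ is the unweighted mean over field points
inside the sensor footprint (a closed region: outline points count).
Projections are kept *signed* by default — compressive components along the
sensor axis reduce or negate the resultant, which is what negative on-body
pumping rates require; a rectified variant (absolute projections) is
available behind a flag since the published procedure does not state the
convention. The sum is invariant under rigid rotation of the whole scene to
$10^{-9}$, and flipping $\hat s$ flips the sign but not the magnitude. Field
files are point-list CSVs $(x, y, M_1, M_2, \text{angle}_1)$ with $\hat u_2$
constructed perpendicular to $\hat u_1$, so orthogonality is exact by
construction — DIC exports are point clouds and are consumed as such.

## Measurement statistics

`fit_pe()` pools both sides of a measurement series (high-AR volumes
sign-flipped, which is also how the equal-and-opposite invariant is
exercised on data), normalises by $V_{total}$ when known, and takes the OLS
slope of $V_{net}/V_{total}$ against actuation count as the measured PE;
a constant response is reported as slope 0 with $R^2 = 0$ by convention, and
fits are unweighted (the published protocol does not state weights).
`pumping_rate()` divides the per-set slope by the repetitions per set.
`correlate_rates()` is the Pearson product-moment correlation (tested
against the covariance definition to $10^{-12}$) with its simple regression
line. `box_stats()` uses linearly interpolated quartiles
(`quantile(type = 7)`; the published convention is unstated) and min/max
whiskers as described for the published box plots.

## Synthetic data: what it emulates and what it does not

`make_meniscus_series()` emulates a benchtop/on-body measurement series as a
linear trend of slope $PE_{true}\cdot V_{total}$ per actuation with i.i.d.
Gaussian readout noise per side; defaults ($PE_{true}=0.02$,
$\sigma = 0.002\ \mu L$, $n = 10$, $V_{total} = 1\ \mu L$) sit at the scale
of the reported wrist measurements (0.01–0.02 µL per actuation).
`make_strain_field()` emulates a DIC export as smooth Gaussian magnitude
bumps with a uniform principal direction, optionally jittered into a point
cloud. Both are deterministic under a fixed seed and restore the caller's
RNG state. What they deliberately do **not** contain: drift or
autocorrelated noise, meniscus readout quantisation, spatially varying
principal directions, or any skin biomechanics — so passing the recovery
tests shows the estimators are unbiased and correctly scaled on clean
linear-trend data, not that the device model captures real skin. The
published human-subject numbers (0.011 and 0.0205 µL/bending, $r = 0.86$)
set these scales but are never asserted as model outputs: they depend on
unrecorded biomechanics.

## Problem sizes used in the checks

Sweeps run on the full $101\times101$ grid (instant). Transient checks use
the default $\tau/100$ step with 1–40 cycles, and the 200-actuation
linearity comparison uses 6 s waits with a 0.02 s step, sizes chosen so the
whole suite exercises every regime in about a minute. Monte-Carlo slope
recovery uses 500 seeded series of 10 actuations.

## Known limitations

* Single-term rectangular-duct resistance (no Fourier series); worst near
  square cross-sections, which is also where the near-unity caveats above
  live.
* No membrane bulging, channel compliance, capillary/surface-energy
  pressure, or air-column resistance; the pressure balance has an obvious
  extension point for a capillary term.
* The strain is assumed uniform and orthogonal to the channels; real
  placements see non-uniform, oblique load profiles.
* Observation-channel sublinearity over long runs is not reproduced (see
  above); treat long-run drift predictions as qualitative.
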