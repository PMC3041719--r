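---
title: "Methods: the cardiolab circulation model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the cardiolab circulation model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiolab)
```

cardiolab is a teaching-oriented simulator of cardiovascular mechanics: a
lumped-parameter network of heart chambers, valves and vessels advanced by
an explicit recursion at a fixed 1 ms step. This vignette documents the
model equations, the constants and the numerical choices, and states what
the shipped tests do and do not establish.

## Model structure

The circulation is a network of *compartments* that store volume and
*connectors* that carry flow.

**Chambers** (ventricles, atria) follow the time-varying elastance
formalism: instantaneous pressure is

$$P(t) = E(t)\,\max(V(t) - V_0,\, 0), \qquad
  E(t) = E_{min} + a(t)\,(E_{max}^{eff} - E_{min}),$$

where $V_0$ is the unstressed volume and $a(t) \in [0,1]$ is the
activation waveform. Contractility (in percent of reference inotropy)
scales the end-systolic elastance only,
$E_{max}^{eff} = (c/100)\,E_{max}^{ref}$: inotropy is an
end-systolic-elastance effect, while passive (diastolic) stiffness
$E_{min}$ is a property of the relaxed wall. Both pressure-volume
relations are linear; the pressure is floored at zero below $V_0$ because
the model carries no blood inertia and therefore no diastolic suction.

**Vessels** are Windkessel compliances, $P = \max((V - V_u)/C,\, 0)$ with
unstressed volume $V_u$. **Valves** are ideal diodes with a small series
resistance, $q = \max(\Delta P, 0)/R$ — strictly unidirectional, no
regurgitant or stenotic states. **Resistors** (venous return, peripheral
and pulmonary beds) conduct $\Delta P / R$ in either direction.

Two ready-made networks are provided:

* **IHL** (isolated heart, 5 compartments): a constant-pressure venous
  source at the configured CVP, left atrium, left ventricle, aorta and a
  distal arterial bed draining through the total peripheral resistance
  into a zero-pressure sink. The constant source realises an unlimited
  blood reservoir on the inflow side; the sink mirrors it on the outflow
  side.
* **CCL** (closed double circulation, 10 compartments): systemic veins,
  right atrium and ventricle, pulmonary artery, pulmonary capillary bed,
  pulmonary veins, left atrium and ventricle, aorta, and the systemic
  arterial bed, closed into a ring with four valves. The assignment of
  the ten slots to anatomical segments is this package's choice; it was
  selected so that the three user-facing vascular parameters (aortic
  compliance, TPR, TLR) each have a natural home. TLR is split equally
  between the two pulmonary segments.

No compartment carries an inertance: high-frequency ejection dynamics and
finite-speed pulse propagation are outside the model by design.

## Electrical cycle and mechanical triggering

A fixed-rate pacemaker replaces autonomic control. For a heart rate `hr`
the cycle length is $rr = 60/\mathit{hr}$ and each electrical interval
(P duration, PR, QRS, QT) is a quadratic in $rr$:
$x = a + b\,rr + c\,rr^2$. The shipped coefficients are anchored to
resting adult values at $rr = 1$ s (P 0.09 s, PR 0.16 s, QRS 0.09 s, QT
0.40 s) with the rate dependence concentrated in QT, whose quadratic
tracks the familiar square-root rate correction over 40-160 min\(^{-1}\).
The table is configuration, so published second-order interval terms can
be substituted verbatim. A bad table (intervals that overlap or spill
past the cycle at any supported rate) is rejected when constants are
constructed, checked on the integer rate grid 40..160.

Mechanical activation is derived from the electrical cycle through an
electromechanical delay (0.02 s): atria contract from the P onset plus
delay for twice the P duration; ventricles from the QRS onset plus delay
for $0.9\,QT$ (a repolarisation margin is excluded). The activation
waveform is a two-phase raised cosine rising over the first 40% of the
systolic window — continuous, peaking at exactly 1. The true activation
shape of elastance hearts is not uniquely specified by the framework; the
raised cosine is the simplest smooth choice and is documented as such.

The diastolic heart fraction is defined against *mechanical* ventricular
systole, $\mathit{DHF} = 1 - (\mathit{delay} + QT)/rr$, because its
physiological significance (myocardial perfusion time) is a
mechanical-diastole quantity. With the default coefficients DHF falls
strictly from `r round(ecg_timing(40)$dhf, 2)` at 40 min\(^{-1}\) to
`r round(ecg_timing(160)$dhf, 2)` at 160 min\(^{-1}\).

The displayed ECG is assembled from parametric template fragments (smooth
unimodal P and T humps, a triphasic QRS) time-scaled to the interval
durations, with an exactly-zero baseline elsewhere and fixed arbitrary
amplitudes. It carries timing information only; no recorded-waveform
library is used.

## Numerical scheme

The state advances by an explicit forward (Euler) recursion at
$dt = 1$ ms: pressures from current volumes, flows from current
pressures, volumes from net flows. In the closed loop every flow leaves
one compartment and enters another, so total volume is conserved to
floating-point accuracy at every step — the 60 s default-parameter run
holds $\sum V$ within $10^{-6}$ ml of the configured 5.2 l.

Numerical checks shipped with the package:

* a single compliant vessel draining through a resistor reproduces the
  closed-form exponential decay within 0.5% over one time constant;
* halving $dt$ to 0.5 ms moves the steady-state stroke volume by well
  under 1% at defaults, so discretization does not dominate results;
* the simulator is seed-free and bitwise reproducible: repeated runs with
  identical inputs give identical traces.

Each electrical cycle is quantized to a whole number of steps
(`round(rr/dt)`), so activation tables and the ECG template can be
pre-computed per cycle; the effective rate error is at most $dt/(2rr)$
(0.06% at 70 min\(^{-1}\)). A negative compartment volume — impossible at
the shipped constants, which the corner-combination tests exercise —
raises a stability error advising a smaller step.

Live parameter changes apply at the next 1 ms step without resetting
state, with two exceptions chosen for consistency: heart-rate changes
wait for the cycle boundary so the trigger schedule and ECG are never
torn mid-cycle, and blood-volume changes rescale all compartment volumes
proportionally so conservation holds at the new total. Out-of-range
values are rejected, never clamped: a library cannot rely on the
input widgets that made invalid values unselectable interactively, and an
explicit error teaches the valid range.

Steady state is detected on the slowest-settling state, end-diastolic
volume: a run counts as settled when consecutive-cycle EDV (left
ventricle, plus right ventricle in the closed loop) changes by less than
0.1 ml. At defaults the isolated heart settles in under 10 cycles and the
closed loop in about a dozen, helped by initial compartment volumes
placed near the operating point.

## Constants and calibration

The user-facing parameters (CVP, heart rate, LV/RV contractility, TPR,
aortic compliance, TLR, blood volume) carry published defaults and closed
limits; everything else lives in `internal_constants()`. Those internal
values — chamber elastance bounds and unstressed volumes, vessel
compliances, valve and venous resistances — are human-adult
textbook-range choices, fixed once so that the all-default closed loop
settles at a physiological operating point: aortic pressure near 120/80
mmHg, cardiac output 4-6 l/min, ejection fraction near 0.6, and an atrial
contribution to cardiac output that stays below 10% at every supported
rate and grows with rate (the atrial kick matters most when the diastolic
filling window is short). Two calibration notes:

* The atria are deliberately stiff ($E_{min}$ 0.35, $E_{max}^{ref}$ 0.80
  mmHg/ml) relative to a naive choice. Very compliant atria buffer
  ventricular filling so well that the kick would contribute *least* at
  high rate, inverting the physiological pattern; the stiffer atrium
  makes filling rate-limited at 160 min\(^{-1}\) and restores the rising
  contribution.
* The 4-6 l/min and 120/80 bands are calibration targets for these
  constants, asserted by the test suite as such; they are not claims
  about any external dataset.

The animation geometry partitions left-ventricular volume change with a
cylinder model $V = \pi r^2 L$: a fraction `f_long` (default 0.60) of
every volume change from end-diastole is attributed to shortening of the
long axis, measured at the end-diastolic radius, and the remainder to
radial contraction. The displacement of the atrioventricular plane is the
length change; with the default setting longitudinal shortening accounts
for exactly 60% of the stroke volume, the ceiling the partition is
designed to respect. Lengths are arbitrary units — the rendered view is
schematic, so only ratios matter.

## What the tests show — and what they do not

The test suite establishes the qualitative behaviours expected of the
physiology on this model: stroke volume non-decreasing in preload at
every tested contractility with curves ordered by contractility
(Frank-Starling); stroke volume strictly falling as rate rises at
constant preload; pulse pressure widening when arterial compliance is
reduced (Windkessel); atrial contribution within (0, 10]%. Problem sizes
used by the tests: steady-state runs of at most a few hundred cycles,
preload/contractility grids of 21 points, rate grids of 13 points, a 60 s
conservation run, and a sampled set of 48 parameter-space corners.

These are model properties, not clinical validation. The model has no
autonomic reflexes, no inertance, linear pressure-volume relations, ideal
valves and a healthy-system parameterisation, so quantitative agreement
with patient data — especially at high rates or during vigorous ejection
— is out of scope. Known limitations worth keeping in mind: the constant
activation shape does not adapt to inotropy; venous beds cannot collapse
(pressures floor at zero rather than going negative); and the CCL segment
layout, while natural for the exposed parameters, is one of several
defensible choices.
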