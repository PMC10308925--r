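---
title: "Methods: partitioning nitrification among ammonia-oxidizer guilds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: partitioning nitrification among ammonia-oxidizer guilds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nitripartition)
```

## The measurement problem

Three guilds oxidize ammonia in sediments: ammonia-oxidizing archaea (AOA),
ammonia-oxidizing bacteria (AOB), and comammox *Nitrospira*, which carry
ammonia all the way to nitrate in one organism. Bulk nitrification assays
cannot tell them apart. The differential-inhibitor design this package
implements can: chlorate poisons nitrite oxidoreductase (its reduction
yields toxic chlorite), which knocks out comammox and strict nitrite
oxidizers (NOB) but spares AOA and AOB; 1-octyne at low micromolar doses
additionally knocks out AOB. Running parallel microcosms —

* treatment I: no inhibitor (all guilds active),
* treatment II: chlorate (AOA + AOB active),
* treatment III: chlorate + 1-octyne (only AOA active),
* treatment IV: nitrate instead of ammonium (control for nitrate-consuming
  processes, DNRA and denitrification),

— and fitting the accumulation of oxidized nitrogen in each gives the
potential ammonium-oxidation rates (PARs)

$$\mathrm{PAR}_{cmx} = \mathrm{PAR}_I - \mathrm{PAR}_{II},\qquad
  \mathrm{PAR}_{aob} = \mathrm{PAR}_{II} - \mathrm{PAR}_{III},\qquad
  \mathrm{PAR}_{aoa} = \mathrm{PAR}_{III}.$$

`partition_guilds()` implements exactly this arithmetic, so the guild rates
sum to the treatment-I rate by construction. Inhibition is treated as
complete, following the inhibitor literature the design rests on; no
dose–response is modeled.

## Rate fitting

`fit_rate()` regresses the **sum** NO2⁻ + NO3⁻ on time by ordinary least
squares. The sum is used rather than nitrate alone because the treatments
leave nitrite oxidation in different states (inhibited in II and III,
active in I); the summed pool measures ammonia oxidation regardless.
Slopes are fitted in mM-N/day in the 30 mL liquid phase and converted to
mg N/day/kg soil by `convert_rate()` — with the default geometry
(30 mL, 5 g wet sediment) the factor is
$14 \times 0.030 / 0.005 = 84$. The soil-mass basis is wet mass, since the
source measurements report "per kg soil" without a dry-mass qualifier.

Saline incubations show low activity in the first half day while the
community adjusts to the salinity shock; `exclude_before = 12` (hours)
drops that window before fitting, mirroring how the saline series are
handled in the study design.

Replicates are fitted separately because the vials are independent: the
treatment PAR is the mean of replicate slopes, its SD the replicate SD
(this is the quantity conventionally printed as ±), and its SE pools the
per-replicate OLS slope standard errors. Differences of treatments
propagate uncertainty as root sums of squares. Published ± values for
derived guild rates do not always obey this rule (a derived 0.60 ± 0.94
from inputs ± 0.69 and ± 0.25 exceeds the root-sum-of-squares 0.73); the
package reports the propagated value and leaves such discrepancies
visible. Negative derived rates, which noise can produce, are flagged with
a warning but never clipped, so uncertainty stays honest.

## The synthetic microcosm

The generator exists so every downstream stage can be tested against known
truth. It integrates

$$\frac{d[\mathrm{NH_4^+}]}{dt} = \mathrm{doses} - v_{aoa} - v_{aob} - v_{cmx},$$
$$\frac{d[\mathrm{NO_2^-}]}{dt} = v_{aoa} + v_{aob} + \ell\, v_{cmx} - v_{nob},\qquad
\frac{d[\mathrm{NO_3^-}]}{dt} = (1-\ell)\, v_{cmx} + v_{nob} - v_{dnra},$$

where each $v$ is a maximal zero-order rate times a Michaelis–Menten
factor $S/(K_m + S)$ of its substrate and $\ell$ is the fraction of
comammox-oxidized nitrogen leaked as nitrite (default 0.1; comammox cells
are known to release part of their nitrite intermediate). Zero-order
kinetics softened by a small $K_m$ (default 0.005 mM) keep concentration
curves linear in time while substrate is present — which is what the
linear PAR fits assume — while preventing negative concentrations as pools
empty. $K_m = 0$ is allowed and makes a guild exactly zero-order, useful
in closed-form checks. Note the softening means fitted slopes sit a few
percent below the configured maximal rates under the standard dosing
(ammonium cycles around 0.1–0.2 mM); a genuinely substrate-replete
configuration (high initial ammonium) removes the gap.

Defaults are anchored to the freshwater study conditions: guild rates
AOA 0.0014, AOB 0.0426, CMX 0.052 mM-N/day (i.e. 0.12, 3.58, 4.37
mg N/day/kg soil), a fast NOB pool (0.24 mM-N/day) that keeps freshwater
nitrite at micromolar levels, 0.1 mM ammonium dosed daily except on day 2
(the sediment already held ~0.09 mM ammonium, the initial condition),
initial nitrite 0.001 mM and nitrate 0.05 mM, and additive Gaussian
measurement noise with SD 0.002 mM (ion-chromatography-scale precision).
Saline (3%) multipliers are the ratios implied by the published
treatment-level rates: AOA 8.5, AOB 0.486, CMX 0.137, plus NOB 0.25.

Integration is fixed-step fourth-order Runge–Kutta (deSolve, step 0.005
day, never allowed above 0.01 day) with dosing as instantaneous events; a
dose scheduled at a sampled time is applied just after the reading. Urea
amendments are modeled as instantaneous ammonium (urease kinetics are out
of scope). The test suite checks nitrogen conservation to 1e-6 mM and
agreement with an independently coded forward-Euler integrator at 10-fold
finer step to 1e-4 mM.

### Salinity adaptation and the nitrite transient

Rates ramp linearly from zero over `lag_hours` (the adaptation lag; the
saline default for ammonia oxidizers is 12 h, matching the window excluded
from saline fits). `lag_hours` accepts a per-guild vector because a
growth-free model cannot otherwise reproduce the transient nitrite
accumulation seen in saline incubations: with constant capacities nitrite
can only plateau or grow. The observed mechanism is that nitrite oxidation
is more salt-sensitive than ammonia oxidation, so the saline defaults give
NOB both a reduced capacity (scale 0.25) and a longer adaptation lag
(72 h); nitrite then accumulates for about two days and is drawn back down
— a genuine peak-then-decline. Biomass growth, pH/CO2 chemistry and
buffering are deliberately not modeled.

## The synthetic gradient and SIP analysis

Isopycnic CsCl gradients are modeled as linear in fraction index, heaviest
first (fractions are collected by displacement from the top):
$\rho_k = 1.7925 - 0.0085\,k$ g/mL, which reproduces the two anchor
densities of the study (fraction 9 at 1.716, fraction 10 at 1.7075 g/mL)
over 15 fractions. A taxon's DNA is a Gaussian band centered at

$$\rho = 1.660 + 0.098\,\mathrm{GC} + 0.036\,E,$$

with $E$ the excess ¹³C atom fraction — standard SIP constants, exposed as
arguments. Band SD defaults to 0.006 g/mL (slightly under one fraction
width) and copy counts get mean-one lognormal noise with CV 0.1. Because
the study does not report the atom enrichment achieved during its 13-day
labeling, the generator's per-scenario excess values (comammox 0.236,
AOB 0.47 freshwater / 0.236 saline, AOA 0.47) were chosen once to
reproduce the observed one- and two-fraction peak shifts, and the band GC
values (0.311, 0.398, 0.485) to put the unlabeled peaks in fractions 12,
11 and 10.

`detect_labeling()` formalizes the visual "peak shift" call with a dual
criterion: labeled when the abundance-weighted mean density (WMD)
increases by at least 0.004 g/mL (about half a fraction) **or** the peak
moves at least one whole fraction heavier. Both thresholds are arguments;
the defaults are declared package choices, not inferred from the source
study, which never states a numeric criterion. For noiseless generator
output the WMD shift equals $0.036\,E$ up to edge truncation (tested to
0.002 g/mL), and WMD is monotone in $E$.

Refractive-index readings convert to density linearly; the shipped
two-standard calibration (RI 1.3990 → 1.690, RI 1.4052 → 1.755 g/mL) is a
documented placeholder — supply your own standards via
`fit_ri_calibration()`.

## qPCR quantification

`fit_standard_curve()` fits Cq against log10 copies; efficiency is
$10^{-1/\mathrm{slope}} - 1$. The QC bands — efficiency within 83–94% and
$r^2 > 0.99$ — describe the assays of the source study and are therefore
warnings, not hard failures (a perfect-doubling 100% assay is flagged,
deliberately). `quantify()` back-calculates copies/µL and scales by
elution volume ÷ template fraction ÷ soil mass; the defaults (30 µL
elution, 1/30 templated, 0.16 g extracted sediment) are declared
placeholders because the back-calculation is rarely printed. Group
comparisons are limited to means, SEs and `fold_change()`; multiple-range
testing is out of scope.

## Numerical and design choices

* All randomness flows from explicit integer seeds; replicate and
  treatment identities are folded into the seed so replicates differ but
  reruns are byte-identical.
* Concentrations are clamped at zero after measurement noise; state
  variables themselves stay non-negative through the Michaelis–Menten
  factors.
* Peak ties in a fraction profile resolve to the heavier (lower-index)
  fraction.
* Readers reject malformed files loudly: wrong treatment labels, strings
  in numeric columns (with row numbers), negative concentrations,
  mismatched fraction grids.
* Contributions are integer percents of the treatment-I PAR. Feeding the
  published treatment-level rates through the partition reproduces the
  published guild values except one: the freshwater comammox difference
  computes to 4.36 against a printed 4.37, a rounding artifact upstream of
  the published table (the contribution rounds to 54% either way).

## Problem sizes used in validation

The shipped checks simulate 48-h panels sampled every 6 h with 3
replicates (the study sampled at least five time points), 50-run
recovery ensembles, 100-gradient classification ensembles, and 200-run
control-check ensembles. These sizes give the Monte-Carlo estimates
quoted by the acceptance checks while keeping the whole suite fast.

## What passing tests do and do not show

The generator emulates the statistical structure the analysis assumes:
linear accumulation with small Gaussian noise, complete inhibition,
Gaussian bands with lognormal count noise. Real incubations add effects
that are out of scope here — community growth during the assay, partial
inhibition, urea hydrolysis kinetics, gradient diffusion and wall effects,
PCR inhibition. Recovery of known rates from synthetic data therefore
validates the estimators and their uncertainty accounting, not the field
accuracy of the inhibitor method itself.
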