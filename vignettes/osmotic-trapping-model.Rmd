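---
title: "Osmotic fluid trapping, colonic sodium absorption, and a pressure surrogate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Osmotic fluid trapping, colonic sodium absorption, and a pressure surrogate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osmotrap)
```

## The model in one paragraph

Hyperosmolar drinks -- most prominently soft drinks sweetened with
high-fructose corn syrup (HFCS), which carry roughly twice the osmole count
of equal-mass sucrose drinks -- must be diluted to isotonicity in the small
bowel before their water can be reabsorbed. The dilution water comes out of
the circulation, and because fructose is absorbed slowly (facilitated
diffusion via GLUT5, along the whole small bowel) that water stays trapped
for hours. The transient circulating-volume deficit stimulates aldosterone
and ADH secretion. Kidneys respond quickly and transiently; the colon
responds slowly: its sodium-absorption capacity reflects the trailing
hormone exposure of the last few days, because the trophic effect of
aldosterone on colonic crypts works through cell renewal. Someone who drinks
several HFCS sodas every day therefore keeps their colon in a
high-absorption state, retains sodium, expands the extracellular fluid (ECF)
compartment, and -- in this model's deliberately simple coupling -- raises a
mean-arterial-pressure (MAP) surrogate. `osmotrap` implements this chain as
three layers: ideal-solution osmolarity arithmetic, a static trapping model
of a single ingestion, and a deterministic multi-day simulation with a
seeded virtual-cohort generator on top.

## Osmolarity arithmetic

Every osmolarity is ideal-solution arithmetic:
`concentration / molar_mass * particles_per_formula * 1000` mosm/L, summed
over components. No osmotic coefficients, no pH or temperature effects --
the reference calculations the package reproduces (sucrose at 125 g/L
$\to$ 365 mosm/L, monosaccharides at the same mass $\to$ 694, salt at
12.7 g/L $\to$ 435) are themselves ideal arithmetic, and matching them is
the point. Two consequences worth knowing:

* **Declared osmolarities take precedence.** Labelled products whose
  printed osmolarity disagrees with ideal arithmetic (the salty-soup and
  sucrose-drink presets, both declared 400 mosm/L) keep their label; the
  composition is still used for the water partition, which only needs
  osmolar *shares*. Ethanol is representable **only** through a declared
  value: ideal arithmetic badly underestimates measured ethanol osmolarity,
  so the package refuses to compute it from mass.
* **The isotonic reference is 300 mosm/L**, a round plasma value, rather
  than a physiological 285--295. The trapping formula is defined with that
  constant and every reference number depends on it; `O_iso` is still a
  parameter for sensitivity exploration.

The shipped HFCS preset is 800 mosm/L (glucose 360 + fructose 440), which
implies 144 g/L of sugar -- more than the 100--125 g/L typical of real
sodas. That tension exists in the source material itself; the preset is
shipped as declared, unreconciled, and the osmolarity-sweep tools accept any
sugar concentration when a realistic intermediate is wanted.

## The static trapping model

For an ingested volume $V$ at osmolarity $O$, the initially trapped dilution
volume is

$$V_d = \max\!\left(0,\; V\,\frac{O}{O_{iso}} - V\right),
\qquad V_a = V + V_d,$$

with $V_a$ the total isotonic volume that must be reabsorbed. Each solute
owns a share of $V_a$ equal to its share of the computed osmolarity; shares
pool into a **fast** class (glucose/galactose via SGLT1, plus electrolytes),
a **slow** class (fructose via GLUT5), and a **nonabsorbed** class
(lactulose), with sucrose splitting 50/50 fast/slow after hydrolysis to
equimolar glucose + fructose. The sucrose split deliberately ignores
hydrolysis-generated osmoles: the reference sucrose-drink row ($V_d \approx
0.16$ L, shares $0.33/0.33$) does the same, and simultaneous glucose
absorption keeps the net extra trapping small.

**Kinetics.** Absorption is zero-order within *sequential* class windows:
the fast share over $[0, 2\,\mathrm{h}]$, then the slow share over
$[2\,\mathrm{h}, T_{slow}]$ (default $T_{slow} = 4$ h). Water trapped with
fructose cannot leave until fructose absorption -- distal and slow --
deals with it, so the fraction of $V_a$ absorbed at two hours equals the
fast osmolar share exactly: 45% for the 800 mosm/L HFCS drink, with the
lumen empty at four hours. Concurrent (rather than sequential) zero-order
windows would instead absorb 72.5% by two hours, contradicting the 45%
share the model is built around. $T_{slow}$ is a parameter so impaired
fructose absorbers can be modelled by raising it; the nonabsorbed share is
released to the colon at $T_{slow}$, a minimal choice that supports the
lactulose corollary without inventing colonic fermentation kinetics.

**Display convention.** Reference volumes are printed truncated toward zero
at two decimals ($1/6 \to 0.16$); `display_2dp()` implements this with a
$10^{-9}$ guard for values sitting exactly on a hundredth boundary. Tests
compare truncated values against printed ones and full-precision values
against analytic ones.

## The homeostasis loop

`simulate_schedule()` integrates, over a multi-day ingestion schedule:

* **Deficit.** Per event, the body-donated water not yet repaid:
  $d_e(t) = \max(0, V_d - \mathrm{absorbed}_e(t))$; absorbed water repays
  the deficit first. Dilution is instantaneous at ingestion (no secretion
  kinetics), so the deficit steps to $V_d$ at the event time.
* **Hormones.** $a(t) = \min(s, k_{aldo}\, D(t)/V_{circ})$ and the ADH
  analogue, with $D$ the summed deficit, $V_{circ}$ baseline circulating
  volume and $s$ a saturation cap. While unabsorbed luminal sodium from an
  electrolyte-rich beverage remains (its 2-h fast window), the aldosterone
  increment is gated to zero -- the salty-soup response is "blunted by
  sodium absorption" -- while ADH, answering volume alone, is not.
* **Colon capacity.** $dC/dt = (C_0 + g\,\bar a - C)/\tau$, with $\bar a$
  the trailing boxcar mean of the aldosterone index over `window_days`
  (default 3 days; "few previous days" is not quantified in the source, nor
  is $\tau$, default 2 days). The update uses the exact exponential step for
  a constant within-step input.
* **Sodium.** $dNa/dt = (1-\phi) I + \min(\phi I, C) - k_{renal}(Na -
  Na_{set}(t))$, where $\phi$ is the fraction of dietary sodium reaching
  the colon, absorption there is capped at what actually arrives, and the
  renal setpoint shifts upward with the hormone indices
  ($Na_{set} = Na_{set,0} + \eta\,(a + adh)$) -- hormones spare sodium.
  Beverage sodium (soup, oral rehydration solution) enters over the fast
  window. $Na_{set,0}$ is derived from the baseline fixed-point condition,
  so an event-free simulation is constant to machine precision.
* **Outcome.** $ECF = Na/[Na] - D(t)$ (isotonic tracking at 140 mmol/L,
  minus the transiently trapped water) and
  $MAP = MAP_0\,(1 + \beta\,(ECF - ECF_0)/ECF_0)$: one linear coefficient,
  no autoregulation and no pressure natriuresis. Excess solute-free water
  is excreted within the step (ADH's water side is folded into the urine
  ledger); ADH has no independent trophic effect on the colon -- it is
  only a "potential mediator" in the source -- though its index is computed
  and exposed should a coupling be wanted.

**Numerics.** The grid is integer seconds: coarse steps (default 15 min)
everywhere, fine steps (default 1 min) inside each event's absorption
window, plus knots at event boundaries and one second before each onset so
the trapezoidal hormone integrals do not smear the deficit jump across a
coarse step. Everything except the two scalar state recurrences (colon
capacity, sodium) is vectorised over the grid. Halving both steps moves
steady-state MAP by about $10^{-5}$ relative, comfortably inside the 0.1%
guard the test suite enforces. The water ledger closes
($\Delta(ECF + \mathrm{luminal}) = \mathrm{intake} - \mathrm{urine} -
\mathrm{stool}$) to ~$10^{-14}$ L at every step.

**Parameter choices.** The source model is qualitative about every gain and
time constant, so the defaults in `physiology_params()` (and the shipped
`default_params.yaml`) are illustrative, not calibrated: baseline MAP
surrogate 93 mmHg; hormone gains 1 per unit fractional deficit with
saturation 2; colon baseline 20 mmol/day gaining 500 mmol/day per unit
trailing aldosterone index; renal constant 0.5/day; sodium setpoint shift
50 mmol per unit summed index; pressure coupling $\beta = 2$. With these, a
3-drinks/day schedule of the 800 mosm/L preset settles ~2.7 mmHg above
baseline -- "a few mmHg" -- with ~0.9 mmHg per additional daily drink, and
steady-state MAP/ECF are non-decreasing in drinks/day, beverage osmolarity
above 300 mosm/L, and fructose completion time. Note one intended
saturation: colonic absorption cannot exceed the sodium reaching the colon
($\phi I = 60$ mmol/day at defaults), so the dose-response flattens at very
high exposures.

```{r dose-response}
p <- physiology_params()
hf <- preset_beverage("hfcs_softdrink")
sapply(0:4, function(k) {
  s <- steady_state_summary(simulate_schedule(regular_schedule(k, hf, 14), p))
  c(drinks = k, MAP = round(s$mean_map_mmHg, 2),
    ECF_pct = round(s$ecf_expansion_pct, 2))
})
```

The grid-search fit `fit_colon_params()` closes the loop on
identifiability: given a trajectory generated by the model with known
(`c_gain`, `tau_colon`), exhaustive search over a parameter grid lands back
on the generating cell.

## The virtual cohort

`cohort_spec()` / `run_cohort()` emulate the *exposure structure* of the
survey population the model was motivated by -- heterogeneous drinking
habits centred near 2.5 sugary drinks/day, with a fructose-malabsorber
subgroup -- without claiming to reproduce its covariate-adjusted odds
ratios, for which the model has no mechanism (no age, BMI, or dietary-salt
effects). Draw order from one seeded stream is fixed and documented:
malabsorber flags, then completion times (log-normal, median 4 h, sigma
0.25; malabsorbers fixed at 8 h; the malabsorption prevalence of 10% is a
placeholder -- the literature gives no usable distribution), then
drinks/day from a discrete distribution over 0..6 with median 2.5. Each
individual runs a 14-day regular schedule and is summarised over the
trailing 3 days; the hypertension flag is `MAP >= 96` mmHg, a few mmHg
above baseline, consistent with the illustrative pressure scale. Fructose
g/day is *derived* from the beverage composition (39.6 g/drink for the
800 mosm/L preset), keeping exposure and physiology consistent rather than
matching the survey's 74 g/day median, which corresponds to a weaker real
soda than the 800 mosm/L preset.

Simulated durations (14 days for cohorts and dose-response grids, 30 days
for fixed-point checks, 6--7 days for identifiability runs) are the
package's own choice: with $\tau = 2$ days and a 3-day averaging window the
loop is within numerical tolerance of its new balance after about ten
days, and longer runs only re-average an already-periodic orbit.

## What passing tests do and do not show

The synthetic cohort and schedules emulate the model's own assumptions:
identical beverages every day, fixed mealtimes, deterministic physiology,
no gastric-emptying kinetics, no transporter saturation (no Km/Vmax), no
potassium, no pressure natriuresis, no ethanol dynamics, and a pressure
"surrogate" that is a linear readout of ECF expansion rather than
hemodynamics. Passing tests therefore show internal consistency -- the
arithmetic of the reference table, conservation, monotone dose-response,
identifiability -- not that real populations behave this way. The
epidemiological association the model interprets lives in external survey
data that this package deliberately does not touch.

## Degenerate inputs and edge behaviour

Isotonic or hypotonic drinks clamp $V_d$ to zero (rehydration without
trapping; the circulatory balance never goes negative). Zero-osmolarity
beverages have no defined partition and raise an error. Pre-diluting any
drink to 300 mosm/L gives trajectories identical to baseline in aldosterone
drive and colon capacity -- the mitigation manoeuvre is exact by
construction. Empty schedules are exact fixed points; empty cohorts return
empty, well-formed tables; an event outside the schedule's duration, a
negative concentration, or a non-finite integration state fail fast with
the offending field or step named.
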