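---
title: "Methods: sedimentation physics, TOC mass balance and uncertainty in fractoc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sedimentation physics, TOC mass balance and uncertainty in fractoc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fractoc)
```

`fractoc` models the use of a liquid TOC analyzer to quantify carbon-based
particle suspensions and to judge size-fractionation steps. This vignette
documents the models, their assumptions, the tunable parameters, and the
design decisions taken where the underlying conventions were genuinely open.

## Carbon mass balance

A polymer with repeat-unit formula known in Hill notation has carbon mass
fraction

$$ w_C = \frac{12.011\, n_C}{\sum_e A_e n_e}, $$

computed with IUPAC 2021 conventional atomic weights (four or more
significant figures). A suspension at mass concentration $c$ (mg/L) then
contributes $c\,w_C$ mg C/L to the TC channel, and the analyzer's
$\mathrm{TOC} = \mathrm{TC} - \mathrm{TIC}$ difference isolates the organic
part. The packaged registry (PS, PE, PP, PVC, PET, cellulose, KHP,
Na₂CO₃) stores formulas only; fractions are always recomputed. The PS
repeat unit C₈H₈ gives 92.26 %C at two-decimal rounding; KHP 47.05 %C;
Na₂CO₃ 11.33 %C. Fractions for PE, PP, PVC, PET and cellulose follow from
the textbook repeat units (CH₂, C₃H₆, C₂H₃Cl, C₁₀H₈O₄ and anhydroglucose
C₆H₁₀O₅); these are the registry's own assumptions, stated here because
polymer-specific additives and dopants are not modeled. In particular the
gold doping of some in-house PE/PP/PVC particles is ignored — the dopant
mass fraction is not available — which biases converted mass
concentrations for those materials slightly low.

## Centrifugal sedimentation

All sedimentation math is creeping-flow Stokes settling of rigid spheres:
$v = d^2 (\rho_p - \rho_f) a / 18\mu$. Defaults are water at 20 °C
($\rho_f = 1.0$ g/cm³, $\mu = 1.0016$ mPa·s; a fixed user input, no
temperature–viscosity lookup), standard gravity $g = 9.81$ m/s², and PS at
$\rho_p = 1.05$ g/cm³. Buoyant particles ($\rho_p < \rho_f$) report a
negative speed and a zero pellet fraction; flotation is not modeled
further. Hindered settling, wall effects, aggregation and fixed-angle
rotors are out of scope.

### Rotor geometry from an RCF gradient

In a spinning rotor the centripetal acceleration grows linearly with
radius, so the relative centrifugal force at the liquid meniscus and at the
tube bottom, together with the column height $H$, determine the geometry
completely:

$$ \frac{r_t}{r_b} = \frac{\mathrm{RCF}_t}{\mathrm{RCF}_b}, \qquad
   r_b - r_t = H, \qquad \omega = \sqrt{\mathrm{RCF}_b\, g / r_b}. $$

`geometry_from_rcf_gradient()` solves these two linear constraints;
recomputing the RCF at the reconstructed radii returns the inputs exactly
(tested to 1e-12). For the study conditions (1042–1976 RCF over 60 mm)
this yields $r_t \approx 66.9$ mm, $r_b \approx 126.9$ mm and a spin speed
within 0.2 % of the printed rpm setting — a useful consistency check, since
rpm and RCF are related through the rotor radius (≈161 mm at the outer
limit for both printed rpm/RCF pairs).

### Effective versus nominal cutoff

Because the driving acceleration grows with radius, a settling particle
follows an exponential trajectory $r(t) = r_0 e^{kt}$ with
$k = d^2 \Delta\rho\, \omega^2 / 18\mu$. The **effective cutoff** is the
diameter that traverses the whole column in exactly the run time,

$$ d_{\mathrm{eff}} = \sqrt{ \frac{18 \mu \ln(r_b/r_t)}
   {\Delta\rho\, \omega^2 t} }, $$

1341 nm for the first study spin (14 min) and 724 nm for the second
(30 min). `spin_time_for_cutoff()` is its exact inverse (round trip tested
to 1e-9 relative).

A separate **nominal** planning mode treats the set-point RCF as uniform
over the column and requires a meniscus particle to traverse $H$ at
constant speed. This is the convention behind "theoretical cutoff" run
planning; for the first spin it gives 14.7 min for a 1000 nm target at
2500 RCF, close to the 14 min actually used. It does **not** reproduce the
second spin's 30 min for a 500 nm target at 4000 RCF (it gives 36.8 min);
the arithmetic behind that published duration is not stated, so the mode is
provided as-is and its outputs are labelled `nominal`. Effective cutoffs,
which depend only on the measured geometry and actual run time, are
unaffected.

### Pellet fractions and sequential fractionation

For a component homogeneously distributed along the column at the start of
the spin (the tube is filled with a stirred suspension; this is *not*
line-start centrifugation), the particles that reach the bottom are exactly
those starting at $r_0 \ge r_b e^{-kt}$, giving

$$ f = \min\!\left(1,\; \frac{r_b}{H}\left(1 - e^{-kt}\right)\right). $$

The initial distribution is uniform *per unit radial length*, i.e. the
swing-bucket tube is taken as fully deflected with its axis along the
radius. This choice reproduces the study's theoretical pellet shares
(75.1 %/21.3 % for the first pellet and 49.5 %/39.9 % for the second); a
constant-velocity alternative does not (it gives 77.5 %/19.4 %). A
Monte-Carlo oracle — 10⁵ uniformly sampled starting radii propagated
through the exponential trajectory — agrees with the closed form within
three binomial standard errors in the test suite.

`simulate_sequential_fractionation()` chains spins: each run pellets
`remaining × f` per component and passes the rest on at unchanged total
volume. Pellet liquid volume (≈0.5 mL in practice) and sampling aliquots
are deliberately **not** deducted: that bookkeeping reproduces all four
published pellet shares, but not the published theoretical supernatant
figures for the final fraction (84.8 % of the 200 nm input and 2.12 mg/L
of 500 nm; this model yields ≈87 % and ≈1.8 mg/L). The volume accounting
behind those two figures is unstated, so they are documented here as a
known limitation rather than matched. Mass is conserved exactly
(pellet + supernatant = input per component, tested to 1e-12 relative).

## TOC instrument model

- **Replicate rule.** Two injections; if their CV exceeds 2 % a third is
  required and the accepted value is the mean of the two closest
  replicates. CV is the sample (n−1) standard deviation over the mean —
  the instrument's convention is unstated, so this choice is explicit and
  the threshold is a parameter. Identical readings (including all-zero
  blanks) have CV 0 by convention. When the third replicate is equidistant
  from both of the first two there is no unique closest pair; the first
  two are kept (deterministic tie-break).
- **Injection plans.** The volume/calibration-range table is reproduced
  verbatim; particles above 10 µm (strictly: at exactly 10 µm both
  procedures were demonstrated, so the boundary stays with the standard
  one) switch TC to the modified plan (500 µL, range to 50 mg/L).
  Concentrations outside every range yield a dilution suggestion targeting
  5 mg/L, rounded up to one decimal.
- **Injection statistics.** The expected number of particles per injection
  is injected carbon mass over carbon mass per particle,
  $(\pi/6) d^3 \rho_p w_C$; counts are reported both as real values and
  display-rounded (half-up), since published tables print both 18 (from
  18.3) and 34 (from 33.8). The injected count is Poisson; for the 90 µm
  standard plan the mean is 0.676, i.e. a roughly even chance of injecting
  zero particles — the quantitative reason the standard procedure fails for
  large particles. The modified-procedure carbon target defaults to
  25 mg C/L (the planning footnote's value); the published table's 1 µm
  and 10 µm modified counts imply a 20 mg C/L target instead, a
  discrepancy that cannot be resolved from the available information and
  is therefore left to the footnote's value.

## Recovery and uncertainty arithmetic

All recoveries are ratios ×100 with first-order (GUM) propagation:
relative uncertainties in quadrature for products/ratios, absolute in
quadrature for sums/differences, inputs assumed uncorrelated. A
Monte-Carlo oracle (10⁵ normal draws) confirms the propagated uncertainty
within 5 % for the tabulated spiked-water cases. A `linear` rule (straight
addition of relative uncertainties) is available and recorded in every
result object, because the study's own "addition of uncertainties" for the
subtraction estimator is not exactly reproduced by either rule (neither
yields the published ±42.6 percentage points); only the central value
(81.5 %) is treated as reproducible. Negative net TOC values and negative
subtraction residuals are returned unclipped with a machine-readable flag —
they are diagnostic of contamination or interference, not numerical noise.
Displayed recoveries round half-up to integer percent; the ±1 percent
tolerance used in tests absorbs the unknown rounding path of published
values (whether subtraction preceded rounding).

The AF4 recovery follows the ISO definition (eluted mass over injected
mass, "absolute") with the no-crossflow reference variant ("relative");
the compliance flag defaults to the ISO ≥ 70 % threshold and is
configurable. Fraction masses are inputs — fractogram peak integration is
out of scope.

## Synthetic measurement generator

The generator emulates the statistical structure the analysis assumes, so
pipeline properties can be tested without instrument data:

- **TOC replicates** are drawn around the scenario's true channel values
  with stated CVs. The noise law is lognormal parameterised to be
  mean-unbiased (keeps concentrations positive; a truncated normal is
  available for small CVs). The true TC includes particulate carbon,
  dissolved background *and* inorganic carbon, and true TIC the inorganic
  part, so that TC − TIC recovers the organic content — TC is total
  carbon, and a TC that excluded carbonates would make the subtraction
  biased. Default dissolved-carbon backgrounds mimic ultrapure water
  (0.03), river (0.2) and lake (0.87 mg C/L).
- **Unstirred settling loss** attenuates each component by
  $\max(0,\, 1 - v\,t_{\mathrm{dead}}/h_{\mathrm{intake}})$ — linear
  depletion of the syringe intake zone during the dead time. This is
  deliberately simple and illustrative (no quantitative loss model is
  available to calibrate against); it reproduces the qualitative collapse
  of recovery for unstirred 90 µm particles (settling at 1.32 cm/min, a
  2 min dead time empties a 2 cm intake zone completely).
- **Particle-counter observations** see only the 250 nm – 5 µm window
  (200 nm particles are invisible — the situation the subtraction
  estimator exists for), with Poisson counting error plus a multiplicative
  instrument CV.
- **Seeding.** One scenario seed fixes every draw; generator functions
  take integer `stream` offsets so that independent draws within one
  scenario remain individually reproducible.

The pipeline uncertainty attached to synthetic TOC results is type-B,
derived from the declared instrument CVs ($u = \mathrm{CV}\cdot x/\sqrt 2$
per channel, combined in quadrature), not from the 1-degree-of-freedom
sample deviation of a replicate pair — a 3-u interval built on a 1-df
estimate would cover at only ≈80 % and misrepresent the instrument's
stated precision.

What passing synthetic tests does **not** show: robustness to
hetero-aggregation, filter fouling, bacterial growth carbon, surfactant
interference or weathered-particle behavior. None of these are modeled;
they are matrix effects the generator cannot emulate.

## Problem sizes and numerical conventions

The test suite uses 10⁵ Monte-Carlo particles for sedimentation
cross-checks, 10⁵ draws for uncertainty-propagation oracles, 200 seeded
scenarios for the 3-combined-uncertainty coverage property (observed
coverage ≈99 %), and 100 seeded full fractionation experiments for the
subtraction-estimator study. Unbiasedness there is asserted against the
Monte-Carlo standard error (|mean bias| < 3·SE) rather than a fixed
percentage, since with the study-scale CVs (TOC 7 %, counter 10 %) a
single subtraction estimate has a standard deviation near 20 percentage
points — the honest scale of that estimator, and the reason its published
uncertainty budget is large. All closed-form identities (mass
conservation, cutoff/time inversion, RCF round trips, number↔mass
conversion) are tested at 1e-9–1e-12 relative; physical reproduction
targets use the tolerances stated alongside them (0.5 % on cutoffs, 0.3
percentage points on shares, ±1 integer percent on displayed recoveries).
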