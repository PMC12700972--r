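---
title: "Models and methods behind radonlung"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind radonlung}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radonlung)
```

`radonlung` estimates, for a configurable human subject breathing indoor
air containing radon progeny, how many progeny atoms deposit in each
bronchial airway generation per hour, where their alpha decays take place
once mucociliary clearance starts moving them, and what absorbed dose
rates this produces in basal and secretory cell nuclei. This vignette
explains the four coupled models, the parameters that matter, the
numerical choices, and the limits of what the package's tests demonstrate.

## Subjects and exposure

Three presets describe the subjects compared throughout: a healthy adult
man (height 176 cm, FRC 3300 cm^3, VT 500 cm^3, 12 breaths/min, 2.5 s
per breath phase), a 5-year-old child (110 cm, 767 cm^3, 213 cm^3,
25 breaths/min, 1.2 s phases) and an adult with severe asthma (FRC
4000 cm^3, 25 breaths/min with an asymmetric 1 s / 1.4 s cycle,
contracted airways, tracheal mucus slowed from 11.8 to 6.3 mm/min and a
three-fold thicker gel layer). Only quiet nose breathing is modelled.

The default exposure is 40 Bq/m^3 of radon — a world-average indoor
level — with progeny activity ratios 0.58/0.44/0.29 for Po-218, Pb-214
and Bi-214. The package computes the implied equilibrium factor at
runtime from the nuclide constants: each nuclide's potential alpha energy
per unit activity is its remaining chain alpha energy divided by its
decay constant, and the normalised weights contract the activity ratios
to `F`:

```{r}
paec_weights()
equilibrium_factor(c(0.58, 0.44, 0.29))
```

Six percent of the potential alpha energy concentration rides on
unattached ~0.8 nm clusters, split 90/10 (by PAEC) between Po-218 and
Pb-214; the attached mode is lognormal around a 230 nm activity median
diameter. The geometric standard deviation of the attached mode is not a
reported quantity; the default (2.0) is typical of indoor accumulation
modes and a monodisperse mode (`gsd = 1`) exists for tests. The activity
ratios are read as ratios of *total* (attached + unattached) activity,
the most direct reading; the unattached share is then carved out of the
totals. Internally everything is counted in atoms: atoms inhaled per
hour are activity concentration times inhaled air volume divided by the
decay constant.

## Stochastic airway geometry (the synthetic-data stage)

The geometry sampler is the package's synthetic-data generator: it draws
independent root-to-terminal airway paths rather than whole bifurcating
trees, which is sufficient for per-generation statistics. Per-generation
lengths and diameters are lognormal around compiled central values
(a regularised human morphometry with the trachea as generation 1),
with log-scale dispersions of 0.35 (length) and 0.25 (diameter),
an AR(1) correlation of 0.7 between successive diameter deviations, and
rejection (up to 100 redraws) of daughters more than 50 % wider than
their parent. The bronchial/acinar boundary generation is itself random
(range 11–21, mean ≈ 14.3), reflecting that a path may hit its terminal
bronchiole anywhere in that range; a nine-step acinar continuation
follows. Tube orientation against gravity is drawn isotropically and
branching angles from a truncated normal around 35 degrees.

Two subject effects modify the geometry. Height scaling: all bronchial
dimensions scale linearly with height over the 176 cm reference (0.625
for the child); the acinar part instead scales with the cube root of the
FRC ratio so the distensible region tracks the subject's resting lung
volume — the geometry/volume split is genuinely open, and the choice is
exposed as `frc_acinar_scaling`. Asthma: each bronchial tube is
independently contracted with a per-generation probability (0 % in the
trachea rising to 75 % from generation 9) and extent (up to 25 %
diameter reduction).

What the generator does *not* emulate: sibling asymmetry and
flow-splitting correlations within a real tree, cartilage/wall detail,
intra-bifurcation geometry, or imaging-derived individual anatomy.
Passing tests therefore demonstrate correctness of the configured
statistical model, not anatomical fidelity beyond per-generation
summary statistics.

## Aerosol deposition

A particle enters the nose at a uniformly random time in the inhalation
phase and is advected by square-wave plug flow (flow = VT / phase
duration; flow in generation g is the tracheal flow divided by
2^(g−1)). The volume inhaled behind the particle fixes its penetration
depth against cumulative airway volume: nasal dead space (50 cm^3 for
the adult, scaled with height cubed), the sampled bronchial tubes, and
FRC-derived acinar compartments that double in volume per step. The
deepest segment accrues the end-inspiratory dwell; exhalation retraces
the path and ends with a second nasal pass. Particles airborne after
exhalation count as exhaled.

Per tube transit, deposition combines three mechanisms by complement
product (independent-mechanism approximation): an Ingham-type diffusion
efficiency written in residence-time form (Graetz parameter
`D t / (4 R^2)`, identical to the classic `pi D L / 4 Q` for flow
transits but also valid for the parked end-inspiratory dwell), an
exponential inclined-tube settling term, and a Stokes-number impaction
term weighted by the branching angle.

The nasal (extrathoracic) filter uses the empirical two-regime form for
nose breathing: diffusion `1 − exp(−a D^p Q^−q h^−s)` (D in cm^2/s, Q in
L/min, h the subject's linear nasal scale) and the logarithmic inertial
form `−0.62 + 0.475 log10(d_ae^2 Q)` clamped to [0, 1]. Published fits
of this family differ in their coefficients with the measurement
geometry, so the constants shipped in `extrathoracic_constants()`
(a = 24.7, p = 0.42, q = 0.40, s = 0.39) were anchored once against the
reported extrathoracic deposition of ultrafine clusters and of the
230 nm attached mode at quiet adult, child and asthmatic breathing, and
are pinned in configuration; swapping in an alternative fit requires no
code change.

Numerically, fractions are scored with the expected-value estimator:
each history contributes its survival-weighted deposition probability to
every segment it visits, while an analog Bernoulli draw still decides
its integer fate. The expectation estimator is unbiased for the same
fractions but far less noisy, which matters for the argmax-type summary
(the generation of maximum deposition rate); the analog fates provide
exact particle accounting. Deposition rates are fractions times the
per-nuclide atoms inhaled per hour, so rates inherit exact linearity in
the radon concentration.

## Clearance and the decay chain

Deposited atoms immediately join the gel layer and move proximally; the
mucus velocity is 11.8 mm/min in the healthy adult trachea (6.3 for the
asthmatic, 2.7 for the child) and attenuates by 0.67 per generation
distally. An atom deposited at generation g with a given axial position
yields a residence schedule — length over velocity, generation by
generation — until it exits the trachea, after which it is no longer
tracked. Acinar deposits are not cleared: they decay in place and are
tallied separately, excluded from the bronchial dose.

Over each residence interval the chain
Po-218 → Pb-214 → Bi-214 → Po-214 is evolved with closed-form Bateman
solutions; the expected 6.00 MeV (Po-218) and 7.69 MeV (Po-214) decays
are credited to the generation occupied at the time. Po-214's 0.164 ms
half-life is negligible against any transport time, so its decay is
assigned to the site of the parent Bi-214 decay. Daughters ride the same
mucus parcel (no recoil relocation), and airborne-phase decays are
neglected — the breath cycle is seconds against half-lives of minutes.
Deposits occur uniformly over a one-hour exposure and every decay
between deposition and trachea exit is credited to that hour; the
alternative of truncating at the hour is a flag on the tally. A Monte
Carlo mode that samples explicit exponential decay times cross-validates
the analytic tally (its per-bin standard errors carry a half-count floor
so empty bins do not claim zero uncertainty). The pipeline averages the
axial deposit position over a five-point grid per tube.

## Microdosimetry

Each bronchial generation is represented by a cylindrical airway with
the subject's central diameter (expected contraction applied for the
asthmatic), a gel layer anchored at 5 um (adult, generation 3) scaling
with the local diameter — times three for asthma, times the height ratio
for the child — above a 6 um sol layer, and target cell nuclei at 25
depths from 2 to 50 um below the epithelium top. Depth weights per
region class (large bronchi > 3 mm, bronchi 1–3 mm, terminal
bronchioles < 1 mm, strict thresholds, assigned by tube diameter rather
than generation number) are a shipped, editable configuration; the
absence of basal cells in terminal bronchioles is enforced structurally.

Decay sites are uniform in radius over the gel annulus and uniform over
the airway surface. Alpha particles travel on straight lines under the
continuous-slowing-down approximation with an embedded stopping-power
table for unit-density tissue (CSDA ranges ≈ 48 um at 6.00 MeV and
≈ 69 um at 7.69 MeV); lumen air is traversed without loss. Ray/layer
path lengths are exact cylinder-shell chords (a plane-parallel slab mode
exists for comparison), so cross-lumen irradiation of the far wall is
included.

For each generation, cell type and energy the estimator samples
emission points, target depths and isotropic directions and reports
three quantities: the reach probability (the chance the track attains
the nucleus depth with residual energy — the weighting-factor quantity),
the mean energy imparted in a nucleus chord conditional on reach, and
the expected energy per decay delivered to one nucleus, which folds in
the geometric factor `pi rho^2 sec(gamma) / A` (nucleus cross-section
over tube shell area, crossing-angle corrected, with the secant capped
at 50 to keep grazing crossings finite). The last quantity is what the
dose rate uses; it equals the naive pair-sampling estimate (random
nucleus, random direction, exact ray/sphere intersection) but with
orders of magnitude less variance, and the two are compared directly in
the test suite. The nucleus is a unit-density 8 um sphere; neither value
is a reported quantity, and absolute dose magnitudes scale inversely
with the nucleus mass while all ratios and orderings are insensitive to
it.

Dose rate per generation and cell type is the sum over the two alpha
energies of decays per hour times energy per decay per nucleus, divided
by the nucleus mass, in uGy/h.

## Reproducibility and problem sizes

A single master seed expands into fixed per-stage substreams (geometry,
deposition, decay, dosimetry), so identical configurations reproduce
identical tables and stages can be rerun independently. Default
production sizes are 10^4 deposition histories per carrier mode and
10^5 dosimetry samples per generation/cell type/energy. The test suite
exercises the same code at reduced sizes (typically 10^3–10^4 histories
and 3·10^3–2·10^5 dosimetry samples) chosen so that every statistical
check retains comfortable power; the decay-chain cross-validation uses
10^5 Monte Carlo atoms and the dosimetry brute-force comparison 10^6
pair samples on a short tube.

## Known limitations

Deposition within a single bifurcation is highly inhomogeneous in
reality; the model reports generation averages only. Translocation to
blood and tissue is neglected (short half-lives make mucus escape
unlikely, but this can overestimate dose). The asthma contraction and
mucus parameters describe one severe phenotype; real patients vary
widely, and the balance between the dose-raising effects of contraction
and slower clearance versus the shielding of thicker mucus shifts with
severity. The same cell-depth distribution is used for all subjects for
lack of age-specific data, and the depth-weight profiles themselves are
synthetic stand-ins with the correct structural features rather than
measured histology. Beta and gamma doses from Pb-214/Bi-214 are not
tallied; only alpha decays contribute.
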