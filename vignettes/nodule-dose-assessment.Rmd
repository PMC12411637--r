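---
title: "Methods: occupational NORM doses from polymetallic nodules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: occupational NORM doses from polymetallic nodules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noduledose)
```

## The assessment problem

Deep-sea polymetallic nodules are naturally occurring radioactive material
(NORM). Their radiological fingerprint is a vector of specific activities
of the long-lived members of the three natural decay series; the packaged
bulk vector has Ra-226 at 2317 Bq/kg, large unsupported Th-230 (620 Bq/kg)
and appreciable Ac-227 and Pa-231, each with a relative measurement
uncertainty between 13% and 45%. No industrial-scale nodule facilities
exist yet, so the package evaluates *generic, deliberately conservative*
scenarios: a reference person in the engine room of a transport bulk
carrier, and one covering every workplace of a pyrometallurgical
processing plant. Doses are annual effective doses in mSv/a, assessed
against the 1 mSv/a classification benchmark for NORM workplaces and the
20 mSv/a limit for occupationally exposed workers. Ingestion is excluded
throughout, assuming standard occupational hygiene.

## Pathway models and their assumptions

### External gamma

The gamma field next to stored nodule material is dominated by the
short-lived daughters of Ra-226 (Pb-214, Bi-214), largely in secular
equilibrium with it, so the ambient dose equivalent rate is modelled as
proportional to the Ra-226 specific activity alone:

\[ H^*(10) = \mathrm{ADR}_{\mathrm{geom}} \cdot C_{\mathrm{Ra\text{-}226}}\,[\mathrm{Bq/g}], \qquad
E_{\gamma} = f_{\mathrm{con}} \cdot H^*(10) \cdot t_{\mathrm{exp}} \cdot a_s . \]

The geometry factors (µSv/h per Bq/g) are tabulated data, not computed
from transport physics: 0.5 for a laterally extended surface, 0.4/0.2 for
a cone-shaped pile (surface / 1 m), 0.3/0.07 for a 1-m³ big bag, 0.3/0.15
for two big bags. An inverse-square helper extrapolates beyond distances
comparable to the source's lateral dimensions, but it is explicitly an
approximation and the tabulated 1-m values take precedence. Two
conventions matter and are fixed here: `a_s` is the *transmitted*
fraction ("shielding by 50%" means `a_s = 0.5`), and the factor-of-1000
in the dose-rate relation is the Bq/kg→Bq/g unit conversion, so all
internal gamma arithmetic runs in Bq/g. Gamma from the low-activity
Th-232 series and from airborne radon progeny is neglected as negligible
against the Ra-226 chain.

### Dust inhalation

\[ E_{\mathrm{dust}} = \dot V \cdot t_{\mathrm{exp}} \cdot \sum_i g_{\mathrm{inh},i} \, C_{\mathrm{air},i},
\qquad C_{\mathrm{air},i} = C_{\mathrm{dust}} \cdot C_i \cdot (1 - f_{\mathrm{inh}}) . \]

The packaged coefficient table holds the occupational inhalation dose
coefficients for AMAD 5 µm aerosols, absorption class S for the thorium
isotopes, F for Ac-227, M otherwise, and only nuclides with coefficients
above 0.1 µSv/Bq — anything below the cutoff is simply absent and
contributes zero. The dust is assumed to carry the bulk material's
nuclide vector; there is no particle-size enrichment or lung-deposition
modelling beyond the fixed coefficient table. Airborne dust defaults are
the maximum allowable concentrations for alveolar dust: 1.25 mg/m³ in
routine plant areas and 3 mg/m³ for occasional work (filter
maintenance). The breathing rate default is 1.2 m³/h (light work). The
respirator factor defaults to 0 (no mask) for conservatism; an FFP-2 mask
would remove up to 94% of the inhaled dust.

A useful identity, exploited by the tests: the dust dose factorises as
`V̇ · t · C_dust · (1 − f_inh) · unit_dust_dose(material)`, where the unit
dust dose (µSv per mg inhaled) is a property of the material alone —
0.060, 0.132 and 0.035 µSv/mg for nodules, third-reduction slag and flue
dust respectively, dominated by Ac-227 and Th-230.

### Radon

For a nodule layer much thicker than the diffusion length (> 3 m), the
exhalation rate of an extended source is

\[ P = C_{\mathrm{Ra\text{-}226}} \cdot E(\Theta) \cdot \rho \cdot \sqrt{D_{\mathrm{bulk}}/\lambda} \cdot \lambda,
\qquad D_{\mathrm{bulk}} = D_{\mathrm{MA}} \cdot R_{\mathrm{por}} , \]

with emanation factor `E = 0.36` for dry nodules (the conservative
choice; saturated nodules exhale roughly half as much, and wet scenarios
require a user-supplied emanation factor since no measured wet value is
packaged), bulk density 3300 kg/m³, porosity 0.6 and molecular diffusion
of radon in air `D_MA = 1e-5 m²/s`. The Rn-222 decay constant is kept at
2.1e-6 1/s — two significant figures, the precision the assessment it
reproduces works at — rather than the textbook 2.0993e-6.

Indoors, one well-mixed compartment balances entry against decay and
ventilation, `dC/dt = e' + vC_a − (λ+v)C`; the steady state is
`C = e'/(λ+v)` with the outdoor term defaulting to zero, and the
transient solution is the closed-form exponential relaxation (verified in
the tests against a stiff-integrator oracle). Two source terms feed it:
surface exhalation `e' = P·A/V`, with the *effective exhaling area equal
to the hold footprint* (only the top surface of the layer feeds the head
space — radon produced deeper stays in the voids when diffusion is the
only transport mechanism); and comminution release
`R = C_Ra-226 · f_com · pc` with release fraction 0.3 and processing
capacity 95 kg/s, of which half is assumed to occur indoors. The radon
dose is `E = C_Rn · t · F · DCF` with equilibrium factor 0.4 and the
ICRP 65 coefficient 7.8e-6 mSv·m³/(Bq·h) — the coefficient current
German regulation is built on (an exposure of 0.32 MBq·h/m³ at F = 0.4
gives ~1 mSv, which the tests verify by unit algebra). The newer ICRP 137
equilibrium-equivalent coefficient (~10 mSv per working-level month,
1.6e-5 mSv·m³/(Bq·h)) is exposed as the constant `DCF_ICRP137` but never
used by default. There is no multi-zone ventilation network and no
progeny attachment/plate-out model — the equilibrium factor subsumes
progeny behaviour.

A symbol note: in the source formulation the letter R denotes both the
nodule porosity and the comminution source term; the package keeps them
apart as `porosity` and `R_source`.

### Flowsheet enrichment

Complete transfer of the nuclides from 3 Mt/a of feed into 1.374 Mt/a of
third-reduction slag enriches specific activities by the mass ratio
(2.18, reported as 2.2); the volatile Pb-210 and Po-210 (boiling off at
1450 °C) transfer into 0.297 Mt/a of flue dust (ratio 10.1). Both
volatiles are *also* retained in the slag vector by default
(`double_count_volatiles_in_slag = TRUE`), deliberately double-counting
them so slag dust doses are not underestimated. Slags of the earlier
reduction stages and dryer dust carry significantly lower concentrations
and are not assessed by default. Partition fractions are inputs — there
is no thermochemical modelling.

`apply_flowsheet()` has two arithmetic modes. `"exact"` applies the
full-precision mass ratios, so activity conservation
`C_out·M_out = C_in·M_in` holds to machine precision (the tests check a
residual of ~1e-16). `"printed"` (default) reproduces the published
stream tables: the enrichment factor is rounded to two significant
figures *before* application and the result rounded to integer Bq/kg.
This was a genuinely open choice: the published derived columns cannot be
regenerated bit-exactly from the published integer feed activities under
any convention (they were evidently computed from unrounded measurement
data — e.g. the printed flue-dust values back-solve to a factor of
exactly 10 on unrounded activities, while the stated mass ratio is 10.1).
The 2-s.f. mode reproduces every printed value within the quantisation of
the integer-rounded inputs (±1 Bq/kg for slag, ±5 Bq/kg for dust), which
is the tolerance the tests assert; published-table comparisons elsewhere
in the suite use one unit in the last printed digit for the same reason
(the published dose table itself mixes rounding conventions: a computed
0.0856 appears as 0.08 while 0.1979 appears as 0.2).

## Scenario composition

A scenario binds pathway configurations to materials from a named
inventory and sums the pathway doses. Radon is reported separately from
the gamma+dust subtotal, because its concentration depends on facility
design and ventilation rather than on the handled mass alone; the
packaged processing scenario uses the fixed 300 Bq/m³ indoor reference
concentration over 2000 h. The surface-layer sensitivity multiplier
(default 1, the ×3 case representing the up-to-threefold higher activity
of the outer ~1 mm of the nodules) scales the material activities — and
therefore the gamma and dust doses exactly linearly — while a fixed radon
concentration, not being material-derived, is held constant. The two
exposure-time budgets (1824 h/a across the gamma+dust pathways vs 2000 h
for radon) are intentionally independent per pathway, as in the
assessment being reproduced. Classification flags compare the total
against 1 mSv/a (occupationally exposed at or above) and 20 mSv/a.

## The synthetic-data generator

`sample_nuclide_vectors()` emulates the measurement variability of the
activity vectors: each nuclide is drawn from a lognormal parameterised so
that the *arithmetic mean* equals the measured value and the CV equals
the printed relative uncertainty. The mean-preserving (rather than
median-preserving) parameterisation is deliberate: every pathway is
linear in the activities, so the expected Monte Carlo dose coincides with
the deterministic central dose — a property the tests verify at
n = 5000. Nuclides are sampled independently by default; an optional
common-mode lognormal multiplier models correlated enrichment (as in the
surface layer, where whole-vector activity rises together). The derived
streams (slag, flue dust) carry the parent nodule uncertainties, since
deterministic mass-ratio scaling leaves CVs unchanged. Scenario
parameters can be perturbed within bounded ranges, and the surface-layer
multiplier is drawn uniformly from [1, 3] by default.

What the generator does *not* emulate: inter-site variability structure
(the measured vectors are averages over sampling locations), correlations
between parent–daughter pairs induced by decay-series relationships,
distribution shape information (the measurements publish only means and
relative uncertainties — lognormality is this package's modelling choice,
standard for strictly positive environmental activities), or any
time-dependence. Passing Monte Carlo tests therefore demonstrate correct
propagation of the *stated* second moments through the dose models, not
that real nodule shipments follow these distributions.

Randomness is seeded explicitly per `sampling_spec`; sampling runs in a
private RNG stream (the caller's `.Random.seed` is saved and restored),
and sub-seeds for each material are drawn below 2³¹.

## Numerical choices

* Activities are stored in Bq/kg, coefficients in µSv/Bq, dose rates in
  µSv/h and reports in mSv/a; all conversions live in one constants file,
  because unit slips (Bq/kg vs Bq/g, µSv vs mSv) are the dominant failure
  mode when reproducing this kind of assessment.
* Ventilation rates are converted exactly (1/h = 1/3600 1/s). Using the
  rounded 3e-4 1/s for one air change per hour shifts the cargo-hold
  steady state from ~6980 to ~6470 Bq/m³ — enough to change the reported
  rounded value — so rounded per-second rates are never used internally.
* Rounding to the published precision happens only at the reporting
  layer (and in the flowsheet's explicit `"printed"` mode); all internal
  computation is full precision.
* Degenerate inputs are handled explicitly: empty nuclide vectors give
  zero dose; zero emanation, zero exposure time or a perfect respirator
  give exactly zero; a zero-ventilation enclosure accumulates to `e'/λ`;
  `λ + v = 0` is rejected as having no sink.
* Monte Carlo problem sizes: the test suite uses 5000 draws for mean
  recovery (sampling error ≪ the 5% assertion tolerance), 10000 for
  moment recovery of a single nuclide, and the analysis scripts use 2000
  draws; all sizes are comfortable for the linear, closed-form pathway
  evaluations.

## Known limitations

* Geometry factors are scalar data for four standard configurations; no
  photon transport, buildup or attenuation physics beyond the scalar
  shielding transmission and the approximate inverse-square helper.
* No decay-chain ingrowth (Bateman) computation — activities are taken as
  measured, appropriate for the assessment horizon but not for long-term
  storage predictions.
* The radon compartment is single-zone and well-mixed; stratification,
  plate-out and multi-room air flows are outside scope.
* Natural background is implicitly contained in the measured vectors; no
  separate background term is added or subtracted.
* The laboratory-scale workplace assessments that accompany the
  industrial scenarios in the source material rely on supplementary data
  not reproduced here and are out of scope.
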