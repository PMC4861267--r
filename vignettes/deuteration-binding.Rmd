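---
title: "Modeling deuteration effects on ligand-receptor binding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling deuteration effects on ligand-receptor binding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoshift)
```

## The problem

When a ligand is assayed in heavy water, its exchangeable protons -- the
hydrogens on nitrogen and oxygen -- swap for deuterium, while C-H
hydrogens do not. Because an X-D bond is effectively shorter than the
same X-H bond, every hydrogen bond the ligand makes (with water, and
with its receptor) is slightly weakened, and the donor-acceptor
heavy-atom distance relaxes outward: the Ubbelohde effect. Whether the
ligand ends up binding its receptor more or less tightly depends on a
balance -- deuteration costs the ligand some hydration energy *and* some
receptor-interaction energy, and the binding shift is the difference of
the two losses. `isoshift` implements the desk-scale pipeline for
studying this balance end to end:

1. **Synthetic assay data** with the statistical structure of
   radioligand saturation and competition experiments.
2. **Nonlinear fitting** of those assays: $K_D$, $B_{max}$, pIC50 and
   Hill slope, with Welch comparisons between conditions.
3. **Thermodynamics**: binding constants to free energies and the
   deuteration shift $\Delta G_{BIND}(H \to D) = -RT\,\ln(K_D/K_H)$.
4. **Geometry**: detection of exchangeable hydrogens and the empirical
   bond-contraction protocol for nuclear quantization, emitting
   frozen-coordinate constraints for an external optimizer.
5. **Cycle bookkeeping**: hydration and receptor-interaction legs
   combined into $\Delta\Delta E_{BIND}(H \to D) =
   \Delta E_{INTER}(H \to D) - \Delta E_{HYDR}(H \to D)$.
6. **A surrogate energy model** so the geometric protocol and the cycle
   can be exercised and tested without external quantum chemistry.

## Assay simulation

Saturation assays follow the one-site model with a linear nonspecific
component,

$$B_{spec}(L) = \frac{B_{max} L}{K_D + L}, \qquad
  B_{ns}(L) = m_{ns} L, \qquad B_{tot} = B_{spec} + B_{ns},$$

on a default grid of 8 radioligand concentrations spanning 1-15 nM.
Competition assays follow the four-parameter logistic in
$\log_{10}$-concentration,

$$y(x) = bottom + \frac{top - bottom}
  {1 + 10^{(\log_{10} x + \mathrm{pIC50})\,h}},$$

on a default grid of 10 concentrations log-spaced over 0.01 nM to 100
uM. Both defaults mirror the concentration ranges of the tiotidine /
histamine-receptor assay design the package emulates.

Noise is additive, homoscedastic and Gaussian: experiments of this kind
are reported as mean +/- SEM of triplicates with no stated variance
model, and the simplest model consistent with that reporting is
independent Gaussian error per replicate. The generator adds
independent noise to the specific and nonspecific signals and returns
their sum as the total, so `specific = total - nonspecific` holds
identically in every dataset, noisy or not, and the specific column has
SD exactly `noise_sd`. Negative noisy responses are kept, not clipped
-- low-concentration points in real filter-binding data go negative
after background subtraction, and the fitting code must cope.

The default nonspecific slope (0.24 fmol/mg per nM) puts nonspecific
binding near 20% of total binding at 15 nM, a realistic fraction for a
washed-membrane assay; assays in heavy water are reported with cleanly
linear nonspecific binding, which is what the generator produces.

Three toy hydrogen-bonded clusters (`water_pentamer`,
`imidazolium_acetate`, `donor_acceptor_pair`) provide structural
fixtures with explicit bonds and fixed internal charge tables
(TIP3P-like water: O $-0.834$, H $+0.417$; the ion-pair charges are a
self-consistent set summing to $\pm 1$). Any self-consistent set would
do: the surrogate model needs signs and rough magnitudes, not fitted
charges.

**What the generator does not emulate:** radioactive counting
statistics (Poisson), filter-binding losses, protein-content
normalization error, inter-experiment variability, or receptor-state
heterogeneity. Passing recovery tests therefore show that the
estimators are correct for the stated error model, not that they are
robust to every pathology of real count data.

## Fitting

```{r fit-example}
truth <- assay_truth("saturation", K_D = 4.7e-9, B_max = 18.6,
                     noise_sd = 0.07 * 18.6, seed = 1)
fit_saturation(gen_saturation(truth))
```

Both fits use Levenberg-Marquardt least squares (`minpack.lm::nlsLM`).
Design choices:

* **Parameterization.** Competition curves are fit in pIC50 (log)
  space, the standard, well-conditioned choice; IC50 is reported by
  back-transform. An IC50-space parameterization (`space = "ic50"`) is
  provided and lands on the same optimum (the package tests require
  agreement to $10^{-4}$ in pIC50). Saturation fits rescale molar
  concentrations to nM internally so both parameters are O(1)-O(10).
* **Starting values.** $K_D$ starts at the concentration nearest
  half-maximal mean response, $B_{max}$ at 1.1x the maximal specific
  response, pIC50 at the grid point nearest the plateau midpoint, Hill
  at 1.
* **Uncertainties.** SEs come from the local covariance
  $(J'J)^{-1} s^2$; a seeded residual-resampling bootstrap
  (`se = "bootstrap"`, default 1000 resamples) is available when the
  quadratic approximation is suspect.
* **Constraints and gates.** `fix_hill = 1` reproduces a one-site
  competition fit; `fix_bottom = TRUE` pins the lower plateau at 0 when
  the curve never samples it. A curve whose mean response does not fall
  by at least 10% of its dynamic range between the lowest and highest
  displacer concentration is rejected as showing no displacement, and
  degenerate inputs (fewer than 4 or 5 distinct concentrations,
  all-zero responses) raise errors instead of returning garbage.
* **Units.** Concentrations are molar everywhere in the API; nM
  appears only inside the optimizer and in printed output.

Group comparisons use Welch's unpaired t-test computed from summary
statistics (mean, SE, n), because fitted binding parameters arrive as
mean +/- SE, not as raw samples. The default $n = 6$ corresponds to two
experiments in triplicate; the 0.05 threshold is reported, never acted
on.

## Thermodynamics

The sign convention is $\Delta G = RT \ln K$ with $K$ a *dissociation*
constant in molar units against the 1 M standard state, so sub-molar
$K$ gives negative $\Delta G$ and tighter binding is more negative. The
deuteration shift $-RT \ln(K_D/K_H)$ is positive when the deuterated
ligand binds more tightly. Temperature defaults to 298.15 K (assays at
25 C); $R = 1.98720425 \times 10^{-3}$ kcal mol$^{-1}$ K$^{-1}$.

```{r thermo}
c(dG_H = dg_from_k(56e-9), dG_D = dg_from_k(16e-9),
  ddG = ddg_deuteration(56e-9, 16e-9))
```

Note that free energies recomputed from rounded nanomolar constants are
sensitive to the $RT$ used: chains of published values rounded to two
decimals can differ from a direct evaluation at 298.15 K by a few
hundredths of a kcal/mol. The package always computes; it never stores
a published chain.

## The deuteration geometry protocol

Classical geometry optimization cannot distinguish H from D, so the
package uses an empirical quantization: contract every acidic X-H bond
(X = N, O) by a fixed fraction and freeze it. The default 2.3% is the
contraction measured for the N-D bond of the alanine zwitterion by
neutron diffraction; it is applied to O-H donors as well, and is
configurable. Only the hydrogen moves, along the donor-to-hydrogen
direction; heavy atoms (and any atoms pre-flagged frozen, such as the
alpha-carbons of a truncated binding-site cluster) are bitwise
untouched. The transform emits a plain-text constraint table (frozen
bonds with 6-decimal target lengths, frozen atoms) for whatever
external optimizer performs the subsequent constrained relaxation --
the package deliberately performs no re-optimization itself.

Two deliberate sharp edges: applying the transform twice would contract
twice, so the output carries a provenance flag and re-application is an
error; and a hydrogen bonded to two donors has no unique contraction
axis, so detection fails loudly with the atom indices rather than
guessing. We move only the hydrogen: acceptor lone-pair geometry is not
adjusted, and every N-H/O-H in the input is scaled (no attempt to
classify which sites exchange slowly).

Bond perception for XYZ input uses distance cutoffs (N-H/O-H 1.25 A,
other X-H 1.35 A, heavy-heavy 1.85 A, H-H never); explicit PDB CONECT
records win when present.

## Cycle bookkeeping

Binding is decomposed into two legs. The hydration leg uses a
homodesmotic scheme -- ligand plus a water pentamer reacting to the
ligand-five-water cluster conserves the hydrogen-bond count on both
sides, cancelling systematic errors -- and the interaction leg is

$$\Delta E_{INTER} = E_{complex}^{\varepsilon=prot}
  - (E_{ligand}^{\varepsilon=water} + E_{receptor}^{\varepsilon=prot}).$$

Component energies arrive as a TSV of records (species, isotope,
dielectric, energy, method tag) rather than being parsed from any
quantum-chemistry package's output files; that keeps the bookkeeping
backend-agnostic, and a worked synthetic example ships in
`inst/extdata/synthetic_m062x_eps4.tsv` (component values are invented;
only their leg differences are meaningful). Conventions, all enforced:

* $\Delta E_{BIND}(i) = \Delta E_{INTER}(i) - \Delta E_{HYDR}(i)$ per
  isotope, exactly.
* Every H-to-D difference is $X(H) - X(D)$, so a positive
  $\Delta\Delta E_{BIND}$ means the deuterated ligand binds more
  tightly.
* Energies are electronic only -- no zero-point or thermal fields
  exist in the record type, mirroring the cycle's own convention.
* Legs carrying different method tags refuse to combine; missing
  records raise errors naming (species, isotope, dielectric).
* `cycle_table()` re-derives $\Delta\Delta E_{BIND}$ from the legs and
  warns if a stored value drifts by more than 0.005 kcal/mol.

A geometric hydrogen-bond counter (donor-acceptor < 3.5 A, D-H...A
angle > 120 degrees) supports the homodesmotic accounting.

```{r cycle}
cy <- deuteration_shift(-67.45, -67.39, -39.64, -40.09,
                        method = "M06-2X", eps = 4)
cy
```

## The surrogate energy model

`total_energy()` is an artifact of this package: a deliberately simple
function embodying the dipole-charge rationalization of the hydrogen
bond isotope effect, so the geometry protocol and the cycle can be
exercised end to end. It is **not** an approximation to any
quantum-chemical surface, and its absolute magnitudes mean nothing.

$$E = \sum_{\substack{i<j\\ \mathrm{non-bonded}}}
      \frac{k_C\, q_i q_j}{\varepsilon\, r_{ij}}
  \;-\; \sum_{\mathrm{H-bonds}}
      \frac{k_{HB}\; \mu_{XH}\, |q_{acc}|}{\varepsilon\, d^2}
  \;+\; \sum_{\mathrm{H-bonds}} k_{rep}
      \left(\frac{r_{min}}{R}\right)^{12},$$

with $\mu_{XH} = |q_H| \cdot r_{XH}$ the donor-bond dipole, $d$ the
H...acceptor distance, and $R$ the donor-acceptor heavy-atom distance.

Design choices worth recording:

* **Exchangeable hydrogens are not Coulomb point charges.** Their
  charge is folded into the donor heavy atom, and they act only
  through the bond-dipole term. This makes the electrostatics exactly
  invariant under the contraction transform, so the *entire* isotope
  effect flows through the hydrogen-bond term -- which is the
  mechanism being modeled: contracting the bond shrinks $\mu_{XH}$ by
  exactly the contraction fraction and lengthens $d$, weakening the
  bond. It also yields clean testable properties: with $k_{HB} = 0$
  the protiated and deuterated surfaces are identical, and deuteration
  can never strengthen a hydrogen bond. C-H hydrogens (never moved)
  keep their point charges.
* **Exclusions.** Only 1-2 (bonded) pairs are excluded from the
  Coulomb sum -- the simplest consistent scheme; no 1-3/1-4 scaling.
* **The repulsive core** attaches to gated donor-acceptor pairs, where
  it is needed to keep the scanned hydrogen bond from collapsing; pure
  point-charge fixtures remain exact Coulomb sums. Defaults
  $r_{min} = 2.9$ A (a typical O...O hydrogen-bond distance) and
  $k_{rep} = 1.2$ kcal/mol balance the dipole-charge attraction so an
  isolated water-water hydrogen bond has its minimum near 2.9 A,
  comfortably interior to the default 2.6-3.6 A scan window.
* **$k_{HB} = 54$** puts the water-water hydrogen-bond term near
  $-5$ kcal/mol at $\varepsilon = 1$, a textbook magnitude.
* **Dielectric** enters as a uniform $1/\varepsilon$ screen, mimicking
  the use of a continuum-solvent dielectric as a bulk parameter.
* **Geometric gates** (3.5 A, 120 degrees) switch the hydrogen-bond
  and core terms on and off discontinuously. That is harmless for the
  fixtures used here but means the surface is not smooth at the gate
  boundary -- another reason it must never be optimized on.

`scan_heavy_distance()` translates the acceptor fragment rigidly along
the donor-acceptor axis and reports the energy minimum, which must be
interior to the grid. On the water-dimer fixture the protiated minimum
sits at 2.90 A and the contracted (deuterated) copy at 2.92 A -- the
Ubbelohde elongation emerging from the functional form rather than
being imposed:

```{r scan}
da <- gen_toy_cluster("donor_acceptor_pair")
dd <- apply_ubbelohde(da)$structure
c(H = scan_minimum(scan_heavy_distance(da)),
  D = scan_minimum(scan_heavy_distance(dd)))
```

`toy_cycle()` runs the full pipeline on ammonium-water clusters. Since
deuteration weakens every hydrogen bond, each leg individually favors
the protiated species; the *net* binding shift takes the sign of
whichever leg has more to lose. With equal dielectrics, three
hydration-side bonds against one interaction-side bond gives a positive
shift (deuterated binds tighter) and the mirrored system gives its
exact negation -- the two-fixture demonstration that the cycle, not
either leg alone, decides the sign.

## Problem sizes and numerical tolerances

The recovery studies run 200 seeded datasets per condition (and 100 in
the faster unit tests), triplicates at 8 saturation / 10 competition
concentrations, with 7% (saturation) and 5% (competition) noise --
sizes chosen to estimate means to well under the 10% acceptance band
while keeping the full suite in the tens of seconds. Noiseless fits
must recover generating parameters to $10^{-6}$ relative; the
contraction ratio is checked to $10^{-12}$; cycle identities to
$10^{-12}$; the pairwise-sum oracle to $10^{-10}$; rigid-body
invariance to $10^{-9}$ (absolute, kcal/mol).

## Limitations

* The surrogate energy model has no polarization, no dispersion, no
  geometry optimization, and gates that make its surface
  discontinuous; it supports property tests and demonstrations only.
* The assay generator's error model is Gaussian and homoscedastic;
  count-based heteroscedasticity is out of scope.
* The cycle module books energies; it cannot validate that the
  dielectric assignments of an input table are physically sensible
  beyond role consistency.
* Protonation-state assignment, tautomer enumeration, hydrogen
  addition to heavy-atom-only structures, and any actual quantum
  chemistry or molecular dynamics are out of scope.
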