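# isoshift

Deuteration effects on ligand–receptor binding affinity.

When a binding assay is run in heavy water, the ligand's exchangeable
protons (N–H, O–H) swap for deuterium while C–H hydrogens do not. The
effectively shorter X–D bond carries a smaller bond dipole, weakening
every hydrogen bond the ligand makes and relaxing donor···acceptor
distances outward (the Ubbelohde effect). Binding affinity can go
either way: the ligand loses hydration energy *and*
receptor-interaction energy, and the measurable shift is the difference
of the two losses. `isoshift` is for pharmacologists and modelers who
want to quantify that balance, from the raw radioligand assay to the
thermodynamic cycle.

The core quantities:

* experimental — saturation binding
  `B(L) = B_max·L/(K_D + L)` (+ linear nonspecific), competition
  binding as a four-parameter logistic in log₁₀ concentration
  (pIC50, Hill slope), and the deuteration shift
  `ΔG_BIND(H→D) = −RT ln(K_D/K_H)` from the fitted binding constants;
* computational — the empirical nuclear-quantization protocol
  (contract every acidic X–H bond by 2.3% and freeze it), and the
  two-leg cycle
  `ΔΔE_BIND(H→D) = ΔE_INTER(H→D) − ΔE_HYDR(H→D)`,
  with `ΔE_INTER = E_complex − (E_ligand + E_receptor)` and a
  homodesmotic five-water hydration scheme;
* a surrogate point-charge/bond-dipole energy model that lets the whole
  pipeline run and be tested end to end without external quantum
  chemistry.

## Worked example

Simulate a competition assay in normal and heavy water, fit both
curves, compare, and convert to a free-energy shift:

```r
library(isoshift)

truth_H <- assay_truth("competition", pIC50 = 7.25, hill = 1.0,
                       top = 100, bottom = 0, noise_sd = 4, seed = 101)
truth_D <- assay_truth("competition", pIC50 = 7.80, hill = 1.1,
                       top = 100, bottom = 0, noise_sd = 4, seed = 202)
fit_H <- fit_competition(gen_competition(truth_H))
fit_D <- fit_competition(gen_competition(truth_D))
fit_H
#> <competition_fit> converged (RSS 321.5, IC50 5.73e-08 M)
#>   param   estimate         se     units
#>   pIC50  7.2415981 0.03595595 -log10(M)
#>    hill  0.9724326 0.06986386
#>     top 99.8259732 1.14334692      resp
#>  bottom -0.7428706 1.27455038      resp

compare_fits(fit_H, fit_D, "pIC50")
#> <welch_comparison> pIC50: 7.242 vs 7.795, t = -10.612 (df 10.0), p = 9.39e-07

ddg_deuteration(fit_H$IC50, fit_D$IC50)
#> [1] 0.7566334
```

The fitted half-maximal concentrations (57.3 nM in H₂O, 16.0 nM in
D₂O) say the deuterated ligand displaces the radioligand at
three-and-a-half-fold lower concentration; the Welch comparison says
the pIC50 difference is far beyond noise; and the conversion puts the
binding free-energy gain on deuteration at about 0.76 kcal/mol.

On the computational side, feed leg energies (e.g. from an external
quantum-chemistry run, entered as a TSV of records) into the cycle:

```r
cy <- deuteration_shift(-67.45, -67.39, -39.64, -40.09,
                        method = "M06-2X", eps = 4)
cy
#> <cycle_result> method M06-2X, eps 4
#>             H2O    D2O ddE(H2O-D2O)
#> dE_HYDR  -67.45 -67.39        -0.06
#> dE_INTER -39.64 -40.09         0.45
#> dE_BIND   27.81  27.30         0.51
```

Hydration favors the protiated ligand by 0.06 kcal/mol, but the
receptor leg favors the deuterated one by 0.45, so the net binding
shift is +0.51 kcal/mol in favor of deuteration — same sign as, and
comparable magnitude to, the experimental estimate above.

And the geometry protocol, on a toy cluster:

```r
da <- gen_toy_cluster("donor_acceptor_pair")   # water dimer, one H-bond
out <- apply_ubbelohde(da)                     # contract O-H by 2.3%
c(H = scan_minimum(scan_heavy_distance(da)),
  D = scan_minimum(scan_heavy_distance(out$structure)))
#>    H    D
#> 2.90 2.92
```

The deuterated copy's optimal O···O distance is 0.02 Å longer — the
Ubbelohde elongation emerging from the surrogate energy model.

A thin command-line wrapper over the same functions lives in
`inst/scripts/isoshift.R` (subcommands `fit-saturation`,
`fit-competition`, `thermo`, `deuterate`, `cycle`, `toy-energy`).

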