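Package: isoshift
Title: Deuteration Effects on Ligand-Receptor Binding Affinity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying how hydrogen-to-deuterium substitution of
    exchangeable (N-H and O-H) protons changes ligand-receptor binding.
    Simulates and fits radioligand saturation and competition assays
    (K_D, B_max, pIC50, Hill slope), converts binding constants to Gibbs
    free energies, applies an empirical nuclear-quantization protocol that
    contracts acidic X-H bonds by 2.3% and emits frozen-coordinate
    constraints for downstream quantum-chemical optimization, books the
    two-leg thermodynamic cycle (hydration plus receptor interaction) that
    yields the deuteration binding shift, and provides a screened
    point-charge surrogate energy model of the Ubbelohde hydrogen-bond
    isotope effect so the whole pipeline can be exercised end to end
    without external quantum chemistry.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    knitr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
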