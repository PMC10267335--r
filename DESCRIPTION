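Package: theratype
Title: CFTR Modulator Theratyping Analysis for Patient-Derived Airway Epithelia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis toolkit for CFTR modulator theratyping in
    patient-derived airway epithelial cell models. Computes residue-ligand
    contact occupancy statistics from molecular dynamics trajectory output
    (multi-model PDB or tabular distance series) to classify ATP binding-site
    disruption in gating mutants; quantifies allele-specific CFTR transcript
    abundance from qPCR CT values by the delta-delta-CT method with an
    estimator for missplicing-associated degradation; segments Ussing-chamber
    short-circuit current recordings by a compound-addition schedule and
    derives baseline and total CFTR-activated currents, fold changes and
    above-baseline increments; estimates ciliary beat frequency as the
    dominant power-spectrum peak of time-lapse pixel intensities; and
    normalises Western blot band C densitometry to a loading control. Seeded
    synthetic-data generators with known ground truth support parameter
    recovery testing of every stage, and a study-level pipeline aggregates
    per-genotype summaries into a combined theratyping report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
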