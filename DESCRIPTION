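Package: mepflux
Title: MEP Pathway Carbon Flux from Dynamic 13C-Isoprene Labeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates carbon flux through the plastidic 2-C-methylerythritol
    4-phosphate (MEP) pathway from 13CO2 dynamic-labeling experiments in
    isoprene-emitting leaves. Provides the closed-form three-pool
    label-incorporation model for the fractional 13C labeling of isoprene,
    nonlinear least-squares flux estimation with measured DXP, MEcDP and
    IDP+DMADP pool sizes as fixed parameters, PTR-MS isotopologue signal
    processing (primary-ion normalization, background subtraction,
    atom-weighted fractional labeling), LC-MS/MS pool quantification with
    internal-standard matrix correction and natural 13C-abundance
    deconvolution, flux control coefficient estimation by log-log regression
    of flux on enzyme activity, a synthetic study generator for the full
    genotype-by-environment design, and an end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
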