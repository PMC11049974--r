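# mepflux

Carbon flux through the plastidic MEP (2-C-methylerythritol 4-phosphate)
pathway supplies the C5 precursors IDP and DMADP for all plastidic
isoprenoids, and in isoprene-emitting trees such as grey poplar the volatile
isoprene released from DMADP makes that flux observable in real time. When a
leaf in a gas-exchange cuvette is switched to a ¹³CO₂ atmosphere, newly fixed
¹³C moves through the pathway intermediates DXP, MEcDP and IDP+DMADP and
appears in the isoprene isotopologues monitored by PTR-MS. `mepflux` turns
those labeling kinetics, together with LC-MS/MS measurements of the
intermediate pool sizes and in vitro DXS activity assays, into absolute
pathway fluxes and an estimate of how much control the first pathway enzyme
(DXS) exerts on that flux.

## The model

Treating DXP (pool size *A*), MEcDP (*B*) and IDP+DMADP (*C*, all in
pmol mg⁻¹ DW) as a linear cascade of well-mixed pools traversed by a constant
flux *J* (pmol min⁻¹ mg⁻¹ DW), the fractional ¹³C labeling of the IDP+DMADP
pool — read out instantaneously as isoprene labeling — after the switch at
*t* = 0 is

    f(t) = m · [ 1 − A²·e^(−Jt/A)/((A−B)(A−C))
                   − B²·e^(−Jt/B)/((B−A)(B−C))
                   − C²·e^(−Jt/C)/((C−A)(C−B)) ]

where *m* is the maximal fractional labeling reached at the end of the run.
The three coefficients sum to 1, so f(0) = 0 and f rises monotonically to
*m*. With the measured pool sizes entered as fixed parameters, *m* and *J*
are estimated by Levenberg–Marquardt least squares against the observed
curve (`fit_flux()`); an independent ODE integration of the cascade
(`cascade_ode_oracle()`) backs the closed form and handles degenerate pool
configurations.

The flux control coefficient of DXS is the slope of log *J* against
log(DXS activity) across lines with silenced, normal and overexpressed DXS
(`fcc_regression()`): 0 means no control, 1 proportional control.

Because no raw instrument data are deposited for this system, the package
ships a first-class synthetic study generator (`generate_study()`) that
emulates the full 3-genotype × 4-condition design — activities, pools,
fluxes via a configurable control law, PTR-MS channel traces with natural
¹³C abundance and instrument noise, and internal-standard-paired pool
measurements — with the generating truth stored alongside for recovery
testing.

## Worked example

Simulate one labeling run for an empty-vector leaf under high light
(pools A = 41.65, B = 85.59, C = 38.09 pmol mg⁻¹ DW; generating flux
J = 28.65, plateau m = 0.912), process the PTR-MS channels, and refit:

```r
library(mepflux)
set.seed(42)
p   <- pool_sizes(A = 41.65, B = 85.59, C = 38.09)
run <- generate_label_run(p, J = 28.65, m = 0.912,
                          channel_frac = 0.01, background_cps = 5)
bg  <- generate_label_run(p, J = 28.65, m = 0.912,
                          total_cps = 0, background_cps = 5)
curve <- ptrms_label_curve(run, background = bg)
fit_flux(curve, p)
#> flux fit: J = 28.87 +/- 0.12 pmol min-1 mg-1 DW, m = 0.9054 +/- 0.0009 (rss 0.00594, n 101)
```

The fitted flux (28.87 ± 0.12) recovers the generating 28.65 to within 1%
under 1% channel noise. An end-to-end study with a generating control
coefficient of 0.18 returns per-condition estimates bracketing it:

```r
res <- run_pipeline(pipeline_config(mode = "simulate", seed = 1, fcc_true = 0.18))
res$fcc_table
#>      condition   fcc     se ci_low ci_high  n    r2 zero_flag
#> 1 1000PPFD_21C 0.203 0.0369 0.1286   0.278 38 0.458     FALSE
#> 2 1000PPFD_30C 0.172 0.0394 0.0924   0.251 42 0.323     FALSE
#> 3  250PPFD_21C 0.180 0.0343 0.1100   0.249 37 0.440     FALSE
#> 4  250PPFD_30C 0.202 0.0336 0.1340   0.270 45 0.456     FALSE
```

`zero_flag` marks conditions whose 95% CI covers zero — with the default
noise and cell sizes a true coefficient of 0.18 is comfortably
distinguishable from no control.

A thin command-line front end over the same functions lives in
`inst/scripts/mepflux.R` (subcommands `simulate`, `ptrms`, `fit`, `fcc`,
`all`).

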