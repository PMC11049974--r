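---
title: "Estimating MEP pathway flux and DXS flux control from dynamic 13C labeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating MEP pathway flux and DXS flux control from dynamic 13C labeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mepflux)
```

## The labeling model and its assumptions

When a leaf at metabolic steady state is switched from normal air to a
¹³CO₂ atmosphere, newly fixed carbon enters the MEP pathway and the
fractional ¹³C labeling of each intermediate rises toward a plateau. We
model the three measurable intermediates — DXP, MEcDP and IDP+DMADP, with
pool sizes $A$, $B$, $C$ in pmol mg⁻¹ DW — as a linear cascade of
well-mixed compartments traversed by a constant flux $J$
(pmol min⁻¹ mg⁻¹ DW). Writing $a(t), b(t), c(t)$ for the fractional
labeling of the three pools, the label balance is

$$\dot a = \frac{J}{A}(m - a), \qquad
  \dot b = \frac{J}{B}(a - b), \qquad
  \dot c = \frac{J}{C}(b - c),$$

from $a(0)=b(0)=c(0)=0$, where $m \in (0,1]$ is the maximal fractional
labeling reached at the end of the run ($m<1$ because a fraction of the
carbon feeding the pathway derives from unlabeled reserves). For pairwise
distinct pool sizes the cascade integrates in closed form to

$$f(t) = c(t) = m\left[1
  - \frac{A^2\,e^{-Jt/A}}{(A-B)(A-C)}
  - \frac{B^2\,e^{-Jt/B}}{(B-A)(B-C)}
  - \frac{C^2\,e^{-Jt/C}}{(C-A)(C-B)}\right],$$

implemented in `label_fraction()`. The three coefficients sum to one
(a Lagrange-interpolation identity, tested to $10^{-10}$), so $f(0)=0$;
$f$ is non-decreasing and bounded by $m$.

Assumptions the model embodies:

* **Isoprene labeling reads out IDP+DMADP labeling.** Isoprene is made
  from DMADP in a single enzymatic step and escapes the leaf immediately,
  so the PTR-MS isoprene labeling curve is taken as the instantaneous
  labeling state of the IDP+DMADP pool.
* **Intermediate pools between the three measured ones are negligible.**
  MEP, ME-CDP, MEP-CDP and HMBDP are below detection in leaf extracts and
  are assumed too small to delay label transfer; no fourth compartment is
  modeled.
* **Only plastidial pools label on the experiment's time scale.** DXP and
  MEcDP also occur outside the chloroplast; the plastidial share is
  estimated from final label incorporation (below) and it is the
  plastidial pool sizes that enter $A$ and $B$. IDP+DMADP is treated as
  entirely plastidic.
* **Metabolic steady state.** Pools and flux are constant over the 50-min
  run; the model describes label movement only.

`cascade_ode_oracle()` integrates the same cascade numerically
(`deSolve::ode`, `rtol = 1e-10`, `atol = 1e-12`). It is the independent
check of the closed form (agreement to $10^{-6}$ is enforced over random
parameter draws) and the evaluation path when two pool sizes coincide
within a relative tolerance of $10^{-6}$, where the closed-form
denominators degenerate. We chose the numerical fallback over an algebraic
limit formula for robustness: the degenerate case is a measure-zero
configuration that real pool measurements essentially never produce, and
the ODE path is exact enough everywhere.

## Flux estimation

`fit_flux()` estimates $m$ and $J$ by least squares with the measured
pools held fixed, using Levenberg–Marquardt (`minpack.lm::nls.lm`,
`ftol = ptol = 1e-13`) with bounds $J \in (0,\infty)$, $m \in (0,1]$.
Because the model is linear in $m$, we first profile $m$ out
($\hat m(J) = \langle g, f\rangle / \langle g,g\rangle$ with
$g = f(\,\cdot\,; J, m{=}1)$) and scan $J$ on a 120-point log grid from
$10^{-3}$ to $10^{6}$; the Levenberg–Marquardt polish then starts from the
better of this variable-projection optimum and the caller's initial guess.
The scan matters: the shape function saturates for large $J$ (the curve
becomes a step), the Jacobian with respect to $J$ vanishes there, and a
pure descent from a far-off start can stall on that plateau. With the
scan, noiseless curves generated from all twelve published
genotype-condition parameter sets refit their generating $J$ to machine
precision even from a deliberately poor start ($J=1$, $m=0.5$).

Default initial guesses when the caller supplies none: $m$ starts at the
maximum observed labeling, and $J$ at $C/t_{1/2}$, the IDP+DMADP pool size
divided by the time at which the curve first passes half its final value —
a turnover-time heuristic.

Diagnostics rather than silent answers: all-zero or plateau-only curves
return `converged = FALSE` with a message (the transient carries all the
information about $J$); a singular Jacobian at the optimum — e.g. when all
three time constants $A/J, B/J, C/J$ are far below the sampling interval —
reports infinite standard errors. Standard errors otherwise come from the
forward-difference Jacobian at the optimum,
$\widehat{\mathrm{Var}} = \hat\sigma^2 (\mathbf{J}^\top\mathbf{J})^{-1}$.

The fitting grid used throughout the package's simulations is 0–50 min at
0.5-min spacing (101 points): 50 min is the labeling run length, and
0.5 min is a typical PTR-MS multi-channel duty cycle; the sampling
interval is a package choice, exposed as an argument.

## PTR-MS processing

Raw counts per second on the six protonated isoprene isotopologue
channels (m/z 69–74, i.e. 0–5 ¹³C atoms) are normalized to the primary-ion
signal and drift pressure:

$$\mathrm{ncps} = \frac{\mathrm{cps}}
  {\mathrm{cps}_{21} + w_{37}\,\mathrm{cps}_{37} + w_{55}\,\mathrm{cps}_{55}}
  \cdot \frac{p_{\mathrm{ref}}}{p_{\mathrm{drift}}} \times 10^6.$$

The hydronium-cluster weights default to $w_{37}=w_{55}=1$ and
$p_\mathrm{ref}$ to 2.2 mbar (the nominal drift pressure of the
instrument class); both are instrument-specific configuration, not
physical constants, and are exposed as arguments. Scans with a
non-positive primary-ion sum are flagged and excluded, never silently
zeroed. Empty-cuvette backgrounds are subtracted channel-wise with
clamping at zero (the clamp count is recorded). Emission per leaf area
requires an explicit gas-standard calibration factor (nmol s⁻¹ per ncps);
there is no default because it cannot be guessed.

Fractional labeling is the atom-weighted isotopologue mean
$f = \sum_i i\,S_i / (5\sum_i S_i)$; it is scale-invariant and returns
$p$ exactly for a Binomial(5, $p$) channel split — the property that ties
the observation model of the generator to the analysis.

**Natural ¹³C abundance.** Normal air carries 1.1% ¹³CO₂, so even
"unlabeled" isoprene shows a ~5.5% ¹³C₁ satellite. Two corrections are
provided (`correct_isoprene_channels()`): the classical quick rule that
subtracts $5 \times 1.1\%$ of the m/z 69 channel from m/z 70, and an
exact binomial deconvolution that inverts the per-atom convolution matrix
(shared with the metabolite workflow). The pipeline defaults to the
binomial method: under the per-carbon observation model (each carbon is
¹³C with probability $f + (1-f)p_{13}$) the deconvolution is the exact
inverse, while the m/z 70 rule leaves a small residual that matters when
flux must be recovered to 0.1%. The quick rule remains available for
comparability with spreadsheet workflows.

## Pool quantification

Pool amounts come from external standard curves (ordinary linear fit,
inverse prediction, negative predictions clamped and flagged). Matrix
suppression and recovery losses are corrected with a paired-run internal
standard design: each extract is measured once with and once without a
spike of unlabeled standard. In a post-labeling extract the channels with
3–5 ¹³C atoms contain essentially only biological material, so the ratio
of their summed intensities between the two runs estimates the
run-to-run endogenous scale $s$; the spike's contribution to the
unlabeled channel is then $\mathrm{spiked}_0 - s\cdot\mathrm{unspiked}_0$,
and the recovery factor is that contribution over the intensity the
standard curve predicts for the spiked amount. We use the ratio of sums
rather than the mean of per-channel ratios because a single near-empty
heavy channel makes the per-channel ratio — and with it the isolated
spike contribution — arbitrarily bad under instrument noise, whereas the
summed ratio is dominated by the well-measured channels. When the heavy
channels are empty (an unlabeled extract), the factor falls back to the
plain channel-0 difference and is flagged `low_confidence`.

Natural-abundance correction of the metabolite channels solves
$M x = \mathrm{areas}$ with the binomial convolution matrix $M$
(carbon-only; O/H/N/P isotopes contribute far less at these masses and
are ignored), clamps at zero and renormalizes to the observed total. The
forward–inverse round trip is exact to $10^{-10}$ and the correction
conserves total signal.

The plastidial share of DXP and MEcDP is `total × (final label of the
metabolite / final label of IDP+DMADP)`, capped at the total with a
warning — a label ratio above one can only be noise under the model's
assumptions.

## Flux control coefficient

`fcc_regression()` estimates the FCC as the OLS slope of $\log J$ on
$\log v$ (natural logs; the slope is base-invariant), per environmental
condition, pooling empty-vector and transgenic lines. Records with
non-positive $J$ or $v$ are excluded with a logged reason; groups with
fewer than three usable records yield no estimate. The 95% confidence
interval is two-sided $t$-based; `zero_flag` marks conditions where it
covers zero. OLS treats activity as error-free; measurement error in $v$
attenuates the slope toward zero, which is a known limitation of the
double-logarithmic regression design and one reason FCC estimates near
zero should be read as "indistinguishable from none" rather than exactly
none. Simulations with per-leaf activity noise inherit this attenuation.

## The synthetic study

`generate_study()` draws the full 3-genotype × 4-condition experiment.
Its defaults are the study conditions themselves:

* **Anchors.** Condition-by-genotype means of plateau, pools and flux
  (and the replicate counts, 8–20 per cell) come from
  `reference_parameters()`, the published summary of the grey poplar
  experiment. Published spreads are standard errors; the generator
  converts them to per-sample coefficients of variation as
  $SE\sqrt{n}/\mathrm{mean}$.
* **Genotypes.** DXS activity multipliers 1.00 (empty vector), 0.45
  (RNAi-silenced; activity about half the control), 1.25
  (overexpressor), matching the measured activity shifts.
* **Flux.** Two modes. `control_law` derives each replicate's flux from
  its activity, $J = J_{EV}(\mathrm{cond})\,(v/v_{EV})^{\mathrm{fcc}}$,
  with lognormal noise — the mode for control-coefficient recovery
  studies. `table1` anchors each cell at its published flux mean; this is
  the mode that reproduces the printed study values exactly at zero
  noise. The two are separate because the published per-genotype fluxes
  do not follow a single power law in activity — that empirical tension
  is precisely what a low FCC with one non-zero condition looks like.
* **Observation model.** Each isoprene carbon is ¹³C with probability
  $f(t) + (1-f(t))\,p_{13}$ (tracer plus natural abundance on the
  remaining carbons); channels are the Binomial(5, ·) split of a total
  signal of 2000 cps, over constant primary-ion channels
  ($10^6$, $2\times10^5$, $5\times10^4$ cps) and 2.2 mbar drift
  pressure, plus a flat 5-cps cuvette background. This per-molecule
  i.i.d.-carbon split is a simplification — real positional labeling is
  not i.i.d. across carbons — but it is exactly the model the
  atom-weighted labeling formula inverts, which is what makes noiseless
  round trips exact.
* **Noise.** Multiplicative lognormal (mean-preserving) for biology —
  activity $sd_{\log}=0.15$, flux around the control law
  $sd_{\log}=0.10$, pools at the published CVs — and additive Gaussian at
  1% of the maximum channel signal for the instrument. These scales match
  the coefficient-of-variation range of the published summary table.
* **Pool measurements.** Plastidial fractions default to 0.80 (DXP) and
  0.85 (MEcDP) — the final-label ratios observed for these metabolites
  are high but below one — with IDP+DMADP fully plastidic. All plastidial
  pools are assumed to share the final labeling of IDP+DMADP at run end,
  which is the same assumption the plastidial-pool estimator inverts.
  A per-sample matrix suppression factor is drawn uniformly on
  [0.65, 0.95] and applied to both runs of the internal-standard pair;
  the spike is modeled on the quantitation channel with the standard
  curve's response. Standard curves are five-point and through the
  origin.

What the generator does **not** emulate: photosynthesis and stomatal
dynamics (no assimilation or $C_i$ traces), diurnal rhythms, instrument
drift within a run, PTR-MS fragmentation and transmission effects,
chromatographic peak shapes. Passing recovery tests on this generator
therefore demonstrates the correctness of the estimators under the
stated observation model, not robustness to every artifact of real
instruments.

Determinism: `study_design(seed = )` seeds R's generator once per study;
identical seeds give bitwise-identical tables.

## Pipeline

`run_pipeline()` chains the stages: simulate (or read a study directory),
PTR-MS channels → labeling curves, pool measurements → plastidial pool
table, per-sample flux fits with that sample's own pools
(`pool_mode = "mean"` switches to genotype-by-condition mean pools, since
it is not knowable whether per-leaf or mean pools were used in the
original fits — per-sample is the default as the less-smoothed choice),
then the per-condition FCC regression. Every input sample ends either in
the flux table or in the exclusion log with a reason; a failed labeling
curve, missing pools, or a non-converged fit excludes that sample without
aborting the run. A flat-text copy of the configuration is written next
to the output tables.

## Problem sizes and numerical checks

The test suite exercises: closed-form/oracle agreement over 1000 random
parameter draws on the 0–50 min grid (tolerance $10^{-6}$); coefficient
normalization to $10^{-10}$; noiseless refits of all 12 published rows to
0.1%; 200-replicate noisy refits per row at 1% curve noise (mean flux
within 5%); 500-replicate coverage of the log-log slope CI; 20 replicate
end-to-end studies at the published cell sizes for the no-control flag;
and exact observation-model round trips. These sizes were chosen to make
Monte-Carlo statements stable at the percent level while keeping the
suite interactive.

## Known limitations

* Pools are fixed, not co-estimated; pool measurement error propagates
  into $J$ unquantified (the fit's standard error reflects curve noise
  only).
* The cascade assumes constant $J$ and pools; transients in
  photosynthesis during the labeling run violate steady state and bias
  the fit in ways the generator does not model.
* OLS in log-log space attenuates the FCC under activity measurement
  error (no errors-in-variables correction is attempted).
* The internal-standard algebra assumes the spike experiences the same
  suppression as the endogenous analyte and that heavy channels are
  biology-only; co-eluting unlabeled contaminants would violate it.
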