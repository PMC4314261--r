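---
title: "Methods: dual-label tracer mass balance in grassland turves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-label tracer mass balance in grassland turves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(turftracer)
library(dplyr)
```

## The measurement model

An isotope ratio mass spectrometer reports δ values: per-mil deviations of
a sample's heavy/light isotope ratio from an international standard,

$$R_\text{sample} = R_\text{std}\left(\frac{\delta}{1000} + 1\right),
\qquad \text{atom \%} = 100\,\frac{R_\text{sample}}{1 + R_\text{sample}}.$$

`turftracer` uses the community-standard reference ratios
$R_\text{VPDB} = 0.0111802$ (¹³C/¹²C) and $R_\text{AIR} = 0.0036765$
(¹⁵N/¹⁴N); both are arguments of `isotope_system()` for laboratories that
calibrate differently. The map is strictly increasing and
`atom_percent_to_delta()` is its exact algebraic inverse; the package tests
hold the round trip to $10^{-9}$ relative error over
$\delta \in [-900, 10^6]$ ‰, which covers everything from strongly depleted
natural material to 99 atom % label stocks. δ values at or below
−1000 ‰ are rejected as physically impossible (they would imply zero or
negative heavy-isotope content).

### Baselines and excess

The tracer signal is atom percent *excess* over natural abundance, and the
two isotopes need different baseline rules:

- **¹⁵N**: controls are the water-injected turves; the baseline is their
  mean atom percent (median available via `n15_baseline_stat`). Negative
  excess values arising from noise are *retained*, because clipping them
  would bias pool averages upward.
- **¹³C**: the added ¹³C is tiny relative to the ambient carbon pool, and
  natural-abundance δ¹³C scatters strongly between samples. The control set
  is therefore enlarged with the inorganic-N turves (which received no ¹³C
  label), and the baseline is the *minimum* control atom percent, which
  guarantees nonnegative ¹³C excess for any sample whose stratum contains
  its own controls. Organic-form turves are never valid ¹³C controls and
  `control_baseline()` refuses them.

Baselines are stratified by site × fraction × species by default
(`baseline_by`), because natural abundance differs systematically between
tissues; a coarser or finer stratification is one argument away. A stratum
without control material is a hard error rather than a silent fallback.

### From excess to mass balance

Excess concentration on a dry-weight basis is
$\text{conc} = (\text{APE}/100)\cdot \text{content}/M \cdot 10^9$
nmol g⁻¹ DW, linear in both the excess and the elemental content.
Microbial enrichment comes from chloroform fumigation–extraction pairs:
the flush (fumigated − non-fumigated extract, per g soil) divided by an
extraction efficiency `k_extract`. The default `k_extract = 1` reports the
uncorrected flush — the conservative convention when no site-specific
efficiency has been calibrated — and Vance-style factors (≈0.54 for N,
≈0.45 for C) can be supplied instead. Percent recovery of added label is
then `100 · conc · pool mass / added label`, with the denominator counting
*labeled atoms* (per-form µmol × label atom fraction, default 0.98 for
97–99 % stocks), since excess enrichment traces labeled atoms only.

The dose bookkeeping treats the printed mixture total (100 µmol N per
turf) as the sum over the four forms, giving 25 µmol N per form —
the only reading consistent with the per-form labeled dose and the
per-form areal rate (8.75 mg N m⁻²) simultaneously. ¹³C recovery is
computed only for organic-form turves; alanine carries 3 C per N and
tri-alanine 9 C per 3 N, both 3 labeled C per labeled N.

### Pool dilution

The injected tracer mixes into the ambient soil pool of the same form, so
raw shoot enrichment under-represents uptake from large pools. No standard
closed form exists for a single-timepoint design; the package multiplies
shoot excess by $(\text{ambient pool} + \text{added})/\text{added}$,
i.e. the tracer's dilution in the target pool, which is 1 when the ambient
pool is empty and monotone in pool size. The alternative convention
$\text{pool}/\text{added}$ is provided (`method = "pool_only"`). Ambient
pools are compared with areal doses directly, without rescaling the
0–15 cm pool inventory to the 8 cm injection depth; a depth-weighted
comparison can be had by rescaling the pool-size table the user passes in.
These factors correct *stock* dilution only — they deliberately ignore the
flux of organic N through its small, fast pool, so scaled organic-N uptake
remains a lower bound.

## The comparison layer

Recovery and concentration responses are compared with a blocked factorial
ANOVA (`fit_factorial_anova()`): site × N form × pool with block always
retained as a factor, Type II sums of squares by default (robust to mild
imbalance from lost samples; Type I available and used for the exact
variance-partition test). Between-site tests default to *block means*
(`site_contrast()`): with 5 blocks per site this gives the small
denominator degrees of freedom (F(1, 8) here) characteristic of blocked
field designs, and avoids pseudo-replication from treating turves within a
block as independent. The raw-observation route is available and flagged
in the output.

Transforms are never silent: `transform = "auto"` fits untransformed,
runs a Shapiro–Wilk check on residuals, refits on
$\log(x + \text{offset})$ (offset = half the smallest positive response,
only when nonpositive values are present) if the check fails at 5 %, and
both messages the switch and records it in the fitted object.

The dual-isotope colocation regression (OLS of ¹³C on ¹⁵N excess
concentration) is the package's inferential tool for *intact* uptake:
material absorbed as intact alanine or tri-alanine carries 3 C per N, so
the slope approaches 3 when intact uptake dominates and 0 when plants
take up only the ¹⁵N-bearing mineralization products. Note that
measurement noise in the ¹⁵N predictor attenuates the fitted slope toward
zero (classical errors-in-variables), so slopes between 0 and 3 on noisy
field data mix pathway contributions with attenuation — one reason the
package demonstrates the discrimination on low-noise simulations and one
known limitation of the method on real data.

## The synthetic experiment

`simulate_experiment()` forward-simulates the full design: two sites of
contrasting productivity, 5 blocks × 5 turves (four labeled forms plus a
water control), 2.5 h chase, harvest into per-species shoots, roots and a
fumigation–extraction pair. Mechanism, per labeled turf:

1. A site×form-specific fraction of the dose is captured *directly*
   (intact, for the organic forms) by microbes and roots; per-turf
   lognormal multipliers (`uptake_cv`, default 0.3) add biological
   variability.
2. The uncaptured organic label mineralizes as a single first-order
   compartment with half-lives of 6 min (alanine) and 7.5 min
   (tri-alanine) — midpoints of the minutes-scale range measured for these
   grassland soils; after one half-life of chase, exactly half the
   uncaptured substrate remains intact (a tested bookkeeping identity).
   Tri-alanine mineralizes directly, without an explicit alanine
   intermediate, for want of branching data.
3. Mineralized N re-enters an ammonium-like pool with its own uptake
   allocation; mineralized C is respired. Intact capture carries 3 C per
   N; microbes respire a fixed fraction (default 0.5) of intact-assimilated
   C, so microbial ¹³C < 3×¹⁵N while plant tissue keeps the full 3:1
   stoichiometry.
4. Root-captured label passes a form-specific translocation fraction to
   shoots, split across species by shoot mass share.
5. Pool label contents become measurements through the *exact inverse* of
   the analysis equations — concentration → APE → atom percent → δ — plus
   Gaussian δ noise (defaults 0.5 ‰ for ¹⁵N and a deliberately noisy
   1.5 ‰ for ¹³C, reflecting how the small ¹³C signal sits on a large,
   variable ambient C pool). The fumigation pair encodes the microbial
   content in its difference: both extracts carry the extractable share of
   residual unassimilated label, the fumigated one additionally
   `k_extract` × microbial content per g soil.

Atom conservation is exact in the truth table: per turf,
microbial + root + shoot + residual ¹⁵N equals the added label, and pools +
residual + respired CO₂ equal the added ¹³C.

Default allocations were chosen once to land recoveries in the low
single-digit to ~15 % per-pool range with higher recovery at the
productive site — the regime such field experiments report — and are not
fitted to any dataset. Turf biomasses use the sites' bulk densities over
the 8 cm injection depth (≈3.5 kg vs ≈1.4 kg soil per 0.04 m² turf) with
greater root mass at the unproductive site; extract C/N contents are
typical K₂SO₄-extractable values (tens of µg N g⁻¹ soil).

**What the simulator does not emulate:** spatial diffusion of the injected
solution, mycorrhizal transfer, root-surface label contamination (removed
by CaCl₂ washes in practice), multi-timepoint chase kinetics, species-level
uptake preferences (species differ only in biomass share), and
inter-laboratory IRMS drift. Passing end-to-end tests therefore shows the
*accounting* is exact and the statistics calibrated — not that the
biological defaults describe any particular grassland.

## Numerical and design choices

- **Noise-free invertibility** is the pipeline's core correctness
  property: with δ noise at zero, estimated recoveries match simulator
  ground truth to ~10⁻¹³ relative (tested at 10⁻⁶ tolerance for margin).
- One master seed drives a run; per-turf seeds are drawn from it, so a
  single turf can be regenerated in isolation and runs are byte-identical
  under a fixed seed.
- Problem sizes in the tests — 2-block designs for unit tests, the full
  5-block design with 100 replicates for the bias study, 1000 replicates
  for null calibration — were chosen as the smallest sizes at which the
  Monte Carlo error is comfortably below the tolerances being asserted.
- Degenerate inputs fail loudly with typed conditions
  (`turftracer_error_*`): empty design cells name the cell, strata without
  controls name the stratum, unpaired fumigation extracts name the turf;
  zero-variance regressions and zero-denominator ratios return flagged
  rows instead of errors, since both occur legitimately in all-control
  subsets.
- Recovery of the water-control turves is reported as 0 (no label was
  added, and by construction their expected excess is 0); their role is to
  supply baselines.

## Known limitations

- The colocation slope is attenuated by predictor noise (see above) and
  cannot, on its own, apportion partial intact uptake quantitatively.
- The pool-dilution factor corrects stocks, not fluxes; for fast-cycling
  organic pools it understates availability.
- Single-timepoint designs cannot separate uptake-then-efflux from net
  uptake; the simulator's allocations are net by construction.
- Between-site tests on block means are conservative when within-block
  replication is informative; the raw-observation route trades that for
  pseudo-replication risk, and the choice is recorded in every result.
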