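---
title: "Assessing metal(loid) contamination in mining-affected rivers with pemriver"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing metal(loid) contamination in mining-affected rivers with pemriver}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pemriver)
```

## The problem

Rivers draining metal-mining districts receive dissolved potentially
ecotoxic metal(loid)s (PEMs) from mine drainage, tailings leachate and
diffuse runoff. Three distinct questions are asked of such data, and
they need three distinct yardsticks:

1. *Is the water compliant?* — concentrations against regulatory limits
   (HEI, WQI, CCME WQI).
2. *How far has it departed from its natural state?* — concentrations
   against a local background (CF, PLI, Er, PERI).
3. *What does exposure do to people?* — doses against toxicological
   reference values (HQ/HI, ELCR/CR).

The package implements all three chains plus multivariate source
apportionment, on a common data model with explicit handling of
left-censored ("below detection limit") measurements. The packaged
fixture, `nyamwamba_waters()`, is a 19-site dry-season survey of the
River Nyamwamba catchment in western Uganda, downstream of the legacy
Kilembe copper/cobalt mine; it exercises every stage and anchors the
regression tests.

## Data model and censoring

A `pem_samples` object couples per-site metadata (group label, optional
downstream distance, pH) with a long table of measurements. A raw
measurement is *either* an observed concentration (µg/L) *or* censored
with a positive detection limit — never both. All concentrations are
µg/L throughout; the health-risk module converts to mg/L at its boundary
with an explicit 10⁻³ factor.

Censored values must be resolved before any index is computed
(`resolve_censored()`), and the applied policy is recorded on the
object. The default is **half the detection limit** (DL/2), the common
single-imputation convention for lightly censored water chemistry. It is
also the policy under which the fixture's published background row
(e.g. Co 0.03, Ni 0.05, Zn 2.45 µg/L) is recovered exactly, which is why
it is the package default rather than DL or zero. The alternatives
(`"zero"`, `"dl"`, `"drop"`) are provided for sensitivity analysis;
`"drop"` removes the measurements entirely, and every downstream stage
raises an error rather than silently skipping an analyte that was
dropped. Cd and Cr are carried in the data model but are fully censored
in the fixture and excluded from index computation by default.

More principled censored-data estimators (Kaplan–Meier, regression on
order statistics, maximum likelihood) are deliberately out of scope:
with ≤ 19 samples per analyte and censoring concentrated in a few
analytes at uncontaminated sites, substitution is transparent and its
effect is bounded by the detection limits themselves.

## Index definitions and parameter choices

**HEI** sums concentration-to-limit ratios over the ten quantified PEMs.
The default limit plan is the Ugandan potable-water standard (UNBS) —
the national yardstick for the fixture — with one gap: neither UNBS nor
WHO sets a cobalt limit, so the British Columbia aquatic-life guideline
(110 µg/L) fills it. Bands: ≤ 40 low, 40–80 medium, > 80 high.

**PLI** is the geometric mean of contamination factors against a
background profile. The background is the arithmetic mean of reference
sites judged uncontaminated — for the fixture, the upstream main-stem
site NY-01 and the Rukoki tributary NY-13 — computed under the same
censoring policy as the samples. The geometric mean is evaluated in log
space (`exp(mean(log(CF)))`); a direct nth-root-of-product oracle backs
it in the tests. Any non-positive CF is an error (impossible under
DL/2).

**WQI** weights each parameter by drinking-water toxicity (integers
1–5) and scales by its standard: pH enters as an ordinary parameter with
the UNBS upper objective (9.5) as its standard, so that a sample sitting
exactly at every standard scores 100 regardless of the weights. The
default weights sum to 37 and the weight sum is always *computed* from
the weights rather than taken as a separate constant, which keeps the
calibration property exact under any override. Weighted-WQI formulations
differ between studies in their S-value bookkeeping; numeric WQI values
are therefore treated as scheme-dependent, and the regression tests pin
the upstream site's value (17.4) plus the classification bands of all
nine main-stem sites rather than every digit.

**CCME WQI** combines the scope F1 (% of parameters failing at least
once), frequency F2 (% of failed tests) and amplitude F3 (an asymptotic
function of the normalised sum of excursions). Upper-bound objectives
fail on strict exceedance; pH is tested against both bounds of its
objective range. The model minimum — at least 4 parameters and 4 tests —
is enforced as an error. Ties at exactly the limit count as *not*
exceeded, here and in `exceedance_summary()`. The fixture scope is the
nine main-stem samples × (pH + 10 PEMs) = 99 tests.

**Ecological risk** multiplies the contamination factor of the *mean*
concentration (at least five sites; fewer warns) by Hakanson
toxic-response factors (Al 5, As 10, Cd 30, Co 5, Cr 2, Cu 5, Fe 1,
Mn 1, Mo 15, Ni 5, Pb 5, Zn 1). The index was conceived for sediments;
its application to filtered water follows the practice of recent river
studies and should be read comparatively, not absolutely. Band
boundaries are printed inconsistently across the literature
(`40 ≤ Er` vs `150 < PERI`); the package uses left-closed intervals
uniformly, so Er = 40 is "moderate" and PERI = 150 is "moderate".

## Health risk: conventions and defaults

Doses follow the US-EPA intake equations: ingestion
`CDD = C·IR·ED·EF/(AT·BW)` and dermal
`DAD = C·Kp·ED·EF·ET·SA·10⁻³/(AT·BW)`. The printed dermal equation in
much of the applied literature is dimensionally incomplete
(mg/L × cm/h × cm² needs a volume conversion); the implementation
applies the 10⁻³ L/cm³ factor explicitly.

Averaging time defaults to `AT = ED × 365` days for *both* the
non-carcinogenic and carcinogenic endpoints. The textbook lifetime
convention (70 y × 365 d) is available via the `AT_cancer` argument, but
it makes risk proportional to exposure *duration*, so an adult with
ED = 30 y would always out-rank a child with ED = 6 y. The
exposure-duration average is the convention under which cohort ordering
is governed by intake-to-body-weight ratios — child above adult — which
is the ordering consistently reported for residential river-water
scenarios and the one the package's structural tests assert.

The shipped cohort scenarios (child: IR 1 L/d, BW 15 kg, ED 6 y, ET 1 h,
SA 6600 cm²; adult: IR 2 L/d, BW 70 kg, ED 30 y, ET 0.58 h,
SA 18000 cm²; EF 350 d/y) and the toxicology table (Kp, RfD, ABS_g,
CSF) are generic US-EPA residential screening defaults, clearly marked
as package defaults rather than site-measured values. Consequently the
fixture's health-risk outputs are screening-level: the tests assert
structure (child > adult everywhere; HI decomposition exact; CR
decomposition exact; Ni dominating the cancer risk at every main-stem
site except the upstream reference, where Ni is below detection),
not absolute magnitudes. Oral slope factors exist only for As, Ni and
Pb; requesting cancer risk for any other analyte is an error, and
analytes lacking an RfD are skipped with an explicit warning. Soil,
dust, food-chain and inhalation routes are out of scope, as is
probabilistic (Monte Carlo) risk — point estimates only.

## Source apportionment

The multivariate stages run on the z-scored site-by-analyte matrix
(default scope: the 15 non-lake samples × 10 quantified PEMs, censored
cells at DL/2). KMO and Bartlett diagnostics are computed from the
correlation and anti-image matrices; no installed package provides KMO,
so it is implemented directly and cross-checked in the tests against a
regression-residual partial-correlation oracle (and the closed form
KMO = 0.5 for any two variables). PCA retains components with
eigenvalue > 1 and applies varimax with Kaiser normalisation
(`stats::varimax`, tolerance 10⁻⁶). Factor signs are fixed so each
factor's largest-magnitude loading is positive, making loading tables
deterministic; loadings are labelled strong (> 0.75), moderate
(0.50–0.75) or weak (< 0.50). Varimax preserves per-variable
communalities; the tests require agreement with the unrotated
communalities to 10⁻⁸. On rank-deficient input the correlation matrix
cannot be inverted, so the adequacy diagnostics degrade to `NA` while
the PCA itself proceeds. Note that on very small, highly symmetric
problems (two near-identical variable blocks of equal size) the
pairwise varimax algorithm can stall at a symmetric stationary point;
this does not arise at the dimensionalities the package targets.

Clustering is average-linkage (UPGMA) on Euclidean distances, with merge
heights rescaled to (D_link/D_max) × 100 and a helper to cut either at a
rescaled height or into *k* groups. Published dendrograms are usually
drawn on software-specific rescaled axes, so cluster *structure* (e.g.
the mine-drainage site and the most contaminated tributary each isolated
at k = 3) is the reproducible quantity, not the printed threshold.
Dendrograms export to Newick via `ape`.

## The synthetic generator

`river_scenario()` + `simulate_river()` produce datasets with known
ground truth. The noise-free surface is
`C(d) = background × Π_s (1 + (m_s − 1)·exp(−(d − d_s)/λ))` over the
sources at or upstream of d — multiplicative combination, exponential
attenuation — and observations multiply it by lognormal noise
`exp(N(0, σ²))`, with values below an analyte's detection limit emitted
censored. This emulates the salient features of a mining-affected
tropical river: a localised mine-drainage input, downstream dilution,
positive right-skewed concentrations, and censoring of near-background
analytes. Defaults: nine main-stem sites over 16 km, the fixture's
baseline as background, one source at km 2.5 with multipliers spanning
the 10³–10⁴-fold Co/Ni enrichment seen in such systems, λ = 5 km,
σ = 0.3, and the fixture's detection limits.

What it deliberately does **not** emulate: hydrodynamic transport,
seasonal/flood dynamics, pH-dependent speciation and precipitation,
correlated (same-water-parcel) noise across analytes, and tributary
dilution mass balance. Passing the synthetic tests therefore
demonstrates that the *index arithmetic and source-recovery machinery*
behave correctly under the stated generative model, not that the model
captures real river chemistry.

Verification uses: (i) a null scenario (no sources, σ = 0) where every
index has a closed form (PLI = 1 everywhere); (ii) censoring honesty —
the censored fraction converges to the lognormal mass below the
detection limit; (iii) ranking — source-influenced sites out-rank
background sites in PLI; (iv) a two-source scenario (30 sites, two
disjoint three-analyte groups, σ = 0.1) where the varimax factors must
recover the groups in at least 95 of 100 seeded replicates.

## Numerical choices and problem sizes

- Geometric means in log space; index/band boundaries left-closed
  except where a published rule is explicitly strict (HEI's ≤ 40,
  cancer-risk "negligible < 10⁻⁶ / unacceptable > 10⁻⁴").
- Varimax convergence 10⁻⁶; communality preservation asserted at 10⁻⁸;
  HI decomposition at 10⁻¹²; CR decomposition exact.
- The test suite runs entirely on the 19-site fixture, small constructed
  matrices, and simulations of at most 30 sites × 10 analytes × 100
  replicates (the two-source recovery study) plus one 3000-site
  single-analyte run for the censoring-fraction check; the full suite
  completes in a few seconds.

## Known limitations

- Substitution-based censoring only; no survival-analysis estimators.
- Single-season snapshots; no temporal aggregation in the CCME index
  (which was designed for repeated sampling — here "tests" are sites).
- Health-risk defaults are generic screening values; site-specific work
  must supply measured exposure parameters and current toxicity values
  via `exposure_scenario()` and `toxicity_table()` overrides.
- The Hakanson formulation is applied to the dissolved phase; sediment
  toxic-response factors are used unchanged.
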