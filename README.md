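# pemriver

Assessment toolkit for dissolved potentially ecotoxic metal(loid)s (PEMs)
in mining-affected river systems. Given a site-by-analyte table of
filtered water concentrations (µg/L, with `<x` detection-limit censoring)
and a configuration of regulatory limits, background references, toxic
response factors and exposure scenarios, the package computes the full
chain used in contemporary river-contamination studies:

- **Regulatory water-quality indices** — the heavy metal evaluation index
  `HEI = Σᵢ Cᵢ/MPLᵢ`, the pollution load index
  `PLI = (CF₁ · CF₂ ⋯ CFₙ)^{1/n}` over contamination factors
  `CFᵢ = Cᵢ/C_{b,i}`, the toxicity-weighted index
  `WQI = Σᵢ 100·Cᵢ·Wᵢ/(Sᵢ·ΣW)`, and the CCME WQI
  `100 − √(F₁² + F₂² + F₃²)/1.732` built from the scope, frequency and
  amplitude of objective exceedances — each with its published
  classification bands.
- **Ecological risk** — Hakanson risk factors `Erᵢ = T_{r,i} · CFᵢ` on
  mean concentrations and their sum, the potential ecological risk index
  `PERI = Σᵢ Erᵢ`.
- **Human health risk** — US-EPA style chronic daily dose (ingestion) and
  dermally absorbed dose, hazard quotients `HQ = CDD/RfD` per pathway,
  hazard index `HI = Σ HQ`, and excess lifetime cancer risk
  `CR = CDD·CSF_oral + DAD·CSF_ABS` for child and adult cohorts.
- **Source apportionment** — KMO and Bartlett adequacy diagnostics,
  varimax-rotated principal components with eigenvalue-1 retention and
  loading-strength labelling, and average-linkage (UPGMA) hierarchical
  clustering of sites and analytes with Newick export.
- **Synthetic rivers** — a seedable generator of longitudinal river
  profiles with point-source contamination, exponential downstream
  attenuation, lognormal noise and detection-limit censoring, with known
  ground truth for verifying every stage.

The package ships a fully worked fixture: a 19-site dry-season survey of
the River Nyamwamba catchment (Kasese, Uganda), a tropical river affected
by legacy copper/cobalt mining — nine main-stem sites, five tributaries,
an underground mine drainage channel and four Lake George sites, with pH
and ten quantified PEMs.

## Worked example

```r
library(pemriver)

water <- nyamwamba_waters()          # packaged survey, censoring preserved
river <- pem_subset(water, "main_stem")
bg    <- derive_background(water, c("NY-01", "NY-13"))  # baseline profile

hei(river)
#> <HEI index, 9 site(s)>
#>  site_id  value classification
#>    NY-01  0.852            low
#>    NY-04 14.600            low
#>    NY-05 15.200            low
#>    NY-07 17.300            low
#>    ...

ccme_wqi(river)
#> CCME WQI = 72.9 (fair)
#>   F1 (scope) = 27.27, F2 (frequency) = 22.22, F3 (amplitude) = 31.05
#>   3/11 parameters failed, 22/99 tests failed, nse = 0.4502

ecological_risk(mean_profile(river), bg)
#> <ecological risk table, 10 analytes>
#>  analyte mean_concentration       cb       cf tr       er       er_class
#>       Co            251.000   0.0265 9470.000  5 4.74e+04 extremely high
#>       Ni             49.800   0.0490 1020.000  5 5.08e+03 extremely high
#>       ...
#> PERI = 52960 (extremely high)
```

Reading: HEI stays below 40 everywhere (regulatory compliance is "low
concern"), but contamination factors against the uncontaminated
NY-01/NY-13 baseline reveal extreme enrichment of Co, Ni and Mn
downstream of the mine — PLI peaks at 14.5 and PERI is four orders of
magnitude above the "low risk" band. Health-risk and source-apportionment
stages follow the same pattern (`hazard_assessment()`,
`cancer_assessment()`, `pca_varimax()`, `pem_cluster()`); see the
vignette in `vignettes/` for the full pipeline and its assumptions.

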