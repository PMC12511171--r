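# glioSpatial

Zonal quantification of tumor and immune cells in glioblastoma,
IDH-wildtype tissue sections.

Infiltrating gliomas have no sharp border: a dense **tumor core** grades
into a **transition zone** and then a **periphery** where single tumor
cells infiltrate near-normal brain. How immune cells — IBA1+
microglia/macrophages, CD8+ cytotoxic T cells, FOXP3+ regulatory T cells —
distribute across these zones matters for immunotherapy, but quantifying it
requires turning classified cell maps of whole tissue sections into
comparable per-patient statistics. glioSpatial is that pipeline. It is
written for pathology/neuro-oncology groups whose upstream cell classifier
(any software) exports per-cell coordinates and classes; the package takes
it from there.

## What it computes

For each patient slide (cell table CSV + ROI polygons GeoJSON) and cohort
(clinical CSV):

* per-zone, per-class cell **densities** `n / A` (cells/mm²), with artifact
  exclusion zones subtracted from both counts and area;
* immune-to-tumor **ratios** and the immunosuppression index
  FOXP3⁺/CD8⁺ (per patient; cohort summaries are medians of per-patient
  ratios);
* per-patient **waterfall differences** between zones (core − periphery,
  transition − periphery, core − transition);
* the **proximity statistic**: the fraction of tumor cells with 1–4, 5–9,
  or ≥10 immune cells of a class within a 30 µm radius, per zone, plus the
  un-normalized density variant, with a closed-form Poisson null
  P(k neighbors) = Pois(k; λ·10⁻⁶·π·r²) as analytic oracle;
* **cohort inference**: paired Wilcoxon signed-rank comparisons between
  zones (exact p for n ≤ 25 without ties) and a median-cutoff univariate
  survival screen — Kaplan–Meier curves and Cox proportional-hazards fits
  (Efron ties, Wald CI) of high-vs-low groups for OS and PFS;
* a fully **synthetic cohort generator** (log-normal interpatient
  intensities calibrated to published zonal medians, Poisson or
  Thomas-clustered cell placement, exponential survival with administrative
  censoring) so the entire pipeline is testable without patient data.

## Worked example

```r
library(glioSpatial)

cfg <- syntheticCohortConfig(nPatients = 12,
                             regionAreas = c(CORE = 2, TRANSITION = 2,
                                             PERIPHERY = 2),
                             seed = 7)
co <- generateCohort(cfg)
dt <- cohortDensityTable(co$cellMaps, co$regionSets)

sapply(c("CORE", "TRANSITION", "PERIPHERY"), function(rl)
  sapply(c("TUMOR", "IBA1", "CD8", "FOXP3"), function(cl)
    median(dt$density[dt$cell_class == cl & dt$region_label == rl])))
#>         CORE TRANSITION PERIPHERY
#> TUMOR 3529.2     1928.8     399.5
#> IBA1   574.5      394.0     173.3
#> CD8     18.0       12.0       2.3
#> FOXP3    1.0        1.5       0.0
```

Cohort medians fall from core to periphery for every class — the zonal
gradient the generator is calibrated to (the configured cohort medians are
tumor 2301/1141/250, IBA1 512/419/179, CD8 14/10/3, FOXP3 1.7/1.2/0.1
cells/mm²; a 12-patient draw scatters around them).

```r
compareRegions(dt[dt$cell_class == "TUMOR", ], "density",
               c("CORE", "PERIPHERY"), "density_TUMOR")
#>          metric region_a  region_b n_pairs statistic  p_value median_a median_b
#> 1 density_TUMOR     CORE PERIPHERY      12        78 0.000488     3529      400
```

All 12 paired differences are positive, so the signed-rank statistic is the
maximal W = 78 and the exact two-sided p is 2/2¹². The proximity statistic
and survival screen run the same way:

```r
pt <- cohortProximityTable(co$cellMaps, co$regionSets)  # 30 µm radius
median(pt$fraction[pt$region_label == "CORE" &
                   pt$neighbor_class == "IBA1" & pt$bin_label == "b1_4"])
#> [1] 0.74    # fraction of core tumor cells with 1-4 IBA1+ cells nearby

feats <- survivalFeatures(dt, buildRatioTable(dt), pt)
runSurvivalScreen(feats[, c("patient_id", "density_CORE_TUMOR")],
                  co$clinical, endpoints = "OS")
#>              feature endpoint cutoff hazard_ratio ci_lower ci_upper p_value
#> 1 density_CORE_TUMOR       OS   3529        0.355   0.0983     1.28   0.113
```

The hazard ratio is below 1 because the generator's survival model makes
high core tumor intensity protective (log HR = log 0.46 by default); at 12
patients the confidence interval is wide, as expected.

A shell entry point wrapping these stages
(`simulate | quantify | proximity | stats`) is installed at
`inst/cli/gliospatial.R`:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/gliospatial.R", package = "glioSpatial"))') \
  simulate --outdir cohort --seed 1
```

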