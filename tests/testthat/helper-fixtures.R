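# In-code fixtures shared across test files.

# axis-aligned rectangle ring
rectRing <- function(x1, x2, y1, y2)
  cbind(c(x1, x2, x2, x1), c(y1, y1, y2, y2))

# unit slide: three 1000x1000 um squares side by side (1 mm^2 each)
threeSquareRegions <- function(patientId = "PT") {
  RegionSet(patientId, list(
    Region("CORE", rectRing(0, 1000, 0, 1000)),
    Region("TRANSITION", rectRing(1000, 2000, 0, 1000)),
    Region("PERIPHERY", rectRing(2000, 3000, 0, 1000))))
}

# a small cell map with known per-region placement
smallCellMap <- function(patientId = "PT") {
  SlideCellMap(patientId, data.frame(
    cell_id = paste0("c", 1:6),
    x_um = c(500, 500, 1500, 1500, 2500, 2500),
    y_um = c(400, 600, 400, 600, 400, 600),
    cell_class = c("TUMOR", "IBA1", "TUMOR", "CD8", "TUMOR", "FOXP3")))
}

cellCsvText <- function(df) {
  c(paste(names(df), collapse = ","),
    apply(df, 1L, paste, collapse = ","))
}

geojsonFeature <- function(label, ring) {
  ring <- rbind(ring, ring[1L, ])
  pts <- paste0("[", ring[, 1L], ",", ring[, 2L], "]", collapse = ",")
  sprintf('{"type":"Feature","properties":{"region_label":"%s"},"geometry":{"type":"Polygon","coordinates":[[%s]]}}',
          label, pts)
}

geojsonText <- function(features, patientId = "PT") {
  sprintf('{"type":"FeatureCollection","patient_id":"%s","features":[%s]}',
          patientId, paste(features, collapse = ","))
}

# labeled-cells data.frame straight from a cell map and region set
labeledCells <- function(cellMap, regionSet)
  assignCellsToRegions(cellMap, regionSet)

# minimal clinical table text (2 patients)
clinicalCsvText <- function() c(
  "patient_id,os_months,os_event,pfs_months,pfs_event,age_group,sex,performance_status,treatment,mgmt,surgery,midline",
  "P1,14,TRUE,7.6,TRUE,under65,male,ps0_2,rt_chemo,methylated,total,none",
  "P2,20,FALSE,10,FALSE,at_least65,female,gt2,palliative,NA,biopsy,yes")
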