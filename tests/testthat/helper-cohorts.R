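# Default-configuration cohorts are the most expensive fixture in the suite;
# several test files need the same 20-seed batch of cohort medians, so it is
# computed lazily once per test run and cached.

.cohortBatchCache <- new.env(parent = emptyenv())

defaultCohortBatch <- function(nSeeds = 20L) {
  key <- paste0("seeds", nSeeds)
  if (!is.null(.cohortBatchCache[[key]])) return(.cohortBatchCache[[key]])
  out <- lapply(seq_len(nSeeds), function(s) {
    cfg <- syntheticCohortConfig(seed = 40000L + s)
    co <- generateCohort(cfg)
    dt <- cohortDensityTable(co$cellMaps, co$regionSets)
    rt <- buildRatioTable(dt)
    densMed <- sapply(REGION_LABELS, function(rl)
      sapply(CELL_CLASSES, function(cl)
        median(dt$density[dt$cell_class == cl & dt$region_label == rl])))
    latentMed <- apply(co$truth$lambda, c(1, 2), median)
    ratioMed <- sapply(REGION_LABELS, function(rl)
      sapply(unique(rt$ratio_name), function(rn)
        median(rt$value[rt$ratio_name == rn & rt$region_label == rl],
               na.rm = TRUE)))
    # mean relative estimation error per (class, region), Poisson noise only
    est <- array(NA_real_, dim = dim(co$truth$lambda))
    for (p in seq_len(dim(est)[3])) {
      pid <- dimnames(co$truth$lambda)[[3]][p]
      sub <- dt[dt$patient_id == pid, ]
      est[cbind(match(sub$cell_class, CELL_CLASSES),
                match(sub$region_label, REGION_LABELS), p)] <- sub$density
    }
    relErr <- apply((est - co$truth$lambda) / co$truth$lambda, c(1, 2), mean,
                    na.rm = TRUE)
    list(densMed = densMed, latentMed = latentMed, ratioMed = ratioMed,
         relErr = relErr, config = cfg)
  })
  .cohortBatchCache[[key]] <- out
  out
}
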