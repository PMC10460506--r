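test_that("config validity is enforced", {
  expect_error(simConfig(doubletFraction = 1), "doubletFraction")
  expect_error(simConfig(isgFoldNeuron = 0), "fold")
  expect_error(simConfig(gliaAmplitudeRange = c(8, 2)), "increasing")
  expect_error(simConfig(barcodeErrorRate = 2), "probabilities")
  ## the gene program needs room for markers + programmed classes
  expect_error(genTaggedReads(simConfig(nGenes = 100)), "too small")
})

test_that("default composition matches the study's published counts", {
  cfg <- simConfig()
  expect_equal(cfg@nCellsByType,
               c(Oligodendrocyte = 1241L, Astrocyte = 194L,
                 Microglia = 134L, Dopamine = 437L,
                 GABAergic = 1257L, VGLUT2 = 1436L))
  sce <- fixture("default_matrix", function()
    genNucleusMatrix(simConfig(), "saline", seed = 2L))
  expect_equal(as.vector(table(SummarizedExperiment::colData(sce)$type)[
    names(cfg@nCellsByType)]),
    unname(cfg@nCellsByType))
})

test_that("YAML configuration round-trips", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "seed: 4",
    "nGenes: 900",
    "markerGenesPerType: 15",
    "nCellsByType:",
    "  GABAergic: 40",
    "  Microglia: 20",
    "doubletFraction: 0.1"), path)
  cfg <- simConfigFromYAML(path)
  expect_s4_class(cfg, "SimConfig")
  expect_equal(cfg@seed, 4L)
  expect_equal(cfg@nCellsByType, c(GABAergic = 40L, Microglia = 20L))
  expect_equal(cfg@doubletFraction, 0.1)
  writeLines("bogusField: 3", path)
  expect_error(simConfigFromYAML(path), "unknown config fields")
})

test_that("generators are pure functions of config and seed", {
  cfg <- simConfig(seed = 31L,
                   nCellsByType = c(GABAergic = 25L, Microglia = 15L),
                   nGenes = 300L, markerGenesPerType = 10L,
                   moleculesPerCellMean = 15)
  expect_identical(genTaggedReads(cfg), genTaggedReads(cfg))
  expect_identical(genNucleusMatrix(cfg, "IFN"),
                   genNucleusMatrix(cfg, "IFN"))
  expect_identical(genBulkSeries(cfg), genBulkSeries(cfg))
  expect_identical(genNucleiImage(cfg), genNucleiImage(cfg))
  ## a different seed changes the draw
  expect_false(identical(genTaggedReads(cfg, seed = 99L)$reads,
                         genTaggedReads(cfg)$reads))
})

test_that("barcode substitution rate matches the binomial closed form", {
  cfg <- simConfig(seed = 41L, nCellsByType = c(GABAergic = 40L),
                   nGenes = 300L, markerGenesPerType = 10L,
                   barcodeErrorRate = 0.1, umiErrorRate = 0,
                   readsPerMoleculeMean = 2.5,
                   moleculesPerCellMean = 100)
  sim <- genTaggedReads(cfg)
  n <- nrow(sim$reads)
  expect_gt(n, 5000)
  ## whitelist min-distance 3 means one substitution always leaves the
  ## whitelist, so the off-whitelist fraction estimates the error rate
  offWl <- mean(!sim$reads$barcode %in% sim$whitelist)
  se <- sqrt(0.1 * 0.9 / n)
  expect_lt(abs(offWl - 0.1), 4 * se)
})

test_that("whitelist guarantees pairwise Hamming distance >= 3", {
  wl <- withr::with_seed(7, generateBarcodeWhitelist(40, 8))
  d <- outer(wl, wl, Vectorize(function(a, b)
    sum(utf8ToInt(a) != utf8ToInt(b))))
  expect_true(all(d[upper.tri(d)] >= 3))
})

test_that("nucleus matrix encodes the planted expression program", {
  cfg <- smallConfig(isgFoldNeuron = 2)
  saline <- fixture("small_saline", function()
    genNucleusMatrix(smallConfig(isgFoldNeuron = 2), "saline",
                     seed = 51L))
  ifn <- fixture("small_ifn", function()
    genNucleusMatrix(smallConfig(isgFoldNeuron = 2), "IFN",
                     seed = 52L))
  type <- SummarizedExperiment::colData(saline)$type
  rd <- SummarizedExperiment::rowData(saline)
  isg <- rownames(saline)[rd$class %in% c("isg_early", "isg_late")]
  fold <- S4Vectors::metadata(ifn)$inductionFolds

  meanBy <- function(sce, genes, ty) {
    m <- SummarizedExperiment::assay(sce)[genes, , drop = FALSE]
    rowMeans(as.matrix(
      m[, SummarizedExperiment::colData(sce)$type == ty, drop = FALSE]))
  }
  ## realized IFN/saline mean ratios track the generating amplitudes:
  ## pooled over ISGs per type to average NB noise out
  for (ty in c("GABAergic", "Oligodendrocyte", "Microglia")) {
    realized <- sum(meanBy(ifn, isg, ty)) / sum(meanBy(saline, isg, ty))
    expected <- sum(meanBy(saline, isg, ty) /
                      pmax(meanBy(saline, isg, ty), 1e-12) *
                      fold[isg, ty] * meanBy(saline, isg, ty)) /
      sum(meanBy(saline, isg, ty))
    expect_lt(abs(realized / expected - 1), 0.25)
  }
  ## neuronal ISG amplitude is the configured 2x; glial is >= that
  gab <- sum(meanBy(ifn, isg, "GABAergic")) /
    sum(meanBy(saline, isg, "GABAergic"))
  oligo <- sum(meanBy(ifn, isg, "Oligodendrocyte")) /
    sum(meanBy(saline, isg, "Oligodendrocyte"))
  expect_gt(oligo, gab)

  ## MHC-II induction is microglia-restricted
  mhc2 <- rownames(saline)[rd$class == "mhc2"]
  expect_gt(sum(meanBy(ifn, mhc2, "Microglia")),
            10 * sum(meanBy(saline, mhc2, "Microglia")))
  expect_lt(sum(meanBy(ifn, mhc2, "GABAergic")),
            3 * max(sum(meanBy(saline, mhc2, "GABAergic")), 0.5))

  ## marker genes are elevated only in their own type
  oligoMark <- plantedMarkers(cfg, "Oligodendrocyte")
  expect_gt(sum(meanBy(saline, oligoMark, "Oligodendrocyte")),
            20 * sum(meanBy(saline, oligoMark, "VGLUT2")))
})

test_that("doublet flags and constraints behave", {
  cfgNo <- smallConfig()
  sce <- fixture("small_saline_nodoub", function()
    genNucleusMatrix(smallConfig(), "saline", seed = 53L))
  expect_false(any(SummarizedExperiment::colData(sce)$doublet))

  cfgD <- smallConfig(doubletFraction = 0.05)
  sceD <- genNucleusMatrix(cfgD, "saline", seed = 54L,
                           doubletHosts = c("GABAergic", "VGLUT2"),
                           doubletPartners = "Oligodendrocyte")
  cd <- SummarizedExperiment::colData(sceD)
  expect_equal(sum(cd$doublet), round(0.05 * ncol(sceD)))
  expect_true(all(cd$type[cd$doublet] %in% c("GABAergic", "VGLUT2")))
  expect_true(all(cd$doublet_partner[cd$doublet] == "Oligodendrocyte"))

  expect_error(
    genNucleusMatrix(simConfig(nCellsByType = c(GABAergic = 50L),
                               doubletFraction = 0.1)),
    "two cell types")
})

test_that("bulk series has the planted kinetics", {
  se <- fixture("bulk_small", function()
    genBulkSeries(simConfig(seed = 61L, nGenes = 1200L,
                            markerGenesPerType = 20L)))
  cd <- SummarizedExperiment::colData(se)
  lcpm <- cpmLog2(SummarizedExperiment::assay(se))
  meanAt <- function(gene, gate, tp, tr = "IFN") {
    sel <- cd$sort_gate == gate & cd$treatment == tr &
      cd$timepoint_h == tp
    mean(lcpm[gene, sel])
  }
  tps <- c(6, 24, 48, 72)
  ## early ISG peaks at 6 h in both gates
  for (gate in c("NeuN+", "NeuN-")) {
    prof <- vapply(tps, function(tp) meanAt("Tap1", gate, tp),
                   numeric(1))
    expect_equal(tps[which.max(prof)], 6)
  }
  ## late ISG peaks at 24 h and is still elevated over saline at 72 h
  profL <- vapply(tps, function(tp) meanAt("H2-K1", "NeuN-", tp),
                  numeric(1))
  expect_equal(tps[which.max(profL)], 24)
  sal <- mean(lcpm["H2-K1", cd$sort_gate == "NeuN-" &
                     cd$treatment == "saline"])
  expect_gt(profL[tps == 72] - sal, 1)
  ## a filler (housekeeping) gene is flat across IFN timepoints
  rdClass <- SummarizedExperiment::rowData(se)$class
  hk <- rownames(se)[rdClass == "filler"][1]
  profH <- vapply(tps, function(tp) meanAt(hk, "NeuN-", tp), numeric(1))
  expect_lt(diff(range(profH)), 0.5)
})

test_that("image generator paints a consistent scene", {
  cfg <- simConfig(seed = 71L)
  img <- genNucleiImage(cfg, noiseSd = 0, background = 100,
                        signalLevels = c(`TH+/NeuN+` = 50,
                                         `TH-/NeuN+` = 50,
                                         `TH-/NeuN-` = 50))
  ## noise-free: ROI pixels sit exactly at background + painted level
  for (i in utils::head(img$truth$roi_id, 3)) {
    px <- img$labels == i
    expect_true(all(img$stack[, , "signal"][px] == 150))
  }
  expect_equal(median(img$stack[, , "signal"]), 100)

  none <- genNucleiImage(cfg, nPerClass = c(`TH+/NeuN+` = 0L,
                                            `TH-/NeuN+` = 0L,
                                            `TH-/NeuN-` = 0L))
  expect_true(all(none$labels == 0L))
  expect_equal(nrow(none$truth), 0L)

  expect_error(genNucleiImage(cfg, width = 40L, height = 40L,
                              nPerClass = c(`TH-/NeuN-` = 100L)),
               "cannot place")
  expect_error(genNucleiImage(cfg, width = 0L), "positive")
})
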