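.bulkPair <- function(seed, nGenes = 400, n = 5, foldGenes = NULL,
                      fold = 8, depth = 2e5, size = 50) {
  withr::with_seed(seed, {
    mu <- rlnorm(nGenes, log(30), 1)
    names(mu) <- paste0("g", seq_len(nGenes))
    muB <- mu
    if (!is.null(foldGenes)) muB[foldGenes] <- muB[foldGenes] * fold
    a <- matrix(rnbinom(nGenes * n, mu = mu / sum(mu) * depth,
                        size = size), nrow = nGenes,
                dimnames = list(names(mu), paste0("a", 1:n)))
    b <- matrix(rnbinom(nGenes * n, mu = muB / sum(muB) * depth,
                        size = size), nrow = nGenes,
                dimnames = list(names(mu), paste0("b", 1:n)))
  })
  list(a = a, b = b)
}

test_that("bulk test: identical groups, planted power, calibration", {
  pair <- .bulkPair(1)
  same <- perGeneBulkTest(pair$a, pair$a)
  expect_true(all(same$log2fc == 0))
  expect_true(all(same$p > 0.999))

  ## planted 8-fold genes pass |log2fc|>1 & fdr<0.01 in most seeds
  hits <- vapply(1:10, function(s) {
    pair <- .bulkPair(s, foldGenes = paste0("g", 1:10))
    tab <- perGeneBulkTest(pair$a, pair$b)
    sub <- tab[tab$gene %in% paste0("g", 1:10), ]
    all(sub$fdr < 0.01 & sub$log2fc > 1)
  }, logical(1))
  expect_gte(sum(hits), 9)

  ## null genes: empirical false-positive rate at fdr<0.01 is tiny
  fp <- vapply(1:10, function(s) {
    pair <- .bulkPair(s + 100)
    tab <- perGeneBulkTest(pair$a, pair$b)
    mean(tab$fdr < 0.01)
  }, numeric(1))
  expect_lte(mean(fp), 0.01)

  expect_error(perGeneBulkTest(pair$a[, 1, drop = FALSE], pair$b),
               ">= 2 replicates")
})

test_that("welch and ranksum methods are available and sane", {
  pair <- .bulkPair(3, foldGenes = "g1", fold = 30)
  tw <- perGeneBulkTest(pair$a, pair$b, method = "welch")
  tr <- perGeneBulkTest(pair$a, pair$b, method = "ranksum")
  expect_lt(tw$p[tw$gene == "g1"], 0.01)
  ## the exact rank-sum p-value floor at 5v5 is 2/choose(10,5)
  expect_equal(min(tr$p), 2 / choose(10, 5))
})

test_that("DEG counts per timepoint with overlap subsets", {
  se <- fixture("bulk_small", function()
    genBulkSeries(simConfig(seed = 61L, nGenes = 1200L,
                            markerGenesPerType = 20L)))
  dc <- fixture("bulk_counts", function()
    degCountsByTimepoint(fixture("bulk_small", function() NULL)))
  cnt <- dc$counts
  ## more glial than neuronal upregulated genes at 6 and 24 h
  for (tp in c(6, 24)) {
    expect_gt(cnt$up[cnt$sort_gate == "NeuN-" & cnt$timepoint_h == tp],
              cnt$up[cnt$sort_gate == "NeuN+" & cnt$timepoint_h == tp])
  }
  ## overlap is a subset of each gate's calls at every timepoint
  for (tp in c(6, 24, 48, 72)) {
    up1 <- dc$calls[["NeuN+"]][[as.character(tp)]]$up
    up2 <- dc$calls[["NeuN-"]][[as.character(tp)]]$up
    ov <- intersect(up1, up2)
    expect_true(all(ov %in% up1) && all(ov %in% up2))
    expect_equal(
      cnt$overlap_up[cnt$sort_gate == "NeuN+" & cnt$timepoint_h == tp],
      length(ov))
  }
})

test_that("persistent core genes require both gates and >= 3 timepoints", {
  calls <- list(
    `NeuN+` = list(
      `6` = list(up = c("x", "y", "zz"), down = character()),
      `24` = list(up = c("x", "y"), down = character()),
      `48` = list(up = c("x", "y"), down = character()),
      `72` = list(up = "x", down = character())),
    `NeuN-` = list(
      `6` = list(up = c("x", "y"), down = character()),
      `24` = list(up = c("x", "y"), down = character()),
      `48` = list(up = "x", down = character()),
      `72` = list(up = c("x", "glia_only"), down = character())))
  ## x: 4 and 4 timepoints; y: 3 and 2 -> excluded; zz/glia_only: one
  ## gate only
  expect_equal(persistentCoreGenes(calls), "x")
  expect_setequal(persistentCoreGenes(calls, minTimepoints = 2),
                  c("x", "y"))
  expect_equal(persistentCoreGenes(calls, minTimepoints = 3,
                                   strictlyGreater = TRUE), "x")
  ## simulated late ISGs persist in both gates
  dc <- fixture("bulk_counts", function() NULL)
  core <- persistentCoreGenes(dc$calls)
  lateIsg <- c("H2-K1", "H2-D1", "B2m", "Psmb9", "Stat1", "Nlrc5",
               "Gbp2", "Tap2", "Psmb8", "Irgm1")
  expect_gte(mean(core %in% lateIsg), 0.7)
})

test_that("kinetics profile: closed form, pooling identity, arg-max", {
  se <- fixture("bulk_small", function() NULL)
  kp <- kineticsProfile(se, c("Tap1", "H2-K1"))
  cd <- SummarizedExperiment::colData(se)
  lcpm <- cpmLog2(SummarizedExperiment::assay(se))

  ## hand-computed mean/SEM for one design cell
  sel <- cd$sort_gate == "NeuN-" & cd$treatment == "IFN" &
    cd$timepoint_h == 6
  v <- lcpm["Tap1", sel]
  row <- kp[kp$gene == "Tap1" & kp$sort_gate == "NeuN-" &
              kp$timepoint_h == 6, ]
  expect_equal(row$mean, mean(v), tolerance = 1e-12)
  expect_equal(row$sem, sd(v) / sqrt(length(v)), tolerance = 1e-12)
  expect_equal(row$n, sum(sel))

  ## saline pooling at t=0: equals the weighted mean of per-timepoint
  ## saline means
  salSel <- cd$sort_gate == "NeuN-" & cd$treatment == "saline"
  row0 <- kp[kp$gene == "Tap1" & kp$sort_gate == "NeuN-" &
               kp$timepoint_h == 0, ]
  expect_equal(row0$mean, mean(lcpm["Tap1", salSel]), tolerance = 1e-12)
  perTp <- tapply(lcpm["Tap1", salSel], cd$timepoint_h[salSel], mean)
  wts <- table(cd$timepoint_h[salSel])
  expect_equal(row0$mean,
               sum(perTp * as.numeric(wts)) / sum(wts),
               tolerance = 1e-12)

  ## early ISG profile peaks at 6 h in both gates
  for (gate in c("NeuN+", "NeuN-")) {
    prof <- kp[kp$gene == "Tap1" & kp$sort_gate == gate &
                 kp$timepoint_h > 0, ]
    expect_equal(prof$timepoint_h[which.max(prof$mean)], 6)
  }
  expect_error(kineticsProfile(se, "NotAGene"), "absent")
})

test_that("interaction permutation test is calibrated and powered", {
  se <- fixture("bulk_small", function() NULL)
  ic <- fixture("bulk_ic", function()
    interactionCalls(fixture("bulk_small", function() NULL), 6,
                     nPerm = 1000, seed = 3))
  tab <- ic$table
  rdClass <- SummarizedExperiment::rowData(se)$class
  names(rdClass) <- rownames(se)

  ## genes induced identically in both gates (none planted) vs planted
  ## glia-only module genes
  expect_true(all(plantedModuleGenes("green") %in% ic$genes))
  expect_true(all(plantedModuleGenes("yellow") %in% ic$genes))

  ## full null: a design with no treatment or interaction effect gives
  ## uniform permutation p-values
  nullSe <- withr::with_seed(99, {
    design <- expand.grid(sort_gate = c("NeuN+", "NeuN-"),
                          treatment = c("saline", "IFN"),
                          stringsAsFactors = FALSE)
    design <- design[rep(1:4, each = 5), ]
    design$timepoint_h <- 6
    mu <- rlnorm(600, log(50), 1)
    counts <- matrix(rnbinom(600 * 20, mu = mu, size = 50), nrow = 600,
                     dimnames = list(paste0("g", 1:600),
                                     paste0("r", 1:20)))
    SummarizedExperiment::SummarizedExperiment(
      assays = list(counts = counts),
      colData = S4Vectors::DataFrame(design,
                                     row.names = colnames(counts)))
  })
  icNull <- interactionCalls(nullSe, 6, nPerm = 500, seed = 4)
  pNull <- icNull$table$p
  ks <- suppressWarnings(ks.test(pNull, "punif"))
  expect_gt(ks$p.value, 0.01)
  ## shared permutations correlate genes, so the point estimate is
  ## noisier than an independent binomial; bound it loosely
  expect_lt(mean(pNull < 0.05), 0.1)
  expect_length(icNull$genes, 0L)
})

test_that("response modules recover planted archetypes", {
  se <- fixture("bulk_small", function() NULL)
  dc <- fixture("bulk_counts", function() NULL)
  ic <- fixture("bulk_ic", function() NULL)
  mods <- classifyResponseModules(
    dc$tables[["NeuN+@6"]], dc$tables[["NeuN-@6"]], ic$genes,
    baselineMeansByGate(se, "NeuN+"), baselineMeansByGate(se, "NeuN-"))
  planted <- c(purple = "purple", green = "green", orange = "orange",
               yellow = "yellow")
  for (m in names(planted)) {
    genes <- plantedModuleGenes(m)
    expect_gte(mean(genes %in% names(mods)[mods == m]), 0.9)
    ## no planted gene of this archetype lands in a different module
    wrong <- mods[intersect(genes, names(mods))]
    expect_true(all(wrong %in% c(m, "UNCLASSIFIED")))
  }
})

test_that("module rules on crafted single-gene tables", {
  mkDE <- function(fc, fdr) data.frame(
    gene = "g", log2fc = fc, statistic = 0, p = fdr, fdr = fdr,
    mean_a = 10, mean_b = 10, stringsAsFactors = FALSE)
  ## up 2-fold in neurons, 6-fold in glia, interaction-significant ->
  ## purple
  out <- classifyResponseModules(
    mkDE(1.1, 1e-5), mkDE(log2(6), 1e-6), "g",
    c(g = 5), c(g = 5))
  expect_equal(unname(out["g"]), "purple")
  ## neuron-only baseline, glia-only downregulation -> orange
  out2 <- classifyResponseModules(
    mkDE(0, 0.9), mkDE(-2.5, 1e-6), "g", c(g = 6), c(g = 1))
  expect_equal(unname(out2["g"]), "orange")
  ## glia-high baseline with glial downregulation -> yellow
  out3 <- classifyResponseModules(
    mkDE(0, 0.9), mkDE(-2.5, 1e-6), "g", c(g = 1), c(g = 6))
  expect_equal(unname(out3["g"]), "yellow")
  ## no interaction call -> no classification
  out4 <- classifyResponseModules(
    mkDE(1.1, 1e-5), mkDE(3, 1e-6), character(0), c(g = 5), c(g = 5))
  expect_length(out4, 0L)
  ## mismatched universes warn
  expect_warning(classifyResponseModules(
    mkDE(1.1, 1e-5), mkDE(3, 1e-6), c("g", "missing"),
    c(g = 5), c(g = 5)), "mismatch")
})
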