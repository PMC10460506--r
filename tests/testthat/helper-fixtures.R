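## Shared fixtures, built once per test run and memoised.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures, inherits = FALSE))
    assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

## A small six-type configuration used by most single-nucleus tests.
smallConfig <- function(seed = 11L, ...) {
  simConfig(
    seed = seed,
    nCellsByType = c(Oligodendrocyte = 120L, Astrocyte = 50L,
                     Microglia = 50L, Dopamine = 60L,
                     GABAergic = 90L, VGLUT2 = 90L),
    nGenes = 1000L,
    markerGenesPerType = 110L,
    moleculesPerCellMean = 40,
    ...
  )
}

## One-type configuration for DE tests (n cells per group).
deConfig <- function(seed = 5L, n = 100L, fold = 16, ...) {
  simConfig(seed = seed, nCellsByType = c(GABAergic = as.integer(n)),
            nGenes = 1200L, markerGenesPerType = 30L,
            isgFoldNeuron = fold, ...)
}

isgGenes <- function() {
  cfg <- deConfig()
  sce <- fixture("de_saline_ref", function()
    genNucleusMatrix(deConfig(), "saline", seed = 1L))
  rownames(sce)[SummarizedExperiment::rowData(sce)$class %in%
                  c("isg_early", "isg_late")]
}

## Exhaustive oracle for UMI collapse: all pairwise Hamming distances,
## connected components via igraph, representative by
## max-support/lexicographic rule. Independent of the package's
## union-find/neighbour-hash implementation.
oracleCollapse <- function(reads, whitelist) {
  corrected <- vapply(reads$barcode, function(bc) {
    if (bc %in% whitelist) return(bc)
    d <- vapply(whitelist, function(w)
      sum(utf8ToInt(w) != utf8ToInt(bc)), numeric(1))
    hits <- whitelist[d == 1]
    if (length(hits) == 1L) hits else NA_character_
  }, character(1), USE.NAMES = FALSE)
  keep <- !is.na(corrected)
  reads <- reads[keep, , drop = FALSE]
  corrected <- corrected[keep]
  out <- list()
  for (bucketKey in unique(paste(corrected, reads$gene_id, sep = "|"))) {
    sel <- paste(corrected, reads$gene_id, sep = "|") == bucketKey
    umis <- reads$umi[sel]
    support <- table(umis)
    u <- names(support)
    n <- length(u)
    adj <- matrix(FALSE, n, n)
    for (i in seq_len(n)) for (j in seq_len(n))
      adj[i, j] <- sum(utf8ToInt(u[i]) != utf8ToInt(u[j])) <= 1
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    comp <- igraph::components(g)$membership
    parts <- strsplit(bucketKey, "|", fixed = TRUE)[[1]]
    for (cid in unique(comp)) {
      members <- u[comp == cid]
      sup <- as.integer(support[members])
      rep_ <- members[order(-sup, members)][1]
      out[[length(out) + 1L]] <- data.frame(
        barcode = parts[1], umi = rep_, gene_id = parts[2],
        read_support = sum(sup), stringsAsFactors = FALSE)
    }
  }
  mol <- do.call(rbind, out)
  if (is.null(mol))
    return(data.frame(barcode = character(), umi = character(),
                      gene_id = character(), read_support = integer(),
                      stringsAsFactors = FALSE))
  mol <- mol[order(mol$barcode, mol$gene_id, mol$umi), , drop = FALSE]
  rownames(mol) <- NULL
  mol
}

## Random small read tables with heavy UMI collisions (short UMIs over
## a reduced alphabet) to exercise the collapse graph.
randomReadInstance <- function(seed, maxReads = 1000L) {
  withr::with_seed(seed, {
    whitelist <- generateBarcodeWhitelist(sample(2:5, 1), 8L)
    nReads <- sample.int(maxReads, 1)
    umiPool <- apply(matrix(sample(c("A", "C"), 4 * 40, replace = TRUE),
                            ncol = 4), 1, paste, collapse = "")
    reads <- data.frame(
      read_id = sprintf("r%04d", seq_len(nReads)),
      barcode = sample(whitelist, nReads, replace = TRUE),
      umi = sample(umiPool, nReads, replace = TRUE),
      gene_id = sample(c("geneA", "geneB", "geneC"), nReads,
                       replace = TRUE),
      stringsAsFactors = FALSE
    )
    ## corrupt a few barcodes so the correction path is exercised
    flip <- runif(nReads) < 0.05
    reads$barcode[flip] <- vapply(reads$barcode[flip], function(bc) {
      pos <- sample.int(nchar(bc), 1)
      substr(bc, pos, pos) <- sample(setdiff(c("A", "C", "G", "T"),
                                             substr(bc, pos, pos)), 1)
      bc
    }, character(1))
  })
  list(reads = reads, whitelist = whitelist)
}
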