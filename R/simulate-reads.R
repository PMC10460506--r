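.BASES <- c("A", "C", "G", "T")

randomTags <- function(n, len) {
  m <- matrix(sample(.BASES, n * len, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

## All strings at Hamming distance exactly 1 from each of `tags`.
hammingBall1 <- function(tags) {
  len <- nchar(tags[1])
  out <- vector("list", len)
  for (pos in seq_len(len)) {
    pre <- substr(tags, 1, pos - 1)
    suf <- substr(tags, pos + 1, len)
    cur <- substr(tags, pos, pos)
    alt <- lapply(.BASES, function(b) {
      keep <- which(cur != b)
      if (!length(keep)) return(character(0))
      paste0(pre[keep], b, suf[keep])
    })
    out[[pos]] <- unlist(alt)
  }
  unlist(out)
}

#' Generate a barcode whitelist with guaranteed error-correction margin
#'
#' Draws `n` random barcodes whose pairwise Hamming distance is at least
#' 3, so that any single-nucleotide error is uniquely correctable (the
#' radius-1 balls around whitelist members are disjoint). Mirrors the
#' design constraint of plate-known barcode sets.
#'
#' @param n number of barcodes.
#' @param length barcode length in nucleotides.
#' @return character vector of `n` distinct barcodes.
#' @export
generateBarcodeWhitelist <- function(n, length = 12L) {
  if (4^length / 50 < n)
    stop("barcode length too short for ", n, " well-separated barcodes")
  accepted <- character(0)
  occupied <- new.env(hash = TRUE, parent = emptyenv())
  while (length(accepted) < n) {
    cand <- unique(randomTags(max(64L, n - length(accepted)), length))
    for (bc in cand) {
      if (length(accepted) >= n) break
      ball <- c(bc, hammingBall1(bc))
      if (any(vapply(ball, exists, logical(1), envir = occupied,
                     inherits = FALSE)))
        next
      for (s in ball) assign(s, TRUE, envir = occupied)
      accepted <- c(accepted, bc)
    }
  }
  accepted
}

## Inject at most one substitution per tag, each tag hit independently
## with probability `rate`. Returns the mutated vector.
injectSubstitutions <- function(tags, rate) {
  n <- length(tags)
  hit <- which(runif(n) < rate)
  if (!length(hit)) return(tags)
  len <- nchar(tags[1])
  pos <- sample.int(len, length(hit), replace = TRUE)
  cur <- substr(tags[hit], pos, pos)
  shift <- sample.int(3, length(hit), replace = TRUE)
  newBase <- .BASES[(match(cur, .BASES) - 1L + shift) %% 4L + 1L]
  mutated <- tags[hit]
  substr(mutated, pos, pos) <- newBase
  tags[hit] <- mutated
  tags
}

#' Simulate barcode/UMI-tagged reads with ground truth
#'
#' Emulates the read table that enters demultiplexing: each cell is a
#' whitelist barcode, each true molecule a (barcode, UMI, gene) triple,
#' and each molecule is sequenced as one or more reads (PCR duplicates)
#' into which single-nucleotide substitutions are injected at the
#' configured barcode/UMI error rates (at most one substitution per tag
#' per read).
#'
#' @param config a [SimConfig-class]. The number of cells is
#'   `sum(nCellsByType)`; per-cell molecule counts are Poisson with mean
#'   `moleculesPerCellMean`.
#' @param seed optional integer overriding `config@seed`.
#' @return list with elements:
#'   \describe{
#'     \item{reads}{data.frame `read_id`, `barcode`, `umi`, `gene_id`,
#'       `true_molecule` (index into `molecules`).}
#'     \item{molecules}{ground-truth data.frame `molecule_id`,
#'       `barcode`, `umi`, `gene_id`, `n_reads`.}
#'     \item{whitelist}{the true barcodes.}
#'   }
#' @export
genTaggedReads <- function(config, seed = config@seed) {
  validObject(config)
  nCells <- sum(config@nCellsByType)
  if (nCells < 1L) stop("config requests zero cells")
  genes <- geneProgram(config)$gene
  withr::with_seed(seed, {
    whitelist <- generateBarcodeWhitelist(nCells, config@barcodeLength)
    molPerCell <- rpois(nCells, config@moleculesPerCellMean)
    if (sum(molPerCell) == 0L) stop("zero molecules requested")
    nMol <- sum(molPerCell)
    mol <- data.frame(
      molecule_id = seq_len(nMol),
      barcode = rep(whitelist, molPerCell),
      umi = randomTags(nMol, config@umiLength),
      gene_id = sample(genes, nMol, replace = TRUE),
      stringsAsFactors = FALSE
    )
    extra <- config@readsPerMoleculeMean - 1
    mol$n_reads <- 1L + rpois(nMol, extra)
    idx <- rep.int(mol$molecule_id, mol$n_reads)
    reads <- data.frame(
      read_id = sprintf("read%07d", seq_along(idx)),
      barcode = injectSubstitutions(mol$barcode[idx],
                                    config@barcodeErrorRate),
      umi = injectSubstitutions(mol$umi[idx], config@umiErrorRate),
      gene_id = mol$gene_id[idx],
      true_molecule = idx,
      stringsAsFactors = FALSE
    )
  })
  list(reads = reads, molecules = mol, whitelist = whitelist)
}
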