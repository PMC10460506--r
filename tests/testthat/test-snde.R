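.randCounts <- function(seed, nGenes = 50, nCells = 30, mu = 2) {
  withr::with_seed(seed, {
    m <- matrix(rnbinom(nGenes * nCells, mu = mu, size = 1),
                nrow = nGenes,
                dimnames = list(paste0("g", seq_len(nGenes)),
                                paste0("c", seq_len(nCells))))
  })
  m
}

test_that("cell-number equalization follows the min rule", {
  a <- .randCounts(1, nCells = 150)
  b <- .randCounts(2, nCells = 100)
  colnames(b) <- paste0("b", seq_len(ncol(b)))
  eq <- equalizeCellNumbers(a, b, seed = 3)
  expect_equal(ncol(eq$a), 100L)
  expect_equal(ncol(eq$b), 100L)
  ## the smaller group is untouched
  expect_identical(eq$b, b)
  ## same seed -> same subset; different seed -> (almost surely) not
  expect_identical(equalizeCellNumbers(a, b, seed = 3)$idx_a, eq$idx_a)
  expect_false(identical(equalizeCellNumbers(a, b, seed = 4)$idx_a,
                         eq$idx_a))
  ## equal sizes -> identity
  eq2 <- equalizeCellNumbers(b, b, seed = 1)
  expect_identical(eq2$a, b)
  expect_error(equalizeCellNumbers(a[, 0], b), "empty")
})

test_that("depth equalization thins binomially toward the target", {
  a <- .randCounts(5, nCells = 40, mu = 5)   # deeper
  b <- .randCounts(6, nCells = 40, mu = 4)
  eq <- equalizeTranscriptDepth(a, b, seed = 7)
  expect_equal(eq$thinned, "a")
  expect_equal(eq$p, mean(colSums(b)) / mean(colSums(a)))
  ## entrywise never exceeds the original
  expect_true(all(eq$a <= a))
  expect_identical(eq$b, b)

  ## realized means across 20 seeds stay within 3 SE of the target
  target <- mean(colSums(b))
  p <- eq$p
  se <- sqrt(p * (1 - p) * sum(a)) / ncol(a)
  realized <- vapply(1:20, function(s)
    mean(colSums(equalizeTranscriptDepth(a, b, seed = s)$a)),
    numeric(1))
  expect_lt(abs(mean(realized) - target), 3 * se / sqrt(20))

  ## equal means -> no thinning
  same <- equalizeTranscriptDepth(b, b, seed = 1)
  expect_equal(same$p, 1)
  expect_error(equalizeTranscriptDepth(a * 0, b), "zero-mean")
})

test_that("rank-sum DE agrees with wilcox.test gene by gene", {
  a <- .randCounts(8, nGenes = 40, nCells = 25)
  b <- .randCounts(9, nGenes = 40, nCells = 25)
  b[1:5, ] <- b[1:5, ] * 10L
  tab <- rankSumDE(a, b)
  ## oracle: per-gene wilcox.test on identically normalized values
  sf <- ifngtools:::.sizeFactorsFor(cbind(a, b))
  norm <- sweep(cbind(a, b), 2, sf, "/")
  for (g in tab$gene[c(1:5, 20:24)]) {
    wt <- suppressWarnings(wilcox.test(
      norm[g, ncol(a) + seq_len(ncol(b))], norm[g, seq_len(ncol(a))],
      correct = TRUE))
    row <- tab[tab$gene == g, ]
    expect_equal(row$p, wt$p.value, tolerance = 1e-10, info = g)
    expect_equal(row$statistic, unname(wt$statistic), info = g)
  }
})

test_that("rank-sum DE basic contracts", {
  a <- .randCounts(10, nGenes = 30, nCells = 20)
  ## identical groups: p = 1 everywhere, log2fc = 0
  tab <- rankSumDE(a, a)
  expect_true(all(tab$p == 1))
  expect_true(all(tab$log2fc == 0))

  ## swapping labels negates log2fc and preserves p
  b <- .randCounts(11, nGenes = 30, nCells = 20)
  t1 <- rankSumDE(a, b)
  t2 <- rankSumDE(b, a)
  expect_equal(t1$log2fc, -t2$log2fc)
  expect_equal(t1$p, t2$p)

  ## BH is monotone with p
  o <- order(t1$p)
  expect_true(all(diff(t1$fdr[o]) >= -1e-15))

  ## all-zero genes are excluded
  z <- rbind(a, zz = 0)
  expect_false("zz" %in% rankSumDE(z, rbind(b, zz = 0))$gene)

  expect_error(rankSumDE(a[, 1:2], b), ">= 3 cells")
})

test_that("small groups use the exact test", {
  a <- .randCounts(12, nGenes = 15, nCells = 5, mu = 10)
  b <- .randCounts(13, nGenes = 15, nCells = 5, mu = 10)
  tab <- rankSumDE(a, b)
  sf <- ifngtools:::.sizeFactorsFor(cbind(a, b))
  norm <- sweep(cbind(a, b), 2, sf, "/")
  for (g in tab$gene[1:5]) {
    wt <- suppressWarnings(wilcox.test(norm[g, 6:10], norm[g, 1:5],
                                       exact = TRUE))
    expect_equal(tab$p[tab$gene == g], wt$p.value, info = g)
  }
})

test_that("replicated DE intersects calls with consistent sign", {
  ctrl <- SummarizedExperiment::assay(
    genNucleusMatrix(deConfig(), "saline", seed = 30L))
  t1 <- SummarizedExperiment::assay(
    genNucleusMatrix(deConfig(), "IFN", seed = 31L))
  t2 <- SummarizedExperiment::assay(
    genNucleusMatrix(deConfig(), "IFN", seed = 32L))
  res <- replicatedDE(ctrl, list(S1 = t1, S2 = t2), seed = 33L)
  isg <- isgGenes()
  ## 16-fold planted ISGs are recovered in both samples
  expect_gte(mean(isg %in% res$up), 0.9)
  ## nothing outside the planted program is called
  expect_length(setdiff(res$up, isg), 0L)
  expect_length(res$down, 0L)

  ## a gene passing in one sample only is not called: replace one
  ## treated sample with a control redraw
  nullS <- SummarizedExperiment::assay(
    genNucleusMatrix(deConfig(), "saline", seed = 35L))
  resHalf <- replicatedDE(ctrl, list(S1 = t1, S2 = nullS), seed = 36L)
  expect_length(resHalf$up, 0L)
})

test_that("opposite-sign passes are never called", {
  ## craft two groups where the same gene flips direction across
  ## "samples" by swapping the treated/control roles
  a <- .randCounts(20, nGenes = 20, nCells = 30, mu = 3)
  up <- a; up["g1", ] <- up["g1", ] + 50L
  res <- replicatedDE(a, list(S1 = up, S2 = a * 0L + a), seed = 2)
  expect_false("g1" %in% res$up)
  down <- a; down["g1", ] <- 0L
  res2 <- replicatedDE(a, list(S1 = up, S2 = down), seed = 2)
  expect_false("g1" %in% res2$up)
  expect_false("g1" %in% res2$down)
})
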