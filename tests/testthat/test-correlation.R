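test_that("promoter bins tile the upstream 2 kb, strand-aware", {
  sl <- c(chr1 = 20000L)
  gp <- GenomicRanges::GRanges("chr1", IRanges::IRanges(10001, 12000),
                               strand = "+", gene_id = "gp", seqlengths = sl)
  bp <- promoterBins(gp)
  expect_length(bp, 10)
  expect_equal(min(GenomicRanges::start(bp)), 8001)
  expect_equal(max(GenomicRanges::end(bp)), 10000)
  b1 <- bp[bp$bin == 1]
  expect_equal(c(GenomicRanges::start(b1), GenomicRanges::end(b1)),
               c(9801, 10000))

  gm <- GenomicRanges::GRanges("chr1", IRanges::IRanges(8001, 10000),
                               strand = "-", gene_id = "gm", seqlengths = sl)
  bm <- promoterBins(gm)
  expect_equal(min(GenomicRanges::start(bm)), 10001)
  expect_equal(max(GenomicRanges::end(bm)), 12000)
  bm1 <- bm[bm$bin == 1]
  expect_equal(c(GenomicRanges::start(bm1), GenomicRanges::end(bm1)),
               c(10001, 10200))

  # strand flip mirrors bin coordinates about the TSS
  dTSSp <- GenomicRanges::start(gp) - GenomicRanges::end(bp)   # plus strand
  dTSSm <- GenomicRanges::start(bm) - GenomicRanges::end(gm)   # minus strand
  expect_equal(sort(dTSSp), sort(dTSSm))

  # truncation at the chromosome start
  edge <- GenomicRanges::GRanges("chr1", IRanges::IRanges(150, 1000),
                                 strand = "+", gene_id = "ge", seqlengths = sl)
  be <- promoterBins(edge)
  expect_length(be, 1)
  expect_equal(c(GenomicRanges::start(be), GenomicRanges::end(be)), c(1, 149))
})

test_that("bin methylation pools replicate counts before dividing", {
  bins <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 201),
                                                          width = 200))
  r1 <- makeTrack(pos = c(10, 50), mc = c(1, 0), cov = c(5, 5))
  r2 <- makeTrack(pos = c(10, 90), mc = c(3, 1), cov = c(15, 5),
                  replicate = "R2")
  lv <- binMethylation(list(S0 = list(r1, r2)), bins)
  expect_equal(unname(lv[1, "S0"]), 5 / 30)  # summed counts, not averaged levels
  expect_true(is.na(lv[2, "S0"]))            # uncovered bin flagged missing
  single <- binMethylation(list(S0 = list(makeTrack(10, 1, 10))), bins)
  expect_equal(unname(single[1, "S0"]), 0.1)
})

test_that("best-bin selection matches an exhaustive brute-force maximizer", {
  set.seed(15)
  nGenes <- 200; nS <- 9
  for (i in seq_len(nGenes)) {
    expr <- rnorm(nS)
    bl <- matrix(runif(10 * nS), nrow = 10)
    got <- bestBinCorrelation(expr, bl)
    # brute force with cor.test over every bin
    rs <- apply(bl, 1L, function(x) cor(x, expr))
    best <- which.max(abs(rs))
    ct <- cor.test(bl[best, ], expr)
    expect_equal(got$bin, unname(best))
    expect_equal(got$r, unname(rs[best]), tolerance = 1e-12)
    expect_equal(got$p_value, ct$p.value, tolerance = 1e-12)
  }
})

test_that("best-bin handles perfect, tied and degenerate inputs", {
  expr <- c(5, 3, 8, 1, 6, 4)
  bl <- matrix(runif(60), nrow = 10)
  bl[4, ] <- 0.9 - 0.1 * expr          # exact negative affine image
  got <- bestBinCorrelation(expr, bl)
  expect_equal(got$bin, 4L)
  expect_equal(got$r, -1)

  dup <- rbind(bl[4, ], bl[4, ], bl[4, ])
  expect_equal(bestBinCorrelation(expr, dup)$bin, 1L)   # TSS-proximal tie

  const <- matrix(0.3, nrow = 2, ncol = 6)
  nores <- bestBinCorrelation(expr, const)
  expect_true(is.na(nores$bin))
  # too few complete pairs
  sparse <- matrix(c(0.1, 0.5, 0.2, NA, NA, NA), nrow = 1)
  expect_true(is.na(bestBinCorrelation(expr, sparse, minSamples = 4)$bin))
})

test_that("BH classification matches an independent step-up oracle", {
  res <- data.frame(r = rep(c(0.9, -0.9), 10), p_value = rep(1, 20))
  out <- fdrAdjustAndClassify(res)
  expect_true(all(out$sign_class == "none"))

  set.seed(16)
  res2 <- data.frame(r = runif(500, -1, 1),
                     p_value = c(runif(100, 0, 1e-4), runif(400)))
  out2 <- fdrAdjustAndClassify(res2)
  expect_equal(out2$q_value, bhOracle(res2$p_value))
  sig <- out2$q_value < 0.01
  expect_identical(out2$sign_class[sig],
                   ifelse(out2$r[sig] > 0, "positive", "negative"))
  expect_true(all(out2$sign_class[!sig] == "none"))
})

test_that("the correlation summary reports the classified fraction in percent", {
  res <- data.frame(r = c(0.9, -0.8, 0.1), p_value = c(1e-6, 1e-5, 0.9))
  out <- fdrAdjustAndClassify(res)
  s <- summarizeCorrelation(out)
  expect_equal(s$n_tested, 3)
  expect_equal(s$n_significant, 2)
  expect_equal(s$percent, 66.67)
})

test_that("modified-promoter rule uses a strict 0.5 level cutoff", {
  proms <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 2001, 4001),
                                                           width = 2000))
  tr <- makeTrack(pos = c(100, 2100), mc = c(6, 5), cov = c(10, 10))
  flag <- modifiedPromoter(list(tr), proms)
  expect_identical(flag, c(TRUE, FALSE, NA))   # 0.6, exactly 0.5, no coverage
})

test_that("planted methylation-expression links are classified with the planted sign", {
  fx <- fixtureNineStage()
  res <- correlateMethylationExpression(fx$tracks,
                                        annotationGenes(fx$annotation),
                                        fx$expr)
  lg <- linkedGenes(fx$truth)
  m <- merge(res, lg, by = "gene_id")
  hit <- m$sign_class == ifelse(m$sign > 0, "positive", "negative")
  expect_gt(mean(hit), 0.8)
  unl <- res[!res$gene_id %in% lg$gene_id, ]
  expect_lt(mean(unl$sign_class != "none"), 0.15)  # small-n fixture bound
})

test_that("classification is invariant to gene order and sample relabeling", {
  fx <- fixtureNineStage()
  genes <- annotationGenes(fx$annotation)
  res <- correlateMethylationExpression(fx$tracks, genes, fx$expr)
  resRev <- correlateMethylationExpression(fx$tracks, rev(genes), fx$expr)
  expect_equal(summarizeCorrelation(res)$percent,
               summarizeCorrelation(resRev)$percent)
  o <- order(res$gene_id)
  oR <- order(resRev$gene_id)
  expect_equal(res$r[o], resRev$r[oR])
  expect_identical(res$sign_class[o], resRev$sign_class[oR])
})
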