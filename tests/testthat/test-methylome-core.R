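test_that("weighted methylation pools counts, never averages levels", {
  tr <- makeTrack(pos = c(5, 20), mc = c(3, 1), cov = c(10, 30))
  expect_equal(weightedMethylation(tr, "CHH")$level, 4 / 40)
  one <- makeTrack(pos = 5, mc = 5, cov = 100)
  expect_equal(weightedMethylation(one, "CHH")$level, 0.05)
  zero <- makeTrack(pos = c(5, 20), mc = c(0, 0), cov = c(10, 30))
  expect_equal(weightedMethylation(zero, "CHH")$level, 0)
})

test_that("weighted methylation is invariant to site order and replicate splits", {
  set.seed(1)
  pos <- sample(1e4, 200)
  cov <- rpois(200, 20) + 1L
  mc <- rbinom(200, cov, 0.2)
  whole <- makeTrack(pos = sort(pos), mc = mc[order(pos)],
                     cov = cov[order(pos)])
  cut <- sample(c(TRUE, FALSE), 200, replace = TRUE)
  partA <- makeTrack(pos = sort(pos[cut]), mc = mc[cut][order(pos[cut])],
                     cov = cov[cut][order(pos[cut])], replicate = "R1")
  partB <- makeTrack(pos = sort(pos[!cut]), mc = mc[!cut][order(pos[!cut])],
                     cov = cov[!cut][order(pos[!cut])], replicate = "R2")
  expect_equal(weightedMethylation(list(partA, partB), "CHH")$level,
               weightedMethylation(whole, "CHH")$level)
})

test_that("undefined level is flagged instead of thrown", {
  tr <- makeTrack(pos = 5, mc = 0, cov = 3, context = "CG")
  w <- weightedMethylation(tr, "CHH")   # no CHH sites at all
  expect_false(w$defined)
  expect_true(is.na(w$level))
})

test_that("binned methylation uses anchored bins and drops empty bins", {
  tr <- makeTrack(pos = c(1, 99999, 100001, 200001, 240000),
                  mc = c(1, 1, 2, 3, 1), cov = c(10, 10, 10, 10, 10),
                  seqlen = 250000)
  b <- methylationByBin(tr, "CHH", binSize = 1e5)
  expect_equal(nrow(b), 3)           # 250 kb: 3 bins, last partial
  expect_equal(b$start, c(1, 100001, 200001))
  expect_equal(b$level[1], 2 / 20)
  expect_equal(b$level[2], 2 / 10)
  expect_equal(b$level[3], 4 / 20)
  # bins with no coverage are excluded
  sparse <- methylationByBin(makeTrack(pos = 5, mc = 1, cov = 10), "CHH", 50)
  expect_equal(nrow(sparse), 1)
})

test_that("percent change reproduces the printed global mCHH arithmetic", {
  cr <- percentChange(5.02, 3.31)
  expect_equal(round(cr$percent, 2), 34.06)
  expect_identical(cr$direction, "decrease")
  lr1 <- percentChange(3.37, 1.86)
  expect_equal(round(lr1$percent, 2), 44.81)
  lr2 <- percentChange(2.11, 1.71)
  expect_equal(round(lr2$percent), 19)
  er <- percentChange(2.44, 3.13)
  expect_equal(round(er$percent, 2), 28.28)
  expect_identical(er$direction, "increase")
  expect_equal(percentChange(4, 4)$percent, 0)
  expect_error(percentChange(0, 1), "undefined")
})

test_that("percent change sign always matches the direction of change", {
  set.seed(2)
  for (i in 1:20) {
    a <- runif(1, 0.1, 10); b <- runif(1, 0.1, 10)
    pc <- percentChange(a, b)
    expect_identical(pc$direction,
                     if (a > b) "decrease" else if (a < b) "increase" else "none")
    expect_equal(pc$signed, 100 * (a - b) / a)
  }
})

test_that("coverage estimate evaluates the printed formula", {
  expect_equal(estimateCoverage(17e6, 17e6), 34e6 * 300 / 373e6)
  expect_equal(estimateCoverage(0, 0), 0)
  expect_equal(estimateCoverage(8e6, 9e6) * 2, estimateCoverage(16e6, 18e6))
})

test_that("metaplot is flat under uniform methylation and conserves counts", {
  set.seed(3)
  pos <- seq(1, 20000, by = 7)
  tr <- makeTrack(pos = pos, mc = rep(2, length(pos)),
                  cov = rep(10, length(pos)), seqlen = 30000)
  feats <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(c(3001, 12001), width = 2000),
                                  strand = c("+", "-"))
  prof <- metaplot(tr, feats, flank = 1000, nBodyBins = 10, nFlankBins = 5)
  expect_true(all(abs(prof$level - 0.2) < 1e-12))
  # count conservation over features + flanks
  ext <- GenomicRanges::resize(feats, GenomicRanges::width(feats) + 2000,
                               fix = "center")
  inReg <- IRanges::overlapsAny(
    GenomicRanges::GRanges("chr1", IRanges::IRanges(pos, width = 1)), ext)
  expect_equal(sum(prof$mc_total), sum(2 * inReg))
  expect_equal(sum(prof$cov_total), sum(10 * inReg))
})

test_that("metaplot reads 5' to 3': strand flip mirrors the profile", {
  set.seed(4)
  pos <- seq(1, 9000, by = 3)
  # methylation rises with coordinate, so the profile is asymmetric
  mcv <- rbinom(length(pos), 10, pos / 10000)
  tr <- makeTrack(pos = pos, mc = mcv, cov = rep(10, length(pos)),
                  seqlen = 10000)
  feat <- GenomicRanges::GRanges("chr1", IRanges::IRanges(4001, 6000),
                                 strand = "+")
  flip <- feat
  GenomicRanges::strand(flip) <- "-"
  p1 <- metaplot(tr, feat, flank = 1000, nBodyBins = 6, nFlankBins = 3)
  p2 <- metaplot(tr, flip, flank = 1000, nBodyBins = 6, nFlankBins = 3)
  expect_equal(p2$level, rev(p1$level))
  expect_false(isTRUE(all.equal(p1$level, rev(p1$level))))
})

test_that("metaplot separates body from flank signal by construction", {
  pos <- seq(1, 10000, by = 5)
  feat <- GenomicRanges::GRanges("chr1", IRanges::IRanges(4001, 6000),
                                 strand = "+")
  inBody <- pos >= 4001 & pos <= 6000
  tr <- makeTrack(pos = pos, mc = ifelse(inBody, 8, 0),
                  cov = rep(10, length(pos)), seqlen = 11000)
  prof <- metaplot(tr, feat, flank = 1000, nBodyBins = 6, nFlankBins = 3)
  expect_true(all(prof$level[prof$region == "body"] > 0.7))
  expect_true(all(prof$level[prof$region != "body"] < 1e-12))
})

test_that("replicate correlation is high for shared proportions, null for independent ones", {
  set.seed(5)
  nbin <- 300; per <- 20
  pos <- seq_len(nbin * per) * 3
  pTrue <- rep(runif(nbin, 0, 0.4), each = per)   # varies between bins
  cov1 <- rpois(length(pos), 40) + 1L; cov2 <- rpois(length(pos), 40) + 1L
  t1 <- makeTrack(pos = pos, mc = rbinom(length(pos), cov1, pTrue), cov = cov1,
                  replicate = "R1")
  t2 <- makeTrack(pos = pos, mc = rbinom(length(pos), cov2, pTrue), cov = cov2,
                  replicate = "R2")
  expect_gt(replicateCorrelation(t1, t2, "CHH", binSize = per * 3), 0.9)

  pA <- rep(runif(nbin, 0, 0.4), each = per)
  pB <- rep(runif(nbin, 0, 0.4), each = per)
  tA <- makeTrack(pos = pos, mc = rbinom(length(pos), cov1, pA), cov = cov1)
  tB <- makeTrack(pos = pos, mc = rbinom(length(pos), cov2, pB), cov = cov2)
  expect_lt(abs(replicateCorrelation(tA, tB, "CHH", binSize = per * 3)), 0.15)
  expect_error(replicateCorrelation(makeTrack(1, 1, 2), makeTrack(1, 1, 2)),
               "fewer than 3")
})
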