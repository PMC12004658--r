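test_that("window partition tiles chromosomes exactly", {
  w <- partitionWindows(c(chrA = 100, chrB = 101), width = 50)
  a <- w[GenomicRanges::seqnames(w) == "chrA"]
  b <- w[GenomicRanges::seqnames(w) == "chrB"]
  expect_length(a, 2); expect_length(b, 3)
  expect_equal(GenomicRanges::start(b), c(1, 51, 101))
  expect_equal(GenomicRanges::end(b), c(50, 100, 101))
  # partition property: disjoint, sorted, union covers [1, length]
  expect_equal(sum(GenomicRanges::width(a)), 100)
  expect_equal(sum(GenomicRanges::width(b)), 101)
  expect_true(all(GenomicRanges::start(b)[-1] ==
                  GenomicRanges::end(b)[-3] + 1))
})

test_that("window counts pool per replicate and respect window boundaries", {
  tA <- makeTrack(pos = 10, mc = 2, cov = 10, seqlen = 200)
  tB <- makeTrack(pos = 10, mc = 1, cov = 10, seqlen = 200)
  ws <- windowCounts(tA, tB, c(chr1 = 200), context = "CHH")
  expect_equal(pooledLevels(ws, "A"), 0.2)
  expect_equal(informative(ws, "A"), 10)
  expect_length(statWindows(ws), 1)

  # moving a site across the 50-bp boundary moves its counts
  t50 <- makeTrack(pos = 50, mc = 5, cov = 10, seqlen = 200)
  t51 <- makeTrack(pos = 51, mc = 5, cov = 10, seqlen = 200)
  w50 <- windowCounts(t50, tB, c(chr1 = 200))
  w51 <- windowCounts(t51, tB, c(chr1 = 200))
  expect_equal(GenomicRanges::start(statWindows(w50))[1], 1)
  expect_true(51 %in% GenomicRanges::start(statWindows(w51)))
})

test_that("Fisher p-values match stats::fisher.test and the enumeration oracle", {
  # exhaustive small sweep against base R's independent implementation
  tab <- expand.grid(covA = 0:8, covB = 0:8)
  for (i in seq_len(nrow(tab))) {
    cA <- tab$covA[i]; cB <- tab$covB[i]
    for (a in 0:cA) for (b in 0:cB) {
      p <- fisherExactTest(a, cA, b, cB)
      pr <- fisher.test(matrix(c(a, cA - a, b, cB - b), 2, byrow = TRUE))$p.value
      expect_equal(p, pr, tolerance = 1e-12)
    }
  }
  # random larger tables against both independent routes
  set.seed(7)
  for (i in 1:200) {
    cA <- sample(0:100, 1); cB <- sample(0:100, 1)
    a <- if (cA) sample(0:cA, 1) else 0L
    b <- if (cB) sample(0:cB, 1) else 0L
    p <- fisherExactTest(a, cA, b, cB)
    expect_equal(p, fisherOracle(a, cA, b, cB), tolerance = 1e-10)
    expect_equal(p, fisher.test(matrix(c(a, cA - a, b, cB - b), 2,
                                       byrow = TRUE))$p.value,
                 tolerance = 1e-10)
  }
})

test_that("Fisher test handles degenerate and symmetric cases", {
  expect_equal(fisherExactTest(5, 10, 5, 10), 1)
  expect_equal(fisherExactTest(0, 0, 0, 0), 1)
  expect_equal(fisherExactTest(0, 20, 20, 20),
               fisherOracle(0, 20, 20, 20), tolerance = 1e-12)
  set.seed(8)
  a <- rbinom(50, 30, 0.3); b <- rbinom(50, 40, 0.5)
  expect_equal(fisherExactTest(a, 30, b, 40), fisherExactTest(b, 40, a, 30))
  expect_error(fisherExactTest(5, 3, 0, 10), "mc <= cov")
})

test_that("DMR filters reject inconsistent replicate pairings and thin coverage", {
  seqlen <- c(chr1 = 100)
  mk <- function(mc, cov, sample, rep)
    makeTrack(pos = 10, mc = mc, cov = cov, sample = sample, replicate = rep,
              seqlen = 100)
  # pooled diff 0.13 > 0.1, but pairing A2 x B* differs by only 0.06
  A <- list(mk(25, 100, "S1", "R1"), mk(11, 100, "S1", "R2"))
  B <- list(mk(5, 100, "S0", "R1"), mk(5, 100, "S0", "R2"))
  ws <- windowCounts(A, B, seqlen)
  expect_length(callDMRs(ws), 0)

  # consistent pairings: all four cross differences > 0.1
  A2 <- list(mk(30, 100, "S1", "R1"), mk(28, 100, "S1", "R2"))
  ws2 <- windowCounts(A2, B, seqlen)
  d <- callDMRs(ws2)
  expect_length(d, 1)
  expect_identical(d$direction, "hyper")
  expect_equal(d$m_A, 0.29)

  # informative coverage below 20 in one sample fails the filter
  A3 <- list(mk(5, 9, "S1", "R1"), mk(5, 9, "S1", "R2"))
  B3 <- list(mk(0, 50, "S0", "R1"), mk(0, 50, "S0", "R2"))
  expect_length(callDMRs(windowCounts(A3, B3, seqlen)), 0)
  # joint rule admits it (18 + 100 >= 20)
  expect_length(callDMRs(windowCounts(A3, B3, seqlen),
                         informativeRule = "joint"), 1)
})

test_that("hypo DMRs of A vs B are the hyper DMRs of B vs A", {
  fx <- fixtureTwoStage()
  sl <- annotationSeqlengths(fx$annotation)
  s0 <- fx$tracks[c("S0_R1", "S0_R2")]; s1 <- fx$tracks[c("S1_R1", "S1_R2")]
  dAB <- callDMRs(windowCounts(s1, s0, sl))
  dBA <- callDMRs(windowCounts(s0, s1, sl))
  expect_gt(length(dAB), 10)
  hypoAB <- dAB[dAB$direction == "hypo"]
  hyperBA <- dBA[dBA$direction == "hyper"]
  expect_equal(GenomicRanges::start(hypoAB), GenomicRanges::start(hyperBA))
  expect_equal(hypoAB$p_value, hyperBA$p_value)
  expect_equal(hypoAB$difference, -hyperBA$difference)
})

test_that("planted CHH windows are recovered with the planted direction", {
  fx <- fixtureTwoStage()
  sl <- annotationSeqlengths(fx$annotation)
  d <- callDMRs(windowCounts(fx$tracks[c("S1_R1", "S1_R2")],
                             fx$tracks[c("S0_R1", "S0_R2")], sl))
  pw <- plantedWindows(fx$truth)
  ov <- GenomicRanges::findOverlaps(pw, d, type = "equal")
  expect_gt(length(ov) / length(pw), 0.8)
  expect_identical(d$direction[S4Vectors::subjectHits(ov)],
                   pw$direction[S4Vectors::queryHits(ov)])
})

test_that("DMR annotation applies the TE > promoter > gene precedence", {
  sl <- c(chr1 = 10000L)
  genes <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5001, 7000),
                                  strand = "+", gene_id = "g1",
                                  seqlengths = sl)
  tes <- GenomicRanges::GRanges("chr1", IRanges::IRanges(3500, 3800),
                                te_id = "te1", seqlengths = sl)
  ann <- new("GenomeAnnotation", seqlengths = sl, genes = genes, tes = tes)
  dmrs <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    c(3551, 4001, 5501, 101), width = 50), seqlengths = sl)
  out <- annotateDMRs(dmrs, ann)
  # window 1 is in a TE that sits inside the promoter: TE wins
  expect_identical(out$feature, c("TE", "promoter", "gene", "intergenic"))
  expect_equal(sum(table(out$feature)), length(dmrs))
})

test_that("DMR set overlaps match brute-force set algebra", {
  set.seed(9)
  universe <- partitionWindows(c(chr1 = 5000), 50)
  sets <- lapply(1:3, function(i) universe[sample(100, 40)])
  names(sets) <- c("CR", "LR", "ER")
  got <- overlapDMRSets(sets)
  key <- function(gr) paste0("chr1:", GenomicRanges::start(gr))
  k <- lapply(sets, key)
  inCR <- k$CR; inLR <- k$LR; inER <- k$ER
  all3 <- intersect(intersect(inCR, inLR), inER)
  expect_equal(unname(got[["CR&LR&ER"]]), length(all3))
  expect_equal(unname(got[["CR&LR"]]),
               length(setdiff(intersect(inCR, inLR), inER)))
  expect_equal(unname(got[["CR"]]),
               length(setdiff(setdiff(inCR, inLR), inER)))
  expect_equal(sum(got), length(unique(unlist(k))))
  # disjoint and identical extremes
  expect_equal(unname(overlapDMRSets(list(a = universe[1:3],
                                          b = universe[4:6]))[["a&b"]]), 0)
  expect_equal(unname(overlapDMRSets(list(a = universe[1:3],
                                          b = universe[1:3]))[["a&b"]]), 3)
})
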