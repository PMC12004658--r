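# Shared fixtures, memoized so several test files can reuse one simulation.

.fixtureCache <- new.env(parent = emptyenv())

cachedFixture <- function(key, config) {
  if (!exists(key, envir = .fixtureCache)) {
    ann <- generateAnnotation(config)
    sim <- simulateMethylome(ann, config)
    expr <- simulateExpression(ann, sim$truth, config)
    assign(key, list(config = config, annotation = ann, tracks = sim$tracks,
                     truth = sim$truth, expr = expr), envir = .fixtureCache)
  }
  get(key, envir = .fixtureCache)
}

# two-stage fixture for DMR-level tests
fixtureTwoStage <- function() {
  cachedFixture("two_stage", SimulationConfig(
    chromLength = 3e5, nGenes = 40, nTEs = 100, plantedDMRCount = 40,
    nSamples = 2, seed = 11))
}

# nine-stage fixture for methylation-expression correlation tests
fixtureNineStage <- function() {
  cachedFixture("nine_stage", SimulationConfig(
    chromLength = 4e5, nGenes = 60, nTEs = 160, plantedDMRCount = 40,
    nSamples = 9, seed = 5))
}

# build a small MethylomeTrack by hand
makeTrack <- function(pos, mc, cov, context = "CHH", chrom = "chr1",
                      strand = "+", sample = "S0", replicate = "R1",
                      seqlen = NULL) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1L),
                               strand = strand, context = context,
                               mc = as.integer(mc), cov = as.integer(cov))
  if (!is.null(seqlen)) {
    GenomeInfoDb::seqlevels(gr) <- unique(chrom)
    GenomeInfoDb::seqlengths(gr) <- seqlen
  }
  MethylomeTrack(gr, sample = sample, replicate = replicate)
}

# independent step-up BH oracle: sort p ascending, p*m/i, cumulative minimum
# from the largest rank down, then map back to the input order
bhOracle <- function(p) {
  m <- sum(!is.na(p))
  o <- order(p, na.last = TRUE)
  ranked <- p[o][seq_len(m)] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  out <- rep(NA_real_, length(p))
  out[o[seq_len(m)]] <- pmin(adj, 1)
  out
}

# two-sided Fisher p by direct hypergeometric enumeration using lchoose
# (independent of stats::dhyper and of the package implementation)
fisherOracle <- function(mcA, covA, mcB, covB) {
  m <- mcA + mcB; nn <- (covA - mcA) + (covB - mcB); k <- covA
  lo <- max(0, k - nn); hi <- min(k, m)
  xs <- lo:hi
  logp <- lchoose(m, xs) + lchoose(nn, k - xs) - lchoose(m + nn, k)
  d <- exp(logp)
  dObs <- d[mcA - lo + 1L]
  min(1, sum(d[d <= dObs * (1 + 1e-7)]))
}
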