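#' Weighted methylation level of a set of cytosines
#'
#' The weighted level pools counts before dividing: total methylated reads
#' over total coverage across all sites of the context. Replicates passed as
#' a list are pooled the same way (summed counts), never averaged per-library.
#'
#' @param x a [MethylomeTrack-class], a sites `GRanges`, or a list of either
#'   (replicates to pool).
#' @param context one of `"CG"`, `"CHG"`, `"CHH"`.
#' @return one-row data.frame: `context`, `level` (`NA` when no coverage),
#'   `mc_total`, `cov_total`, `defined`.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(2, 9), width = 1),
#'                              strand = "+", context = "CHH",
#'                              mc = c(3L, 1L), cov = c(10L, 30L))
#' weightedMethylation(gr, "CHH")$level  # 4/40 = 0.1, not mean(0.3, 1/30)
#' @export
weightedMethylation <- function(x, context = "CHH") {
  context <- .checkContext(context)
  dt <- .siteDT(x)
  keep <- which(dt$context == context)
  dt <- dt[keep]
  mc <- sum(as.numeric(dt$mc)); cov <- sum(as.numeric(dt$cov))
  data.frame(context = context,
             level = if (cov > 0) mc / cov else NA_real_,
             mc_total = mc, cov_total = cov, defined = cov > 0)
}

#' Weighted methylation per fixed-width genomic bin
#'
#' Bins are anchored at position 1 of each chromosome; the final partial bin
#' is kept. Bins with no covered cytosine of the context are omitted. The
#' default 100-kb width gives the genome-wide methylation distribution used
#' for global-level box plots.
#'
#' @inheritParams weightedMethylation
#' @param binSize bin width in bp.
#' @return data.frame: `chrom`, `start`, `end` (1-based inclusive), `level`,
#'   `mc_total`, `cov_total`, one row per covered bin.
#' @export
methylationByBin <- function(x, context = "CHH", binSize = 1e5) {
  context <- .checkContext(context)
  dt <- .siteDT(x)
  keep <- which(dt$context == context & dt$cov > 0L)
  dt <- dt[keep]
  if (!nrow(dt))
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      level = numeric(), mc_total = numeric(),
                      cov_total = numeric()))
  dt[, bin := .windowIndex(pos, binSize)]
  agg <- dt[, .(mc_total = sum(as.numeric(mc)),
                cov_total = sum(as.numeric(cov))), by = .(chrom, bin)]
  setorder(agg, chrom, bin)
  data.frame(chrom = agg$chrom,
             start = agg$bin * as.integer(binSize) + 1L,
             end = (agg$bin + 1L) * as.integer(binSize),
             level = agg$mc_total / agg$cov_total,
             mc_total = agg$mc_total, cov_total = agg$cov_total)
}

#' Signed percent change between two methylation levels
#'
#' Returns `100 * (before - after) / before`: positive for a decrease,
#' negative for an increase, e.g. global mCHH falling from 5.02% to 3.31%
#' is a 34.06% decrease.
#'
#' @param before,after levels on the same scale (proportions or percent).
#' @return named list: `percent` (absolute value), `signed`, `direction`
#'   (`"decrease"`, `"increase"` or `"none"`).
#' @examples
#' percentChange(5.02, 3.31)$percent   # 34.06
#' percentChange(2.44, 3.13)$direction # "increase"
#' @export
percentChange <- function(before, after) {
  stopifnot(length(before) == 1L, length(after) == 1L)
  if (!is.finite(before) || before <= 0)
    stop("percent change is undefined for a non-positive baseline level")
  signed <- 100 * (before - after) / before
  list(percent = abs(signed), signed = signed,
       direction = if (signed > 0) "decrease"
                   else if (signed < 0) "increase" else "none")
}

#' Coverage estimate from unique read counts
#'
#' Fold coverage of a two-replicate bisulfite library pair:
#' `(r1 + r2) * readLength * 2 / genomeSize` (paired-end reads, rice-sized
#' genome by default).
#'
#' @param uniqueReadsRep1,uniqueReadsRep2 unique read counts per replicate.
#' @param readLength read length in bp.
#' @param genomeSize genome size in bp.
#' @return fold coverage (numeric).
#' @export
estimateCoverage <- function(uniqueReadsRep1, uniqueReadsRep2,
                             readLength = 150, genomeSize = 373e6) {
  stopifnot(uniqueReadsRep1 >= 0, uniqueReadsRep2 >= 0)
  (uniqueReadsRep1 + uniqueReadsRep2) * readLength * 2 / genomeSize
}

#' Pearson correlation of binned methylation between two replicates
#'
#' Both tracks are binned with [methylationByBin()]; the correlation is taken
#' over bins covered in both replicates.
#'
#' @param track1,track2 [MethylomeTrack-class] replicates.
#' @inheritParams methylationByBin
#' @return Pearson correlation coefficient.
#' @export
replicateCorrelation <- function(track1, track2, context = "CHH",
                                 binSize = 1e5) {
  b1 <- methylationByBin(track1, context, binSize)
  b2 <- methylationByBin(track2, context, binSize)
  m <- merge(b1[, c("chrom", "start", "level")],
             b2[, c("chrom", "start", "level")],
             by = c("chrom", "start"))
  if (nrow(m) < 3L)
    stop("fewer than 3 bins covered in both replicates")
  cor(m$level.x, m$level.y)
}

# map cytosines (or any 1-bp positions) onto scaled feature/flank bins,
# 5'->3' relative to each feature. Returns a data.table of (site row, bin).
.featureBins <- function(posGR, features, flank, nBodyBins, nFlankBins) {
  ext <- GRanges(seqnames(features),
                 IRanges(pmax(1L, start(features) - flank),
                         end(features) + flank))
  GenomeInfoDb::seqlevels(ext) <- GenomeInfoDb::seqlevels(features)
  if (!all(is.na(seqlengths(features)))) {
    GenomeInfoDb::seqlengths(ext) <- seqlengths(features)
    suppressWarnings(ext <- trim(ext))
  }
  ov <- findOverlaps(posGR, ext)
  if (!length(ov)) return(data.table(site = integer(), bin = integer()))
  i <- queryHits(ov); j <- subjectHits(ov)
  pos <- start(posGR)[i]
  fs <- start(features)[j]; fe <- end(features)[j]
  fw <- fe - fs + 1L
  minus <- as.character(strand(features))[j] == "-"
  K <- 2L * nFlankBins + nBodyBins
  bin <- integer(length(i))
  up <- pos < fs      # left of body
  dn <- pos > fe      # right of body
  body <- !up & !dn
  # left flank: distance from flank edge, scaled to nFlankBins
  bin[up] <- pmin(nFlankBins - 1L,
                  ((pos[up] - (fs[up] - flank)) * nFlankBins) %/% flank) + 1L
  bin[body] <- nFlankBins +
    pmin(nBodyBins - 1L, ((pos[body] - fs[body]) * nBodyBins) %/% fw[body]) + 1L
  bin[dn] <- nFlankBins + nBodyBins +
    pmin(nFlankBins - 1L, ((pos[dn] - fe[dn] - 1L) * nFlankBins) %/% flank) + 1L
  bin[minus] <- K + 1L - bin[minus]
  data.table(site = i, bin = bin)
}

#' Metaplot: pooled methylation over scaled features and flanks
#'
#' Each feature body is scaled to `nBodyBins` bins and each flank to
#' `nFlankBins`; methylated and total counts are pooled (weighted-level rule)
#' per bin across all features. Minus-strand features are reversed so the
#' profile reads 5' to 3'.
#'
#' @inheritParams weightedMethylation
#' @param features stranded feature `GRanges` (genes or TEs).
#' @param flank flank width in bp on each side.
#' @param nBodyBins,nFlankBins bin counts for body and each flank.
#' @return data.frame: `bin` (1..2*nFlankBins+nBodyBins), `region`
#'   (upstream/body/downstream), `level`, `mc_total`, `cov_total`.
#' @export
metaplot <- function(x, features, flank = 2000, nBodyBins = 20,
                     nFlankBins = 10, context = "CHH") {
  context <- .checkContext(context)
  stopifnot(length(features) > 0)
  dt <- .siteDT(x)
  keep <- which(dt$context == context)
  dt <- dt[keep]
  K <- 2L * nFlankBins + nBodyBins
  out <- data.frame(bin = seq_len(K),
                    region = rep(c("upstream", "body", "downstream"),
                                 c(nFlankBins, nBodyBins, nFlankBins)),
                    level = NA_real_, mc_total = 0, cov_total = 0)
  if (nrow(dt)) {
    posGR <- GRanges(dt$chrom, IRanges(dt$pos, width = 1L))
    hits <- .featureBins(posGR, features, flank, nBodyBins, nFlankBins)
    if (nrow(hits)) {
      hits[, `:=`(mc = dt$mc[site], cov = dt$cov[site])]
      agg <- hits[, .(mc_total = sum(as.numeric(mc)),
                      cov_total = sum(as.numeric(cov))), by = bin]
      out$mc_total[agg$bin] <- agg$mc_total
      out$cov_total[agg$bin] <- agg$cov_total
      out$level <- ifelse(out$cov_total > 0, out$mc_total / out$cov_total,
                          NA_real_)
    }
  }
  out
}
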