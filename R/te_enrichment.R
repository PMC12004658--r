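#' Sample random 50-bp control windows per chromosome
#'
#' Draws `nPerChromosome` windows per chromosome with uniformly random start
#' positions (with replacement, so windows may overlap), fully in-bounds —
#' the null set against which DMR-associated TE lengths are compared. With
#' 12 chromosomes and the default 2000 per chromosome this yields 24,000
#' windows.
#'
#' @param seqlengths named chromosome lengths.
#' @param nPerChromosome windows per chromosome.
#' @param width window width in bp.
#' @param seed optional integer seed (RNG state is restored afterwards).
#' @return a `GRanges` of control windows.
#' @export
sampleControlWindows <- function(seqlengths, nPerChromosome = 2000, width = 50,
                                 seed = NULL) {
  if (any(seqlengths < width))
    stop("every chromosome must be at least ", width, " bp long")
  .withSeed(seed, {
    starts <- unlist(lapply(names(seqlengths), function(ch)
      sample.int(as.integer(seqlengths[[ch]]) - as.integer(width) + 1L,
                 nPerChromosome, replace = TRUE)))
    GRanges(rep(names(seqlengths), each = nPerChromosome),
            IRanges(starts, width = as.integer(width)),
            seqlengths = setNames(as.integer(seqlengths), names(seqlengths)))
  })
}

#' Lengths of TEs overlapped by a window set
#'
#' For every window overlapping at least one TE, the lengths of all
#' overlapped TEs are collected; by default a TE overlapped by k windows
#' contributes k times (the unit of observation is the window-TE association).
#'
#' @param windows a `GRanges` of windows (DMRs or controls).
#' @param tes a TE `GRanges`.
#' @param distinct if `TRUE`, count each distinct TE once.
#' @return integer vector of TE lengths in bp.
#' @export
associatedTELengths <- function(windows, tes, distinct = FALSE) {
  ov <- findOverlaps(windows, tes, ignore.strand = TRUE)
  j <- subjectHits(ov)
  if (distinct) j <- unique(j)
  width(tes)[j]
}

#' Compare two TE length distributions
#'
#' Rank-based (Wilcoxon-Mann-Whitney) two-sample comparison of
#' DMR-associated versus control-associated TE lengths, with medians,
#' quartiles and the fraction of each group shorter than `shortCutoff`.
#'
#' @param dmrLengths,controlLengths TE lengths (bp) per group.
#' @param shortCutoff the short-TE length threshold in bp.
#' @return list: `summary` (data.frame of group, n, median, q25, q75,
#'   fraction_short), `p_value`, `statistic` and the cutoff.
#' @export
compareLengthDistributions <- function(dmrLengths, controlLengths,
                                       shortCutoff = 500) {
  if (!length(dmrLengths) || !length(controlLengths))
    stop("both length groups must be non-empty")
  wt <- suppressWarnings(wilcox.test(dmrLengths, controlLengths))
  smry <- function(x) c(n = length(x), median = median(x),
                        q25 = unname(quantile(x, 0.25)),
                        q75 = unname(quantile(x, 0.75)),
                        fraction_short = mean(x < shortCutoff))
  s <- rbind(dmr = smry(dmrLengths), control = smry(controlLengths))
  list(summary = data.frame(group = rownames(s), s, row.names = NULL),
       p_value = wt$p.value, statistic = unname(wt$statistic),
       short_cutoff = shortCutoff)
}

#' Positional density of short TEs across genic regions
#'
#' Bins the midpoints of TEs shorter than `lengthCutoff` onto scaled
#' gene-body and flank bins (strand-aware, 5' to 3') and normalises each bin
#' count by the total bp it represents across all genes, giving a density
#' per bp.
#'
#' @param tes TE `GRanges`.
#' @param genes stranded gene `GRanges`.
#' @param lengthCutoff maximum TE length (bp) to include, exclusive.
#' @param flank flank width in bp; @param nBodyBins,nFlankBins bin counts.
#' @return data.frame: `bin`, `region`, `count`, `bp`, `density`.
#' @export
shortTEGenicProfile <- function(tes, genes, lengthCutoff = 500, flank = 2000,
                                nBodyBins = 20, nFlankBins = 10) {
  stopifnot(length(genes) > 0)
  short <- tes[width(tes) < lengthCutoff]
  K <- 2L * nFlankBins + nBodyBins
  out <- data.frame(bin = seq_len(K),
                    region = rep(c("upstream", "body", "downstream"),
                                 c(nFlankBins, nBodyBins, nFlankBins)),
                    count = 0L)
  if (length(short)) {
    mids <- GRanges(seqnames(short),
                    IRanges((start(short) + end(short)) %/% 2L, width = 1L))
    hits <- .featureBins(mids, genes, flank, nBodyBins, nFlankBins)
    if (nrow(hits)) {
      tb <- table(hits$bin)
      out$count[as.integer(names(tb))] <- as.integer(tb)
    }
  }
  bodyBp <- sum(as.numeric(width(genes))) / nBodyBins
  flankBp <- as.numeric(length(genes)) * flank / nFlankBins
  out$bp <- rep(c(flankBp, bodyBp, flankBp), c(nFlankBins, nBodyBins, nFlankBins))
  out$density <- out$count / out$bp
  out
}
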