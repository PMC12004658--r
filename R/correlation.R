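# Promoter-bin CHH methylation versus gene expression: strand-aware 2-kb
# promoters split into 200-bp bins, per-stage weighted bin levels, best-bin
# Pearson correlation per gene, and BH FDR classification.

#' Tile 2-kb promoters into 200-bp bins
#'
#' Bins tile the region upstream of each gene's TSS, strand-aware: bin 1 is
#' nearest the TSS. Bins are truncated (or dropped when fully outside) at
#' chromosome edges.
#'
#' @param genes stranded `GRanges` with a `gene_id` column; TSS is `start`
#'   on `+` and `end` on `-` genes.
#' @param span promoter span upstream of the TSS (bp).
#' @param binWidth bin width (bp).
#' @return `GRanges` of bins with `gene_id` and `bin` (1 = TSS-proximal).
#' @export
promoterBins <- function(genes, span = 2000, binWidth = 200) {
  stopifnot(span %% binWidth == 0, !is.null(genes$gene_id))
  nb <- as.integer(span / binWidth)
  if (!length(genes)) return(GRanges())
  g <- rep(seq_along(genes), each = nb)
  bin <- rep(seq_len(nb), length(genes))
  plus <- as.character(strand(genes))[g] != "-"
  tss <- ifelse(plus, start(genes)[g], end(genes)[g])
  s <- ifelse(plus, tss - bin * binWidth, tss + (bin - 1L) * binWidth + 1L)
  e <- ifelse(plus, tss - (bin - 1L) * binWidth - 1L, tss + bin * binWidth)
  sl <- seqlengths(genes)[as.character(seqnames(genes))[g]]
  s2 <- pmax(s, 1L)
  e2 <- if (all(is.na(sl))) e else pmin(e, ifelse(is.na(sl), e, sl))
  keep <- e2 >= s2 & e2 >= 1 & (is.na(sl) | s2 <= sl)
  out <- GRanges(as.character(seqnames(genes))[g][keep],
                 IRanges(s2[keep], e2[keep]),
                 strand = strand(genes)[g][keep],
                 gene_id = genes$gene_id[g][keep], bin = bin[keep])
  GenomeInfoDb::seqlevels(out) <- GenomeInfoDb::seqlevels(genes)
  if (!all(is.na(seqlengths(genes))))
    GenomeInfoDb::seqlengths(out) <- seqlengths(genes)
  out
}

# pooled (mc, cov) sums of `tracks` per region; tracks is a list of
# MethylomeTrack (replicates are pooled by concatenation)
.regionCounts <- function(tracks, regions, context) {
  dt <- .siteDT(tracks)
  keep <- which(dt$context == context & dt$cov > 0L)
  dt <- dt[keep]
  mc <- numeric(length(regions)); cov <- numeric(length(regions))
  if (nrow(dt)) {
    posGR <- GRanges(dt$chrom, IRanges(dt$pos, width = 1L))
    GenomeInfoDb::seqlevels(posGR) <-
      union(GenomeInfoDb::seqlevels(posGR), GenomeInfoDb::seqlevels(regions))
    ov <- findOverlaps(posGR, regions, ignore.strand = TRUE)
    if (length(ov)) {
      agg <- data.table(j = subjectHits(ov),
                        mc = dt$mc[queryHits(ov)],
                        cov = dt$cov[queryHits(ov)])[
        , .(mc = sum(as.numeric(mc)), cov = sum(as.numeric(cov))), by = j]
      mc[agg$j] <- agg$mc; cov[agg$j] <- agg$cov
    }
  }
  list(mc = mc, cov = cov)
}

#' Weighted CHH methylation per promoter bin per sample
#'
#' @param tracksBySample named list (one element per sample/stage) of lists of
#'   [MethylomeTrack-class] replicates; replicates are pooled by summing
#'   counts.
#' @param bins promoter bins from [promoterBins()] (or any region `GRanges`).
#' @param context methylation context (default CHH).
#' @return numeric matrix, regions x samples; `NA` where a bin has no
#'   coverage in a sample.
#' @export
binMethylation <- function(tracksBySample, bins, context = "CHH") {
  context <- .checkContext(context)
  stopifnot(is.list(tracksBySample), !is.null(names(tracksBySample)))
  levels <- vapply(tracksBySample, function(trs) {
    cc <- .regionCounts(trs, bins, context)
    ifelse(cc$cov > 0, cc$mc / cc$cov, NA_real_)
  }, numeric(length(bins)))
  matrix(levels, nrow = length(bins),
         dimnames = list(NULL, names(tracksBySample)))
}

# Pearson r and its two-sided p (t distribution, n - 2 df) for one pair,
# pairwise-complete; NA when fewer than minSamples pairs or zero variance
.pearsonRP <- function(x, y, minSamples) {
  ok <- is.finite(x) & is.finite(y)
  n <- sum(ok)
  if (n < minSamples || sd(x[ok]) == 0 || sd(y[ok]) == 0)
    return(c(r = NA_real_, p = NA_real_, n = n))
  r <- cor(x[ok], y[ok])
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  c(r = r, p = 2 * pt(-abs(tstat), df = n - 2), n = n)
}

#' Best promoter-bin correlation for one gene
#'
#' Correlates the gene's expression across samples with each promoter bin's
#' methylation and selects the bin with the highest absolute coefficient
#' (`mode = "signed"` selects the highest signed coefficient instead). Ties
#' break toward the TSS-proximal bin. Bins with fewer than `minSamples`
#' complete pairs or constant values are excluded.
#'
#' @param expression numeric vector of expression per sample.
#' @param binLevels bins x samples methylation matrix ([binMethylation()]),
#'   rows ordered by bin index (1 = TSS-proximal).
#' @param minSamples minimum complete sample pairs per bin.
#' @param mode `"absolute"` or `"signed"`.
#' @return list: `bin`, `r`, `p_value`, `n`; `bin` is `NA` when no bin is
#'   testable.
#' @export
bestBinCorrelation <- function(expression, binLevels,
                               minSamples = 4, mode = c("absolute", "signed")) {
  mode <- match.arg(mode)
  stopifnot(length(expression) == ncol(binLevels))
  rp <- t(apply(binLevels, 1L, .pearsonRP, y = expression,
                minSamples = minSamples))
  score <- if (mode == "absolute") abs(rp[, "r"]) else rp[, "r"]
  if (all(is.na(score)))
    return(list(bin = NA_integer_, r = NA_real_, p_value = NA_real_, n = 0L))
  best <- which.max(score)   # first maximum = TSS-proximal tie-break
  list(bin = as.integer(best), r = unname(rp[best, "r"]),
       p_value = unname(rp[best, "p"]), n = as.integer(rp[best, "n"]))
}

#' BH adjustment and sign classification of best-bin correlations
#'
#' Benjamini-Hochberg adjusts the best-bin p-values across all genes and
#' classifies each gene `"positive"` or `"negative"` by the sign of its
#' coefficient when `q < qThreshold`, else `"none"`.
#'
#' @param results data.frame with columns `r` and `p_value` (one row per
#'   gene), e.g. from [correlateMethylationExpression()].
#' @param qThreshold FDR threshold (default 0.01).
#' @return `results` with added `q_value` and `sign_class` columns.
#' @export
fdrAdjustAndClassify <- function(results, qThreshold = 0.01) {
  stopifnot(all(c("r", "p_value") %in% names(results)))
  results$q_value <- p.adjust(results$p_value, method = "BH")
  results$sign_class <- ifelse(
    !is.na(results$q_value) & results$q_value < qThreshold,
    ifelse(results$r > 0, "positive", "negative"), "none")
  results
}

#' Summary of the correlation classification
#'
#' @param results output of [fdrAdjustAndClassify()].
#' @return list: `n_tested` (genes with a defined p-value), `n_significant`,
#'   `percent` (share of tested genes classified, in percent, 2 decimals).
#' @export
summarizeCorrelation <- function(results) {
  tested <- sum(!is.na(results$p_value))
  sig <- sum(results$sign_class %in% c("positive", "negative"))
  list(n_tested = tested, n_significant = sig,
       percent = if (tested > 0) round(100 * sig / tested, 2) else NA_real_)
}

#' Promoter methylation versus expression across all genes
#'
#' End-to-end promoter-bin analysis: builds strand-aware promoter bins,
#' computes per-stage weighted bin methylation (replicates pooled by counts),
#' averages expression replicates per stage (optionally log2(x+1)
#' transformed), selects each gene's best bin and applies BH classification.
#'
#' @param tracks flat list of [MethylomeTrack-class] objects (grouped into
#'   stages by their `sample` label) or a named per-sample list of replicate
#'   lists.
#' @param genes stranded gene `GRanges` with `gene_id`.
#' @param expr expression `SummarizedExperiment` or matrix (see
#'   [countTranscribed()]).
#' @param span,binWidth promoter geometry (bp).
#' @param context methylation context.
#' @param qThreshold FDR threshold.
#' @param minSamples minimum complete pairs per bin.
#' @param mode best-bin rule, `"absolute"` or `"signed"`.
#' @param logTransform correlate log2(RPKM + 1) rather than raw RPKM.
#' @return data.frame, one row per gene: `gene_id`, `bin`, `chrom`, `start`,
#'   `end`, `r`, `p_value`, `n`, `q_value`, `sign_class`.
#' @export
correlateMethylationExpression <- function(tracks, genes, expr,
                                           span = 2000, binWidth = 200,
                                           context = "CHH", qThreshold = 0.01,
                                           minSamples = 4,
                                           mode = c("absolute", "signed"),
                                           logTransform = TRUE) {
  mode <- match.arg(mode)
  if (!is.null(names(tracks)) && all(vapply(tracks, is.list, logical(1)))) {
    bySample <- tracks
  } else {
    labs <- vapply(tracks, trackSample, "")
    bySample <- split(tracks, labs)
  }
  m <- .rpkmMatrix(expr)
  stage <- .stageOf(expr, m)
  stages <- intersect(unique(stage), names(bySample))
  if (length(stages) < minSamples)
    stop("need methylation and expression for at least ", minSamples,
         " shared stages")
  bySample <- bySample[stages]
  exprStage <- vapply(stages, function(s)
    rowMeans(m[, stage == s, drop = FALSE]), numeric(nrow(m)))
  if (logTransform) exprStage <- log2(exprStage + 1)

  bins <- promoterBins(genes, span = span, binWidth = binWidth)
  levels <- binMethylation(bySample, bins, context = context)
  binIdx <- split(seq_along(bins), bins$gene_id)

  rows <- lapply(genes$gene_id, function(gid) {
    idx <- binIdx[[gid]]
    if (is.null(idx) || !(gid %in% rownames(exprStage)))
      return(data.frame(gene_id = gid, bin = NA_integer_,
                        chrom = NA_character_, start = NA_integer_,
                        end = NA_integer_, r = NA_real_, p_value = NA_real_,
                        n = 0L))
    idx <- idx[order(bins$bin[idx])]
    bb <- bestBinCorrelation(exprStage[gid, ], levels[idx, , drop = FALSE],
                             minSamples = minSamples, mode = mode)
    sel <- if (is.na(bb$bin)) NA_integer_ else idx[bb$bin]
    data.frame(gene_id = gid, bin = if (is.na(sel)) NA_integer_
                                    else bins$bin[sel],
               chrom = if (is.na(sel)) NA_character_
                       else as.character(seqnames(bins))[sel],
               start = if (is.na(sel)) NA_integer_ else start(bins)[sel],
               end = if (is.na(sel)) NA_integer_ else end(bins)[sel],
               r = bb$r, p_value = bb$p_value, n = bb$n)
  })
  fdrAdjustAndClassify(do.call(rbind, rows), qThreshold = qThreshold)
}

#' Modified-promoter flag
#'
#' A promoter is "modified" when its pooled weighted CHH level over the full
#' promoter region strictly exceeds `levelThreshold`.
#'
#' @param tracks list of [MethylomeTrack-class] (pooled by counts).
#' @param promoters promoter `GRanges` (e.g.
#'   `GenomicRanges::promoters(genes, 2000, 0)`).
#' @param context methylation context.
#' @param levelThreshold level cutoff (default 0.5).
#' @return logical vector per promoter; `NA` where no coverage
#'   (not evaluable).
#' @export
modifiedPromoter <- function(tracks, promoters, context = "CHH",
                             levelThreshold = 0.5) {
  context <- .checkContext(context)
  cc <- .regionCounts(if (is(tracks, "MethylomeTrack")) list(tracks) else tracks,
                      promoters, context)
  ifelse(cc$cov > 0, cc$mc / cc$cov > levelThreshold, NA)
}
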