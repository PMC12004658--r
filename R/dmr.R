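.DMR_THRESHOLDS <- c(CG = 0.5, CHG = 0.3, CHH = 0.1)

#' Tile chromosomes into fixed-width windows
#'
#' Disjoint windows anchored at position 1; the last window of a chromosome
#' may be shorter. `ceiling(length / width)` windows per chromosome.
#'
#' @param seqlengths named vector of chromosome lengths (bp).
#' @param width window width in bp.
#' @return a `GRanges` tiling each chromosome exactly.
#' @export
partitionWindows <- function(seqlengths, width = 50) {
  stopifnot(all(seqlengths > 0), width >= 1)
  sl <- setNames(as.integer(seqlengths), names(seqlengths))
  tileGenome(sl, tilewidth = as.integer(width),
             cut.last.tile.in.chrom = TRUE)
}

#' Per-window methylation counts for a two-sample comparison
#'
#' Sums methylated and total read counts of all cytosines of the context
#' (both strands) falling in each 50-bp window, separately per replicate of
#' sample A and sample B. Windows are half-open internally: a site at
#' position 51 (1-based) belongs to the second 50-bp window.
#'
#' @param tracksA,tracksB list of [MethylomeTrack-class] replicates for each
#'   sample of the comparison (A versus B).
#' @param seqlengths chromosome lengths; taken from the first track's
#'   `GRanges` if `NULL`.
#' @param width window width in bp.
#' @param context methylation context.
#' @return a [WindowStats-class] covering every window with at least one
#'   sequenced cytosine of the context in any replicate.
#' @export
windowCounts <- function(tracksA, tracksB, seqlengths = NULL, width = 50,
                         context = "CHH") {
  context <- .checkContext(context)
  if (is(tracksA, "MethylomeTrack")) tracksA <- list(tracksA)
  if (is(tracksB, "MethylomeTrack")) tracksB <- list(tracksB)
  if (is.null(seqlengths)) {
    sl <- seqlengths(trackSites(tracksA[[1]]))
    if (anyNA(sl)) stop("seqlengths must be supplied or set on the tracks")
    seqlengths <- sl
  }
  width <- as.integer(width)
  aggOne <- function(tr) {
    dt <- .siteDT(tr)
    keep <- which(dt$context == context)
    dt <- dt[keep]
    dt[, win := .windowIndex(pos, width)]
    dt[, .(mc = sum(as.numeric(mc)), cov = sum(as.numeric(cov))),
       by = .(chrom, win)]
  }
  aggs <- c(lapply(tracksA, aggOne), lapply(tracksB, aggOne))
  universe <- unique(rbindlist(lapply(aggs, function(a) a[, .(chrom, win)])))
  setorder(universe, chrom, win)
  fill <- function(a) {
    m <- merge(universe, a, by = c("chrom", "win"), all.x = TRUE, sort = FALSE)
    setorder(m, chrom, win)
    m[is.na(mc), `:=`(mc = 0, cov = 0)]
    m
  }
  filled <- lapply(aggs, fill)
  nA <- length(tracksA)
  getMat <- function(idx, col)
    matrix(unlist(lapply(filled[idx], `[[`, col)), ncol = length(idx))
  ends <- pmin((universe$win + 1L) * width,
               as.integer(seqlengths[universe$chrom]))
  win <- GRanges(universe$chrom,
                 IRanges(universe$win * width + 1L, ends),
                 seqlengths = setNames(as.integer(seqlengths),
                                       names(seqlengths)))
  new("WindowStats", windows = win, context = context,
      mcA = getMat(seq_len(nA), "mc"), covA = getMat(seq_len(nA), "cov"),
      mcB = getMat(nA + seq_along(tracksB), "mc"),
      covB = getMat(nA + seq_along(tracksB), "cov"),
      sampleA = trackSample(tracksA[[1]]), sampleB = trackSample(tracksB[[1]]))
}

#' Call differentially methylated regions from window counts
#'
#' A window is a DMR when all four conditions hold:
#' \enumerate{
#'   \item informative coverage (pooled cytosine depth over replicates) is at
#'     least `minInformative` — in each sample under the default
#'     `"per-sample"` rule, or summed over both under `"joint"`;
#'   \item the absolute replicate-pooled level difference exceeds the
#'     context threshold (0.5 CG / 0.3 CHG / 0.1 CHH);
#'   \item the two-sided Fisher exact p-value on the pooled counts is below
#'     `alpha`;
#'   \item every A-replicate x B-replicate pairing shows a level difference
#'     exceeding the threshold with the same sign as the pooled difference
#'     (pairings with zero coverage on either side fail the filter).
#' }
#' Direction is `"hypo"` when sample A is less methylated than sample B.
#'
#' @param stats a [WindowStats-class] from [windowCounts()].
#' @param minInformative minimum informative sequenced-cytosine depth.
#' @param threshold level-difference threshold; defaults to the context's
#'   standard value.
#' @param alpha Fisher-test significance level.
#' @param informativeRule `"per-sample"` (default) or `"joint"`.
#' @return a `GRanges` of DMRs with columns `context`, `m_A`, `m_B`,
#'   `difference` (m_A - m_B), `p_value`, `direction`.
#' @export
callDMRs <- function(stats, minInformative = 20, threshold = NULL,
                     alpha = 0.05, informativeRule = c("per-sample", "joint")) {
  stopifnot(is(stats, "WindowStats"))
  informativeRule <- match.arg(informativeRule)
  if (is.null(threshold)) threshold <- .DMR_THRESHOLDS[[stats@context]]
  infA <- rowSums(stats@covA); infB <- rowSums(stats@covB)
  keep <- if (informativeRule == "per-sample")
    infA >= minInformative & infB >= minInformative
  else infA + infB >= minInformative & infA > 0 & infB > 0
  mA <- rowSums(stats@mcA) / infA
  mB <- rowSums(stats@mcB) / infB
  diff <- mA - mB
  keep <- keep & !is.na(diff) & abs(diff) > threshold
  # replicate-consistency: every A x B replicate pairing must clear the
  # threshold with the pooled difference's sign
  if (any(keep)) {
    sgn <- sign(diff)
    for (i in seq_len(ncol(stats@mcA))) {
      for (j in seq_len(ncol(stats@mcB))) {
        cA <- stats@covA[, i]; cB <- stats@covB[, j]
        dij <- stats@mcA[, i] / cA - stats@mcB[, j] / cB
        ok <- cA > 0 & cB > 0 & !is.na(dij) &
          abs(dij) > threshold & sign(dij) == sgn
        keep <- keep & ok
      }
    }
  }
  idx <- which(keep)
  p <- if (length(idx))
    fisherExactTest(rowSums(stats@mcA)[idx], infA[idx],
                    rowSums(stats@mcB)[idx], infB[idx])
  else numeric()
  idx <- idx[p < alpha]
  p <- p[p < alpha]
  out <- stats@windows[idx]
  mcols(out) <- S4Vectors::DataFrame(
    context = rep(stats@context, length(idx)),
    m_A = mA[idx], m_B = mB[idx], difference = diff[idx], p_value = p,
    direction = ifelse(mA[idx] < mB[idx], "hypo", "hyper"))
  out
}

#' Annotate DMRs with their genomic feature category
#'
#' Each DMR is assigned exactly one category by any-overlap with precedence
#' TE > promoter > gene body > intergenic. Promoters are the strand-aware
#' regions `promoterSpan` bp upstream of the TSS.
#'
#' @param dmrs a DMR `GRanges` from [callDMRs()].
#' @param annotation a [GenomeAnnotation-class].
#' @param promoterSpan promoter width in bp upstream of the TSS.
#' @return `dmrs` with an added `feature` column
#'   (`"TE"`, `"promoter"`, `"gene"`, `"intergenic"`).
#' @export
annotateDMRs <- function(dmrs, annotation, promoterSpan = 2000) {
  stopifnot(is(annotation, "GenomeAnnotation"))
  feature <- rep("intergenic", length(dmrs))
  genes <- annotation@genes
  if (length(genes)) {
    feature[overlapsAny(dmrs, genes, ignore.strand = TRUE)] <- "gene"
    proms <- trim(promoters(genes, upstream = promoterSpan, downstream = 0))
    feature[overlapsAny(dmrs, proms, ignore.strand = TRUE)] <- "promoter"
  }
  if (length(annotation@tes))
    feature[overlapsAny(dmrs, annotation@tes, ignore.strand = TRUE)] <- "TE"
  dmrs$feature <- feature
  dmrs
}

#' Tabulate DMR counts by direction and feature
#'
#' @param dmrs an (optionally annotated) DMR `GRanges`.
#' @return data.frame of counts per `direction` (and `feature` when present).
#' @export
summarizeDMRs <- function(dmrs) {
  if (!is.null(dmrs$feature)) {
    tb <- table(direction = dmrs$direction, feature = dmrs$feature)
    as.data.frame(tb, responseName = "n")
  } else {
    tb <- table(direction = factor(dmrs$direction, c("hypo", "hyper")))
    data.frame(direction = names(tb), n = as.integer(tb), row.names = NULL)
  }
}

#' Venn-partition counts of several DMR sets
#'
#' Windows are identified by coordinates; the result counts every exclusive
#' region of the Venn partition, named by the set names joined with `"&"`.
#'
#' @param sets named list of DMR `GRanges` sharing one window partition.
#' @return named integer vector of exclusive-region counts.
#' @export
overlapDMRSets <- function(sets) {
  ids <- lapply(sets, function(gr)
    paste0(as.character(seqnames(gr)), ":", start(gr), "-", end(gr)))
  .vennCounts(ids)
}

#' Write a DMR table (1-based, tab-separated)
#'
#' @param dmrs annotated DMR `GRanges`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeDMRTable <- function(dmrs, path) {
  dt <- data.table(chrom = as.character(seqnames(dmrs)),
                   start = start(dmrs), end = end(dmrs),
                   context = dmrs$context, difference = dmrs$difference,
                   p_value = dmrs$p_value, direction = dmrs$direction,
                   feature = if (is.null(dmrs$feature)) NA_character_
                             else dmrs$feature)
  fwrite(dt, path, sep = "\t", col.names = TRUE)
  invisible(path)
}
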