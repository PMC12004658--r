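#' Generate a synthetic genome annotation
#'
#' Lays out non-overlapping, stranded genes on each chromosome and places
#' transposable elements, with short TEs (< 500 bp) preferentially dropped
#' into the 2-kb regions upstream of transcription start sites — the genomic
#' configuration whose methylation dynamics the downstream modules analyse.
#'
#' @param config a [SimulationConfig-class].
#' @return a [GenomeAnnotation-class].
#' @examples
#' ann <- generateAnnotation(SimulationConfig(chromLength = 2e5, nGenes = 20,
#'                                            nTEs = 50, seed = 3))
#' @export
generateAnnotation <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  .withSeed(config@seed, {
    L <- config@chromLength
    chroms <- paste0("chr", seq_len(config@nChromosomes))
    seqlengths <- setNames(rep(L, config@nChromosomes), chroms)

    # distribute genes round-robin over chromosomes, pack without overlap
    geneChrom <- if (config@nGenes > 0)
      chroms[((seq_len(config@nGenes) - 1L) %% config@nChromosomes) + 1L]
    else character()
    genes <- GRanges()
    if (config@nGenes > 0) {
      parts <- lapply(chroms, function(ch) {
        g <- sum(geneChrom == ch)
        if (g == 0L) return(NULL)
        len <- sample(1000:4000, g, replace = TRUE)
        slack <- L - sum(len)
        if (slack < 0)
          stop("infeasible packing: ", g, " genes of total ", sum(len),
               " bp do not fit in a ", L, " bp chromosome")
        floorGap <- min(2500L, slack %/% (g + 1L))
        extra <- slack - floorGap * (g + 1L)
        u <- runif(g + 1L)
        gaps <- floorGap + floor(extra * u / sum(u))
        starts <- cumsum(gaps[seq_len(g)]) + c(0L, cumsum(len[-g]))[seq_len(g)] + 1L
        GRanges(ch, IRanges(starts, width = len),
                strand = sample(c("+", "-"), g, replace = TRUE))
      })
      genes <- do.call(c, parts[!vapply(parts, is.null, logical(1))])
      genes$gene_id <- sprintf("g%04d", seq_along(genes))
    }

    tes <- GRanges()
    if (config@nTEs > 0) {
      nShort <- round(config@shortTEFraction * config@nTEs)
      lens <- c(if (nShort) sample(80:499, nShort, replace = TRUE),
                if (config@nTEs - nShort)
                  sample(500:6000, config@nTEs - nShort, replace = TRUE))
      inProm <- logical(config@nTEs)
      if (length(genes) && nShort)
        inProm[seq_len(nShort)] <- runif(nShort) < config@promoterTEFraction
      starts <- integer(config@nTEs)
      chrom <- character(config@nTEs)
      proms <- if (length(genes)) trim(promoters(.withSeqlengths(genes, seqlengths),
                                                 upstream = 2000, downstream = 0))
      for (i in seq_len(config@nTEs)) {
        if (inProm[i]) {
          ok <- which(width(proms) >= lens[i])
          j <- if (length(ok)) sample(ok, 1L) else NA_integer_
          if (!is.na(j)) {
            chrom[i] <- as.character(seqnames(proms))[j]
            starts[i] <- start(proms)[j] +
              sample.int(width(proms)[j] - lens[i] + 1L, 1L) - 1L
            next
          }
        }
        chrom[i] <- sample(chroms, 1L)
        if (L < lens[i]) stop("infeasible packing: TE longer than chromosome")
        starts[i] <- sample.int(L - lens[i] + 1L, 1L)
      }
      tes <- GRanges(chrom, IRanges(starts, width = lens),
                     strand = sample(c("+", "-"), config@nTEs, replace = TRUE))
      tes$te_id <- sprintf("te%04d", seq_along(tes))
      tes <- sort(tes)
      tes$te_id <- sprintf("te%04d", seq_along(tes))
    }
    new("GenomeAnnotation", seqlengths = seqlengths,
        genes = .withSeqlengths(genes, seqlengths),
        tes = .withSeqlengths(tes, seqlengths))
  })
}

.withSeqlengths <- function(gr, seqlengths) {
  if (!length(gr)) return(GRanges(seqlengths = seqlengths))
  GenomeInfoDb::seqlevels(gr) <- names(seqlengths)
  GenomeInfoDb::seqlengths(gr) <- seqlengths
  gr
}

# expected planted CHH proportion per stage: a linear gradient from
# baseline+delta down to baseline (hypo) or the reverse (hyper)
.plantedGradient <- function(direction, baseline, delta, nSamples) {
  if (nSamples == 1L) return(baseline + delta)
  g <- (seq_len(nSamples) - 1L) / (nSamples - 1L)
  if (direction == "hypo") baseline + delta * (1 - g) else baseline + delta * g
}

#' Simulate two-replicate bisulfite count data with planted CHH shifts
#'
#' Simulates a nucleotide sequence per chromosome (so cytosine contexts are
#' genome-driven), draws per-cytosine coverage from a negative binomial with
#' variance twice the mean, and draws methylated counts binomially around the
#' per-context baseline. A configured number of 50-bp windows — restricted to
#' short TEs (< 500 bp) inside 2-kb promoters with at least
#' `minSitesPerDMR` CHH sites — receive a planted CHH shift: over the stage
#' series their expected level runs linearly from baseline + delta down to
#' baseline ("hypo") or the reverse ("hyper"). Both replicates of a stage
#' share the same expected proportion.
#'
#' @param annotation a [GenomeAnnotation-class] from [generateAnnotation()].
#' @param config the same [SimulationConfig-class] used for the annotation.
#' @return a list with `tracks` (list of [MethylomeTrack-class], one per
#'   stage x replicate, named `"S0_R1"`, ...) and `truth`
#'   (a [GroundTruth-class]).
#' @export
simulateMethylome <- function(annotation, config) {
  stopifnot(is(annotation, "GenomeAnnotation"), is(config, "SimulationConfig"))
  .withSeed(config@seed + 1L, {
    base <- config@baselineMethylation
    bases <- c("A", "C", "G", "T")
    pbase <- c((1 - config@gcContent) / 2, config@gcContent / 2,
               config@gcContent / 2, (1 - config@gcContent) / 2)
    siteList <- lapply(names(annotation@seqlengths), function(ch) {
      L <- annotation@seqlengths[[ch]]
      s <- sample(bases, L, replace = TRUE, prob = pbase)
      iP <- which(s == "C")
      iP <- iP[iP <= L - 2L]
      ctxP <- ifelse(s[iP + 1L] == "G", "CG",
                     ifelse(s[iP + 2L] == "G", "CHG", "CHH"))
      iM <- which(s == "G")
      iM <- iM[iM >= 3L]
      ctxM <- ifelse(s[iM - 1L] == "C", "CG",
                     ifelse(s[iM - 2L] == "C", "CHG", "CHH"))
      data.table(chrom = ch, pos = c(iP, iM),
                 strand = rep(c("+", "-"), c(length(iP), length(iM))),
                 context = c(ctxP, ctxM))
    })
    sites <- rbindlist(siteList)
    setorder(sites, chrom, pos, strand)
    n <- nrow(sites)

    # eligible windows: 50-bp tiles over short promoter TEs, enough CHH sites
    planted <- GRanges(seqlengths = annotation@seqlengths)
    hostGene <- character()
    if (config@plantedDMRCount > 0) {
      genes <- annotation@genes
      shortTEs <- annotation@tes[width(annotation@tes) < 500L]
      if (!length(genes) || !length(shortTEs))
        stop("planting requires genes and short TEs in the annotation")
      proms <- trim(promoters(genes, upstream = 2000, downstream = 0))
      promTEs <- shortTEs[overlapsAny(shortTEs, proms)]
      tiles <- partitionWindows(annotation@seqlengths, width = 50L)
      cand <- tiles[overlapsAny(tiles, promTEs)]
      chh <- sites[context == "CHH"]
      chh[, win := .windowIndex(pos, 50L)]
      nchh <- chh[, .N, by = .(chrom, win)]
      candDT <- data.table(chrom = as.character(seqnames(cand)),
                           win = .windowIndex(start(cand), 50L),
                           idx = seq_along(cand))
      candDT <- merge(candDT, nchh, by = c("chrom", "win"))
      candDT <- candDT[N >= config@minSitesPerDMR]
      if (nrow(candDT) < config@plantedDMRCount)
        stop("only ", nrow(candDT), " windows are eligible for planting; ",
             config@plantedDMRCount, " requested")
      pick <- sort(sample(candDT$idx, config@plantedDMRCount))
      planted <- cand[pick]
      ov <- findOverlaps(planted, proms)
      hostGene <- rep(NA_character_, length(planted))
      hostGene[queryHits(ov)] <- genes$gene_id[subjectHits(ov)]
      planted$gene_id <- hostGene
      # direction is assigned per host gene so that all planted windows in
      # one promoter shift the same way and the planted sign is recoverable
      hosts <- unique(hostGene[!is.na(hostGene)])
      nHypo <- round(config@hypoFraction * length(hosts))
      dirByGene <- setNames(sample(rep(c("hypo", "hyper"),
                                       c(nHypo, length(hosts) - nHypo))),
                            hosts)
      planted$direction <- ifelse(is.na(hostGene), "hypo",
                                  dirByGene[hostGene])
    }

    # expected proportion per site per stage
    p0 <- unname(base[sites$context])
    pStage <- matrix(rep(p0, config@nSamples), ncol = config@nSamples)
    if (length(planted)) {
      sw <- data.table(chrom = sites$chrom,
                       win = .windowIndex(sites$pos, 50L),
                       row = seq_len(n))[sites$context == "CHH"]
      pw <- data.table(chrom = as.character(seqnames(planted)),
                       win = .windowIndex(start(planted), 50L),
                       direction = planted$direction)
      hits <- merge(sw, pw, by = c("chrom", "win"))
      grad <- vapply(c("hypo", "hyper"), .plantedGradient,
                     numeric(config@nSamples), baseline = base[["CHH"]],
                     delta = config@plantedDelta, nSamples = config@nSamples)
      grad <- matrix(grad, ncol = 2L, dimnames = list(NULL, c("hypo", "hyper")))
      pStage[hits$row, ] <- t(grad[, hits$direction, drop = FALSE])
    }

    tracks <- list()
    for (s in seq_len(config@nSamples)) {
      for (r in seq_len(config@nReplicates)) {
        cov <- rnbinom(n, size = config@depthMean, mu = config@depthMean)
        mc <- rbinom(n, cov, pStage[, s])
        keep <- cov > 0L
        gr <- GRanges(sites$chrom[keep], IRanges(sites$pos[keep], width = 1L),
                      strand = sites$strand[keep],
                      context = sites$context[keep],
                      mc = mc[keep], cov = cov[keep],
                      seqlengths = annotation@seqlengths)
        nm <- sprintf("S%d_R%d", s - 1L, r)
        tracks[[nm]] <- MethylomeTrack(gr, sample = sprintf("S%d", s - 1L),
                                       replicate = sprintf("R%d", r))
      }
    }

    linked <- data.frame(gene_id = character(), sign = integer(),
                         window = integer())
    if (length(planted)) {
      hosts <- unique(planted$gene_id[!is.na(planted$gene_id)])
      nLink <- min(length(hosts),
                   round(config@correlatedGeneFraction * config@nGenes))
      if (nLink > 0) {
        pickG <- sample(hosts, nLink)
        linked <- data.frame(
          gene_id = pickG,
          sign = sample(c(-1L, 1L), nLink, replace = TRUE),
          window = vapply(pickG, function(g)
            which(planted$gene_id == g)[1L], integer(1)),
          row.names = NULL)
      }
    }
    list(tracks = tracks,
         truth = new("GroundTruth", plantedWindows = planted,
                     linkedGenes = linked))
  })
}

#' Simulate an RPKM expression matrix coupled to planted promoter methylation
#'
#' Expression is log-normal. For every linked gene in the ground truth, the
#' log2 expression across stages follows the expected methylation level of its
#' planted promoter window — rescaled to `linkEffect` log2 units over the full
#' planted swing, with the sign recorded in the truth — plus Gaussian noise of
#' sd `linkNoiseSD` per library. Unlinked genes are independent of
#' methylation.
#'
#' @param annotation a [GenomeAnnotation-class].
#' @param truth the [GroundTruth-class] from [simulateMethylome()].
#' @param config the matching [SimulationConfig-class].
#' @return a [SummarizedExperiment::SummarizedExperiment] with an `rpkm`
#'   assay (genes x libraries) and colData columns `stage` and `replicate`.
#' @export
simulateExpression <- function(annotation, truth, config) {
  stopifnot(is(annotation, "GenomeAnnotation"), is(truth, "GroundTruth"),
            is(config, "SimulationConfig"))
  .withSeed(config@seed + 2L, {
    genes <- annotation@genes$gene_id
    nG <- length(genes)
    nS <- config@nSamples; nR <- config@nReplicates
    cols <- as.vector(t(outer(seq_len(nS) - 1L, seq_len(nR),
                              function(s, r) sprintf("S%d_R%d", s, r))))
    stage <- rep(sprintf("S%d", seq_len(nS) - 1L), each = nR)
    mu <- rnorm(nG, mean = 3, sd = 1.5)
    log2e <- matrix(mu, nrow = nG, ncol = nS * nR)
    if (nrow(truth@linkedGenes)) {
      for (i in seq_len(nrow(truth@linkedGenes))) {
        g <- match(truth@linkedGenes$gene_id[i], genes)
        w <- truth@linkedGenes$window[i]
        p <- .plantedGradient(truth@plantedWindows$direction[w],
                              config@baselineMethylation[["CHH"]],
                              config@plantedDelta, nS)
        z <- (p - mean(p)) / config@plantedDelta
        log2e[g, ] <- log2e[g, ] +
          truth@linkedGenes$sign[i] * config@linkEffect * rep(z, each = nR)
      }
    }
    log2e <- log2e + matrix(rnorm(nG * nS * nR, sd = config@linkNoiseSD),
                            nrow = nG)
    rpkm <- 2^log2e
    dimnames(rpkm) <- list(genes, cols)
    SummarizedExperiment::SummarizedExperiment(
      assays = list(rpkm = rpkm),
      colData = S4Vectors::DataFrame(stage = stage,
                                     replicate = rep(sprintf("R%d", seq_len(nR)), nS),
                                     row.names = cols))
  })
}

#' Simulate a differential-expression table for a stage comparison
#'
#' Produces the (gene, fold change, q value) table that the expression
#' filters consume, from mean RPKM per stage with a pseudocount; q values for
#' genes whose planted link makes them differential are drawn small, others
#' near-uniform. This is a convenience for exercising [filterDEGs()]; DE
#' testing itself is an input to the pipeline, not part of it.
#'
#' @param expr the expression `SummarizedExperiment`.
#' @param stageA,stageB stage labels; fold change is `stageA / stageB`
#'   (later over earlier by convention).
#' @param truth optional [GroundTruth-class]; linked genes get q values
#'   drawn from (0, 0.005), others from (0.02, 1).
#' @param seed integer seed for the q-value draw.
#' @return data.frame with columns `gene_id`, `fold_change`, `q_value`.
#' @export
simulateDETable <- function(expr, stageA, stageB, truth = NULL, seed = 1L) {
  rpkm <- SummarizedExperiment::assay(expr, "rpkm")
  st <- SummarizedExperiment::colData(expr)$stage
  mA <- rowMeans(rpkm[, st == stageA, drop = FALSE])
  mB <- rowMeans(rpkm[, st == stageB, drop = FALSE])
  fc <- (mA + 0.1) / (mB + 0.1)
  .withSeed(seed, {
    q <- runif(length(fc), 0.02, 1)
    if (!is.null(truth) && nrow(linkedGenes(truth)))
      q[rownames(rpkm) %in% linkedGenes(truth)$gene_id] <-
        runif(sum(rownames(rpkm) %in% linkedGenes(truth)$gene_id), 0, 0.005)
    data.frame(gene_id = rownames(rpkm), fold_change = unname(fc),
               q_value = q, row.names = NULL)
  })
}
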