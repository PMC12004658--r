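#' @import methods
#' @importFrom GenomicRanges GRanges granges seqnames start end width strand
#'   findOverlaps tileGenome promoters trim mcols mcols<-
#' @importFrom IRanges IRanges overlapsAny subjectHits queryHits
#' @importFrom S4Vectors DataFrame metadata metadata<- queryHits subjectHits
#' @importFrom GenomeInfoDb seqlengths seqlevels seqnames
#' @importFrom data.table data.table fread fwrite setkey setorder as.data.table
#'   rbindlist :=
#' @importFrom stats rbinom rnbinom rnorm runif dhyper p.adjust cor cor.test
#'   cmdscale dist median quantile sd wilcox.test pt pnorm setNames
#' @importFrom utils head tail
NULL

.CONTEXTS <- c("CG", "CHG", "CHH")

#' Parameters of the synthetic methylome/transcriptome generator
#'
#' A `SimulationConfig` bundles every knob of the synthetic-data generator:
#' genome geometry, annotation density, per-context baseline methylation,
#' the planted differential-methylation signal, sequencing depth, the
#' sample/replicate design and the methylation-expression coupling.
#'
#' The defaults describe the study design the generator emulates: two
#' replicates per developmental stage, negative-binomial coverage with
#' variance about twice the mean, CHH baseline near 5% (plant-typical
#' CG > CHG > CHH ordering), planted CHH shifts of 0.3 restricted to short
#' transposable elements (< 500 bp) inside 2-kb promoters, and a subset of
#' genes whose expression follows their planted promoter methylation.
#'
#' @slot nChromosomes number of chromosomes.
#' @slot chromLength length of each chromosome in bp.
#' @slot nGenes,nTEs number of genes / transposable elements per genome.
#' @slot shortTEFraction proportion of TEs shorter than 500 bp.
#' @slot promoterTEFraction proportion of short TEs placed inside the 2-kb
#'   region upstream of a TSS.
#' @slot baselineMethylation named numeric of length 3 (CG, CHG, CHH):
#'   baseline methylation proportion per context.
#' @slot plantedDMRCount number of 50-bp windows carrying a planted CHH shift.
#' @slot plantedDelta magnitude of the planted methylation-proportion shift.
#' @slot hypoFraction proportion of planted windows that lose methylation
#'   over the stage series (the rest gain).
#' @slot minSitesPerDMR minimum CHH sites required in a window for it to be
#'   eligible for planting.
#' @slot depthMean mean per-cytosine read coverage (negative binomial with
#'   size = mean, i.e. variance = 2 x mean).
#' @slot nSamples number of stages; @slot nReplicates replicates per stage.
#' @slot correlatedGeneFraction proportion of genes whose expression is tied
#'   to a planted promoter window.
#' @slot linkEffect log2-expression swing across the full planted methylation
#'   gradient for linked genes.
#' @slot linkNoiseSD sd (log2 units) of expression noise per library.
#' @slot gcContent genome GC proportion used when simulating sequence.
#' @slot seed integer seed fixing every random draw of the generator.
#' @export
setClass("SimulationConfig", representation(
  nChromosomes = "integer", chromLength = "integer",
  nGenes = "integer", nTEs = "integer",
  shortTEFraction = "numeric", promoterTEFraction = "numeric",
  baselineMethylation = "numeric",
  plantedDMRCount = "integer", plantedDelta = "numeric",
  hypoFraction = "numeric", minSitesPerDMR = "integer",
  depthMean = "numeric", nSamples = "integer", nReplicates = "integer",
  correlatedGeneFraction = "numeric",
  linkEffect = "numeric", linkNoiseSD = "numeric",
  gcContent = "numeric", seed = "integer"
))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  prop <- c(object@shortTEFraction, object@promoterTEFraction,
            object@baselineMethylation, object@hypoFraction,
            object@correlatedGeneFraction, object@gcContent)
  if (any(prop < 0 | prop > 1)) msg <- c(msg, "all proportions must lie in [0, 1]")
  if (length(object@baselineMethylation) != 3L ||
      !identical(names(object@baselineMethylation), .CONTEXTS))
    msg <- c(msg, "baselineMethylation must be named c(CG=, CHG=, CHH=)")
  if (object@plantedDelta <= 0 || object@plantedDelta > 1)
    msg <- c(msg, "plantedDelta must lie in (0, 1]")
  if (object@baselineMethylation[["CHH"]] + object@plantedDelta > 1)
    msg <- c(msg, "CHH baseline + plantedDelta must not exceed 1")
  if (object@depthMean <= 0) msg <- c(msg, "depthMean must be positive")
  if (object@nChromosomes < 1L || object@chromLength < 1L)
    msg <- c(msg, "genome must have at least one chromosome of positive length")
  if (object@nGenes < 0L || object@nTEs < 0L || object@plantedDMRCount < 0L)
    msg <- c(msg, "feature counts must be non-negative")
  if (object@nSamples < 1L || object@nReplicates < 1L)
    msg <- c(msg, "need at least one sample and one replicate")
  if (length(msg)) msg else TRUE
})

#' Construct a [SimulationConfig-class]
#'
#' @param nChromosomes,chromLength,nGenes,nTEs genome geometry and annotation
#'   density.
#' @param shortTEFraction,promoterTEFraction TE length/placement mix.
#' @param baselineMethylation per-context baseline proportions (CG, CHG, CHH).
#' @param plantedDMRCount,plantedDelta,hypoFraction,minSitesPerDMR planted
#'   differential-methylation signal.
#' @param depthMean,nSamples,nReplicates sequencing design.
#' @param correlatedGeneFraction,linkEffect,linkNoiseSD methylation-expression
#'   coupling for linked genes.
#' @param gcContent simulated genome GC proportion.
#' @param seed integer seed.
#' @return a validated `SimulationConfig`.
#' @examples
#' cfg <- SimulationConfig(nChromosomes = 1, chromLength = 2e5, seed = 7)
#' @export
SimulationConfig <- function(nChromosomes = 1, chromLength = 1e6,
                             nGenes = 100, nTEs = 250,
                             shortTEFraction = 0.7, promoterTEFraction = 0.8,
                             baselineMethylation = c(CG = 0.40, CHG = 0.10, CHH = 0.05),
                             plantedDMRCount = 200, plantedDelta = 0.3,
                             hypoFraction = 0.8, minSitesPerDMR = 10,
                             depthMean = 25, nSamples = 2, nReplicates = 2,
                             correlatedGeneFraction = 0.3,
                             linkEffect = 4, linkNoiseSD = 0.5,
                             gcContent = 0.44, seed = 1L) {
  new("SimulationConfig",
      nChromosomes = as.integer(nChromosomes), chromLength = as.integer(chromLength),
      nGenes = as.integer(nGenes), nTEs = as.integer(nTEs),
      shortTEFraction = as.numeric(shortTEFraction),
      promoterTEFraction = as.numeric(promoterTEFraction),
      baselineMethylation = setNames(as.numeric(baselineMethylation), .CONTEXTS),
      plantedDMRCount = as.integer(plantedDMRCount),
      plantedDelta = as.numeric(plantedDelta),
      hypoFraction = as.numeric(hypoFraction),
      minSitesPerDMR = as.integer(minSitesPerDMR),
      depthMean = as.numeric(depthMean),
      nSamples = as.integer(nSamples), nReplicates = as.integer(nReplicates),
      correlatedGeneFraction = as.numeric(correlatedGeneFraction),
      linkEffect = as.numeric(linkEffect), linkNoiseSD = as.numeric(linkNoiseSD),
      gcContent = as.numeric(gcContent), seed = as.integer(seed))
}

#' Chromosome lengths plus gene and TE intervals
#'
#' @slot seqlengths named integer vector of chromosome lengths (bp).
#' @slot genes [GenomicRanges::GRanges] with a `gene_id` column; strand-aware,
#'   non-overlapping. The TSS is `start` on `+` genes and `end` on `-` genes.
#' @slot tes `GRanges` of transposable elements with a `te_id` column.
#' @export
setClass("GenomeAnnotation", representation(
  seqlengths = "integer", genes = "GRanges", tes = "GRanges"))

setValidity("GenomeAnnotation", function(object) {
  msg <- character()
  if (is.null(names(object@seqlengths)) || any(object@seqlengths < 1L))
    msg <- c(msg, "seqlengths must be a named vector of positive lengths")
  for (what in c("genes", "tes")) {
    gr <- slot(object, what)
    if (length(gr)) {
      sl <- object@seqlengths[as.character(seqnames(gr))]
      if (anyNA(sl) || any(start(gr) < 1L) || any(end(gr) > sl))
        msg <- c(msg, sprintf("%s must lie within the declared chromosomes", what))
    }
  }
  if (length(object@genes) && is.null(object@genes$gene_id))
    msg <- c(msg, "genes need a gene_id column")
  if (length(msg)) msg else TRUE
})

#' Accessors for [GenomeAnnotation-class]
#' @param x a `GenomeAnnotation`.
#' @return `annotationGenes`/`annotationTEs` return a `GRanges`;
#'   `annotationSeqlengths` a named integer vector.
#' @export
annotationGenes <- function(x) x@genes
#' @rdname annotationGenes
#' @export
annotationTEs <- function(x) x@tes
#' @rdname annotationGenes
#' @export
annotationSeqlengths <- function(x) x@seqlengths

#' One bisulfite library: per-cytosine methylated/total read counts
#'
#' Sites are stored as a position-width `GRanges` (1-based) with metadata
#' columns `context` (CG/CHG/CHH), `mc` (methylated reads) and `cov` (total
#' reads), sorted by chromosome, position and strand with no duplicates.
#'
#' @slot sample sample (stage) identifier.
#' @slot replicate replicate identifier.
#' @slot sites the per-cytosine `GRanges`.
#' @export
setClass("MethylomeTrack", representation(
  sample = "character", replicate = "character", sites = "GRanges"))

setValidity("MethylomeTrack", function(object) {
  s <- object@sites
  msg <- character()
  need <- c("context", "mc", "cov")
  if (!all(need %in% names(mcols(s))))
    return("sites need metadata columns context, mc, cov")
  if (length(s)) {
    if (any(width(s) != 1L)) msg <- c(msg, "sites must be single positions")
    if (any(s$mc < 0L) || any(s$cov < 0L) || any(s$mc > s$cov))
      msg <- c(msg, "counts must satisfy 0 <= mc <= cov")
    if (!all(as.character(s$context) %in% .CONTEXTS))
      msg <- c(msg, "context must be CG, CHG or CHH")
    key <- paste(as.character(seqnames(s)), start(s), as.character(strand(s)))
    if (anyDuplicated(key)) msg <- c(msg, "duplicate (chrom, pos, strand) sites")
    o <- order(as.character(seqnames(s)), start(s), as.character(strand(s)))
    if (!identical(o, seq_along(s))) msg <- c(msg, "sites must be sorted by (chrom, pos, strand)")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a [MethylomeTrack-class]
#'
#' @param sites a `GRanges` of cytosine positions with `context`, `mc`, `cov`
#'   metadata columns (rows are sorted on construction).
#' @param sample,replicate library labels.
#' @return a validated `MethylomeTrack`.
#' @export
MethylomeTrack <- function(sites, sample = "S0", replicate = "R1") {
  o <- order(as.character(seqnames(sites)), start(sites), as.character(strand(sites)))
  sites <- sites[o]
  sites$context <- factor(as.character(sites$context), levels = .CONTEXTS)
  sites$mc <- as.integer(sites$mc)
  sites$cov <- as.integer(sites$cov)
  new("MethylomeTrack", sample = as.character(sample),
      replicate = as.character(replicate), sites = sites)
}

#' Accessors for [MethylomeTrack-class]
#' @param x a `MethylomeTrack`.
#' @export
trackSites <- function(x) x@sites
#' @rdname trackSites
#' @export
trackSample <- function(x) x@sample
#' @rdname trackSites
#' @export
trackReplicate <- function(x) x@replicate

#' Planted truth of a synthetic dataset
#'
#' @slot plantedWindows `GRanges` of planted 50-bp CHH windows with columns
#'   `direction` ("hypo"/"hyper" over the stage series) and `gene_id` (the
#'   gene whose promoter hosts the window).
#' @slot linkedGenes data.frame with columns `gene_id`, `sign` (+1/-1: sign of
#'   the planted methylation-expression relationship) and `window` (index into
#'   `plantedWindows`).
#' @export
setClass("GroundTruth", representation(
  plantedWindows = "GRanges", linkedGenes = "data.frame"))

#' Accessors for [GroundTruth-class]
#' @param x a `GroundTruth`.
#' @export
plantedWindows <- function(x) x@plantedWindows
#' @rdname plantedWindows
#' @export
linkedGenes <- function(x) x@linkedGenes

#' Per-window methylation counts for a two-sample comparison
#'
#' Holds, for every 50-bp window with at least one covered cytosine of the
#' chosen context, the per-replicate methylated and total read-count sums for
#' sample A and sample B of a comparison.
#'
#' @slot windows covered windows (`GRanges`).
#' @slot context the methylation context summarised.
#' @slot mcA,covA,mcB,covB integer matrices, windows x replicates.
#' @slot sampleA,sampleB sample labels of the comparison (A versus B).
#' @export
setClass("WindowStats", representation(
  windows = "GRanges", context = "character",
  mcA = "matrix", covA = "matrix", mcB = "matrix", covB = "matrix",
  sampleA = "character", sampleB = "character"))

setValidity("WindowStats", function(object) {
  n <- length(object@windows)
  dims <- vapply(list(object@mcA, object@covA, object@mcB, object@covB),
                 function(m) nrow(m), integer(1))
  if (!all(dims == n)) return("count matrices must have one row per window")
  if (any(object@mcA > object@covA) || any(object@mcB > object@covB))
    return("methylated counts cannot exceed coverage")
  TRUE
})

#' Accessors for [WindowStats-class]
#'
#' `pooledLevels` returns the replicate-pooled methylation level per window
#' (sum of methylated reads over sum of coverage); `informative` the pooled
#' coverage sums, i.e. the informative sequenced-cytosine depth.
#'
#' @param x a `WindowStats`.
#' @param sample `"A"` or `"B"`.
#' @export
pooledLevels <- function(x, sample = c("A", "B")) {
  sample <- match.arg(sample)
  mc <- if (sample == "A") x@mcA else x@mcB
  cov <- if (sample == "A") x@covA else x@covB
  lv <- rowSums(mc) / rowSums(cov)
  lv[rowSums(cov) == 0L] <- NA_real_
  lv
}
#' @rdname pooledLevels
#' @export
informative <- function(x, sample = c("A", "B")) {
  sample <- match.arg(sample)
  rowSums(if (sample == "A") x@covA else x@covB)
}
#' @rdname pooledLevels
#' @export
statWindows <- function(x) x@windows

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@nChromosomes, "chromosome(s) x",
      object@chromLength, "bp;", object@nGenes, "genes,", object@nTEs, "TEs\n")
  cat("  baseline mCG/mCHG/mCHH:",
      paste(sprintf("%.2f", object@baselineMethylation), collapse = "/"),
      "| planted:", object@plantedDMRCount, "windows, delta",
      object@plantedDelta, "\n")
  cat("  design:", object@nSamples, "stage(s) x", object@nReplicates,
      "replicate(s), depth", object@depthMean, "| seed", object@seed, "\n")
})

setMethod("show", "GenomeAnnotation", function(object) {
  cat("GenomeAnnotation:", length(object@seqlengths), "chromosome(s),",
      sum(as.numeric(object@seqlengths)), "bp;",
      length(object@genes), "genes,", length(object@tes), "TEs\n")
})

setMethod("show", "MethylomeTrack", function(object) {
  cat("MethylomeTrack", paste0(object@sample, "/", object@replicate), "-",
      length(object@sites), "cytosines\n")
  if (length(object@sites)) {
    tb <- table(object@sites$context)
    cat("  context counts:", paste(names(tb), tb, sep = "=", collapse = " "), "\n")
  }
})

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:", length(object@plantedWindows), "planted windows (",
      sum(object@plantedWindows$direction == "hypo"), "hypo ),",
      nrow(object@linkedGenes), "linked genes\n")
})

setMethod("show", "WindowStats", function(object) {
  cat("WindowStats [", object@context, "] ", object@sampleA, " vs ",
      object@sampleB, ": ", length(object@windows), " covered windows, ",
      ncol(object@mcA), "+", ncol(object@mcB), " replicates\n", sep = "")
})
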