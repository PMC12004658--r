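# Pipeline orchestration: a validated parameter bundle, fixture generation,
# the full multi-stage analysis with a run manifest, and the global-level
# percent-change report.

#' Pipeline parameter bundle
#'
#' Collects every stage threshold with its standard default: 50-bp windows,
#' >= 20 informative cytosines, level-difference thresholds 0.5/0.3/0.1 for
#' CG/CHG/CHH, Fisher alpha 0.05, transcribed-gene RPKM > 1, variation filter
#' max RPKM > 2 and CV > 1, DEG fold change > 4 at q < 0.01, 2-kb promoters in
#' 200-bp bins at FDR < 0.01, short-TE cutoff 500 bp, and 2000 control windows
#' per chromosome.
#'
#' @param simulation a [SimulationConfig-class] describing the synthetic
#'   input (used by [runSimulation()] and by [runFullAnalysis()] when no
#'   `fixtureDir` exists yet).
#' @param windowWidth,minInformative,dmrThresholds,alpha DMR-calling stage.
#' @param transcribedRPKM,minMaxRPKM,minCV,degMinFold,degMaxQ expression
#'   stage.
#' @param promoterSpan,promoterBinWidth,correlationFDR,minSamples correlation
#'   stage.
#' @param shortTECutoff,controlsPerChromosome TE-enrichment stage.
#' @param seed integer seed for every stochastic stage.
#' @param outDir output directory for tables and the manifest.
#' @return a validated `pipeline_config` list.
#' @export
pipelineConfig <- function(simulation = SimulationConfig(),
                           windowWidth = 50, minInformative = 20,
                           dmrThresholds = c(CG = 0.5, CHG = 0.3, CHH = 0.1),
                           alpha = 0.05,
                           transcribedRPKM = 1, minMaxRPKM = 2, minCV = 1,
                           degMinFold = 4, degMaxQ = 0.01,
                           promoterSpan = 2000, promoterBinWidth = 200,
                           correlationFDR = 0.01, minSamples = 4,
                           shortTECutoff = 500, controlsPerChromosome = 2000,
                           seed = 1L, outDir = tempfile("rootmeth_run_")) {
  cfg <- list(simulation = simulation, windowWidth = windowWidth,
              minInformative = minInformative, dmrThresholds = dmrThresholds,
              alpha = alpha, transcribedRPKM = transcribedRPKM,
              minMaxRPKM = minMaxRPKM, minCV = minCV,
              degMinFold = degMinFold, degMaxQ = degMaxQ,
              promoterSpan = promoterSpan,
              promoterBinWidth = promoterBinWidth,
              correlationFDR = correlationFDR, minSamples = minSamples,
              shortTECutoff = shortTECutoff,
              controlsPerChromosome = controlsPerChromosome,
              seed = as.integer(seed), outDir = outDir)
  for (nm in c("windowWidth", "minInformative", "alpha", "transcribedRPKM",
               "minMaxRPKM", "minCV", "degMinFold", "degMaxQ", "promoterSpan",
               "promoterBinWidth", "correlationFDR", "minSamples",
               "shortTECutoff", "controlsPerChromosome"))
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1L || cfg[[nm]] < 0 ||
        !is.finite(cfg[[nm]]))
      stop("invalid pipeline parameter: ", nm)
  if (!identical(names(cfg$dmrThresholds), c("CG", "CHG", "CHH")) ||
      any(cfg$dmrThresholds <= 0 | cfg$dmrThresholds > 1))
    stop("invalid pipeline parameter: dmrThresholds")
  stopifnot(is(simulation, "SimulationConfig"))
  validObject(simulation)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Generate and write a synthetic fixture
#'
#' @param config a [pipelineConfig()] bundle.
#' @param dir fixture directory (defaults to `<outDir>/fixture`).
#' @return the fixture directory, invisibly.
#' @export
runSimulation <- function(config, dir = file.path(config$outDir, "fixture")) {
  stopifnot(inherits(config, "pipeline_config"))
  ann <- generateAnnotation(config$simulation)
  sim <- simulateMethylome(ann, config$simulation)
  expr <- simulateExpression(ann, sim$truth, config$simulation)
  writeFixture(ann, sim$tracks, expr, sim$truth, dir)
  invisible(dir)
}

.stageStep <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis on a fixture directory
#'
#' Sequences the stages: global methylation summaries and replicate QC ->
#' windowed DMR calling for every consecutive stage comparison (all three
#' contexts) -> DMR annotation and cross-comparison overlap -> DMR-TE length
#' enrichment against random control windows -> expression filters and MDS ->
#' promoter-bin methylation-expression correlation. Every stage's table is
#' written under `config$outDir` together with a `manifest.yaml` recording
#' parameters, seed and per-stage row counts. A failing stage halts the run
#' with an error naming it.
#'
#' @param config a [pipelineConfig()] bundle.
#' @param fixtureDir directory holding the input files (layout of
#'   [writeFixture()]); simulated on the fly when missing.
#' @return invisibly, a list with every stage's in-memory result.
#' @export
runFullAnalysis <- function(config,
                            fixtureDir = file.path(config$outDir, "fixture")) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(fixtureDir)) runSimulation(config, fixtureDir)
  if (!dir.exists(config$outDir)) dir.create(config$outDir, recursive = TRUE)
  fx <- .stageStep("read-input", {
    fx <- readFixture(fixtureDir)
    if (!length(fx$tracks)) stop("no cytosine reports found")
    fx
  })
  byStage <- split(fx$tracks, vapply(fx$tracks, trackSample, ""))
  stages <- names(byStage)
  sl <- annotationSeqlengths(fx$annotation)

  global <- .stageStep("global-methylation", {
    rows <- lapply(stages, function(s) {
      do.call(rbind, lapply(.CONTEXTS, function(ctx) {
        w <- weightedMethylation(byStage[[s]], ctx)
        cbind(stage = s, w)
      }))
    })
    do.call(rbind, rows)
  })
  fwrite(global, file.path(config$outDir, "global_methylation.tsv"), sep = "\t")

  repQC <- .stageStep("replicate-qc", {
    do.call(rbind, lapply(stages, function(s) {
      trs <- byStage[[s]]
      if (length(trs) < 2L) return(NULL)
      r <- tryCatch(replicateCorrelation(trs[[1]], trs[[2]], "CHH"),
                    error = function(e) NA_real_)   # too few shared bins
      data.frame(stage = s, r = r)
    }))
  })

  dmrs <- .stageStep("call-dmrs", {
    out <- list()
    if (length(stages) >= 2L) {
      for (i in seq_len(length(stages) - 1L)) {
        comp <- paste0(stages[i + 1L], "/", stages[i])  # later versus earlier
        for (ctx in .CONTEXTS) {
          ws <- windowCounts(byStage[[stages[i + 1L]]], byStage[[stages[i]]],
                             seqlengths = sl, width = config$windowWidth,
                             context = ctx)
          d <- callDMRs(ws, minInformative = config$minInformative,
                        threshold = config$dmrThresholds[[ctx]],
                        alpha = config$alpha)
          out[[paste(comp, ctx)]] <- annotateDMRs(d, fx$annotation,
                                                  config$promoterSpan)
        }
      }
    }
    out
  })
  for (nm in names(dmrs))
    writeDMRTable(dmrs[[nm]], file.path(config$outDir,
      paste0("dmrs_", gsub("[^A-Za-z0-9]+", "_", nm), ".tsv")))

  overlaps <- .stageStep("dmr-overlaps", {
    chh <- dmrs[grepl(" CHH$", names(dmrs))]
    hypo <- lapply(chh, function(d) d[d$direction == "hypo"])
    if (length(hypo) >= 2L) overlapDMRSets(hypo) else NULL
  })

  teEnrich <- .stageStep("te-enrichment", {
    chh <- dmrs[grepl(" CHH$", names(dmrs))]
    allCHH <- if (length(chh)) unique(do.call(c, unname(lapply(chh, granges))))
              else GRanges()
    if (!length(allCHH)) NULL else {
      ctrl <- sampleControlWindows(sl, config$controlsPerChromosome,
                                   config$windowWidth, seed = config$seed)
      cmp <- compareLengthDistributions(
        associatedTELengths(allCHH, annotationTEs(fx$annotation)),
        associatedTELengths(ctrl, annotationTEs(fx$annotation)),
        shortCutoff = config$shortTECutoff)
      fwrite(cmp$summary, file.path(config$outDir, "te_length_summary.tsv"),
             sep = "\t")
      profile <- shortTEGenicProfile(annotationTEs(fx$annotation),
                                     annotationGenes(fx$annotation),
                                     lengthCutoff = config$shortTECutoff)
      fwrite(profile, file.path(config$outDir, "short_te_profile.tsv"),
             sep = "\t")
      list(comparison = cmp, profile = profile)
    }
  })

  expression <- .stageStep("expression", {
    if (is.null(fx$expr)) NULL else {
      transcribed <- countTranscribed(fx$expr, config$transcribedRPKM)
      varGenes <- variationFilter(fx$expr, config$minMaxRPKM, config$minCV)
      nlib <- ncol(.rpkmMatrix(fx$expr))
      mds <- if (nlib >= 4L) mdsEmbedding(fx$expr, dimensions = 3)
      fwrite(data.frame(stage = names(transcribed), n = transcribed),
             file.path(config$outDir, "transcribed_counts.tsv"), sep = "\t")
      list(transcribed = transcribed, variable_genes = varGenes, mds = mds)
    }
  })

  correlation <- .stageStep("correlation", {
    if (is.null(fx$expr) || length(stages) < config$minSamples) NULL else {
      res <- correlateMethylationExpression(
        fx$tracks, annotationGenes(fx$annotation), fx$expr,
        span = config$promoterSpan, binWidth = config$promoterBinWidth,
        qThreshold = config$correlationFDR, minSamples = config$minSamples)
      fwrite(res, file.path(config$outDir, "promoter_correlation.tsv"),
             sep = "\t")
      list(results = res, summary = summarizeCorrelation(res))
    }
  })

  report <- .stageStep("report", {
    chh <- global[global$context == "CHH", ]
    reportPercentChanges(data.frame(stage = chh$stage,
                                    level = chh$level,
                                    mc = chh$mc_total, cov = chh$cov_total))
  })
  fwrite(report, file.path(config$outDir, "percent_changes.tsv"), sep = "\t")

  manifest <- list(
    seed = config$seed,
    parameters = config[setdiff(names(config), c("simulation", "outDir"))],
    simulation = list(seed = config$simulation@seed,
                      nChromosomes = config$simulation@nChromosomes,
                      chromLength = config$simulation@chromLength),
    rows = list(global = nrow(global),
                dmrs = lapply(dmrs, length),
                correlation = if (!is.null(correlation))
                  nrow(correlation$results) else 0L))
  manifest$parameters$dmrThresholds <- as.list(config$dmrThresholds)
  yaml::write_yaml(manifest, file.path(config$outDir, "manifest.yaml"))

  invisible(list(global = global, replicate_qc = repQC, dmrs = dmrs,
                 overlaps = overlaps, te_enrichment = teEnrich,
                 expression = expression, correlation = correlation,
                 percent_changes = report))
}

#' Percent-change report for global methylation levels
#'
#' Pairwise consecutive-stage comparisons of global weighted levels with the
#' signed percent change and, when pooled counts are supplied, a
#' two-proportion z-test on the pooled methylated/total counts.
#'
#' @param levels data.frame with columns `stage`, `level` and optionally
#'   `mc`, `cov` (pooled counts, enabling the z-test); one row per stage, in
#'   stage order. An optional `group` column keeps root types separate.
#' @return data.frame: `comparison`, `before`, `after`, `percent`,
#'   `direction`, and (with counts) `z`, `p_value`.
#' @examples
#' reportPercentChanges(data.frame(stage = c("S0", "S1"),
#'                                 level = c(5.02, 3.31)))
#' @export
reportPercentChanges <- function(levels) {
  stopifnot(all(c("stage", "level") %in% names(levels)))
  groups <- if ("group" %in% names(levels)) split(levels, levels$group)
            else list(levels)
  out <- lapply(groups, function(lv) {
    if (nrow(lv) < 2L) return(NULL)
    rows <- lapply(seq_len(nrow(lv) - 1L), function(i) {
      pc <- percentChange(lv$level[i], lv$level[i + 1L])
      row <- data.frame(
        comparison = paste0(lv$stage[i + 1L], "/", lv$stage[i]),
        before = lv$level[i], after = lv$level[i + 1L],
        percent = pc$percent, direction = pc$direction)
      if (all(c("mc", "cov") %in% names(lv))) {
        p1 <- lv$mc[i] / lv$cov[i]; p2 <- lv$mc[i + 1L] / lv$cov[i + 1L]
        pp <- (lv$mc[i] + lv$mc[i + 1L]) / (lv$cov[i] + lv$cov[i + 1L])
        se <- sqrt(pp * (1 - pp) * (1 / lv$cov[i] + 1 / lv$cov[i + 1L]))
        z <- if (se > 0) (p1 - p2) / se else 0
        row$z <- z
        row$p_value <- 2 * pnorm(-abs(z))
      }
      if ("group" %in% names(lv)) row <- cbind(group = lv$group[1], row)
      row
    })
    do.call(rbind, rows)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(out) <- NULL
  out
}
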