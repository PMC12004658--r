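# RNA-seq-side computations: transcribed-gene counts, DEG filtering, the
# variation pre-filter for co-expression analysis, and classical MDS of
# expression profiles.

.rpkmMatrix <- function(expr) {
  if (is(expr, "SummarizedExperiment"))
    SummarizedExperiment::assay(expr, "rpkm")
  else as.matrix(expr)
}

.stageOf <- function(expr, m) {
  if (is(expr, "SummarizedExperiment"))
    as.character(SummarizedExperiment::colData(expr)$stage)
  else sub("_[^_]+$", "", colnames(m))
}

#' Count transcribed genes per stage
#'
#' A gene counts as transcribed in a stage when its RPKM exceeds `threshold`
#' (strictly). Replicates are averaged per stage before thresholding under
#' the default `"mean"` mode; `"both"` requires every replicate to exceed the
#' threshold.
#'
#' @param expr a `SummarizedExperiment` with an `rpkm` assay and `stage`
#'   colData, or a genes x libraries matrix with `<stage>_<rep>` column names.
#' @param threshold RPKM threshold (default 1).
#' @param mode `"mean"` or `"both"`.
#' @return named integer vector of transcribed-gene counts per stage.
#' @export
countTranscribed <- function(expr, threshold = 1, mode = c("mean", "both")) {
  mode <- match.arg(mode)
  m <- .rpkmMatrix(expr)
  stage <- .stageOf(expr, m)
  vapply(unique(stage), function(s) {
    sub <- m[, stage == s, drop = FALSE]
    if (mode == "mean") sum(rowMeans(sub) > threshold)
    else sum(apply(sub, 1L, function(r) all(r > threshold)))
  }, integer(1))
}

#' Filter differentially expressed genes
#'
#' Retains genes with fold change strictly above `minFold` (up) or below
#' `1/minFold` (down) and q value strictly below `maxQ`. Fold changes follow
#' the later-over-earlier stage convention.
#'
#' @param table data.frame with columns `gene_id`, `fold_change`, `q_value`.
#' @param minFold fold-change cutoff (default 4).
#' @param maxQ q-value cutoff (default 0.01).
#' @return data.frame of retained genes with a `direction` column
#'   (`"up"`/`"down"`).
#' @export
filterDEGs <- function(table, minFold = 4, maxQ = 0.01) {
  stopifnot(all(c("gene_id", "fold_change", "q_value") %in% names(table)),
            all(table$fold_change > 0))
  keep <- (table$fold_change > minFold | table$fold_change < 1 / minFold) &
    table$q_value < maxQ
  out <- table[keep, , drop = FALSE]
  out$direction <- ifelse(out$fold_change > 1, "up", "down")
  rownames(out) <- NULL
  out
}

#' Variation pre-filter for co-expression analysis
#'
#' Keeps genes with maximum RPKM strictly above `minMaxRPKM` and coefficient
#' of variation (sd / mean across libraries) strictly above `minCV`. Genes
#' with zero mean have an undefined CV and are excluded.
#'
#' @inheritParams countTranscribed
#' @param minMaxRPKM maximum-RPKM cutoff (default 2).
#' @param minCV coefficient-of-variation cutoff (default 1).
#' @return character vector of retained gene ids.
#' @export
variationFilter <- function(expr, minMaxRPKM = 2, minCV = 1) {
  m <- .rpkmMatrix(expr)
  stopifnot(ncol(m) >= 2L)
  mx <- apply(m, 1L, max)
  mu <- rowMeans(m)
  cv <- ifelse(mu > 0, apply(m, 1L, sd) / mu, NA_real_)
  rownames(m)[which(mx > minMaxRPKM & !is.na(cv) & cv > minCV)]
}

#' Classical MDS of expression profiles
#'
#' Pairwise Euclidean distances between library expression vectors, embedded
#' by classical (metric) multidimensional scaling. The reported stress is
#' `sqrt(sum((d - dhat)^2) / sum(d^2))` over all pairs.
#'
#' @inheritParams countTranscribed
#' @param dimensions embedding dimension (default 3).
#' @return list: `distances` (a `dist`), `coordinates` (libraries x
#'   dimensions), `eig`, `stress`.
#' @export
mdsEmbedding <- function(expr, dimensions = 3) {
  m <- .rpkmMatrix(expr)
  stopifnot(ncol(m) >= dimensions + 1L)
  d <- dist(t(m))
  fit <- cmdscale(d, k = dimensions, eig = TRUE)
  coords <- fit$points
  if (ncol(coords) < dimensions)    # degenerate: pad collapsed dimensions
    coords <- cbind(coords, matrix(0, nrow(coords),
                                   dimensions - ncol(coords)))
  dhat <- dist(coords)
  stress <- if (sum(d^2) > 0) sqrt(sum((d - dhat)^2) / sum(d^2)) else 0
  list(distances = d, coordinates = coords, eig = fit$eig, stress = stress)
}

#' Summarize DEG direction counts and cross-comparison overlaps
#'
#' @param degSets named list of [filterDEGs()] outputs, one per comparison.
#' @return list: `counts` (data.frame comparison/up/down) and `overlaps`
#'   (list with Venn-partition counts of up- and down-gene sets across
#'   comparisons).
#' @export
summarizeDEGDirection <- function(degSets) {
  stopifnot(is.list(degSets), !is.null(names(degSets)))
  counts <- data.frame(
    comparison = names(degSets),
    up = vapply(degSets, function(d) sum(d$direction == "up"), integer(1)),
    down = vapply(degSets, function(d) sum(d$direction == "down"), integer(1)),
    row.names = NULL)
  pick <- function(dir) lapply(degSets, function(d)
    d$gene_id[d$direction == dir])
  list(counts = counts,
       overlaps = list(up = .vennCounts(pick("up")),
                       down = .vennCounts(pick("down"))))
}
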