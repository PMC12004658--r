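# Readers and writers for the pipeline's plain-text interchange formats:
# six-column cytosine reports, BED6 feature intervals, expression matrices
# and the ground-truth manifest of the synthetic generator.

.REPORT_COLS <- c("chrom", "pos", "strand", "context", "mc", "cov")

#' Read a per-cytosine methylation report
#'
#' The report is tab-separated with a header and six columns: chrom, 1-based
#' position, strand (+/-), context (CG/CHG/CHH), methylated read count, total
#' read count. Gzip-compressed files (`.gz`) are accepted. Rows violating the
#' count invariant (mc > cov) or carrying an unknown context or strand are
#' rejected with the offending line numbers.
#'
#' @param path file path (optionally `.gz`).
#' @param sample,replicate labels for the returned track; defaults are parsed
#'   from a `<sample>_<replicate>` file-name stem when possible.
#' @return a [MethylomeTrack-class].
#' @export
readCytosineReport <- function(path, sample = NULL, replicate = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "rt")
    on.exit(close(con))
    dt <- as.data.table(utils::read.table(con, header = TRUE, sep = "\t",
                                          colClasses = c("character", "integer",
                                                         "character", "character",
                                                         "integer", "integer")))
  } else {
    dt <- fread(path, sep = "\t", header = TRUE,
                colClasses = list(character = c(1, 3, 4), integer = c(2, 5, 6)))
  }
  if (!identical(names(dt), .REPORT_COLS))
    stop("cytosine report must have columns ", paste(.REPORT_COLS, collapse = ", "))
  bad <- which(is.na(dt$pos) | is.na(dt$mc) | is.na(dt$cov) | dt$pos < 1L |
               dt$mc < 0L | dt$mc > dt$cov |
               !dt$strand %in% c("+", "-") | !dt$context %in% .CONTEXTS)
  if (length(bad))
    stop("malformed cytosine-report rows (data line ",
         paste(head(bad, 5L), collapse = ", "),
         if (length(bad) > 5L) ", ..."  else "", ") in ", path)
  if (is.null(sample) || is.null(replicate)) {
    stem <- sub("\\.tsv(\\.gz)?$", "", basename(path))
    parts <- strsplit(stem, "_")[[1]]
    if (is.null(sample))
      sample <- if (length(parts) >= 2L) parts[length(parts) - 1L] else stem
    if (is.null(replicate))
      replicate <- if (length(parts) >= 2L) parts[length(parts)] else "R1"
  }
  gr <- GRanges(dt$chrom, IRanges(dt$pos, width = 1L), strand = dt$strand,
                context = dt$context, mc = dt$mc, cov = dt$cov)
  MethylomeTrack(gr, sample = sample, replicate = replicate)
}

#' Write a [MethylomeTrack-class] as a cytosine report
#'
#' @param track the track to write.
#' @param path output path (plain text, tab-separated, with header).
#' @return the path, invisibly.
#' @export
writeCytosineReport <- function(track, path) {
  stopifnot(is(track, "MethylomeTrack"))
  dt <- .siteDT(track)
  fwrite(dt, path, sep = "\t", col.names = TRUE)
  invisible(path)
}

#' Read/write BED6 feature intervals
#'
#' Thin wrappers over [rtracklayer::import()]/[rtracklayer::export()] that
#' carry the feature identifier in the BED name column.
#'
#' @param path a `.bed` file.
#' @param idColumn name under which the BED name field is returned
#'   (`"gene_id"` or `"te_id"`).
#' @return `readBED` returns a `GRanges` with the id column; `writeBED`
#'   returns `path` invisibly.
#' @export
readBED <- function(path, idColumn = "name") {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "BED")
  if (idColumn != "name" && !is.null(gr$name)) {
    mcols(gr)[[idColumn]] <- gr$name
    gr$name <- NULL
  }
  gr$score <- NULL
  gr
}

#' @rdname readBED
#' @param gr a `GRanges`; the column named `idColumn` becomes the BED name.
#' @export
writeBED <- function(gr, path, idColumn = "name") {
  out <- granges(gr)
  out$name <- if (idColumn %in% names(mcols(gr))) mcols(gr)[[idColumn]]
              else as.character(seq_along(gr))
  out$score <- 0L
  rtracklayer::export(out, path, format = "BED")
  invisible(path)
}

#' Read/write a tab-separated expression matrix
#'
#' Layout: a `gene_id` column followed by one column per library, named
#' `<stage>_<replicate>`.
#'
#' @param path a `.tsv` file.
#' @return `readExpressionMatrix` returns a `SummarizedExperiment` with an
#'   `rpkm` assay and `stage`/`replicate` colData.
#' @export
readExpressionMatrix <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE)
  genes <- dt[[1]]
  m <- as.matrix(dt[, -1, drop = FALSE])
  rownames(m) <- genes
  parts <- strsplit(colnames(m), "_")
  SummarizedExperiment::SummarizedExperiment(
    assays = list(rpkm = m),
    colData = S4Vectors::DataFrame(
      stage = vapply(parts, `[`, "", 1L),
      replicate = vapply(parts, function(p) paste(p[-1], collapse = "_"), ""),
      row.names = colnames(m)))
}

#' @rdname readExpressionMatrix
#' @param expr a `SummarizedExperiment` with an `rpkm` assay.
#' @export
writeExpressionMatrix <- function(expr, path) {
  m <- SummarizedExperiment::assay(expr, "rpkm")
  dt <- data.table(gene_id = rownames(m))
  for (j in colnames(m)) dt[[j]] <- m[, j]
  fwrite(dt, path, sep = "\t", col.names = TRUE)
  invisible(path)
}

#' Write a complete synthetic fixture to a directory
#'
#' Writes one cytosine report per library (`cytosine_<stage>_<rep>.tsv`),
#' `genes.bed` and `tes.bed`, `expression.tsv`, and a key-value
#' `ground_truth.txt` manifest holding chromosome lengths, planted windows
#' and linked genes. [readFixture()] restores all of it losslessly.
#'
#' @param annotation a [GenomeAnnotation-class].
#' @param tracks named list of [MethylomeTrack-class].
#' @param expr expression `SummarizedExperiment` (or `NULL` to skip).
#' @param truth a [GroundTruth-class] (or `NULL`).
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
writeFixture <- function(annotation, tracks, expr, truth, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (tr in tracks)
    writeCytosineReport(tr, file.path(dir, sprintf("cytosine_%s_%s.tsv",
                                                   trackSample(tr),
                                                   trackReplicate(tr))))
  writeBED(annotation@genes, file.path(dir, "genes.bed"), idColumn = "gene_id")
  writeBED(annotation@tes, file.path(dir, "tes.bed"), idColumn = "te_id")
  if (!is.null(expr)) writeExpressionMatrix(expr, file.path(dir, "expression.tsv"))
  lines <- c(
    paste0("chrom_length.", names(annotation@seqlengths), "\t",
           annotation@seqlengths))
  if (!is.null(truth)) {
    pw <- plantedWindows(truth)
    if (length(pw))
      lines <- c(lines, sprintf("planted_window.%d\t%s:%d-%d:%s:%s",
                                seq_along(pw), as.character(seqnames(pw)),
                                start(pw), end(pw), pw$direction, pw$gene_id))
    lg <- linkedGenes(truth)
    if (nrow(lg))
      lines <- c(lines, sprintf("linked_gene.%d\t%s:%d:%d",
                                seq_len(nrow(lg)), lg$gene_id, lg$sign,
                                lg$window))
  }
  writeLines(lines, file.path(dir, "ground_truth.txt"))
  invisible(dir)
}

#' Read a fixture directory written by [writeFixture()]
#'
#' @param dir the fixture directory.
#' @return list with `annotation`, `tracks`, `expr` (or `NULL`) and `truth`.
#' @export
readFixture <- function(dir) {
  kv <- strsplit(readLines(file.path(dir, "ground_truth.txt")), "\t")
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, `[`, "", 2L)
  isLen <- startsWith(keys, "chrom_length.")
  seqlengths <- setNames(as.integer(vals[isLen]),
                         sub("^chrom_length\\.", "", keys[isLen]))
  genes <- .withSeqlengths(readBED(file.path(dir, "genes.bed"), "gene_id"),
                           seqlengths)
  tes <- .withSeqlengths(readBED(file.path(dir, "tes.bed"), "te_id"), seqlengths)
  annotation <- new("GenomeAnnotation", seqlengths = seqlengths,
                    genes = genes, tes = tes)
  files <- sort(list.files(dir, pattern = "^cytosine_.*\\.tsv(\\.gz)?$",
                           full.names = TRUE))
  tracks <- lapply(files, readCytosineReport)
  names(tracks) <- vapply(tracks, function(tr)
    paste(trackSample(tr), trackReplicate(tr), sep = "_"), "")
  exprPath <- file.path(dir, "expression.tsv")
  expr <- if (file.exists(exprPath)) readExpressionMatrix(exprPath)
  pw <- GRanges(seqlengths = seqlengths)
  if (any(startsWith(keys, "planted_window."))) {
    f <- do.call(rbind, strsplit(vals[startsWith(keys, "planted_window.")], ":"))
    se <- do.call(rbind, strsplit(f[, 2], "-"))
    pw <- GRanges(f[, 1], IRanges(as.integer(se[, 1]), as.integer(se[, 2])),
                  direction = f[, 3], gene_id = f[, 4],
                  seqlengths = seqlengths)
  }
  lg <- data.frame(gene_id = character(), sign = integer(), window = integer())
  if (any(startsWith(keys, "linked_gene."))) {
    f <- do.call(rbind, strsplit(vals[startsWith(keys, "linked_gene.")], ":"))
    lg <- data.frame(gene_id = f[, 1], sign = as.integer(f[, 2]),
                     window = as.integer(f[, 3]), row.names = NULL)
  }
  list(annotation = annotation, tracks = tracks, expr = expr,
       truth = new("GroundTruth", plantedWindows = pw, linkedGenes = lg))
}
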