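# Internal helpers shared across modules.

# Run `expr` under a locally seeded RNG, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (has) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Collapse a MethylomeTrack / GRanges / list thereof into one data.table of
# sites: chrom, pos, strand, context, mc, cov. Pooling replicates is just
# concatenation; weighted summaries sum the counts afterwards.
.siteDT <- function(x) {
  if (is(x, "MethylomeTrack")) x <- list(x)
  if (is(x, "GRanges")) x <- list(x)
  dts <- lapply(x, function(el) {
    gr <- if (is(el, "MethylomeTrack")) trackSites(el) else el
    data.table(chrom = as.character(seqnames(gr)), pos = start(gr),
               strand = as.character(strand(gr)),
               context = as.character(gr$context),
               mc = as.integer(gr$mc), cov = as.integer(gr$cov))
  })
  rbindlist(dts)
}

# Counts of every exclusive region of the Venn partition of named id sets.
# Names of the result are the set names joined by "&" (exclusive regions),
# e.g. c(A = 3, `A&B` = 1); empty regions are reported as 0.
.vennCounts <- function(sets) {
  stopifnot(is.list(sets), !is.null(names(sets)), all(nzchar(names(sets))))
  sets <- lapply(sets, unique)
  ids <- unique(unlist(sets, use.names = FALSE))
  k <- length(sets)
  combos <- unlist(lapply(seq_len(k), function(m)
    utils::combn(names(sets), m, paste, collapse = "&", simplify = FALSE)))
  out <- setNames(integer(length(combos)), combos)
  if (length(ids)) {
    member <- vapply(sets, function(s) ids %in% s, logical(length(ids)))
    member <- matrix(member, nrow = length(ids),
                     dimnames = list(NULL, names(sets)))
    pat <- apply(member, 1L, function(r) paste(names(sets)[r], collapse = "&"))
    tb <- table(pat)
    out[names(tb)] <- as.integer(tb)
  }
  out
}

# 1-based window id for a 1-based position and fixed window width.
.windowIndex <- function(pos, width) (pos - 1L) %/% as.integer(width)

.checkContext <- function(context) {
  match.arg(context, .CONTEXTS)
}
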