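#' Vectorized two-sided Fisher's exact test for methylation counts
#'
#' Exact two-sided p-value for the 2x2 table
#' `[[mcA, covA - mcA], [mcB, covB - mcB]]`, computed by summing all
#' hypergeometric point probabilities not exceeding that of the observed
#' table (with the customary `1 + 1e-7` relative guard against floating-point
#' ties). Tables sharing margins are evaluated together, so the function is
#' fast over the tens of thousands of windows a genome scan produces.
#'
#' @param mcA,covA methylated/total counts of sample A (vectors).
#' @param mcB,covB methylated/total counts of sample B.
#' @return vector of two-sided p-values; degenerate all-zero margins give 1.
#' @examples
#' fisherExactTest(5, 10, 5, 10)   # identical proportions: p = 1
#' fisherExactTest(0, 20, 20, 20)  # complete separation
#' @export
fisherExactTest <- function(mcA, covA, mcB, covB) {
  nTab <- max(length(mcA), length(covA), length(mcB), length(covB))
  mcA <- rep_len(as.numeric(mcA), nTab); covA <- rep_len(as.numeric(covA), nTab)
  mcB <- rep_len(as.numeric(mcB), nTab); covB <- rep_len(as.numeric(covB), nTab)
  if (any(mcA < 0 | mcB < 0 | mcA > covA | mcB > covB))
    stop("counts must satisfy 0 <= mc <= cov")
  m <- mcA + mcB                      # methylated margin
  nn <- (covA - mcA) + (covB - mcB)   # unmethylated margin
  k <- covA                           # sample-A margin
  x <- mcA
  dt <- data.table(m = m, nn = nn, k = k, x = x, idx = seq_len(nTab))
  p <- numeric(nTab)
  relErr <- 1 + 1e-7
  groups <- dt[, .(xs = list(x), idxs = list(idx)), by = .(m, nn, k)]
  for (gi in seq_len(nrow(groups))) {
    gm <- groups$m[gi]; gn <- groups$nn[gi]; gk <- groups$k[gi]
    lo <- max(0, gk - gn); hi <- min(gk, gm)
    d <- dhyper(lo:hi, gm, gn, gk)
    o <- order(d)
    cs <- cumsum(d[o])
    xs <- groups$xs[[gi]]
    dx <- d[xs - lo + 1L]
    pos <- findInterval(dx * relErr, d[o])
    p[groups$idxs[[gi]]] <- pmin(1, cs[pos])
  }
  p
}
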