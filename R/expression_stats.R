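## Expression summaries for endosymbiont transcripts: logCPM, expression
## tiers, the Ex90 statistic, mapping-fraction bookkeeping, and the
## tier-versus-quadrant overlay.

#' Construct an expression table
#'
#' @param counts Non-negative integer matrix, genes x samples, with
#'   dimnames.
#' @param lib_sizes Optional per-sample library sizes; default column
#'   sums.
#' @return Object of class `ExpressionTable`: list with `genes`,
#'   `samples`, `counts`, `lib_sizes`.
#' @export
ExpressionTable <- function(counts, lib_sizes = NULL) {
  stopifnot(is.matrix(counts), all(counts >= 0))
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  stopifnot(length(lib_sizes) == ncol(counts))
  structure(list(genes = rownames(counts), samples = colnames(counts),
                 counts = counts, lib_sizes = lib_sizes),
            class = "ExpressionTable")
}

#' Read a genes-x-samples count TSV into an ExpressionTable
#' @param path TSV with a header row; first column gene ids.
#' @return An `ExpressionTable`.
#' @export
read_counts_tsv <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                         check.names = FALSE)
  ExpressionTable(as.matrix(d))
}

#' log2 counts per million
#'
#' `log2((count + prior) / (lib_size + 2 * prior) * 1e6)`. The default
#' prior of 0.5 damps the log of zero counts, mirroring common practice
#' in count-based expression analysis; prior 0 gives plain log2-CPM.
#'
#' @param t An `ExpressionTable` (or bare counts matrix).
#' @param prior Pseudo-count (default 0.5).
#' @return Numeric matrix of logCPM values.
#' @export
log_cpm <- function(t, prior = 0.5) {
  if (is.matrix(t)) t <- ExpressionTable(t)
  if (any(t$lib_sizes <= 0)) stop("zero library size")
  sweep_den <- matrix(rep(t$lib_sizes + 2 * prior, each = nrow(t$counts)),
                      nrow = nrow(t$counts))
  log2((t$counts + prior) / sweep_den * 1e6)
}

#' Classify logCPM values into expression tiers
#'
#' Low below `lo`, high above `hi`, otherwise mid; values exactly on a
#' boundary are mid.
#'
#' @param logcpm Numeric vector or matrix.
#' @param lo,hi Tier boundaries (defaults 9 and 11).
#' @return Character vector/matrix of `"low"`, `"mid"`, `"high"`.
#' @export
tier_classify <- function(logcpm, lo = 9, hi = 11) {
  out <- ifelse(logcpm < lo, "low", ifelse(logcpm > hi, "high", "mid"))
  if (is.matrix(logcpm)) dim(out) <- dim(logcpm)
  out
}

#' Ex90: transcripts needed to reach 90% of total expression
#'
#' The smallest number k such that the k most expressed genes account for
#' at least `fraction` of the total.
#'
#' @param expr Non-negative expression vector with positive sum.
#' @param fraction Target fraction (default 0.9).
#' @return Integer count.
#' @export
ex90 <- function(expr, fraction = 0.9) {
  if (!length(expr) || any(expr < 0)) stop("expression must be non-negative")
  tot <- sum(expr)
  if (tot <= 0) stop("all-zero expression vector")
  cs <- cumsum(sort(expr, decreasing = TRUE))
  which(cs >= fraction * tot)[1]
}

#' Percentage of reads mapping to the endosymbiont
#' @param mapped,total Read counts, `0 <= mapped <= total`, `total > 0`.
#' @return Percentage.
#' @export
mapping_fraction <- function(mapped, total) {
  if (any(total <= 0)) stop("total read count must be positive")
  if (any(mapped < 0 | mapped > total)) stop("need 0 <= mapped <= total")
  100 * mapped / total
}

#' Expression tier versus conservation quadrant overlay
#'
#' Cross-tabulates genes by expression tier and quadrant and tests
#' independence with a chi-squared test on the 3x4 table ((3-1)(4-1) = 6
#' degrees of freedom when all levels occur); the usual expected-count
#' warning is propagated when cells are sparse.
#'
#' @param tiers Named character vector gene -> tier.
#' @param quadrants Named character vector gene -> quadrant.
#' @return List with `table` (tiers x quadrants contingency table over
#'   the common genes) and `test` (the `htest`).
#' @export
tier_quadrant_overlay <- function(tiers, quadrants) {
  genes <- intersect(names(tiers), names(quadrants))
  if (!length(genes)) stop("no genes present in both maps")
  tab <- table(factor(tiers[genes], levels = c("low", "mid", "high")),
               factor(quadrants[genes], levels = c("Q1", "Q2", "Q3", "Q4")))
  test <- if (length(genes) > 1L && sum(tab > 0) > 1L)
    tryCatch(stats::chisq.test(tab[rowSums(tab) > 0, colSums(tab) > 0,
                                   drop = FALSE]),
             error = function(e) NULL)
  else NULL
  list(table = tab, test = test)
}
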