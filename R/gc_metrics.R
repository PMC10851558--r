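## Composition statistics: %GC at genome, window and gene level, intergenic
## distances, and the homopolymer-run gene census.

#' Percent G+C of nucleotide sequences
#'
#' `N` bases are excluded from both numerator and denominator.
#'
#' @param seq Character vector of nucleotide sequences.
#' @return Numeric vector of percentages in `[0, 100]`.
#' @export
gc_percent <- function(seq) {
  if (!length(seq)) return(numeric(0))
  x <- Biostrings::DNAStringSet(toupper(seq))
  f <- Biostrings::letterFrequency(x, letters = c("A", "C", "G", "T"))
  tot <- rowSums(f)
  if (any(tot == 0))
    stop("sequence empty or all-N; cannot compute %GC")
  unname(100 * (f[, "G"] + f[, "C"]) / tot)
}

#' Percent A+T of nucleotide sequences
#' @param seq Character vector of nucleotide sequences.
#' @return `100 - gc_percent(seq)` for N-free sequences.
#' @export
at_percent <- function(seq) 100 - gc_percent(seq)

#' Sliding-window %GC profile of a genome
#'
#' Only full windows are emitted. On a circular genome with `wrap = TRUE`
#' additional windows wrapping the origin are appended so that every start
#' position `0, step, 2*step, ...` below the genome length is covered.
#'
#' @param g A `GenomeRecord`.
#' @param window Window size in bp.
#' @param step Step size in bp; `0 < step <= window`.
#' @param wrap Emit origin-wrapping windows for circular genomes?
#' @return An object of class `GcProfile`: list with `window`, `step`,
#'   `positions` (0-based window starts) and `values` (%GC).
#' @export
sliding_window_gc <- function(g, window = 1000L, step = 200L, wrap = FALSE) {
  L <- nchar(g$sequence)
  if (window > L) stop("window (", window, ") exceeds genome length (", L, ")")
  if (step <= 0 || step > window) stop("need 0 < step <= window")
  last <- if (wrap && g$circular) L - 1L else L - window
  positions <- seq(0L, last, by = step)
  seq2 <- if (wrap && g$circular)
    paste0(g$sequence, substr(g$sequence, 1L, window)) else g$sequence
  chunks <- substring(seq2, positions + 1L, positions + window)
  structure(list(window = as.integer(window), step = as.integer(step),
                 positions = as.integer(positions),
                 values = gc_percent(chunks)),
            class = "GcProfile")
}

#' Write a GcProfile as a two-column TSV
#' @param profile A `GcProfile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gc_profile <- function(profile, path) {
  utils::write.table(
    data.frame(start = profile$positions, value = profile$values),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Protein-coding gene %GC statistics across genomes
#'
#' Pools the non-pseudo CDS of all genomes into one per-gene table and
#' summarizes %GC: pooled mean/SD (unweighted over genes, so gene-rich
#' genomes contribute more), per-genome mean/SD, and a histogram over 1%
#' bins. SD is the sample SD (n-1) by default.
#'
#' @param genomes List of `GenomeRecord`s.
#' @param include_pseudo Include pseudogenes? Default `FALSE`.
#' @param sd_type `"sample"` (n-1, default) or `"population"`.
#' @return List with `per_gene` (data.frame `genome_id, gene_id, length,
#'   gc`), `pooled` (mean, sd, n), `per_genome` (data.frame) and
#'   `histogram` (counts per 1% bin, named by bin lower edge).
#' @export
pcg_gc_stats <- function(genomes, include_pseudo = FALSE,
                         sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  per <- lapply(genomes, function(g) {
    gn <- g$genes
    keep <- gn$kind == "CDS" & (include_pseudo | !gn$pseudo)
    if (!any(keep)) stop("genome ", g$genome_id, " has no eligible CDS")
    ids <- gn$gene_id[keep]
    data.frame(genome_id = g$genome_id, gene_id = ids,
               length = (gn$end - gn$start)[keep],
               gc = gc_percent(gene_sequence(g, ids)))
  })
  per_gene <- do.call(rbind, per)
  rownames(per_gene) <- NULL
  sdfun <- function(x) {
    s <- stats::sd(x)
    if (sd_type == "population") s * sqrt((length(x) - 1) / length(x)) else s
  }
  per_genome <- do.call(rbind, lapply(split(per_gene, per_gene$genome_id),
    function(d) data.frame(genome_id = d$genome_id[1], n = nrow(d),
                           mean_gc = mean(d$gc), sd_gc = sdfun(d$gc))))
  rownames(per_genome) <- NULL
  bins <- table(factor(floor(per_gene$gc),
                       levels = 0:100))
  list(per_gene = per_gene,
       pooled = list(mean = mean(per_gene$gc), sd = sdfun(per_gene$gc),
                     n = nrow(per_gene)),
       per_genome = per_genome,
       histogram = bins)
}

#' Signed intergenic distances of a genome
#'
#' Gaps are `start[i+1] - end[i]` over genes sorted by start; overlapping
#' genes give negative gaps which are retained in the mean (clipping would
#' bias the average upward). On circular genomes the wrap-around gap from
#' the last gene back to the first is included when `wrap = TRUE`.
#'
#' @param g A `GenomeRecord` with at least two eligible genes.
#' @param include_rnas Include RNA genes (default `TRUE`) or restrict to
#'   protein-coding genes.
#' @param include_pseudo Include pseudogenes? Default `FALSE`.
#' @param wrap Include the origin wrap gap (circular genomes only)?
#' @return List with `gaps` (signed integer vector) and `mean`.
#' @export
intergenic_stats <- function(g, include_rnas = TRUE, include_pseudo = FALSE,
                             wrap = FALSE) {
  gn <- g$genes
  if (!include_pseudo) gn <- gn[!gn$pseudo, , drop = FALSE]
  if (!include_rnas) gn <- gn[gn$kind == "CDS", , drop = FALSE]
  if (nrow(gn) < 2L) stop("need at least two genes")
  gn <- gn[order(gn$start), , drop = FALSE]
  gaps <- gn$start[-1L] - gn$end[-nrow(gn)]
  if (wrap && g$circular) {
    L <- nchar(g$sequence)
    gaps <- c(gaps, gn$start[1L] + L - gn$end[nrow(gn)])
  }
  list(gaps = as.integer(gaps), mean = mean(gaps))
}

#' Census of genes containing long homopolymer runs
#'
#' A gene is counted once if its annotated span on the forward strand of
#' the record contains a run of any single base in `bases` of length at
#' least `min_run`. For the base set `{A, T}` the census is strand
#' symmetric, which is the natural set for polyA/polyT carry-through in
#' poly-dT-primed libraries.
#'
#' @param g A `GenomeRecord`.
#' @param bases Subset of `c("A","C","G","T")`; default `c("A","T")`.
#' @param min_run Minimum run length (>= 2); default 10.
#' @param kinds Restrict to these gene kinds; `NULL` (default) for all.
#' @param include_pseudo Include pseudogenes? Default `FALSE`.
#' @return List with `count` and `gene_ids`.
#' @export
homopolymer_gene_census <- function(g, bases = c("A", "T"), min_run = 10L,
                                    kinds = NULL, include_pseudo = FALSE) {
  stopifnot(min_run >= 2L, all(bases %in% c("A", "C", "G", "T")))
  gn <- g$genes
  if (!include_pseudo) gn <- gn[!gn$pseudo, , drop = FALSE]
  if (!is.null(kinds)) gn <- gn[gn$kind %in% kinds, , drop = FALSE]
  if (!nrow(gn)) return(list(count = 0L, gene_ids = character(0)))
  L <- nchar(g$sequence)
  fwd <- vapply(seq_len(nrow(gn)), function(i) {
    s <- gn$start[i]; e <- gn$end[i]
    if (e <= L) substr(g$sequence, s + 1L, e)
    else paste0(substr(g$sequence, s + 1L, L), substr(g$sequence, 1L, e - L))
  }, character(1))
  pat <- paste(sprintf("%s{%d}", bases, min_run), collapse = "|")
  hit <- grepl(pat, fwd)
  list(count = sum(hit), gene_ids = gn$gene_id[hit])
}
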