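## Cluster genomes by shared gene content from the binary presence/absence
## matrix of the gene array, and emit a dendrogram (gene-content tree).

#' Spearman rank-correlation distance between genome columns
#'
#' `d = 1 - rho` between the binary presence columns; 0 for identical
#' gene content, 2 for perfectly complementary content.
#'
#' @param matrix Binary matrix (rows = gene-array rows, columns =
#'   genomes), e.g. from [presence_matrix()].
#' @return Symmetric numeric distance matrix with zero diagonal.
#' @export
spearman_distance <- function(matrix) {
  if (ncol(matrix) < 2L) stop("need at least two genomes")
  empty <- colSums(matrix != 0) == 0
  if (any(empty))
    stop("genome column with no genes: ",
         paste(colnames(matrix)[empty], collapse = ", "))
  novar <- apply(matrix, 2, function(x) stats::sd(x) == 0)
  if (any(novar))
    stop("zero-variance presence column (all genes present or absent): ",
         paste(colnames(matrix)[novar], collapse = ", "))
  d <- 1 - stats::cor(matrix, method = "spearman")
  diag(d) <- 0
  d
}

#' Hierarchical clustering of genomes into a dendrogram
#'
#' Agglomerative clustering of a genome distance matrix. Default linkage
#' is average (UPGMA-style); complete and single linkage are available.
#' The merge history comes from [stats::hclust()]; the tree is also
#' serialized to Newick.
#'
#' @param d Symmetric distance matrix (or `dist`).
#' @param linkage One of `"average"`, `"complete"`, `"single"`.
#' @return Object of class `Dendrogram`: list with `merge`, `height`,
#'   `labels`, `newick` and the underlying `hclust`.
#' @export
hierarchical_cluster <- function(d, linkage = c("average", "complete",
                                                "single")) {
  linkage <- match.arg(linkage)
  dm <- as.matrix(d)
  if (any(!is.finite(dm))) stop("non-finite values in distance matrix")
  hc <- stats::hclust(stats::as.dist(dm), method = linkage)
  newick <- ape::write.tree(ape::as.phylo(hc))
  structure(list(merge = hc$merge, height = hc$height, labels = hc$labels,
                 newick = newick, hclust = hc),
            class = "Dendrogram")
}

#' @export
print.Dendrogram <- function(x, ...) {
  cat("Dendrogram over", length(x$labels), "genomes:\n", x$newick, "\n")
  invisible(x)
}

#' Write a dendrogram as a Newick file
#' @param dendro A `Dendrogram`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(dendro, path) {
  writeLines(dendro$newick, path)
  invisible(path)
}
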